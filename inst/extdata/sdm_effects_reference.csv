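variable,direct,indirect,total
lnpgdp,-0.7022,1.1840,0.4818
lnfiscal,-0.2856,-0.4215,-0.7072
lnurban,-0.1785,-0.2546,-0.4331
lnedu,-0.0289,-0.0923,-0.1212
lndepend,0.2505,0.3039,0.5544
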