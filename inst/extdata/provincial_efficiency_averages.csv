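unit,overall,stage1,stage2
Beijing,0.3210,0.5617,0.5686
Tianjin,0.5076,0.5672,0.8930
Hebei,0.7510,0.7815,0.9585
Shanxi,0.5693,0.8644,0.6610
Inner Mongolia,0.4041,0.6399,0.6327
Liaoning,0.6924,0.9590,0.7175
Jilin,0.5808,0.7216,0.7942
Heilongjiang,0.6738,0.8418,0.7953
Shanghai,0.5255,0.5255,1.0000
Jiangsu,0.7844,0.7844,1.0000
Zhejiang,0.6756,0.8204,0.8230
Anhui,0.6218,0.6234,0.9977
Fujian,0.5919,0.6755,0.8758
Jiangxi,0.6196,0.6196,1.0000
Shandong,0.9546,0.9803,0.9738
Henan,0.7939,0.7963,0.9968
Hubei,0.6724,0.7711,0.8710
Hunan,0.7170,0.8483,0.8453
Guangdong,0.7168,0.7168,1.0000
Guangxi,0.6162,0.6805,0.9059
Hainan,0.4132,0.5136,0.8063
Chongqing,0.5482,0.6448,0.8503
Sichuan,0.6869,0.7527,0.9156
Guizhou,0.4957,0.5894,0.8449
Yunnan,0.5450,0.5854,0.9347
Tibet,0.1902,0.2571,0.7463
Shaanxi,0.5327,0.7826,0.6814
Gansu,0.5192,0.6101,0.8524
Qinghai,0.2638,0.3972,0.6643
Ningxia,0.4305,0.5727,0.7532
Xinjiang,0.4882,0.7179,0.6838
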