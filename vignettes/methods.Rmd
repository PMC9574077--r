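---
title: "Methods: relational two-stage network DEA and spatial spillover analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relational two-stage network DEA and spatial spillover analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models, the choices made
where the design was genuinely open, and what the test suite does and does
not establish. It states no empirical result that the tests or
`scripts/acceptance.R` do not themselves compute.

## The production model

A regional health system is modelled as a series (two-stage) technology
under constant returns to scale. Stage 1 (*resource allocation*) converts
the single initial input — per-capita health expenditure `I1` — into three
intermediate outputs: institutions (`M1`), technicians (`M2`) and beds
(`M3`), all per thousand population. Stage 2 (*service operation*)
converts those intermediates into five final outputs: diagnosis/treatment
volume (`F1`), bed-utilization rate (`F2`), and three negative-direction
outcomes — infectious-disease incidence (`F3`), maternal mortality (`F4`)
and perinatal mortality (`F5`) — that enter as reciprocals
(`positivize_indicators()`). A zero rate would make the reciprocal
undefined; it is rejected rather than patched, and applying the transform
twice is an error rather than a silent round trip.

Efficiency is measured with the multiplier ("ratio") form. The
*relational* feature is that one multiplier set `(u, v, w)` prices the
final outputs, inputs and intermediates for both stages simultaneously;
with the evaluated unit's weighted input normalized to 1 and three
families of ratio constraints (overall, stage 1, stage 2, each at most 1
for every unit), the overall score factorizes exactly into the product of
the two stage scores. Because the optimal multipliers need not be unique,
the decomposition is pinned down by a second linear program that maximizes
the stage-1 score while the overall score is held fixed; the symmetric
stage-2-first order is also available, `run_dea_year()` computes both, and
units where the two orders disagree by more than `1e-6` are flagged
`nonunique`. Frontiers are cross-sectional: each year is scored against
that year's units only, and study-period results are averages of yearly
scores.

### Numerical choices

* **LP backend.** All programs are small dense LPs (for the 31-unit panel:
  9 multiplier variables, ~95 constraints). They are solved by an internal
  two-phase primal simplex with a `1e-9` pivot tolerance and a Bland's-rule
  fallback against degenerate cycling (DEA multiplier programs are
  routinely degenerate). The backend is validated in the test suite
  against brute-force maximization of the ratio form: a grid-plus-polish
  oracle for single-technology scores and a 100-start nonlinear oracle for
  the relational program; agreement is ~`1e-6`, far inside the `1e-3`
  contract.
* **Non-Archimedean bound.** Every multiplier is bounded below by
  `epsilon` (default `1e-6`). Column magnitudes of real indicator panels
  span eight orders of magnitude, so a fixed bound in raw units would be
  arbitrary; the package therefore normalizes each column of X, Z, Y to
  unit mean internally and applies `epsilon` on that scale. CRS efficiency
  is invariant to per-column rescaling, so this changes nothing at
  `epsilon = 0` and makes results exactly units-invariant (a tested
  property) at `epsilon > 0`. Scores can shift by a small multiple of
  `epsilon` when the bound binds; at the full 31 × 12 scale the planted
  stage-1 truths are recovered to about `5e-6` with the default and the
  error scales linearly in `epsilon`. A diagnostic warns when any score
  lies within `10 · epsilon · (m + q + s)` of a bound.
* **Decomposition slack.** The second LP pins the overall score with an
  equality constraint relaxed by `1e-9`, so floating-point noise from the
  first solve cannot make the second infeasible; a genuine infeasibility
  is reported, never repaired silently.
* **Clamping.** Scores are clamped at 1 from above only within LP
  tolerance (~`1e-12` overshoots); the product identity
  `|E − E1·E2| ≤ 1e-6` is asserted for every unit.

## Spatial autocorrelation

`morans_i()` implements the classic cross-product statistic with the
biased (`/n`) variance in the denominator, for any nonnegative zero-diagonal
weight matrix. The packaged contiguity fixture links the 31 provinces by
first-order land adjacency; Hainan, an island, is linked to its nearest
mainland neighbour (Guangdong) because an unlinked island leaves a zero
row and makes row standardization undefined. The default weight matrix is
row-standardized binary contiguity — the convention of the desktop spatial
software this literature uses.

Default inference is a 999-shuffle permutation test (one-sided, positive
autocorrelation, rank-based p-value that can never be exactly zero),
seed-controlled; the closed-form randomization-moment normal approximation
is also provided and its type-I error is verified by simulation to sit at
the nominal 5% level.

## The spatial Durbin panel model

The drivers of efficiency are analysed with
`Y = α + ρWY + Xβ + WXη + μ + v + ε` on the balanced panel, with the
overall efficiency untransformed as the dependent variable and the five
covariates (per-capita GDP, fiscal decentralization, urbanization,
illiteracy rate, old-age dependency) entering in logs — hence the strict
positivity requirement on the covariate panel.

Estimation: two-way demeaning absorbs `μ`, `v` and `α`; the concentrated
log-likelihood over `ρ` uses the log-Jacobian `T·log|I − ρW|` evaluated
through the (generally complex) eigenvalues of W, with the coefficients
and error variance profiled out by least squares at each `ρ`. The search
runs on `(−0.999, 0.999)` — valid for row-standardized W — with Brent's
method (golden-section plus parabolic acceleration), and an estimate at
the boundary triggers a warning rather than silent clamping. The reported
error variance applies the lost-degrees-of-freedom correction for the
demeaning (`(n−1)(T−1)` effective observations under two-way effects;
switchable). The covariance matrix comes from the analytic information
matrix of (coefficients, ρ, σ²); the test suite checks it against a
numerical Hessian of the full log-likelihood.

Effects: for covariate *r*, `S_r = (I − ρW)^{-1}(Iβ_r + Wη_r)`; the direct
effect is the mean diagonal, the total effect the mean row sum, the
indirect effect their difference, so additivity is exact by construction.
Dispersion comes from 1000 seed-controlled draws of (β, η, ρ) from the
asymptotic normal, the simulation approach standard in the
spillover-decomposition literature; z-values are mean/sd of the simulated
distributions.

Specification battery: the four LM statistics are computed on the
residuals of the non-spatial two-way within regression with the standard
panel scaling (`T·tr(W'W + WW)`); LR tests compare the SDM with the
spatial lag model (`η = 0`) and the spatial error model (the common-factor
restriction `η + ρβ = 0`), each with k degrees of freedom, and the Wald
counterparts use the SDM covariance (delta method for the common-factor
restriction). The Hausman row is the *classical* panel test — within
versus Swamy–Arora GLS with spatial terms omitted — because the published
table does not say whether a spatial variant was used; the RE covariance
uses the common within variance estimate, which keeps `V_FE − V_RE`
positive semidefinite, and a generalized inverse with a warning handles
any residual indefiniteness.

## What the synthetic generators emulate

`generate_dea_panel()` plants every unit of a year on a common supporting
hyperplane of the two-stage technology: frontier units are random rays
normalized against shared supporting multipliers, inefficient units are
convex combinations of frontier units with the initial input inflated by
`f1 ≥ 1` and final outputs deflated by `f2 ≥ 1`. With a single initial
input this makes the true stage-1 efficiency exactly `1/f1` and the
stage-2 efficiency `1/f2` (recorded as such, with the exactness flag
dropped as soon as measurement noise is switched on). Indicator columns
are rescaled to the magnitudes of real provincial health statistics
(expenditure ~900 currency units per capita, ~0.75 institutions and ~5–6
technicians/beds per thousand, incidence ~0.005, perinatal mortality ~2),
and the negative-direction indicators are emitted as reciprocals so the
standard pipeline entry point restores the generated outputs. When a
weight matrix is supplied, a spatially autoregressive score (coefficient
0.5 by default) orders units so that efficient units cluster — producing
the positive Moran's I that the end-to-end tests detect. Defaults — 31
units, 12 years, 5 frontier units, inefficiency factors uniform on
[1, 3], no noise — define the canonical study design (372 records).

`generate_sdm_panel()` draws covariates i.i.d. log-normal (so the logged
regressors are well-conditioned normals) at provincial magnitudes, and
builds Y period by period from the SDM process with drawn unit and time
effects. Defaults: ρ = 0.4 for recovery exercises, coefficient magnitudes
matching the fitted provincial model, error sd 0.1 (error variance ~0.01),
unit/time effect sds 0.1/0.05 — moderate relative to the signal, chosen
once as plausible for efficiency panels. An optional persistent unit-level
covariate component (`cov_unit_sdlog`, default 0) emulates the fact that
real provincial covariates differ persistently across units; it is what
gives the Hausman test its power scenario, since with purely i.i.d.
covariates the RE and FE estimators coincide almost exactly.

All randomness flows from one master seed through named substreams (one
per generated object), so identical seeds give byte-identical panels and
adding a new draw does not shift existing ones.

**What passing tests do not show:** the generators produce no measurement
error by default, no missing data, no serial correlation in the SDM
errors, no slack-based (non-radial) inefficiency, and only
contiguity-based spatial structure. Recovery results on these panels
demonstrate the correctness of the estimators under their own assumptions,
not robustness to the violations real yearbook data would bring.

## Orchestration choices

* Five-class natural-breaks classification uses the exact Fisher dynamic
  program (optimal contiguous partition by within-class squared
  deviation), verified against exhaustive enumeration up to the study size
  of 31. Breaks are computed per year by default (first and last study
  year), since pooled-versus-yearly breaks is an open presentational
  choice.
* Regional aggregation is the unweighted mean over the fixed 11/8/12
  eastern/central/western partition, with a national row; the
  weighted-average identity between regional and national means is tested.
* `run_pipeline()` writes every table as CSV plus a JSON-lines run log
  recording ε, decomposition priority, weight standardization, permutation
  and draw counts, and the seed; reruns with the same config are
  byte-identical (tested).

## Problem sizes used by the test suite

Simulation-backed checks run at sizes chosen to make Monte-Carlo error
small while keeping the default suite around a minute: 200 replicates at
n = 49, T = 12 for ρ recovery and confidence-interval coverage, 500
replicates for test size (LM-lag and the Moran normal approximation), 100
replicates for LR/Wald power, 60 for Hausman power, 50 random small
instances (n ≤ 6, dimensions ≤ 2) for LP-versus-oracle equivalence, and
the spec'd 10-unit construction-versus-LP truth recovery. The acceptance
script runs the full 31 × 12 study once.

## Known limitations

* Constant returns to scale only; no variable-returns, slack-based,
  super-efficiency, bootstrap or Malmquist variants.
* The published provincial tables shipped as reference data are inputs
  for arithmetic-consistency checks; the underlying yearbook panel is not
  deposited, so those tables cannot be — and are not — recomputed from raw
  data here.
* Published efficiency values depend on an unstated ε, solver and
  decomposition order; third-decimal agreement with them is therefore not
  an implementable contract even with the raw data in hand.
* The Hausman statistic is the classical, not spatial, variant; whether a
  σ² bias correction was applied in the published fixed-effects estimation
  is unstated, so both paths are switchable (`sigma2_correct`).
* Global Moran's I only; no local indicators (LISA) and no Geary's C.
* No map rendering: classified tables stand in for choropleths.
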