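---
title: "Methods: the renormalized msBMR and its downstream models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the renormalized msBMR and its downstream models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmsbmr)
```

## The problem

Basal metabolic rate per unit mass (msBMR, kcal·day⁻¹·kg⁻¹) declines
with age, but any cross-sectional cohort shows wide scatter around
that decline because body composition varies. The idea implemented
here is that the scatter is almost entirely a body-weight artefact:
once weight is standardized away in two steps, every male subject
falls on a single exponential decline `F(T) = F0·exp(-u·T)`, and that
one-parameter decline is enough to reproduce old-age mortality rates,
survival curves, the centenarian mortality plateau, organ-weight
patterns, and — rescaled — the mammalian allometric law.

## Renormalization

The Harris–Benedict msBMR for men,
`(88.362 + 13.397 W + 4.799 H − 5.677 T)/W`, is strictly decreasing
in `W` with asymptote 13.397 as `W → ∞`.

**Step 1** (`first_renorm()`) replaces the recorded weight by
`(H/100)² × 21.5`. The reference BMI of 21.5 kg/m² is the value on
which the cohort BMI dispersion converges in extreme old age and sits
mid-range of healthy BMI; it is a tunable argument. The recorded
weight is deliberately ignored — this is what makes the first step a
renormalization rather than a regression adjustment.

**Step 2** (`second_renorm()`) solves `msBMR(W, H, T) = F(T)` for
`W`. Because msBMR is linear in `1/W` the solution is closed-form:

```
W = (88.362 + 4.799 H − 5.677 T) / (F(T) − 13.397)
```

We use the closed form rather than a numeric root-finder for
exactness and speed; a `uniroot()` cross-check lives in the test
suite. The solution exists only while `F(T) > 13.397`; with the
default law that covers every age up to well past 120, and
`renormalize_cohort()` collects infeasible rows (possible under
user-supplied steeper laws) instead of aborting.

Two precision conventions are exposed: `bmi` from the full-precision
weight, and `bmi_printed` from the weight rounded to 0.1 kg, matching
how such results are typically quoted. Note one boundary case: the
closed form gives 59.8492 kg for the short worked subject
(160.9 cm, age 50), which sits essentially on the 0.1-kg rounding
boundary, so quoted values for this subject can differ by one unit in
the last digit depending on intermediate rounding.

**Fitting `F(T)`** (`fit_decay_law()`) is unweighted ordinary least
squares of `log(msBMR)` on age — exact on noiseless exponential data.
The default law `(F0, u) = (27.63, 0.00364)` is a constructor default,
not a constant baked into the computations, so refits never overwrite
it.

## Mortality and survival

`mortality_rate()` implements
`P(T) = plogis(C · {F(T_c) − F(T)})`: a Gompertz-like exponential
increase at old ages that saturates in centenarians. `P(T)` is read
as an **annual death probability** and the survival transform as the
yearly product `S(T+1) = S(T)(1 − P(T))` on integer ages; a
continuous-hazard reading would change the late-life arithmetic and
push `S` out of the simple product form. The anchor age defaults to
80 because the model targets mortality of the elderly; it is an
argument.

The **plateau** clamps `F`, not `P` (the metabolic rate has a floor
below which life cannot be sustained; the mortality plateau is its
shadow) — numerically the two are equivalent for `P`. With US
parameters `P(108) = 0.678`; a commonly quoted rounded plateau value
is 0.67, within 2 % of the computed value. Survival with the plateau
dominates survival without it at every age, yet
`S(120)/S(80) < 10⁻⁴`: the plateau prolongs life but not past ~120.

**Fitting** (`fit_mortality()`): since
`logit P(T) = C·F(T_c) − C·F(T)` is an exact linear reparametrization
of intercept and slope, OLS of `logit(rate)` on `F(T)` *is* the joint
least-squares solution over `(C, T_c)`; `T_c` follows by inverting
the decay law at the fitted `F(T_c)`. No grid search is needed, and
the estimate is deterministic given the data. Because it is unclear
in general whether `T_c` should be estimated or pinned at the
observed age where the rate crosses 0.5, both modes are provided
(`T_c = NULL` fits it; a supplied value fixes it). Plateau ages are
excluded from fitting via the default window 80–104.

## Synthetic data: what it emulates and what it does not

`generate_cohort()` emulates the structure the analysis needs from an
anthropometric survey of men aged 16–80: five population groups with
different height distributions, and a per-age BMI distribution whose
mean declines linearly from 26.1 (age 16) to 21.5 (age 105) and whose
SD shrinks linearly from 5.0 to 0 over the same span — so the
dispersion converges, by construction, exactly where the BMI
reference of the first renormalization sits. Ages are integers,
uniform over the range, because the analysis bins by integer age.
Group height means default to {178, 177, 170, 168, 165} cm with a
common 7-cm SD and equal mixing proportions. These values are
placeholders — no per-group distributions are published — and only
the tall/short ordering matters for demonstrating the second
renormalization's height effect. BMI draws are truncated below at
10 kg/m² to keep weights physical; at the default curves the
truncation touches well under 0.1 % of draws, and only at the
youngest ages where the BMI SD is widest.

Features of real survey data the generator does **not** emulate:
sampling weights and survey design; correlation between height and
BMI; secular (birth-cohort) trends; and any shrinking of *height*
dispersion with age. The last one matters: because heights stay
dispersed at all ages, the raw msBMR dispersion retains a small
height-driven floor (~0.3 kcal·day⁻¹·kg⁻¹), so the msBMR SD bands of
a synthetic cohort need not extrapolate to an exact zero crossing
the way the BMI bands do. Passing tests therefore demonstrate that
the pipeline recovers what the generator put in — not that real
cohorts behave this way.

`generate_mortality_series()` draws observed rates as
`Binomial(n_at_risk, P(T))/n_at_risk` per age, or returns `P(T)`
exactly with `n_at_risk = Inf`. The binomial model gives the standard
error `sqrt(P(1−P)/n)` that the recovery tests check against.

**Randomness contract**: every generator takes an explicit seed and
is byte-reproducible given it. The pipeline derives per-stage seeds
from its root seed (cohort: `seed`; mortality series: `seed + 1`).

## Binned statistics and the convergence extrapolation

`bin_stats()` uses the sample SD (n−1); bins with fewer than 10
subjects report no SD (both choices are conventions, exposed as
arguments). `quadratic_summary()` fits `a·T² + b·T + c` to a chosen
series over 45–80, and `convergence_age()` intersects the
extrapolated `mean+SD` and `mean−SD` bands analytically from the
quadratic gap polynomial, reporting the smallest root beyond the
window (a double root is reported as is; parallel bands are reported
as non-convergent rather than an error). Quadratic extrapolation 25
years past the data is intrinsically noisy: at n = 20,000 the BMI
convergence age scatters over roughly 100–145 across seeds even
though the generator's truth is exactly 105. The tests therefore pin
the exact intersection on noiseless band inputs and use wide, honest
bands for sampled cohorts.

## Organ model

The reference male carries seven organ categories (skeletal muscle,
liver, brain, heart, kidneys, adipose tissue, residual) with fixed
mass-specific rates; his renormalized organ weights total 67.0 kg at
height 175.6 cm and age 32. Two facts about the published table do
not cohere with the stated procedure, and the package handles both
explicitly rather than papering over them:

* the weight-averaged organ msBMR of the tabulated renormalized
  weights is 22.16, not the whole-body 24.59 = F(32); and
* the tabulated per-organ redistribution of a 3-kg reduction differs
  from pure `msBMR^−q` shares.

`calibrate_reference()` therefore has a **fixture mode** (default)
returning the published reference male — the basis of all
decomposition arithmetic — and a **search mode** that runs the stated
fixed-point procedure honestly (closed-form residual, bisection
polish, tolerance 0.01 kcal·day⁻¹·kg⁻¹ on |organ mean − F(T)|); the
search settles near age 60 with the tabulated rates. When no sign
change exists in [16, 106] the error object carries the whole
residual curve for diagnosis.

`decompose_subject()` scales the reference organ weights by
`W(i)/W(r)` — the condition that keeps organ fractions, and hence
the weighted organ msBMR, identical across subjects so that age alone
drives the decline. The surplus of a recorded weight over the
renormalized one is pushed back onto the organs with
`distribute_delta()` (q = 1.15). The published original-weight
columns for the worked subjects are not reproducible from any pure
`msBMR^−q` rule and are treated as illustrations, not oracles.

Organ-level decay constants (`organ_decay_constants()`) are
0.00181 (muscle), 0.00624 (liver), 0.00239 (brain), 0.00326 (heart),
0.00532 (kidneys), with adipose and residual set to the global mean
0.00364 for lack of turnover data. Their BMR-weighted mean
(`mean_decay_constant()`) reproduces the global `u` within 1 % — the
first-order consistency that justifies using one `u` for the whole
body.

## Allometric sweep

`sweep_body_mass()` carries the reference composition from 1 to
800 kg in 0.5-kg steps, each step split ∝ `msBMR_k(r)^−q_k` with
`q = 1.05` generally and 1.4 for the brain, rates held at their
reference values throughout. Design choices where the procedure is
underdetermined:

* **One joint normalization per step** with organ-specific exponents
  (`share_k ∝ msBMR_k^−q_k`), so each step conserves mass in a single
  pass.
* **Brain start-down-scaling**: the initial brain weight is divided
  by 8 (the human brain being disproportionately large for a generic
  mammal) and the freed mass simply lowers the starting total (to
  ~65.8 kg) rather than being reassigned to other organs.
* **Zero floor**: on the downward branch the low-rate organs run out
  — adipose tissue near ~32 kg, residual near ~15 kg — and are
  floored at zero, the remaining reduction falling on the surviving
  organs with shares renormalized. This floor is an active part of
  the default sweep, and is what steepens the BMR–mass relation at
  small masses.

The resulting log–log slope of BMR against mass over the full range
is ~0.79, inside the 0.70–0.80 band consistent with the empirical
¾-power law; per-decade slopes vary (shallower mid-range, steeper at
the top), so the exponent is reported over an explicit mass window.
No fitted exponent is published for this construction, so tests
check the band, not a point value.

## Mitochondrial fusion/fission dynamics

The two-state linear system (fission count `N1`, fusion count `N2`,
biogenesis `P11`, mitophagy `P13`, exchange `P12`, `P21`; all
per-year) reduces to `N2'' + B N2' + C N2 = 0` with
`B = P12 + P21 + P13 − P11`, `C = P21(P13 − P11)`. The slow root
`u = (B − sqrt(B² − 4C))/2` is reported positive for net decay
(`P13 > P11`). Two analytic facts the implementation leans on:

* the discriminant satisfies
  `B² − 4C = (P13 − P11 + P12 − P21)² + 4·P12·P21 ≥ 0` for all
  non-negative rates, so the roots are always real (the complex
  branch is guarded against but unreachable in the valid domain);
* on the slow eigenmode `N1 = (P21 − u)·N2 / P12` — the eigenvector
  relation obtained directly from the `N2` equation — which fixes the
  fission-state amplitude in `mito_analytic()`. The total
  `N1 + N2` is then a single exponential, i.e. a Markov decay.

`mito_numeric()` (deSolve, `lsoda`, tolerances 1e−12) is the
independent oracle; analytic and numeric totals agree to better than
1e−6 relative over 100 seeded random parameter sets drawn in the
exchange-dominated regime. A warning (ratio < 10) flags parameter
sets where the `u ≈ P21(P13−P11)/(P12+P21)` approximation degrades.
The turnover identity `N1·P11·TOT = N1 + N2` gives
`u = (P13 − P11)/(P11·TOT)`: a 2 % biogenesis/mitophagy imbalance
over a 5.49-year turnover reproduces the global 0.00364/year, i.e. a
0.36 % yearly loss, and 1,000 → 685 mitochondria over the 104 years
from age 16 to 120. Only the deterministic mean is modelled; a
stochastic (Gillespie) treatment would be a natural extension but the
claims here concern the mean decay only.

The mouse rescaling multiplies an organ's human decay constant by the
human/mouse lifespan ratio 30 (liver: 30 × 0.00624 = 0.1872/year)
anchored at adulthood (0.5 y), with a Gaussian development curve
`58·exp(−0.8(T−0.5)²)` rising to the same adult value, so the two
pieces are continuous at 0.5 y.

## Problem sizes and runtime choices

The recovery studies use a 20,000-subject cohort (decay-law recovery,
~6 % relative error on `u`, dominated by the small curvature bias of
fitting a log-linear model to a nearly-linear decline, not by
sampling noise), a mortality series over ages 80–104 with
10,000 at risk per age (`C` to ~1 %, `T_c` to ~0.1 y), 200 replicates
for the binomial-noise calibration, and 100 random parameter sets for
the ODE-oracle comparison. These sizes make every stochastic check
stable across seeds while the full suite runs in seconds.

## Known limitations

* Male-only: the Harris–Benedict form and all published anchors used
  here are for men.
* The synthetic cohort is distribution-level plumbing; it cannot
  validate the renormalization against real anthropometry, only
  exercise it.
* The organ table's internal inconsistencies (above) mean the organ
  module's search mode and fixture mode answer different questions;
  both are exposed deliberately.
* The mortality model is cross-sectional (period rates); no
  cohort-vs-period life-table distinction, and no cause-of-death
  structure.
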