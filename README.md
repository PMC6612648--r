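# rmsbmr

Models of human aging and longevity built on the **renormalized
mass-specific basal metabolic rate (RmsBMR)**.

The mass-specific BMR (msBMR, kcal·day⁻¹·kg⁻¹) declines with age but
scatters widely between individuals because body weight does. This
package implements a two-step renormalization that removes that
scatter and collapses every (male) subject onto a single universal
decline, then builds the downstream machinery that decline supports:
a logistic mortality-rate model with a centenarian plateau, survival
curves, an organ-level decomposition against a reference male, an
allometric body-mass sweep reproducing the ¾-power scaling of BMR in
mammals, and a two-compartment fusion/fission model of mitochondrial
number decay. It is aimed at biostatisticians and aging researchers
who want the full pipeline — from anthropometric records to survival
curves — as tested, seedable code, with synthetic-data generators
standing in for survey and life-table inputs.

## The model

Starting from the Harris–Benedict equation for men,

    msBMR(W, H, T) = (88.362 + 13.397·W + 4.799·H − 5.677·T) / W,

with weight *W* (kg), height *H* (cm) and age *T* (years):

1. **First renormalization** — replace the recorded weight by the
   weight implied by a healthy reference BMI,
   `W = (H/100)² × 21.5`. This removes the weight-driven scatter.
2. **Fit the universal decline** — the per-age means of the
   first-renormalized msBMR follow
   `F(T) = F₀·e^(−uT)` with `F₀ = 27.63` and `u = 0.00364 /year`
   (a 0.36 % loss per year).
3. **Second renormalization** — readjust the weight so the msBMR
   equals `F(T)` exactly. Because the msBMR is linear in 1/W this has
   the closed form `W = (88.362 + 4.799·H − 5.677·T)/(F(T) − 13.397)`.

On top of `F(T)`:

* **Mortality**: `P(T) = logistic(C·{F(T_c) − F(T)})`, with `T_c` the
  age where `P = 0.5` (US: `C = 1.55`, `T_c = 101`). Freezing `F` at
  `F(108)` yields the observed mortality plateau in centenarians;
  survival follows by `S(T+1) = S(T)·(1 − P(T))`.
* **Organs**: each subject's renormalized organ weights are
  proportional to a reference male's (`w_k(i) = w_k(r)·W(i)/W(r)`);
  deviations of recorded from renormalized weight are distributed
  across organs ∝ `msBMR_k^−q` (q = 1.15), falling mostly on adipose
  tissue and the residual mass.
* **Allometry**: iterating that redistribution (q = 1.05; brain 1.4)
  from 1 to 800 kg reproduces `BMR ∝ W^(~3/4)`.
* **Mitochondria**: the linear fusion/fission system
  `N₂′ = −P₂₁N₂ + P₁₂N₁`, `N₁′ = −(P₁₂+P₁₃−P₁₁)N₁ + P₂₁N₂` has a slow
  eigenmode decaying at `u = (P₁₃−P₁₁)/(P₁₁·TOT)` — the mechanistic
  reading of the 0.36 %/year metabolic loss.

## Worked example

```r
library(rmsbmr)

law <- decay_law()          # F(T) = 27.63 * exp(-0.00364 T)
second_renorm(c(187.7, 160.9), 50)
#>   weight   bmi bmi_printed
#> 1  73.20 20.78       20.78
#> 2  59.85 23.12       23.10
```

The tall 50-year-old (187.7 cm) renormalizes to 73.2 kg — a BMI of
20.78, *below* the 21.5 reference, because tall bodies carry extra
low-rate skeletal muscle — while the short one (160.9 cm) moves the
other way. Both now sit exactly on `F(50) = 23.0`.

```r
m <- mortality_model()                      # US parameters
mortality_rate(c(90, 101, 108, 115), m)
#> 0.229 0.500 0.678 0.678                   # plateau from age 108
survival_curve(m, 80, 120)                  # S(120) ~ 5e-12: nobody
                                            # outlives 120 by much

run <- run_full_pipeline(seed = 1, n_subjects = 20000)
run
#> RmsBMR pipeline run (seed 1)
#>   fitted decline: F0 = 28.230, u = 0.00387 /year
#>   fitted mortality: C = 1.555, T_c = 100.94 years
#>   S(120 | alive at 80): 4.53e-12 with plateau, 2.51e-14 without
```

The end-to-end run generates a synthetic 20,000-man cohort, refits the
decline from it (`u` recovered within ~6 %), refits `(C, T_c)` from a
binomially noised mortality series, and decomposes the exemplar
subjects into organ weights:

```r
ref <- calibrate_reference()                # 67 kg reference male
decompose_subject(157.7, 80, ref, recorded_weight = 64.6)$w_k
#> skeletal_muscle  liver  brain  heart  kidneys  adipose  residual
#>           22.10   1.43   1.11   0.26     0.24    10.61     18.16

loglog_slope(sweep_body_mass(ref))
#> 0.787                                      # allometric exponent

project_decline(1000, law$u, 104)
#> 685                                        # mitochondria left at 120
```

## Package layout

| file | contents |
|---|---|
| `R/metabolic-core.R` | Harris–Benedict msBMR, `decay_law`, binned statistics, SD-convergence extrapolation |
| `R/cohort-synth.R` | seeded synthetic cohort and mortality-series generators |
| `R/renormalization.R` | first/second renormalization, decay-law fit |
| `R/mortality.R` | logistic mortality model, plateau, survival, fitting |
| `R/organ-model.R` | reference male, organ redistribution and decomposition |
| `R/allometry.R` | body-mass sweep and scaling exponent |
| `R/mito-dynamics.R` | fusion/fission ODE system, analytic + numeric solutions |
| `R/pipeline.R` | `run_full_pipeline()` orchestration |

The methods vignette (`vignettes/rmsbmr-methods.Rmd`) documents the
modelling assumptions, parameter choices and known limitations.
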