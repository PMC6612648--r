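Package: rmsbmr
Title: Renormalized Mass-Specific Basal Metabolic Rate Models of Human Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying human aging through the renormalized
    mass-specific basal metabolic rate (RmsBMR). Implements the
    Harris-Benedict mass-specific BMR, a two-step renormalization that
    collapses individual metabolic rates onto a universal exponential
    decline with age, a logistic mortality-rate model with a centenarian
    plateau and its survival-curve transform, an organ-level decomposition
    of the decline against a reference male, an allometric body-mass sweep
    reproducing the 3/4-power scaling of BMR in mammals, and a linear
    fusion/fission compartment model of mitochondrial number decay.
    Includes seeded generators for synthetic anthropometric cohorts and
    mortality-rate series for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
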