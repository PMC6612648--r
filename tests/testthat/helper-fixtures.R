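# Small deterministic fixtures shared across test files.

tiny_cohort <- function(n = 200, seed = 42) {
  generate_cohort(cohort_spec(n_subjects = n, seed = seed))
}

default_cohort_20k <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(
      cohort_spec(n_subjects = 20000, seed = 11))
    cache
  }
})

us_model <- function(...) mortality_model(C = 1.55, T_c = 101, ...)

table1_rates <- function() {
  p <- reference_organ_profile()
  stats::setNames(p$msbmr_k, p$organ)
}
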