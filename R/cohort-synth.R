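#' Default BMI mean curve for synthetic cohorts
#'
#' Linear decline from 26.1 kg/m^2 at age 16 to 21.5 kg/m^2 at age 105,
#' the endpoint on which the observed BMI dispersion converges.
#' @param age Age in years.
#' @return BMI mean in kg/m^2.
#' @export
default_bmi_mean_curve <- function(age) {
  26.1 + (21.5 - 26.1) * (age - 16) / (105 - 16)
}

#' Default BMI SD curve for synthetic cohorts
#'
#' Linear shrinkage from 5.0 kg/m^2 at age 16 to 0 at age 105, emulating
#' the observed convergence of the BMI dispersion with age.
#' @param age Age in years.
#' @return BMI SD in kg/m^2 (floored at 0).
#' @export
default_bmi_sd_curve <- function(age) {
  pmax(0, 5.0 * (105 - age) / (105 - 16))
}

#' Specification of a synthetic anthropometric cohort
#'
#' Describes the male cohort the generator emulates: five population
#' groups with group-dependent height distributions, integer ages uniform
#' on `[age_min, age_max]`, and a per-age BMI distribution whose
#' dispersion shrinks with age. Defaults mirror a large US male survey
#' cohort (ages 16-80, five self-identified origin groups). The group
#' height means are placeholders -- only their tall/short ordering
#' matters for demonstrating the height effect that the second
#' renormalization removes.
#'
#' @param n_subjects Number of subjects to generate.
#' @param age_min,age_max Integer age bounds (default 16, 80).
#' @param group_mix Named proportions over the group labels, summing to 1.
#' @param height_mean Named mean heights (cm) per group.
#' @param height_sd Named height SDs (cm) per group (default 7 cm each).
#' @param bmi_mean_curve,bmi_sd_curve Functions of age giving the BMI
#'   mean and SD (kg/m^2) at that age.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 25000,
                        age_min = 16, age_max = 80,
                        group_mix = NULL,
                        height_mean = NULL,
                        height_sd = NULL,
                        bmi_mean_curve = default_bmi_mean_curve,
                        bmi_sd_curve = default_bmi_sd_curve,
                        seed = 1L) {
  groups <- c("white", "black", "other", "mexican_american",
              "other_hispanic")
  if (is.null(group_mix)) {
    group_mix <- stats::setNames(rep(1 / 5, 5), groups)
  }
  if (is.null(names(group_mix)))
    stop("`group_mix` must be a named vector of proportions",
         call. = FALSE)
  if (abs(sum(group_mix) - 1) > 1e-9)
    stop("group proportions must sum to 1", call. = FALSE)
  if (any(group_mix < 0)) stop("group proportions must be >= 0",
                               call. = FALSE)
  if (is.null(height_mean)) {
    height_mean <- stats::setNames(
      rep_len(c(178, 177, 170, 168, 165), length(group_mix)),
      names(group_mix))
  }
  if (is.null(height_sd)) {
    height_sd <- stats::setNames(rep(7, length(group_mix)),
                                 names(group_mix))
  }
  if (!setequal(names(group_mix), names(height_mean)) ||
      !setequal(names(group_mix), names(height_sd)))
    stop("group_mix, height_mean and height_sd must share group names",
         call. = FALSE)
  if (any(height_sd < 0)) stop("height SDs must be >= 0", call. = FALSE)
  if (!(age_min < age_max)) stop("age_min must be < age_max", call. = FALSE)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (any(bmi_sd_curve(seq(age_min, age_max)) < 0))
    stop("bmi_sd_curve must be non-negative on the age range",
         call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    age_min = as.integer(age_min), age_max = as.integer(age_max),
    group_mix = group_mix,
    height_mean = height_mean[names(group_mix)],
    height_sd = height_sd[names(group_mix)],
    bmi_mean_curve = bmi_mean_curve,
    bmi_sd_curve = bmi_sd_curve,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort spec: n = %d, ages %d-%d, %d groups, seed %d\n",
    x$n_subjects, x$age_min, x$age_max, length(x$group_mix), x$seed))
  invisible(x)
}

#' Generate a synthetic anthropometric cohort
#'
#' Draws a cohort of male subjects per a [cohort_spec()]: group labels
#' from the mixing proportions, integer ages uniform over the age range,
#' heights normal within group, and BMI normal with age-dependent mean
#' and SD (truncated below at 10 kg/m^2 to keep weights physical).
#' Weight is derived as `(height/100)^2 * bmi`, so BMI, height and
#' weight are mutually consistent by construction.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with columns
#'   `id, age, height_cm, weight_kg, bmi, group`.
#' @examples
#' head(generate_cohort(cohort_spec(n_subjects = 100, seed = 7)))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  group <- sample(names(spec$group_mix), n, replace = TRUE,
                  prob = spec$group_mix)
  age <- sample(seq(spec$age_min, spec$age_max), n, replace = TRUE)
  height <- stats::rnorm(n, spec$height_mean[group], spec$height_sd[group])
  bmi <- stats::rnorm(n, spec$bmi_mean_curve(age), spec$bmi_sd_curve(age))
  bmi <- pmax(bmi, 10)
  weight <- (height / 100)^2 * bmi
  data.frame(
    id = sprintf("S%06d", seq_len(n)),
    age = as.integer(age),
    height_cm = height,
    weight_kg = weight,
    bmi = bmi,
    group = group,
    stringsAsFactors = FALSE
  )
}

#' Generate an age-indexed mortality-rate series from a model
#'
#' Produces the annual death probabilities \eqn{P(T)} of a
#' [mortality_model()] at the requested ages, optionally with binomial
#' sampling noise: at each age the observed rate is drawn as
#' `Binomial(n_at_risk, P(T)) / n_at_risk`. With `n_at_risk = Inf`
#' (noise off) the exact model rates are returned.
#'
#' @param model A [mortality_model()].
#' @param ages Integer ages (all >= 16, the model's validity range).
#' @param n_at_risk Number at risk per age (>= 1), or `Inf` for no noise.
#' @param seed Optional integer seed for the binomial draws.
#' @return A data frame `age, rate` plus `n_at_risk` when finite.
#' @export
generate_mortality_series <- function(model, ages = 80:104,
                                      n_at_risk = Inf, seed = NULL) {
  stopifnot(inherits(model, "mortality_model"))
  if (any(ages < 16))
    stop("ages below 16 are outside the model's validity range",
         call. = FALSE)
  if (any(diff(ages) <= 0))
    stop("`ages` must be strictly increasing", call. = FALSE)
  p <- mortality_rate(ages, model)
  if (is.infinite(n_at_risk)) {
    return(data.frame(age = as.integer(ages), rate = p))
  }
  if (n_at_risk < 1) stop("`n_at_risk` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rate <- stats::rbinom(length(ages), size = n_at_risk, prob = p) / n_at_risk
  data.frame(age = as.integer(ages), rate = rate,
             n_at_risk = as.integer(n_at_risk))
}
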