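#' Mass-specific basal metabolic rate from the Harris-Benedict equation
#'
#' Evaluates the (male) Harris-Benedict basal metabolic rate per unit body
#' mass,
#' \deqn{msBMR = (88.362 + 13.397 W + 4.799 H - 5.677 T) / W}
#' in kcal day^-1 kg^-1, for body weight \eqn{W} (kg), height \eqn{H} (cm)
#' and age \eqn{T} (years).
#'
#' The function is strictly decreasing in weight at fixed height and age,
#' with infimum 13.397 kcal day^-1 kg^-1 as \eqn{W \to \infty}; that
#' asymptote is the reason a finite positive weight solving
#' `msBMR = F(T)` exists only while `F(T) > 13.397` (see
#' [second_renorm()]).
#'
#' @param weight Body weight in kg (> 0). Recycled against the other
#'   arguments.
#' @param height Height in cm (> 0).
#' @param age Age in years (>= 0).
#' @return Mass-specific BMR in kcal day^-1 kg^-1.
#' @examples
#' hbe_msbmr(70, 175, 30)
#' @export
hbe_msbmr <- function(weight, height, age) {
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("`weight` must be positive and finite", call. = FALSE)
  if (any(!is.finite(height)) || any(height <= 0))
    stop("`height` must be positive and finite", call. = FALSE)
  if (any(age < 0)) stop("`age` must be non-negative", call. = FALSE)
  (88.362 + 13.397 * weight + 4.799 * height - 5.677 * age) / weight
}

#' Exponential decay law for the universal metabolic decline
#'
#' Constructs the pair \eqn{(F_0, u)} defining the universal metabolic
#' decline function \eqn{F(T) = F_0 e^{-uT}} that the renormalized
#' mass-specific BMR follows with age. The defaults are the values fitted
#' to the first-renormalized msBMR of a large male cohort:
#' \eqn{F_0 = 27.63} kcal day^-1 kg^-1 and \eqn{u = 0.00364} year^-1
#' (a 0.36% loss per year).
#'
#' @param F0 Metabolic rate at age 0, kcal day^-1 kg^-1 (> 0).
#' @param u Decay constant, year^-1 (>= 0).
#' @return An object of class `decay_law`.
#' @seealso [universal_decline()], [fit_decay_law()]
#' @examples
#' law <- decay_law()
#' universal_decline(50, law)
#' @export
decay_law <- function(F0 = 27.63, u = 0.00364) {
  if (!is.numeric(F0) || length(F0) != 1L || !is.finite(F0) || F0 <= 0)
    stop("`F0` must be a single positive number", call. = FALSE)
  if (!is.numeric(u) || length(u) != 1L || !is.finite(u) || u < 0)
    stop("`u` must be a single non-negative number", call. = FALSE)
  structure(list(F0 = F0, u = u), class = "decay_law")
}

#' @export
print.decay_law <- function(x, ...) {
  cat("Universal metabolic decline F(T) = F0 * exp(-u*T)\n")
  cat(sprintf("  F0 = %.4g kcal/day/kg,  u = %.4g /year", x$F0, x$u))
  cat(sprintf("  (%.2f%% loss per year)\n", 100 * (1 - exp(-x$u))))
  invisible(x)
}

#' Evaluate the universal metabolic decline function F(T)
#'
#' @param age Age in years (vectorized).
#' @param law A [decay_law()].
#' @return \eqn{F_0 e^{-u \cdot age}} in kcal day^-1 kg^-1.
#' @export
universal_decline <- function(age, law = decay_law()) {
  stopifnot(inherits(law, "decay_law"))
  law$F0 * exp(-law$u * age)
}

#' Age-binned msBMR and BMI statistics for a cohort
#'
#' Computes, per integer age, the number of subjects and the mean and
#' sample standard deviation (n-1 denominator) of the Harris-Benedict
#' msBMR and of BMI. SDs are reported only for bins with at least
#' `min_n` subjects, since small-bin sample SDs are too noisy to be
#' meaningful for the convergence extrapolation.
#'
#' @param cohort A cohort data frame as produced by [generate_cohort()],
#'   with columns `age`, `height_cm`, `weight_kg` (and optionally `bmi`).
#' @param min_n Minimum bin size for reporting an SD (default 10).
#' @return A data frame with columns
#'   `age, n, msbmr_mean, msbmr_sd, bmi_mean, bmi_sd`, one row per
#'   observed integer age.
#' @export
bin_stats <- function(cohort, min_n = 10) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("`cohort` must be a non-empty data frame", call. = FALSE)
  need <- c("age", "height_cm", "weight_kg")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  msbmr <- hbe_msbmr(cohort$weight_kg, cohort$height_cm, cohort$age)
  bmi <- if ("bmi" %in% names(cohort)) cohort$bmi else
    cohort$weight_kg / (cohort$height_cm / 100)^2
  age <- as.integer(round(cohort$age))
  ages <- sort(unique(age))
  stat1 <- function(x, f) vapply(ages, function(a) f(x[age == a]), numeric(1))
  n <- vapply(ages, function(a) sum(age == a), integer(1))
  out <- data.frame(
    age = ages,
    n = n,
    msbmr_mean = stat1(msbmr, mean),
    msbmr_sd = stat1(msbmr, stats::sd),
    bmi_mean = stat1(bmi, mean),
    bmi_sd = stat1(bmi, stats::sd)
  )
  out$msbmr_sd[n < min_n] <- NA_real_
  out$bmi_sd[n < min_n] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Quadratic summary of an age-binned statistic
#'
#' Least-squares fit of `value = a*T^2 + b*T + c` to one of the binned
#' series over an age window (default 45-80, the window used before
#' extrapolating towards the SD-convergence age).
#'
#' @param stats Output of [bin_stats()].
#' @param series One of `"msbmr_mean"`, `"msbmr_sd"`, `"bmi_mean"`,
#'   `"bmi_sd"`, or the composite bands `"msbmr_upper"`/`"msbmr_lower"`
#'   (mean +/- SD) and `"bmi_upper"`/`"bmi_lower"`.
#' @param age_range Length-2 numeric, inclusive fitting window.
#' @return Named numeric `c(a =, b =, c =)` of quadratic coefficients.
#' @export
quadratic_summary <- function(stats, series = "msbmr_mean",
                              age_range = c(45, 80)) {
  series <- match.arg(series, c(
    "msbmr_mean", "msbmr_sd", "bmi_mean", "bmi_sd",
    "msbmr_upper", "msbmr_lower", "bmi_upper", "bmi_lower"
  ))
  y <- switch(series,
    msbmr_mean = stats$msbmr_mean,
    msbmr_sd = stats$msbmr_sd,
    bmi_mean = stats$bmi_mean,
    bmi_sd = stats$bmi_sd,
    msbmr_upper = stats$msbmr_mean + stats$msbmr_sd,
    msbmr_lower = stats$msbmr_mean - stats$msbmr_sd,
    bmi_upper = stats$bmi_mean + stats$bmi_sd,
    bmi_lower = stats$bmi_mean - stats$bmi_sd
  )
  keep <- !is.na(y) & stats$age >= age_range[1] & stats$age <= age_range[2]
  x <- stats$age[keep]
  y <- y[keep]
  if (length(unique(x)) < 3L)
    stop("need at least 3 populated age bins in range for a quadratic fit",
         call. = FALSE)
  fit <- stats::lm(y ~ x + I(x^2))
  co <- stats::coef(fit)
  c(a = unname(co[3]), b = unname(co[2]), c = unname(co[1]))
}

#' Convergence age of extrapolated upper and lower quadratic bands
#'
#' Given quadratic fits to the (mean + SD) and (mean - SD) bands of a
#' statistic, finds the smallest age beyond `age_max` at which the two
#' extrapolated curves intersect -- the age at which the dispersion
#' extrapolates to zero -- and the common value there.
#'
#' @param upper,lower Quadratic coefficient vectors `c(a, b, c)` as
#'   returned by [quadratic_summary()].
#' @param age_max Upper end of the observed window (default 80); only
#'   intersections strictly beyond it count, except in the degenerate
#'   case `upper == lower` where the bands already coincide.
#' @param horizon Oldest age searched (default 200).
#' @return A list with `converged` (logical), `age`, and `value`
#'   (`NA` when non-convergent).
#' @export
convergence_age <- function(upper, lower, age_max = 80, horizon = 200) {
  stopifnot(length(upper) == 3L, length(lower) == 3L)
  d <- unname(upper - lower) # (a, b, c) of the gap polynomial
  evalq_ <- function(co, t) co[1] * t^2 + co[2] * t + co[3]
  if (all(abs(d) < 1e-12)) {
    return(list(converged = TRUE, age = age_max,
                value = unname(evalq_(upper, age_max))))
  }
  roots <- if (abs(d[1]) < 1e-12) {
    if (abs(d[2]) < 1e-12) numeric(0) else -d[3] / d[2]
  } else {
    disc <- d[2]^2 - 4 * d[1] * d[3]
    if (disc < 0) numeric(0) else (-d[2] + c(-1, 1) * sqrt(disc)) / (2 * d[1])
  }
  roots <- sort(roots[roots > age_max & roots <= horizon])
  if (length(roots) == 0L)
    return(list(converged = FALSE, age = NA_real_, value = NA_real_))
  list(converged = TRUE, age = roots[1],
       value = unname(evalq_(upper, roots[1])))
}
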