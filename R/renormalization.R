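#' First renormalization: fix BMI at a healthy reference value
#'
#' Replaces a subject's recorded weight with the weight implied by a
#' reference BMI (default 21.5 kg/m^2, the value on which the cohort BMI
#' dispersion converges in extreme old age), then evaluates the
#' Harris-Benedict msBMR at that weight. The recorded weight plays no
#' role: two subjects of equal height and age always map to the same
#' result, which is what removes the bulk of the between-subject
#' variation in msBMR.
#'
#' @param height Height in cm (vectorized).
#' @param age Age in years.
#' @param bmi_ref Reference BMI in kg/m^2 (> 0, default 21.5).
#' @return A data frame with columns `weight` (kg) and `msbmr`
#'   (kcal day^-1 kg^-1).
#' @examples
#' first_renorm(187.7, 50) # tall 50-year-old
#' @export
first_renorm <- function(height, age, bmi_ref = 21.5) {
  if (any(bmi_ref <= 0)) stop("`bmi_ref` must be positive", call. = FALSE)
  weight <- (height / 100)^2 * bmi_ref
  data.frame(weight = weight, msbmr = hbe_msbmr(weight, height, age))
}

#' Fit the exponential decline F(T) to per-age msBMR means
#'
#' Ordinary least squares of `log(msbmr)` on age: the decline
#' \eqn{F(T) = F_0 e^{-uT}} is log-linear, so the fit is exact on
#' noiseless exponential data and recovers `(F0, u)` identically.
#' The fit is unweighted.
#'
#' @param age Ages in years (>= 3 distinct values).
#' @param msbmr Per-age mean msBMR values (all > 0).
#' @param age_range Optional length-2 window restricting the fit.
#' @return A [decay_law()] carrying the fitted `(F0, u)`.
#' @export
fit_decay_law <- function(age, msbmr, age_range = NULL) {
  if (!is.null(age_range)) {
    keep <- age >= age_range[1] & age <= age_range[2]
    age <- age[keep]
    msbmr <- msbmr[keep]
  }
  keep <- !is.na(msbmr)
  age <- age[keep]
  msbmr <- msbmr[keep]
  if (any(msbmr <= 0))
    stop("msBMR values must be positive for a log-scale fit",
         call. = FALSE)
  if (length(unique(age)) < 3L)
    stop("need at least 3 distinct ages to fit a decay law",
         call. = FALSE)
  fit <- stats::lm(log(msbmr) ~ age)
  u <- -unname(stats::coef(fit)[2])
  if (u < 0)
    stop("fitted msBMR increases with age; no decay law", call. = FALSE)
  decay_law(F0 = exp(unname(stats::coef(fit)[1])), u = u)
}

#' Second renormalization: solve the Harris-Benedict equation for weight
#'
#' Readjusts the body weight (and hence BMI) so that the subject's msBMR
#' equals the universal decline `F(T)` exactly. Because the
#' Harris-Benedict msBMR is linear in 1/W, the equation
#' `hbe_msbmr(W, H, T) = F(T)` has the closed-form solution
#' \deqn{W = (88.362 + 4.799 H - 5.677 T) / (F(T) - 13.397),}
#' the unique positive root whenever `F(T) > 13.397` (the large-weight
#' asymptote of the msBMR). Under the default law this holds for all
#' ages up to well beyond 120.
#'
#' `bmi_printed` recomputes BMI from the weight rounded to 0.1 kg --
#' the convention used when quoting results to printed precision --
#' while `bmi` uses full precision.
#'
#' @param height Height in cm (vectorized).
#' @param age Age in years.
#' @param law A [decay_law()].
#' @return Data frame with `weight` (kg), `bmi`, and `bmi_printed`
#'   (kg/m^2).
#' @examples
#' second_renorm(c(187.7, 160.9), 50) # tall vs short 50-year-olds
#' @export
second_renorm <- function(height, age, law = decay_law()) {
  ft <- universal_decline(age, law)
  if (any(ft <= 13.397))
    stop("F(T) <= 13.397, the large-weight asymptote of the ",
         "Harris-Benedict msBMR: no positive weight solves the equation",
         call. = FALSE)
  weight <- (88.362 + 4.799 * height - 5.677 * age) / (ft - 13.397)
  if (any(weight <= 0))
    stop("renormalized weight is non-positive (height too small at ",
         "this age)", call. = FALSE)
  h2 <- (height / 100)^2
  data.frame(weight = weight,
             bmi = weight / h2,
             bmi_printed = round(weight, 1) / h2)
}

#' Renormalize a whole cohort onto the universal decline
#'
#' Applies [first_renorm()] and [second_renorm()] to every subject. Rows
#' whose age is infeasible for the law (F(T) at or below the msBMR
#' asymptote) are returned with `NA` results and collected in the
#' `"failures"` attribute rather than aborting the run.
#'
#' @param cohort Cohort data frame with `id`, `age`, `height_cm`.
#' @param law A [decay_law()].
#' @param bmi_ref Reference BMI for the first step (default 21.5).
#' @return Data frame with columns `id, age, height_cm, first_weight,
#'   first_msbmr, second_weight, second_bmi, target_msbmr`; attribute
#'   `"failures"` holds the ids of infeasible rows (if any).
#' @export
renormalize_cohort <- function(cohort, law = decay_law(), bmi_ref = 21.5) {
  if (nrow(cohort) == 0L) {
    out <- data.frame(id = character(), age = integer(),
                      height_cm = numeric(), first_weight = numeric(),
                      first_msbmr = numeric(), second_weight = numeric(),
                      second_bmi = numeric(), target_msbmr = numeric())
    attr(out, "failures") <- character()
    return(out)
  }
  ft <- universal_decline(cohort$age, law)
  ok <- ft > 13.397
  r1 <- first_renorm(cohort$height_cm, cohort$age, bmi_ref)
  second_weight <- second_bmi <- rep(NA_real_, nrow(cohort))
  if (any(ok)) {
    r2 <- second_renorm(cohort$height_cm[ok], cohort$age[ok], law)
    second_weight[ok] <- r2$weight
    second_bmi[ok] <- r2$bmi
  }
  out <- data.frame(
    id = cohort$id,
    age = cohort$age,
    height_cm = cohort$height_cm,
    first_weight = r1$weight,
    first_msbmr = r1$msbmr,
    second_weight = second_weight,
    second_bmi = second_bmi,
    target_msbmr = ifelse(ok, ft, NA_real_),
    stringsAsFactors = FALSE
  )
  attr(out, "failures") <- cohort$id[!ok]
  out
}
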