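#' Logistic mortality-rate model built on the metabolic decline
#'
#' The annual death probability is modelled as a logistic function of
#' the universal metabolic decline,
#' \deqn{P(T) = \frac{e^{G(T)}}{1 + e^{G(T)}}, \quad
#'       G(T) = C \{F(T_c) - F(T)\},}
#' where \eqn{T_c} is the age at which the modelled rate equals 0.5 and
#' \eqn{C} a dimensionless slope. Above `plateau_age` the decline is
#' frozen at `F(plateau_age)` -- the metabolic rate cannot fall further
#' while sustaining life -- so the rate is constant there (the
#' centenarian mortality plateau). Defaults are the US parameters
#' `C = 1.55`, `T_c = 101` (Italy: 1.4/101, Japan: 1.5/102).
#'
#' @param C Positive dimensionless slope.
#' @param T_c Age (years) at which P = 0.5.
#' @param law A [decay_law()].
#' @param plateau_age Age from which F is clamped (default 108);
#'   `NULL` disables the plateau.
#' @return An object of class `mortality_model`.
#' @examples
#' m <- mortality_model()
#' mortality_rate(c(90, 101, 108, 115), m)
#' @export
mortality_model <- function(C = 1.55, T_c = 101, law = decay_law(),
                            plateau_age = 108) {
  if (!is.numeric(C) || length(C) != 1L || C < 0)
    stop("`C` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(T_c) || length(T_c) != 1L || T_c <= 0)
    stop("`T_c` must be a single positive number", call. = FALSE)
  stopifnot(inherits(law, "decay_law"))
  if (!is.null(plateau_age))
    stopifnot(is.numeric(plateau_age), length(plateau_age) == 1L)
  structure(list(C = C, T_c = T_c, law = law, plateau_age = plateau_age),
            class = "mortality_model")
}

#' @export
print.mortality_model <- function(x, ...) {
  cat("Logistic mortality model P(T) = plogis(C * {F(T_c) - F(T)})\n")
  cat(sprintf("  C = %.4g, T_c = %.4g years, plateau %s\n", x$C, x$T_c,
              if (is.null(x$plateau_age)) "disabled"
              else sprintf("from age %g", x$plateau_age)))
  print(x$law)
  invisible(x)
}

#' Annual mortality rate P(T)
#'
#' @param age Age in years (vectorized, >= 16).
#' @param model A [mortality_model()].
#' @return Annual death probability in (0, 1); constant for ages at or
#'   beyond the plateau age.
#' @export
mortality_rate <- function(age, model) {
  stopifnot(inherits(model, "mortality_model"))
  if (any(age < 16))
    stop("model is defined for ages >= 16", call. = FALSE)
  age_eff <- if (is.null(model$plateau_age)) age else
    pmin(age, model$plateau_age)
  g <- model$C * (universal_decline(model$T_c, model$law) -
                    universal_decline(age_eff, model$law))
  stats::plogis(g)
}

#' Survival curve from the mortality model
#'
#' Transforms annual death probabilities into a survival curve on
#' integer ages: `S(anchor) = 1` and
#' `S(T + 1) = S(T) * (1 - P(T))`. The default anchor of 80 reflects
#' that the model targets mortality of the elderly.
#'
#' @param model A [mortality_model()].
#' @param anchor_age First age, where survival is 1 (default 80).
#' @param end_age Last age (default 120).
#' @return Data frame `age, survival`, non-increasing in `[0, 1]`.
#' @export
survival_curve <- function(model, anchor_age = 80, end_age = 120) {
  stopifnot(inherits(model, "mortality_model"))
  if (!(anchor_age < end_age))
    stop("`anchor_age` must be below `end_age`", call. = FALSE)
  ages <- seq(anchor_age, end_age)
  p <- mortality_rate(ages, model)
  s <- cumprod(c(1, 1 - p[-length(p)]))
  data.frame(age = ages, survival = s)
}

#' Fit the logistic mortality model to an observed rate series
#'
#' Least squares on the logit scale. Since
#' `logit P(T) = C F(T_c) - C F(T)` is linear in `F(T)` with slope
#' `-C` and intercept `C F(T_c)`, an ordinary regression of
#' `logit(rate)` on `F(T)` is the exact joint least-squares solution
#' over `(C, T_c)`; `T_c` is recovered by inverting the decay law at
#' the fitted `F(T_c)`. When `T_c` is supplied it is held fixed (e.g.
#' at the observed age where the rate crosses 0.5) and only `C` is
#' estimated. Ages in the plateau regime should be excluded via
#' `age_range` (default 80-104, pre-plateau).
#'
#' @param series Data frame with `age` and `rate` columns.
#' @param law A [decay_law()].
#' @param age_range Inclusive fitting window (default `c(80, 104)`).
#' @param T_c Optional fixed crossing age; `NULL` (default) fits it.
#' @param plateau_age Plateau age carried into the returned model.
#' @return A [mortality_model()] with the fitted parameters.
#' @export
fit_mortality <- function(series, law = decay_law(),
                          age_range = c(80, 104), T_c = NULL,
                          plateau_age = 108) {
  keep <- series$age >= age_range[1] & series$age <= age_range[2] &
    series$rate > 0 & series$rate < 1
  age <- series$age[keep]
  rate <- series$rate[keep]
  if (length(age) < 4L)
    stop("need at least 4 ages with rates strictly inside (0, 1)",
         call. = FALSE)
  if (stats::sd(rate) == 0)
    stop("rates are constant over the fitting window; ",
         "the model is unidentifiable", call. = FALSE)
  y <- stats::qlogis(rate)
  fv <- universal_decline(age, law)
  if (is.null(T_c)) {
    fit <- stats::lm(y ~ fv)
    co <- stats::coef(fit)
    C <- -unname(co[2])
    if (C <= 0)
      stop("fitted slope implies non-increasing mortality; ",
           "series inconsistent with the model", call. = FALSE)
    f_tc <- unname(co[1]) / C
    if (f_tc <= 0 || f_tc > law$F0)
      stop("fitted F(T_c) outside (0, F0]; cannot invert for T_c",
           call. = FALSE)
    T_c <- log(law$F0 / f_tc) / law$u
  } else {
    x <- universal_decline(T_c, law) - fv
    C <- sum(x * y) / sum(x * x)
    if (C <= 0)
      stop("fitted slope implies non-increasing mortality; ",
           "series inconsistent with the model", call. = FALSE)
  }
  mortality_model(C = C, T_c = T_c, law = law, plateau_age = plateau_age)
}
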