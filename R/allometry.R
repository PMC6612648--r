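#' Configuration of the allometric body-mass sweep
#'
#' Parameters of the iterative organ-weight redistribution that carries
#' the reference male's organ composition across the mammalian
#' body-mass range. Mass moves in steps of `step` kg, each step split
#' across organs proportionally to `msbmr_k^-q` (exponent `q_general`,
#' except the brain which uses the steeper `q_brain` because the human
#' brain is disproportionately large). The starting brain weight is
#' likewise scaled down by `brain_start_fraction` before the sweep, the
#' freed mass simply reducing the starting total.
#'
#' @param step Step size in kg (> 0, default 0.5).
#' @param mass_min,mass_max Sweep range in kg (default 1 to 800).
#' @param q_general Redistribution exponent for all organs but the
#'   brain (default 1.05).
#' @param q_brain Brain exponent (default 1.4).
#' @param brain_start_fraction Initial brain-weight scaling
#'   (default 1/8).
#' @param start_mass Nominal starting body mass in kg before the brain
#'   adjustment (default 67, the reference male's renormalized weight).
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(step = 0.5, mass_min = 1, mass_max = 800,
                         q_general = 1.05, q_brain = 1.4,
                         brain_start_fraction = 1 / 8,
                         start_mass = 67.0) {
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  if (mass_min <= 0 || mass_max <= mass_min)
    stop("mass range must satisfy 0 < mass_min < mass_max", call. = FALSE)
  if (start_mass < mass_min || start_mass > mass_max)
    stop("`start_mass` must lie inside the mass range", call. = FALSE)
  if (brain_start_fraction <= 0 || brain_start_fraction > 1)
    stop("`brain_start_fraction` must be in (0, 1]", call. = FALSE)
  structure(list(step = step, mass_min = mass_min, mass_max = mass_max,
                 q_general = q_general, q_brain = q_brain,
                 brain_start_fraction = brain_start_fraction,
                 start_mass = start_mass),
            class = "sweep_config")
}

# One redistribution step: move `delta` kg across organs with fixed
# shares, flooring any organ at zero and re-assigning the shortfall to
# the organs that still have mass (shares renormalized over them).
redistribute_step <- function(w, delta, share) {
  target <- w + delta * share
  repeat {
    neg <- target < 0
    if (!any(neg)) break
    shortfall <- sum(target[neg])
    target[neg] <- 0
    active <- target > 0
    if (!any(active)) stop("all organ masses exhausted", call. = FALSE)
    target[active] <- target[active] +
      shortfall * share[active] / sum(share[active])
  }
  target
}

#' Sweep the reference organ composition across body masses
#'
#' Starting from the reference male's renormalized organ weights (brain
#' scaled down per the configuration), repeatedly adds or removes
#' `step` kg of body mass, splitting each increment across organs in
#' proportion to `msbmr_k(r)^-q_k` -- low-rate tissues (adipose,
#' residual) absorb most of it. The sweep runs upward from the start
#' mass to `mass_max`, then downward to `mass_min` (final partial steps
#' land exactly on the bounds). Whole-body BMR per row uses the fixed
#' reference rates: `BMR = sum_k w_k * msbmr_k(r)`. On the downward
#' branch low-rate organs can be driven to zero; their mass floor is
#' honoured and the remaining reduction falls on the surviving organs.
#'
#' @param reference A `reference_male` from [calibrate_reference()].
#' @param config A [sweep_config()].
#' @return Data frame (class `sweep_table`) sorted by ascending mass
#'   with columns `mass_kg`, one column per organ, and `bmr_kcal_day`.
#' @examples
#' tab <- sweep_body_mass(calibrate_reference())
#' loglog_slope(tab)
#' @export
sweep_body_mass <- function(reference, config = sweep_config()) {
  stopifnot(inherits(reference, "reference_male"),
            inherits(config, "sweep_config"))
  rates <- reference$rates
  w0 <- reference$w_k_r
  if (any(w0 <= 0)) stop("reference organ masses must be positive",
                         call. = FALSE)
  if (!"brain" %in% names(w0))
    stop("reference must include a 'brain' organ", call. = FALSE)
  w0 <- w0 * config$start_mass / sum(w0) # honour nominal start mass
  w0["brain"] <- w0["brain"] * config$brain_start_fraction
  m0 <- sum(w0)
  q <- rep(config$q_general, length(rates))
  names(q) <- names(rates)
  q["brain"] <- config$q_brain
  share <- rates^(-q)
  share <- share / sum(share)

  walk <- function(masses) {
    w <- w0
    out <- matrix(NA_real_, nrow = length(masses), ncol = length(w0),
                  dimnames = list(NULL, names(w0)))
    m_prev <- m0
    for (i in seq_along(masses)) {
      w <- redistribute_step(w, masses[i] - m_prev, share)
      m_prev <- masses[i]
      out[i, ] <- w
    }
    out
  }
  up <- unique(c(seq(m0 + config$step, config$mass_max, by = config$step),
                 config$mass_max))
  up <- up[up > m0]
  down <- unique(c(seq(m0 - config$step, config$mass_min,
                       by = -config$step), config$mass_min))
  down <- down[down < m0]
  masses <- c(rev(down), m0, up)
  organs <- rbind(apply(walk(down), 2, rev), w0, walk(up))
  bmr <- as.numeric(organs %*% rates)
  out <- data.frame(mass_kg = masses, organs, bmr_kcal_day = bmr,
                    row.names = NULL, check.names = FALSE)
  class(out) <- c("sweep_table", class(out))
  out
}

#' Log-log slope of BMR against body mass
#'
#' Ordinary least-squares slope of `log(BMR)` on `log(mass)` over a
#' sweep table -- the allometric scaling exponent (empirically about
#' 3/4 across mammals).
#'
#' @param table A [sweep_body_mass()] table (or any data frame with
#'   `mass_kg` and `bmr_kcal_day`).
#' @param mass_range Optional length-2 window in kg.
#' @return The fitted exponent (single number).
#' @export
loglog_slope <- function(table, mass_range = NULL) {
  m <- table$mass_kg
  b <- table$bmr_kcal_day
  if (!is.null(mass_range)) {
    keep <- m >= mass_range[1] & m <= mass_range[2]
    m <- m[keep]
    b <- b[keep]
  }
  if (length(m) < 3L || length(unique(m)) < 3L)
    stop("need at least 3 distinct masses in range", call. = FALSE)
  unname(stats::coef(stats::lm(log(b) ~ log(m)))[2])
}
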