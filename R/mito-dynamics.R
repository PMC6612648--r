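#' Rate parameters of the mitochondrial fusion/fission system
#'
#' The mitochondrial population of a standard cell is modelled as a
#' two-compartment linear flow: `N1` organelles in the fission state,
#' `N2` in the fusion state, with
#' \deqn{N_2' = -P_{21} N_2 + P_{12} N_1,}
#' \deqn{N_1' = -(P_{12} + P_{13} - P_{11}) N_1 + P_{21} N_2,}
#' where `P11` is the biogenesis rate, `P13` the mitophagy rate, and
#' `P12`/`P21` the fission-to-fusion / fusion-to-silence transition
#' rates (all per year). The slow eigenmode of this system decays as a
#' single exponential with constant `u`; the approximation
#' `u = (P13 - P11)/(P11 * TOT)` (with `TOT` the turnover time) holds
#' when the exchange rates dominate the biogenesis/mitophagy imbalance,
#' so a warning is issued when `P12 + P21 < 10 |P13 - P11|`.
#'
#' @param P11 Biogenesis rate (>= 0, per year).
#' @param P12 Fission-to-fusion transition rate (>= 0).
#' @param P21 Fusion-to-fission transition rate (>= 0).
#' @param P13 Mitophagy rate (>= 0).
#' @param TOT Optional turnover time (years).
#' @return An object of class `mito_params`.
#' @export
mito_params <- function(P11, P12, P21, P13, TOT = NULL) {
  vals <- c(P11 = P11, P12 = P12, P21 = P21, P13 = P13)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all rates must be finite and >= 0", call. = FALSE)
  if (!is.null(TOT) && TOT <= 0)
    stop("`TOT` must be positive", call. = FALSE)
  if (P12 + P21 < 10 * abs(P13 - P11))
    warning("P12 + P21 is not large relative to |P13 - P11|; the ",
            "single-exponential approximation of u degrades",
            call. = FALSE)
  structure(list(P11 = P11, P12 = P12, P21 = P21, P13 = P13, TOT = TOT),
            class = "mito_params")
}

#' Exact slow decay constant of the fusion/fission system
#'
#' The slow characteristic root of
#' `N2'' + B N2' + C N2 = 0` with `B = P12 + P21 + P13 - P11` and
#' `C = P21 (P13 - P11)`:
#' \deqn{u = \{B - \sqrt{B^2 - 4C}\} / 2,}
#' positive for net decay (`P13 > P11`) and exactly 0 when biogenesis
#' balances mitophagy.
#'
#' @param params A [mito_params()].
#' @return Decay constant u in year^-1.
#' @seealso [mito_u_approx()] for the large-exchange-rate limit.
#' @export
mito_u_exact <- function(params) {
  stopifnot(inherits(params, "mito_params"))
  B <- params$P12 + params$P21 + params$P13 - params$P11
  C <- params$P21 * (params$P13 - params$P11)
  disc <- B^2 - 4 * C
  if (disc < 0)
    stop("complex characteristic roots (B^2 < 4C): parameters outside ",
         "the overdamped regime of the model", call. = FALSE)
  (B - sqrt(disc)) / 2
}

#' Approximate decay constant in the fast-exchange limit
#'
#' `u ~ P21 (P13 - P11) / (P12 + P21)`, the first-order expansion of
#' the exact root when the exchange rates dominate; agrees with
#' [mito_u_exact()] within 1% once `P12 + P21 >= 100 |P13 - P11|`.
#'
#' @param params A [mito_params()].
#' @return Approximate u in year^-1.
#' @export
mito_u_approx <- function(params) {
  stopifnot(inherits(params, "mito_params"))
  params$P21 * (params$P13 - params$P11) / (params$P12 + params$P21)
}

#' Analytic slow-mode trajectory of the mitochondrial system
#'
#' On the slow eigenmode the fusion-state count decays as
#' `N2(T) = N2(0) exp(-u T)` with u the exact slow root, and the
#' fission-state count rides the same exponential with amplitude fixed
#' by the eigenvector relation `N1 = (P21 - u) N2 / P12` (the
#' eigenvalue correction to the fast-exchange balance
#' `P12 N1 = P21 N2`). The total `N1 + N2` is therefore a single
#' exponential -- the Markov decay of the mitochondrial number.
#'
#' @param params A [mito_params()] with `P12 > 0`.
#' @param N2_0 Initial fusion-state count (>= 0).
#' @param times Numeric vector of times (years).
#' @return Data frame `time, N1, N2, N_total`.
#' @export
mito_analytic <- function(params, N2_0, times) {
  stopifnot(inherits(params, "mito_params"), N2_0 >= 0)
  if (params$P12 <= 0)
    stop("P12 must be positive for the slow-mode solution", call. = FALSE)
  u <- mito_u_exact(params)
  decay <- exp(-u * times)
  N2 <- N2_0 * decay
  N1 <- N2_0 * (params$P21 - u) / params$P12 * decay
  data.frame(time = times, N1 = N1, N2 = N2, N_total = N1 + N2)
}

#' Numerical integration of the fusion/fission equations
#'
#' High-accuracy initial-value integration of the two-compartment
#' linear system, used as an independent oracle for the analytic
#' solution. Any initial condition is allowed; off the slow eigenmode
#' the fast mode produces a transient before the trajectory locks into
#' the single-exponential decay.
#'
#' @param params A [mito_params()].
#' @param N1_0,N2_0 Initial counts (>= 0).
#' @param times Times (years); must start at 0.
#' @param rtol,atol Integration tolerances (default 1e-12).
#' @return Data frame `time, N1, N2, N_total`.
#' @export
mito_numeric <- function(params, N1_0, N2_0, times,
                         rtol = 1e-12, atol = 1e-12) {
  stopifnot(inherits(params, "mito_params"), N1_0 >= 0, N2_0 >= 0)
  deriv <- function(t, y, p) {
    list(c(
      N1 = -(p$P12 + p$P13 - p$P11) * y[1] + p$P21 * y[2],
      N2 = p$P12 * y[1] - p$P21 * y[2]
    ))
  }
  sol <- deSolve::ode(y = c(N1 = N1_0, N2 = N2_0), times = times,
                      func = deriv, parms = params,
                      rtol = rtol, atol = atol)
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  out$N_total <- out$N1 + out$N2
  out
}

#' Decay constant from biogenesis, mitophagy and turnover time
#'
#' The turnover identity `N1 * P11 * TOT = N1 + N2` (the whole
#' population is replaced once per turnover time) reduces the decay
#' constant to
#' \deqn{u = (P_{13} - P_{11}) / (P_{11} \cdot TOT).}
#'
#' @param P11 Biogenesis rate (> 0).
#' @param P13 Mitophagy rate.
#' @param TOT Turnover time in years (> 0).
#' @return u in year^-1.
#' @export
mito_decay_constant <- function(P11, P13, TOT) {
  if (P11 * TOT == 0)
    stop("P11 * TOT must be non-zero", call. = FALSE)
  if (P11 <= 0 || TOT <= 0)
    stop("P11 and TOT must be positive", call. = FALSE)
  (P13 - P11) / (P11 * TOT)
}

#' Project the mitochondrial count forward in time
#'
#' `N(t) = N0 * exp(-u * years)`, rounded to the nearest whole
#' organelle for display when `round = TRUE`. At the global decay
#' constant, a cell holding 1,000 mitochondria at age 16 retains 685
#' at age 120.
#'
#' @param N0 Initial count (>= 0).
#' @param u Decay constant in year^-1.
#' @param years Elapsed time in years (>= 0).
#' @param round Round to the nearest integer (default TRUE).
#' @return Projected count.
#' @examples
#' project_decline(1000, 0.00364, 104)
#' @export
project_decline <- function(N0, u, years, round = TRUE) {
  if (any(N0 < 0) || any(years < 0))
    stop("N0 and years must be >= 0", call. = FALSE)
  out <- N0 * exp(-u * years)
  if (round) round(out) else out
}

#' Metabolic decline rescaled to the mouse lifespan
#'
#' Maps a human organ decay constant onto the mouse timescale by the
#' lifespan ratio (120 years vs 4 years, ratio 30), anchored at
#' adulthood (`t_offset`, default 0.5 years):
#' `F(T) = F0_mouse * exp(-ratio * u_organ * (T - t_offset))` for
#' `T >= t_offset`. With the liver constant 0.00624/year the effective
#' mouse rate is 0.1872/year.
#'
#' @param u_organ Human organ decay constant in year^-1 (> 0).
#' @param lifespan_ratio Human/mouse lifespan ratio (default 30).
#' @param F0_mouse Adult mouse mitochondrial density (default 58.0).
#' @param t_offset Age of adulthood in years (default 0.5).
#' @return A function of mouse age (years >= `t_offset`), with the
#'   effective rate in attribute `"rate"`.
#' @export
mouse_rescale <- function(u_organ = 0.00624, lifespan_ratio = 30,
                          F0_mouse = 58.0, t_offset = 0.5) {
  if (u_organ <= 0 || lifespan_ratio <= 0 || F0_mouse <= 0)
    stop("inputs must be positive", call. = FALSE)
  rate <- lifespan_ratio * u_organ
  f <- function(T) {
    if (any(T < t_offset))
      stop("rescaled decline is defined for ages >= ", t_offset,
           " (use mouse_development_curve() below that)", call. = FALSE)
    F0_mouse * exp(-rate * (T - t_offset))
  }
  attr(f, "rate") <- rate
  f
}

#' Mitochondrial density during mouse development
#'
#' Gaussian rise of the mouse liver mitochondrial density to its adult
#' value: `y = F0 * exp(-k (T - t_adult)^2)` on `0 <= T <= t_adult`,
#' continuous with the adult decline of [mouse_rescale()] at
#' `T = t_adult`.
#'
#' @param T Mouse age in years, within `[0, t_adult]`.
#' @param F0 Adult density (default 58.0).
#' @param k Rise curvature (default 0.8).
#' @param t_adult Age of adulthood (default 0.5).
#' @return Density at age `T`.
#' @export
mouse_development_curve <- function(T, F0 = 58.0, k = 0.8,
                                    t_adult = 0.5) {
  if (any(T < 0) || any(T > t_adult))
    stop("development curve is defined on [0, ", t_adult, "]",
         call. = FALSE)
  F0 * exp(-k * (T - t_adult)^2)
}
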