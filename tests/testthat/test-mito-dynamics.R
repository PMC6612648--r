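# random parameter sets in the overdamped, exchange-dominated regime
random_mito_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    P11 <- runif(1, 0.5, 2)
    mito_params(
      P11 = P11,
      P12 = runif(1, 5, 50),
      P21 = runif(1, 5, 50),
      P13 = P11 * (1 + runif(1, 0.01, 0.05))
    )
  })
}

test_that("decay constant vanishes when biogenesis balances mitophagy", {
  p <- mito_params(P11 = 1, P12 = 20, P21 = 15, P13 = 1)
  expect_identical(mito_u_exact(p), 0)
  traj <- mito_analytic(p, N2_0 = 500, times = 0:40)
  expect_equal(diff(traj$N_total), rep(0, 40), tolerance = 1e-12)
})

test_that("exact root approaches the fast-exchange approximation", {
  # within 1% once the exchange rates exceed 100x the imbalance
  p <- mito_params(P11 = 1, P12 = 60, P21 = 50, P13 = 1.5)
  expect_lt(abs(mito_u_exact(p) - mito_u_approx(p)) / mito_u_exact(p),
            0.01)
  # convergence improves as the ratio grows
  rel_err <- vapply(c(20, 100, 500, 2500), function(scale) {
    pp <- suppressWarnings(
      mito_params(P11 = 1, P12 = scale * 0.55, P21 = scale * 0.45,
                  P13 = 1.5))
    abs(mito_u_exact(pp) - mito_u_approx(pp)) / mito_u_exact(pp)
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))
})

test_that("characteristic roots stay real over valid rate space", {
  # B^2 - 4C = (P13 - P11 + P12 - P21)^2 + 4 P12 P21 >= 0, so the slow
  # root is real for every non-negative rate set
  set.seed(31)
  for (i in 1:50) {
    p <- suppressWarnings(mito_params(
      P11 = runif(1, 0, 50), P12 = runif(1, 0, 50),
      P21 = runif(1, 0, 50), P13 = runif(1, 0, 50)))
    expect_true(is.finite(mito_u_exact(p)))
  }
  expect_error(mito_params(P11 = -1, P12 = 1, P21 = 1, P13 = 1), ">= 0")
  expect_warning(mito_params(P11 = 1, P12 = 2, P21 = 2, P13 = 3),
                 "approximation")
})

test_that("total count obeys the Markov semigroup property", {
  p <- mito_params(P11 = 1, P12 = 30, P21 = 25, P13 = 1.04)
  u <- mito_u_exact(p)
  traj <- mito_analytic(p, N2_0 = 1000, times = c(0, 10, 25, 60, 85))
  n_at <- function(t) traj$N_total[traj$time == t]
  expect_equal(n_at(60), n_at(25) * exp(-u * 35), tolerance = 1e-12)
  expect_equal(n_at(85), n_at(10) * exp(-u * 75), tolerance = 1e-12)
})

test_that("analytic totals match the ODE oracle on 100 random sets", {
  params <- random_mito_params(100, seed = 2024)
  times <- seq(0, 30, by = 5)
  worst <- 0
  for (p in params) {
    ana <- mito_analytic(p, N2_0 = 1000, times = times)
    num <- mito_numeric(p, N1_0 = ana$N1[1], N2_0 = 1000, times = times)
    rel <- max(abs(num$N_total - ana$N_total) / ana$N_total)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-6)
})

test_that("off-mode starts relax onto the slow eigenmode", {
  p <- mito_params(P11 = 1, P12 = 30, P21 = 25, P13 = 1.04)
  u <- mito_u_exact(p)
  num <- mito_numeric(p, N1_0 = 0, N2_0 = 1000,
                      times = c(0, 0.01, 0.05, 2, 3))
  # N1 rises from zero, then the total decays at the slow rate
  expect_gt(num$N1[2], 0)
  expect_gt(num$N1[3], num$N1[2])
  expect_equal(num$N_total[num$time == 3] / num$N_total[num$time == 2],
               exp(-u), tolerance = 1e-9)
  # zero rates: nothing moves
  still <- mito_numeric(mito_params(0, 0, 0, 0), 10, 20, times = 0:3)
  expect_equal(still$N1, rep(10, 4), tolerance = 1e-10)
  expect_equal(still$N2, rep(20, 4), tolerance = 1e-10)
})

test_that("symmetric exchange keeps the states near balance", {
  p <- mito_params(P11 = 1, P12 = 20, P21 = 20, P13 = 1.02)
  ana <- mito_analytic(p, N2_0 = 800, times = seq(0, 40, 10))
  # N1/N2 constant at (P21 - u)/P12, i.e. 1 up to the u-correction
  expect_equal(ana$N1 / ana$N2,
               rep((p$P21 - mito_u_exact(p)) / p$P12, 5),
               tolerance = 1e-12)
  expect_equal(ana$N1 / ana$N2, rep(1, 5), tolerance = 1e-3)
})

test_that("turnover identity yields the published decay constant", {
  # 2% biogenesis/mitophagy imbalance over a 5.49-year turnover
  expect_equal(mito_decay_constant(P11 = 1, P13 = 1.02, TOT = 5.49),
               0.00364, tolerance = 1e-3)
  expect_identical(mito_decay_constant(1, 1, 10), 0)
  # doubling the turnover time halves u
  expect_equal(mito_decay_constant(1, 1.02, 11),
               mito_decay_constant(1, 1.02, 5.5) / 2)
  expect_error(mito_decay_constant(0, 1, 5), "P11")
})

test_that("mitochondrial attrition over a lifetime is small but real", {
  expect_identical(project_decline(1000, 0.00364, 104), 685)
  expect_identical(project_decline(1000, 0.00364, 0), 1000)
  # one-year fractional loss of 0.36%
  one_year <- project_decline(1, 0.00364, 1, round = FALSE)
  expect_equal(signif(1 - one_year, 2), 0.0036)
})

test_that("mouse rescaling matches the human decline scaled by 30", {
  f <- mouse_rescale()
  expect_equal(attr(f, "rate"), 0.1872)
  expect_equal(f(0.5), 58.0)
  expect_equal(f(1.5), 58 * exp(-0.1872), tolerance = 1e-12)
  expect_error(f(0.2), ">= 0.5")
  # ratio 1 reproduces the human organ rate
  g <- mouse_rescale(lifespan_ratio = 1)
  expect_equal(attr(g, "rate"), 0.00624)

  # development curve rises to the adult value, continuous at 0.5
  expect_equal(mouse_development_curve(0.5), 58.0)
  expect_equal(mouse_development_curve(0), 58 * exp(-0.2))
  expect_equal(mouse_development_curve(0.5), f(0.5))
  expect_error(mouse_development_curve(0.7), "defined on")
})
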