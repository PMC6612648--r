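test_that("weight-averaged organ msBMR behaves as a weighted mean", {
  rates <- table1_rates()
  # single organ: its own rate
  expect_equal(organ_msbmr_mean(c(1, 0, 0, 0, 0, 0, 0), rates),
               unname(rates[1]))
  # equal weights: arithmetic mean
  expect_equal(organ_msbmr_mean(rep(2, 7), rates), mean(rates))
  # reference-male renormalized weights: about 22.16, not the printed
  # whole-body 24.59 (the tabulated organ rates undershoot it)
  p <- reference_organ_profile()
  expect_equal(organ_msbmr_mean(p$wk_r, p$msbmr_k), 22.16,
               tolerance = 1e-3)
  expect_error(organ_msbmr_mean(rep(0, 7), rates), "zero")
})

test_that("redistribution shares follow msBMR^-q and conserve mass", {
  rates <- table1_rates()
  # q = 0: equal split
  expect_equal(distribute_delta(7, rates, q = 0), rep(1, 7),
               ignore_attr = TRUE)
  # conservation to 1e-12 for arbitrary inputs
  for (d in c(3, -12.5, 0.001)) {
    expect_equal(sum(distribute_delta(d, rates, 1.15)), d,
                 tolerance = 1e-12)
  }
  # closed-form shares at q = 1.15 over 3 kg: adipose/residual/muscle
  # absorb almost all of it
  dk <- distribute_delta(3, rates, 1.15)
  expect_equal(unname(dk["adipose_tissue"]), 1.20, tolerance = 0.01)
  expect_equal(unname(dk["residual"]), 1.36, tolerance = 0.01)
  expect_equal(unname(dk["skeletal_muscle"]), 0.40, tolerance = 0.01)
})

test_that("fixture reference male matches the published calibration", {
  ref <- calibrate_reference()
  expect_equal(ref$W_r, 67.0)
  expect_equal(ref$age_r, 32)
  expect_equal(ref$H_r, 175.6)
  expect_equal(ref$msbmr_r, 24.59)
  expect_equal(sum(ref$w_k_r), 67.01, tolerance = 0.011)
  # the whole-body value is the decline evaluated at the reference age
  expect_equal(universal_decline(32), 24.59, tolerance = 0.005)
  # and the renormalized weight solves the HBE at that age/height
  expect_equal(second_renorm(175.6, 32)$weight, 67.0, tolerance = 0.1)
})

test_that("search-mode calibration finds a genuine fixed point", {
  ref <- calibrate_reference(mode = "search")
  expect_true(ref$age_r > 16 && ref$age_r < 106)
  expect_lt(abs(ref$residual), 0.01)
  # fixed-point condition: organ mean equals F at the calibrated age
  expect_equal(organ_msbmr_mean(ref$w_k_r, ref$rates),
               universal_decline(ref$age_r), tolerance = 1e-6)
  expect_equal(sum(ref$w_k_r), ref$W_r, tolerance = 1e-9)
})

test_that("search mode reports failure when no fixed point exists", {
  p <- reference_organ_profile()
  p$msbmr_k <- p$msbmr_k * 3 # organ mean everywhere above F(T)
  err <- tryCatch(calibrate_reference(p, mode = "search"),
                  error = function(e) e)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "no fixed point")
  expect_s3_class(err$residual_curve, "data.frame")
})

test_that("proportional decomposition reproduces the organ table", {
  ref <- calibrate_reference()
  s3 <- decompose_subject(170.0, 50, ref)
  s4 <- decompose_subject(157.7, 80, ref)
  expect_equal(s3$W, 64.38, tolerance = 0.02)
  expect_equal(s4$W, 53.92, tolerance = 0.02)

  wk_s3 <- c(skeletal_muscle = 26.39, liver = 1.71, brain = 1.33,
             heart = 0.31, kidneys = 0.29, adipose_tissue = 12.67,
             residual = 21.69)
  wk_s4 <- c(skeletal_muscle = 22.10, liver = 1.43, brain = 1.11,
             heart = 0.26, kidneys = 0.24, adipose_tissue = 10.61,
             residual = 18.16)
  expect_true(all(abs(s3$w_k[names(wk_s3)] - wk_s3) <= 0.011))
  expect_true(all(abs(s4$w_k[names(wk_s4)] - wk_s4) <= 0.011))

  # organ fractions are identical across subjects (the defining
  # condition of the decomposition)
  expect_equal(s3$w_k / s3$W, s4$w_k / s4$W, tolerance = 1e-12)
  expect_equal(s3$w_k / s3$W, ref$w_k_r / ref$W_r, tolerance = 1e-12)

  # the reference male decomposes to himself
  self <- decompose_subject(ref$H_r, ref$age_r, ref)
  expect_equal(self$w_k, ref$w_k_r * self$W / ref$W_r, tolerance = 1e-12)
  expect_equal(self$W, ref$W_r, tolerance = 0.1)
})

test_that("recorded weight splits back into original organ weights", {
  ref <- calibrate_reference()
  d <- decompose_subject(170.0, 50, ref, recorded_weight = 135.10)
  # conserved up to the 0.01-kg rounding of the organ-table column
  expect_lt(abs(sum(d$w0_k) - 135.10), 0.011)
  # the redistribution itself is exact: surplus deltas sum to the gap
  expect_equal(sum(d$w0_k - d$w_k), 135.10 - d$W, tolerance = 1e-12)
  expect_true(all(d$w0_k > 0))
  # a very light recorded weight drives low-rate organs negative
  expect_error(
    decompose_subject(170.0, 50, ref, recorded_weight = 20),
    "negative original organ weight")
})

test_that("organ decay constants average to the global u", {
  p <- reference_organ_profile()
  u_k <- organ_decay_constants()
  bmr_k <- p$wk_r * p$msbmr_k
  u_bar <- mean_decay_constant(bmr_k, u_k[p$organ])
  expect_equal(signif(u_bar, 2), 0.0037)
  expect_lt(abs(u_bar - 0.00364) / 0.00364, 0.01)

  # trivial aggregations
  expect_equal(mean_decay_constant(c(5, 3), c(0.002, 0.002)), 0.002)
  expect_equal(mean_decay_constant(c(7), c(0.0061)), 0.0061)
  expect_error(mean_decay_constant(c(0, 0), c(0.1, 0.1)), "zero")
})

test_that("organ trajectories decay exponentially at their own rate", {
  p <- reference_organ_profile()
  ms_liver <- p$msbmr_k[p$organ == "liver"]
  expect_equal(organ_trajectory("liver", 32), ms_liver)
  expect_equal(organ_trajectory("liver", 42),
               ms_liver * exp(-0.0624), tolerance = 1e-12)
  expect_error(organ_trajectory("spleen", 50), "unknown organ")

  # first-order consistency: the weighted trajectory sum 5 years out
  # matches the linearized whole-body decline within 0.1%
  ref <- calibrate_reference()
  u_k <- organ_decay_constants()[p$organ]
  T0 <- 32
  Tt <- 37
  traj <- vapply(p$organ, function(o) organ_trajectory(o, Tt),
                 numeric(1))
  lhs <- sum(ref$w_k_r * traj) / sum(ref$w_k_r)
  ms0 <- organ_msbmr_mean(ref$w_k_r, p$msbmr_k)
  u_bar <- mean_decay_constant(ref$w_k_r * p$msbmr_k, u_k)
  rhs <- ms0 * (1 - u_bar * (Tt - T0))
  expect_lt(abs(lhs - rhs) / rhs, 0.001)
})
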