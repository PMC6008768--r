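test_that("plasma parameter constructor enforces ordering invariants", {
  expect_error(plasma_biexp_params(1, 2, 0.01, 0.1), "lambda1 > lambdaz")
  expect_error(plasma_biexp_params(3, 2, 0.1, 0.01), "vz >= v1")
  expect_error(plasma_biexp_params(-1, 2, 0.1, 0.01), "positive")
  expect_s3_class(plasma_biexp_params(1, 2, 0.1, 0.01), "plasma_biexp_params")
})

test_that("infusion model satisfies structural identities on random draws", {
  for (s in 1:50) {
    p <- random_plasma_params(s)
    dose <- 7.1; T_inf <- 1 / 6
    # starts at zero and stays non-negative
    expect_identical(c_plasma_infusion(0, p, dose, T_inf), 0)
    tt <- c(seq(0.01, 5, length.out = 40), seq(6, 120, length.out = 40))
    cc <- c_plasma_infusion(tt, p, dose, T_inf)
    expect_true(all(cc >= 0))
    # continuity at the end of the infusion
    expect_equal(c_plasma_infusion(T_inf - 1e-9, p, dose, T_inf),
                 c_plasma_infusion(T_inf + 1e-9, p, dose, T_inf),
                 tolerance = 1e-5)
    # the concentration peaks at the end of the infusion
    expect_true(all(cc <= c_plasma_infusion(T_inf, p, dose, T_inf) * (1 + 1e-9)))
  }
})

test_that("AUC equals dose / (lambda_z Vz) against adaptive quadrature", {
  for (s in 1:50) {
    p <- random_plasma_params(100 + s)
    dose <- 10; T_inf <- 1 / 6
    auc <- stats::integrate(function(t) c_plasma_infusion(t, p, dose, T_inf),
                            0, Inf, rel.tol = 1e-9, abs.tol = 0)$value
    expect_equal(auc, dose / (p$lambdaz * p$vz), tolerance = 1e-6)
  }
})

test_that("bolus limit: C(T) -> dose / V1 as T -> 0", {
  p <- random_plasma_params(7)
  dose <- 5
  expect_equal(c_plasma_infusion(1e-8, p, dose, 1e-8), dose / p$v1,
               tolerance = 1e-5)
})

test_that("frame averages agree with numerical integration", {
  p <- random_plasma_params(3)
  fg <- default_frame_schedule()
  avg <- c_plasma_frame_avg(fg, p, 7.1, 1 / 6)
  for (i in c(1, 5, 12)) {
    num <- stats::integrate(function(t) c_plasma_infusion(t, p, 7.1, 1 / 6),
                            fg[i, 1], fg[i, 2], rel.tol = 1e-10)$value /
      (fg[i, 2] - fg[i, 1])
    expect_equal(avg[i], num, tolerance = 1e-8, ignore_attr = TRUE)
  }
  # an interval straddling the infusion end exercises both branches
  straddle <- c_plasma_frame_avg(rbind(c(0.05, 0.5)), p, 7.1, 1 / 6)
  num <- stats::integrate(function(t) c_plasma_infusion(t, p, 7.1, 1 / 6),
                          0.05, 0.5, rel.tol = 1e-10)$value / 0.45
  expect_equal(straddle[1], num, tolerance = 1e-8)
})

test_that("fit_plasma recovers noise-free parameters within 1 percent", {
  truth <- plasma_biexp_params(v1 = 1.49, vz = 2.66,
                               lambda1 = 0.121, lambdaz = 0.0210)
  scan <- make_test_scan(bw = 19, dose = 7.1)
  cp <- c_plasma_frame_avg(scan$frame_grid, truth, scan$dose_a0 * 1000,
                           scan$infusion_duration_T)
  fit <- fit_plasma(cp, scan, seed = 5)
  for (f in c("v1", "vz", "lambda1", "lambdaz"))
    expect_equal(fit[[f]], truth[[f]], tolerance = 1e-2)
  # the returned parameterisation always satisfies the ordering invariants
  expect_gt(fit$lambda1, fit$lambdaz)
  expect_gte(fit$vz, fit$v1)
})

test_that("fit_plasma requires at least 5 frames", {
  scan <- make_test_scan()
  short <- scan
  short$frame_grid <- scan$frame_grid[1:3, ]
  for (nm in names(short$curves))
    short$curves[[nm]]$values <- short$curves[[nm]]$values[1:3]
  expect_error(fit_plasma(c(1, 2, 3), short), "5 frames")
})

test_that("plasma-derived CL and half-life match the printed relationships", {
  # terminal-phase values from the second control column of the summary table
  p <- plasma_biexp_params(v1 = 2.3, vz = 9.4, lambda1 = 0.295,
                           lambdaz = 0.0270)
  d <- plasma_derived(p)
  expect_equal(d$cl, 253.8)                     # 0.0270 x 9.4 x 1000
  expect_equal(d$cl, 253, tolerance = 5e-3)     # printed rounding
  p2 <- plasma_biexp_params(v1 = 1.38, vz = 3.33, lambda1 = 0.139,
                            lambdaz = 0.0140)
  expect_equal(plasma_derived(p2)$t_half, log(2) / 0.0140)
  expect_equal(plasma_derived(p2)$t_half, 49.5, tolerance = 1e-3)
  # cl -> 0 as lambdaz -> 0
  p3 <- plasma_biexp_params(1, 5, 0.1, 1e-9)
  expect_lt(plasma_derived(p3)$cl, 1e-5)
})
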