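phys <- physiology_constants()

noise_free_prep <- function(preset = "mt107_control_like") {
  pres <- scenario_presets(noise_cv = 0)
  g <- generate_scan(pres[[preset]])
  list(prep = prepare_scan(g$scan), truth = g$truth, scan = g$scan)
}

truth_par <- function(truth) {
  stats::setNames(c(petpbpk:::.rate_vector(truth), truth$f_bt1, truth$v_tissue),
                  petpbpk:::.par_names)
}

test_that("objective is zero at the generating parameters and weights the
           early frames of plasma, liver and kidney by the squared factor", {
  nf <- noise_free_prep()
  cfg <- fit_config()
  base <- objective(nf$truth, nf$prep, cfg, phys)
  expect_lt(base, 1e-6)

  # a unit residual on the first plasma frame contributes 5^2
  bump <- nf$prep
  bump$a_plasma[1] <- bump$a_plasma[1] + 1
  expect_equal(objective(nf$truth, bump, cfg, phys) - base, 25,
               tolerance = 1e-4)
  # ... on the third plasma frame (past the weighted window), 1
  bump <- nf$prep
  bump$a_plasma[3] <- bump$a_plasma[3] + 1
  expect_equal(objective(nf$truth, bump, cfg, phys) - base, 1,
               tolerance = 1e-4)
  # ... on any gi frame, 1
  bump <- nf$prep
  bump$a_gi[1] <- bump$a_gi[1] + 1
  expect_equal(objective(nf$truth, bump, cfg, phys) - base, 1,
               tolerance = 1e-4)
})

test_that("initial bounds cap hepatic and renal uptake by plasma flow", {
  cfg <- fit_config()
  b <- initial_bounds(phys, 20, cfg)
  vp <- plasma_volume(20, phys)
  expect_equal(unname(b$upper["k_bh1"]), 1.0 / vp)   # 1.526 /min
  expect_equal(unname(b$upper["k_br1"]), 0.73 / vp)  # 1.114 /min
  expect_equal(unname(b$upper["k_bh1"]), 1.526, tolerance = 1e-3)
  expect_equal(unname(b$upper["k_br1"]), 1.114, tolerance = 1e-3)
  expect_true(all(b$lower[petpbpk:::.rate_names] == 0))
  # k_bg fixed at zero unless requested
  expect_identical(unname(b$upper["k_bg"]), 0)
  b2 <- initial_bounds(phys, 20, fit_config(fit_k_bg = TRUE))
  expect_gt(b2$upper["k_bg"], 0)
  expect_equal(unname(b$lower["v_tissue"]), 0.2 * 20)
  expect_equal(unname(b$upper["v_tissue"]), 1.5 * 20)
})

test_that("a single start at the truth converges to a ~zero objective", {
  nf <- noise_free_prep()
  fit <- multistart_fit(nf$prep, fit_config(n_starts = 1, seed = 1), phys,
                        starts = list(truth_par(nf$truth)))
  expect_lt(fit$objective, 1e-6)
})

test_that("multistart fit is deterministic given the seed", {
  pres <- scenario_presets(noise_cv = 0.05)
  g <- generate_scan(pres$mt107_control_like)
  prep <- prepare_scan(g$scan)
  cfg <- fit_config(n_starts = 4, seed = 99)
  f1 <- multistart_fit(prep, cfg, phys)
  f2 <- multistart_fit(prep, cfg, phys)
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$start_objectives, f2$start_objectives)
  expect_identical(unlist(f1$best_params), unlist(f2$best_params))
})

test_that("best objective is non-increasing in the number of starts", {
  pres <- scenario_presets(noise_cv = 0.05)
  g <- generate_scan(pres$mt107_cyclosporine_like)
  prep <- prepare_scan(g$scan)
  b <- initial_bounds(phys, g$scan$body_weight, fit_config())
  starts6 <- petpbpk:::.draw_starts(6, b, 5)
  f3 <- multistart_fit(prep, fit_config(n_starts = 3), phys,
                       starts = starts6[1:3])
  f6 <- multistart_fit(prep, fit_config(n_starts = 6), phys, starts = starts6)
  expect_lte(f6$objective, f3$objective)
})

test_that("noise-free multistart recovers the clearance functionals", {
  nf <- noise_free_prep("mt107_cyclosporine_like")
  fit <- multistart_fit(nf$prep, fit_config(n_starts = 8, seed = 42), phys)
  dt <- derive_all(nf$truth, nf$scan, phys)
  df <- derive_all(fit$best_params, nf$scan, phys)
  expect_equal(df$cl_h, dt$cl_h, tolerance = 0.1)
  expect_equal(df$cl_r, dt$cl_r, tolerance = 0.1)
  expect_equal(df$d_tissue, dt$d_tissue, tolerance = 0.1)
})

test_that("refine_bounds applies the 0.5x / 2x rule per parameter", {
  fake_fit <- function(kb) structure(list(best_params = kb), class = "pbpk_fit")
  k1 <- rate_constant_set(k_bh1 = 0.02, k_h1b = 0.1, v_tissue = 10)
  k2 <- rate_constant_set(k_bh1 = 0.08, k_h1b = 0.4, v_tissue = 20)
  b <- refine_bounds(list(fake_fit(k1), fake_fit(k2)))
  expect_equal(unname(b$lower["k_bh1"]), 0.01)
  expect_equal(unname(b$upper["k_bh1"]), 0.16)
  expect_equal(unname(b$lower["k_h1b"]), 0.05)
  expect_equal(unname(b$upper["k_h1b"]), 0.8)
  # single result
  b1 <- refine_bounds(list(fake_fit(rate_constant_set(k_br1 = 0.04))))
  expect_equal(unname(b1$lower["k_br1"]), 0.02)
  expect_equal(unname(b1$upper["k_br1"]), 0.08)
  # a parameter fixed at zero stays fixed
  expect_identical(unname(b$lower["k_bg"]), 0)
  expect_identical(unname(b$upper["k_bg"]), 0)
  # fractions stay inside [0, 1]
  expect_lte(b$upper["f_bt1"], 1)
  expect_error(refine_bounds(list()), "empty")
})
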