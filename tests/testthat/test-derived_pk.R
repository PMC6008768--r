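phys <- physiology_constants()
vp20 <- plasma_volume(20, phys)

test_that("hepatic clearance limits and symmetry", {
  k <- rate_constant_set(k_bh1 = 0.08, k_h1b = 1e-7, k_h1h2 = 0.1)
  expect_equal(cl_hepatic(k, vp20), 0.08 * vp20 * 1000, tolerance = 1e-5)
  k2 <- rate_constant_set(k_bh1 = 0.08, k_h1b = 0.1, k_h1h2 = 0.1)
  expect_equal(cl_hepatic(k2, vp20), 0.08 / 2 * vp20 * 1000)
  expect_equal(cl_hepatic(rate_constant_set(), vp20), 0)
  expect_error(cl_hepatic(rate_constant_set(k_bh1 = 0.1), vp20), "k_h1b")
})

test_that("renal clearance collapses to the single-compartment form when
           the deep compartment is disconnected", {
  k <- rate_constant_set(k_br1 = 0.04, k_r1b = 0.05, k_r1u = 0.1)
  expect_equal(cl_renal(k, vp20), 0.04 * 0.1 / 0.15 * vp20 * 1000)
  # uptake-limited: everything taken up is excreted
  k2 <- rate_constant_set(k_br1 = 0.04, k_r1b = 1e-8, k_r1u = 10)
  expect_equal(cl_renal(k2, vp20), 0.04 * vp20 * 1000, tolerance = 1e-6)
  expect_error(cl_renal(rate_constant_set(k_br1 = 1, k_r1r2 = 0.1, k_r1u = 1),
                        vp20), "irreversible trap")
})

test_that("clearances are bounded by uptake and monotone in the rates", {
  for (s in 1:20) {
    k <- random_rate_set(500 + s)
    expect_lte(cl_hepatic(k, vp20), k$k_bh1 * vp20 * 1000 + 1e-9)
    expect_lte(cl_renal(k, vp20), k$k_br1 * vp20 * 1000 + 1e-9)
    bump <- function(kk, field, f) { kk[[field]] <- kk[[field]] * f; kk }
    expect_gt(cl_hepatic(bump(k, "k_h1h2", 1.5), vp20), cl_hepatic(k, vp20))
    expect_lt(cl_hepatic(bump(k, "k_h1b", 1.5), vp20), cl_hepatic(k, vp20))
    expect_gt(cl_renal(bump(k, "k_r1u", 1.5), vp20), cl_renal(k, vp20))
    expect_gt(cl_renal(bump(k, "k_r2r1", 1.5), vp20), cl_renal(k, vp20))
    expect_lt(cl_renal(bump(k, "k_r1b", 1.5), vp20), cl_renal(k, vp20))
    expect_lt(cl_renal(bump(k, "k_r1r2", 1.5), vp20), cl_renal(k, vp20))
  }
})

test_that("hepatic clearance equals the steady-state flux into gi over the
           steady-state plasma concentration", {
  for (s in 1:20) {
    k <- random_rate_set(600 + s)
    k$k_gh1 <- 0  # gi absorbing: hepatic throughput fully reaches gi
    ss <- oracle_steady_state(k, rate_in = 1)
    cl_ss <- k$k_h2g * ss[["H2"]] / (ss[["B"]] / vp20) * 1000
    expect_equal(cl_hepatic(k, vp20), cl_ss, tolerance = 5e-3)
  }
})

test_that("renal formula relates to the steady-state urinary clearance by the
           exact mass-ratio factor", {
  # The printed formula applies the 1/(1 + rho) correction (rho =
  # k_r1r2/k_r2r1) to the urinary rate only. At steady state rho cancels:
  # flux_U / C_plasma = k_br1 k_r1u / (k_r1b + k_r1u) V_Plasma. The ratio of
  # the two is (k_r1b + k_r1u) / (k_r1b (1 + rho) + k_r1u), 1 iff rho = 0.
  for (s in 1:20) {
    k <- random_rate_set(700 + s)
    ss <- oracle_steady_state(k, rate_in = 1)
    cl_ss <- k$k_r1u * ss[["R1"]] / (ss[["B"]] / vp20) * 1000
    expect_equal(cl_ss, k$k_br1 * k$k_r1u / (k$k_r1b + k$k_r1u) * vp20 * 1000,
                 tolerance = 1e-6)
    rho <- k$k_r1r2 / k$k_r2r1
    expect_equal(cl_renal(k, vp20) / cl_ss,
                 (k$k_r1b + k$k_r1u) / (k$k_r1b * (1 + rho) + k$k_r1u),
                 tolerance = 1e-6)
    # with the deep compartment disconnected the formula is the steady state
    k0 <- k; k0$k_r1r2 <- 0
    ss0 <- oracle_steady_state(k0, rate_in = 1)
    expect_equal(cl_renal(k0, vp20),
                 k0$k_r1u * ss0[["R1"]] / (ss0[["B"]] / vp20) * 1000,
                 tolerance = 5e-3)
  }
})

test_that("tissue distribution coefficient matches the no-elimination
           equilibrium partition", {
  expect_equal(d_tissue(rate_constant_set(k_bt = 0.3, k_tb1 = 0.15,
                                          f_bt1 = 1, v_tissue = 14.8), vp20),
               (0.3 / 0.15) * vp20 / 14.8)
  # equal efflux rates make the split fraction irrelevant
  for (f in c(0.1, 0.5, 0.9))
    expect_equal(d_tissue(rate_constant_set(k_bt = 0.3, k_tb1 = 0.2,
                                            k_tb2 = 0.2, f_bt1 = f,
                                            v_tissue = 10), vp20),
                 (0.3 / 0.2) * vp20 / 10)
  expect_error(d_tissue(rate_constant_set(k_bt = 0.3, k_tb1 = 0, f_bt1 = 1),
                        vp20), "efflux")
  # ODE equilibrium oracle: closed system (no elimination) converges to the
  # algebraic partition
  scan <- make_test_scan(bw = 20)
  for (s in 1:5) {
    k <- random_rate_set(800 + s)
    # close the system: no irreversible hepatic step, no urinary output
    k$k_h1h2 <- 0; k$k_h2g <- 0; k$k_r1u <- 0; k$k_bg <- 0
    traj <- simulate_pbpk(k, scan, phys, times = c(0, 4000))
    a <- traj$amounts[2, ]
    ratio <- ((a[["T1"]] + a[["T2"]]) / k$v_tissue) / (a[["B"]] / vp20)
    expect_equal(d_tissue(k, vp20), ratio, tolerance = 5e-3)
  }
})

test_that("derive_all assembles extraction ratio and flow-referenced ratios", {
  # construct rate sets whose clearances equal the printed group means
  make_k <- function(cl_h, cl_r, vp) {
    rate_constant_set(k_bh1 = cl_h / 1000 / vp, k_h1b = 0, k_h1h2 = 0.1,
                      k_br1 = cl_r / 1000 / vp, k_r1b = 0, k_r1u = 0.1)
  }
  scan <- make_test_scan(bw = 19)
  vp <- plasma_volume(19, phys)
  d <- derive_all(make_k(35.2, 11.9, vp), scan, phys)
  expect_equal(d$cl_h, 35.2, tolerance = 1e-9)
  expect_equal(d$e_h, 0.0352)
  expect_equal(d$e_h, 0.035, tolerance = 6e-3)          # printed precision
  expect_equal(d$cl_r_over_gfr, 11.9 / 160)
  expect_equal(d$cl_r_over_gfr, 0.074, tolerance = 6e-3)
  expect_equal(d$cl_ti, 0)
  expect_equal(d$cl_total, d$cl_h + d$cl_r)
  # with transintestinal excretion the total includes k_bg V_Plasma
  k <- make_k(30, 10, vp); k$k_bg <- 0.01
  d2 <- derive_all(k, scan, phys)
  expect_equal(d2$cl_ti, 0.01 * vp * 1000)
  expect_equal(d2$cl_total, d2$cl_h + d2$cl_r + d2$cl_ti)
  # E_H stays in [0, 1] whenever uptake respects the flow bound
  for (s in 1:10) {
    k <- random_rate_set(900 + s)
    k$k_bh1 <- min(k$k_bh1, phys$q_p_hepatic / vp)
    eh <- derive_all(k, scan, phys)$e_h
    expect_gte(eh, 0); expect_lte(eh, 1)
  }
})

test_that("pooled-variance t-test matches stats::t.test and handles
           degenerate variance", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  cm <- compare_groups(a, b)
  or <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(cm$t, unname(or$statistic))
  expect_equal(cm$p, or$p.value)
  expect_identical(cm$df, 6L)
  expect_false(cm$significant)
  # random draws against the reference implementation
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(7, mean = runif(1, 0, 3))
    cm <- compare_groups(x, y)
    or <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(cm$t, unname(or$statistic))
    expect_equal(cm$p, or$p.value)
  }
  # identical groups
  cm0 <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cm0$t, 0); expect_equal(cm0$p, 1)
  # large shift drives p to zero
  expect_lt(compare_groups(c(1, 2, 3), c(1, 2, 3) + 100)$p, 1e-6)
  # zero pooled variance
  expect_equal(compare_groups(c(2, 2), c(2, 2))$p, 1)
  deg <- compare_groups(c(1, 1), c(2, 2))
  expect_equal(deg$p, 0); expect_true(deg$degenerate)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
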