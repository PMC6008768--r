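# Independent oracles and fixture builders. The transfer matrix here is
# written out from the model diagram by hand, on purpose: it must not share
# code with the package's ODE right-hand side.

oracle_transfer_matrix <- function(k) {
  M <- matrix(0, 9, 9)
  rn <- c("B", "H1", "H2", "G", "R1", "R2", "T1", "T2", "U")
  dimnames(M) <- list(rn, rn)
  M["B", "B"] <- -(k$k_bh1 + k$k_br1 + k$k_bg + k$k_bt)
  M["B", "H1"] <- k$k_h1b
  M["B", "R1"] <- k$k_r1b
  M["B", "T1"] <- k$k_tb1
  M["B", "T2"] <- k$k_tb2
  M["H1", "B"] <- k$k_bh1
  M["H1", "G"] <- k$k_gh1
  M["H1", "H1"] <- -(k$k_h1b + k$k_h1h2)
  M["H2", "H1"] <- k$k_h1h2
  M["H2", "H2"] <- -k$k_h2g
  M["G", "H2"] <- k$k_h2g
  M["G", "B"] <- k$k_bg
  M["G", "G"] <- -k$k_gh1
  M["R1", "B"] <- k$k_br1
  M["R1", "R2"] <- k$k_r2r1
  M["R1", "R1"] <- -(k$k_r1b + k$k_r1r2 + k$k_r1u)
  M["R2", "R1"] <- k$k_r1r2
  M["R2", "R2"] <- -k$k_r2r1
  M["T1", "B"] <- k$f_bt1 * k$k_bt
  M["T1", "T1"] <- -k$k_tb1
  M["T2", "B"] <- (1 - k$f_bt1) * k$k_bt
  M["T2", "T2"] <- -k$k_tb2
  M["U", "R1"] <- k$k_r1u
  M
}

# matrix-exponential solution of the linear system with constant infusion
# dose/T_inf on [0, T_inf]: augment the state with a constant-1 input channel
oracle_expm_solution <- function(k, dose, T_inf, times) {
  M <- oracle_transfer_matrix(k)
  u <- c(dose / T_inf, rep(0, 8))
  Maug <- rbind(cbind(M, u), 0)
  state_at <- function(t) {
    if (t <= T_inf) {
      x <- as.matrix(Matrix::expm(Maug * t)) %*% c(rep(0, 9), 1)
      x[1:9]
    } else {
      xT <- state_at(T_inf)
      as.vector(as.matrix(Matrix::expm(M * (t - T_inf))) %*% xT)
    }
  }
  out <- t(vapply(times, state_at, numeric(9)))
  colnames(out) <- rownames(M)
  out
}

# steady state under constant infusion rate_in into B; drops U (absorbing)
# and optionally G (absorbing when k_gh1 = 0)
oracle_steady_state <- function(k, rate_in = 1) {
  M <- oracle_transfer_matrix(k)
  keep <- c("B", "H1", "H2", "R1", "R2", "T1", "T2")
  if (k$k_gh1 > 0) keep <- c(keep, "G")
  Ms <- M[keep, keep]
  u <- stats::setNames(numeric(length(keep)), keep)
  u["B"] <- rate_in
  stats::setNames(solve(Ms, -u), keep)
}

# a random fully-connected rate set with moderate magnitudes
random_rate_set <- function(seed) {
  set.seed(seed)
  r <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  rate_constant_set(
    k_bh1 = r(0.01, 0.5), k_h1b = r(0.01, 0.5), k_h1h2 = r(0.01, 0.5),
    k_h2g = r(0.01, 0.5), k_gh1 = r(0.001, 0.1), k_bg = 0,
    k_br1 = r(0.01, 0.5), k_r1b = r(0.01, 0.5), k_r1r2 = r(0.01, 0.5),
    k_r2r1 = r(0.01, 0.5), k_r1u = r(0.01, 0.5),
    k_bt = r(0.05, 0.8), k_tb1 = r(0.02, 0.5), k_tb2 = r(0.02, 0.5),
    f_bt1 = stats::runif(1, 0.2, 0.8), v_tissue = stats::runif(1, 8, 25))
}

# Draws satisfy the physical realizability condition lambda1 V1 >= lambdaz Vz
# (equivalently CL <= lambda1 V1), which together with lambda1 > lambdaz and
# Vz >= V1 guarantees C(t) >= 0; ordering alone does not.
random_plasma_params <- function(seed) {
  set.seed(seed)
  lz <- exp(stats::runif(1, log(0.005), log(0.05)))
  l1 <- lz + exp(stats::runif(1, log(0.05), log(0.5)))
  v1 <- exp(stats::runif(1, log(0.5), log(5)))
  vz <- v1 * stats::runif(1, 1.05, min(5, 0.9 * l1 / lz))
  plasma_biexp_params(v1, vz, l1, lz)
}

# small scan skeleton used where only metadata and frames matter
make_test_scan <- function(n_frames = 12, bw = 19, dose = 7.1,
                           curves = NULL, group = "control") {
  fg <- default_frame_schedule()[seq_len(n_frames), , drop = FALSE]
  if (is.null(curves)) {
    v <- seq(1, 2, length.out = n_frames)
    curves <- list(
      blood = list(values = v, kind = "conc"),
      liver = list(values = 2 * v, kind = "conc"),
      gi = list(values = 3 * v, kind = "amount"),
      kidney = list(values = v / 2, kind = "conc"),
      tissue = list(values = v / 3, kind = "conc"))
  }
  scan_record("test-scan", bw, dose, fg, curves, group_label = group)
}
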