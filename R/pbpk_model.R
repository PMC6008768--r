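# Whole-body compartment model: plasma (B), liver (H1 reversible, H2
# irreversible), gallbladder + intestine (G), kidneys (R1, R2), peripheral
# tissue (T1, T2) and urine (U). All transfers are first order; tracer enters
# B as a constant infusion of duration T. k_BG (plasma -> intestine,
# transintestinal excretion) is 0 in the default configuration.

# canonical rate-constant order shared with src/pbpk_ode.cpp
.rate_names <- c("k_bh1", "k_h1b", "k_h1h2", "k_h2g", "k_gh1", "k_bg",
                 "k_br1", "k_r1b", "k_r1r2", "k_r2r1", "k_r1u",
                 "k_bt", "k_tb1", "k_tb2")

.compartment_names <- c("B", "H1", "H2", "G", "R1", "R2", "T1", "T2", "U")

#' Mass-transfer rate constants of the whole-body model
#'
#' All rate constants are first-order (1/min); indices name source and
#' target compartment (e.g. \code{k_bh1}: plasma to reversible hepatic
#' compartment). \code{k_bt} is the total plasma-to-tissue rate, split
#' between the two tissue sub-compartments by the fraction \code{f_bt1}.
#' \code{v_tissue} is the peripheral tissue volume (cm^3), estimated during
#' fitting.
#'
#' @param k_bh1,k_h1b,k_h1h2,k_h2g,k_gh1,k_bg Hepatic/intestinal transfer
#'   rates, 1/min: plasma->H1, H1->plasma, H1->H2, H2->G, G->H1
#'   (enterohepatic reabsorption), plasma->G (transintestinal, default 0).
#' @param k_br1,k_r1b,k_r1r2,k_r2r1,k_r1u Renal transfer rates, 1/min.
#' @param k_bt,k_tb1,k_tb2 Tissue exchange rates, 1/min.
#' @param f_bt1 Fraction of \code{k_bt} routed to tissue compartment 1.
#' @param v_tissue Peripheral tissue volume, cm^3 (> 0).
#' @return An object of class \code{rate_constant_set}.
#' @export
rate_constant_set <- function(k_bh1 = 0, k_h1b = 0, k_h1h2 = 0, k_h2g = 0,
                              k_gh1 = 0, k_bg = 0,
                              k_br1 = 0, k_r1b = 0, k_r1r2 = 0, k_r2r1 = 0,
                              k_r1u = 0,
                              k_bt = 0, k_tb1 = 0, k_tb2 = 0,
                              f_bt1 = 0.5, v_tissue = 14.8) {
  k <- c(k_bh1 = k_bh1, k_h1b = k_h1b, k_h1h2 = k_h1h2, k_h2g = k_h2g,
         k_gh1 = k_gh1, k_bg = k_bg, k_br1 = k_br1, k_r1b = k_r1b,
         k_r1r2 = k_r1r2, k_r2r1 = k_r2r1, k_r1u = k_r1u,
         k_bt = k_bt, k_tb1 = k_tb1, k_tb2 = k_tb2)
  if (any(!is.finite(k)) || any(k < 0))
    stop("rate_constant_set: rate constants must be finite and >= 0")
  if (!is.finite(f_bt1) || f_bt1 < 0 || f_bt1 > 1)
    stop("rate_constant_set: f_bt1 must lie in [0, 1]")
  if (!is.finite(v_tissue) || v_tissue <= 0)
    stop("rate_constant_set: v_tissue must be positive (cm^3)")
  structure(c(as.list(k), list(f_bt1 = f_bt1, v_tissue = v_tissue)),
            class = "rate_constant_set")
}

#' @export
print.rate_constant_set <- function(x, ...) {
  cat("Rate constants (1/min):\n")
  k <- unlist(x[.rate_names])
  print(round(k, 5))
  cat(sprintf("f_bt1 %.3f, V_Tissue %.2f cm^3\n", x$f_bt1, x$v_tissue))
  invisible(x)
}

# numeric vector of the 14 rates in canonical order
.rate_vector <- function(k) {
  stopifnot(inherits(k, "rate_constant_set"))
  unlist(k[.rate_names], use.names = FALSE)
}

#' Build a rate_constant_set from a named numeric vector
#'
#' @param v Named numeric vector with entries for the 14 rate constants
#'   plus \code{f_bt1} and \code{v_tissue} (missing rates default to 0).
#' @return A \code{rate_constant_set}.
#' @export
rate_constant_set_from_vector <- function(v) {
  args <- as.list(v[intersect(names(v), c(.rate_names, "f_bt1", "v_tissue"))])
  do.call(rate_constant_set, args)
}

#' Right-hand side of the compartment ODE system
#'
#' Amount derivatives for state (B, H1, H2, G, R1, R2, T1, T2, U) under the
#' first-order mass-transfer model, with constant input dose/T into plasma
#' for t <= T. Exposed mainly for inspection and testing; simulation uses a
#' compiled adaptive integrator.
#'
#' @param state Named or ordered numeric vector of 9 compartment amounts.
#' @param t Time, min.
#' @param k A \code{\link{rate_constant_set}}.
#' @param dose Dose A(0).
#' @param T_inf Infusion duration, min.
#' @return Numeric vector of 9 derivatives.
#' @export
ode_rhs <- function(state, t, k, dose, T_inf) {
  stopifnot(inherits(k, "rate_constant_set"))
  if (length(state) != 9L) stop("ode_rhs: state must have 9 components")
  if (any(state < 0)) stop("ode_rhs: negative compartment amount")
  input <- if (t >= 0 && t <= T_inf) dose / T_inf else 0
  B <- state[1]; H1 <- state[2]; H2 <- state[3]; G <- state[4]
  R1 <- state[5]; R2 <- state[6]; T1 <- state[7]; T2 <- state[8]
  with(k, c(
    B = input - (k_bh1 + k_br1 + k_bg + k_bt) * B +
        k_h1b * H1 + k_r1b * R1 + k_tb1 * T1 + k_tb2 * T2,
    H1 = k_bh1 * B + k_gh1 * G - (k_h1b + k_h1h2) * H1,
    H2 = k_h1h2 * H1 - k_h2g * H2,
    G = k_h2g * H2 + k_bg * B - k_gh1 * G,
    R1 = k_br1 * B + k_r2r1 * R2 - (k_r1b + k_r1r2 + k_r1u) * R1,
    R2 = k_r1r2 * R1 - k_r2r1 * R2,
    T1 = f_bt1 * k_bt * B - k_tb1 * T1,
    T2 = (1 - f_bt1) * k_bt * B - k_tb2 * T2,
    U = k_r1u * R1))
}

#' Transfer matrix of the compartment system
#'
#' The 9 x 9 matrix M with d(state)/dt = M state + input e_B. Useful for
#' linear-algebra analyses (steady states, eigen-decomposition).
#'
#' @param k A \code{\link{rate_constant_set}}.
#' @return A 9 x 9 matrix with dimnames B..U.
#' @export
transfer_matrix <- function(k) {
  stopifnot(inherits(k, "rate_constant_set"))
  M <- matrix(0, 9, 9, dimnames = list(.compartment_names, .compartment_names))
  with(k, {
    M["B", "B"] <<- -(k_bh1 + k_br1 + k_bg + k_bt)
    M["B", "H1"] <<- k_h1b; M["B", "R1"] <<- k_r1b
    M["B", "T1"] <<- k_tb1; M["B", "T2"] <<- k_tb2
    M["H1", "B"] <<- k_bh1; M["H1", "G"] <<- k_gh1
    M["H1", "H1"] <<- -(k_h1b + k_h1h2)
    M["H2", "H1"] <<- k_h1h2; M["H2", "H2"] <<- -k_h2g
    M["G", "H2"] <<- k_h2g; M["G", "B"] <<- k_bg; M["G", "G"] <<- -k_gh1
    M["R1", "B"] <<- k_br1; M["R1", "R2"] <<- k_r2r1
    M["R1", "R1"] <<- -(k_r1b + k_r1r2 + k_r1u)
    M["R2", "R1"] <<- k_r1r2; M["R2", "R2"] <<- -k_r2r1
    M["T1", "B"] <<- f_bt1 * k_bt; M["T1", "T1"] <<- -k_tb1
    M["T2", "B"] <<- (1 - f_bt1) * k_bt; M["T2", "T2"] <<- -k_tb2
    M["U", "R1"] <<- k_r1u
  })
  M
}

#' Simulate the whole-body model
#'
#' Integrates the compartment system from zero initial amounts through the
#' requested times with a compiled adaptive Dormand-Prince 5(4) integrator
#' (relative tolerance 1e-8 by default); the infusion discontinuity at T is
#' a split point, never interior to a step. Cumulative hepatobiliary
#' (H2->G), reabsorbed (G->H1) and transintestinal (B->G) fluxes are
#' integrated as auxiliary states.
#'
#' @param k A \code{\link{rate_constant_set}}.
#' @param scan A \code{\link{scan_record}} (dose, infusion duration, frames).
#' @param phys A \code{\link{physiology_constants}} (kept for interface
#'   symmetry; the state equations need no physiology).
#' @param times Output times in min; default a dense grid with >= 21 points
#'   per frame from 0 to the last frame end.
#' @param rtol,atol Integrator tolerances.
#' @return Object of class \code{state_trajectory}: list with \code{times},
#'   amounts matrix (columns B..U), and cumulative flux columns
#'   \code{cum_h2g}, \code{cum_gh1}, \code{cum_bg}. Dose is in the scan's
#'   dose unit (kBq internally: MBq x 1000).
#' @export
simulate_pbpk <- function(k, scan, phys = physiology_constants(),
                          times = NULL, rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(k, "rate_constant_set"))
  validate_scan_record(scan)
  dose_kBq <- scan$dose_a0 * 1000
  if (is.null(atol)) atol <- 1e-10 * dose_kBq
  if (is.null(times)) times <- dense_times(scan$frame_grid, npts = 21)
  sol <- .solve_pbpk_cpp(.rate_vector(k), k$f_bt1, times, dose_kBq,
                         scan$infusion_duration_T, rtol, atol)
  structure(list(times = times,
                 amounts = sol[, .compartment_names, drop = FALSE],
                 cum_h2g = sol[, "cum_h2g"],
                 cum_gh1 = sol[, "cum_gh1"],
                 cum_bg = sol[, "cum_bg"],
                 dose = dose_kBq,
                 infusion_duration_T = scan$infusion_duration_T,
                 k = k),
            class = "state_trajectory")
}

# dense time grid covering [0, last frame end] with npts points per frame and
# a coarse pre-scan segment (needed so trajectories start at t = 0)
dense_times <- function(frame_grid, npts = 21) {
  fg <- as.matrix(frame_grid)
  pre <- seq(0, fg[1, 1], length.out = 11L)
  per_frame <- lapply(seq_len(nrow(fg)), function(i)
    seq(fg[i, 1], fg[i, 2], length.out = npts))
  sort(unique(c(pre, unlist(per_frame))))
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("State trajectory: %d time points, %.2f-%.2f min, dose %.0f kBq\n",
              length(x$times), min(x$times), max(x$times), x$dose))
  invisible(x)
}

#' Frame-averaged observed regional amounts from a trajectory
#'
#' Applies the observation model: plasma = B; liver = H1 + H2 + vascular
#' term; kidney = R1 + R2 + vascular term; tissue = T1 + T2 + vascular
#' term; gi = G; urine = U. Vascular terms are v_blood x organ volume x
#' C_blood(t) with C_blood = (B/V_Plasma)(1 - hematocrit); gi and urine
#' carry none. Each curve is averaged over every frame by the trapezoid
#' rule on the trajectory grid.
#'
#' @param traj A \code{\link{simulate_pbpk}} trajectory covering the frames.
#' @param k The \code{rate_constant_set} (supplies v_tissue).
#' @param scan The \code{scan_record} (frame grid, body weight).
#' @param phys A \code{\link{physiology_constants}}.
#' @return Matrix n_frames x 6 (plasma, liver, gi, kidney, tissue, urine),
#'   amounts in kBq.
#' @export
observe <- function(traj, k, scan, phys = physiology_constants()) {
  stopifnot(inherits(traj, "state_trajectory"), inherits(k, "rate_constant_set"))
  fg <- scan$frame_grid
  tt <- traj$times
  if (min(tt) > fg[1, 1] + 1e-9 || max(tt) < fg[nrow(fg), 2] - 1e-9)
    stop("observe: trajectory does not cover the frame grid")
  bw <- scan$body_weight
  v_plasma <- plasma_volume(bw, phys)
  A <- traj$amounts
  c_blood <- (A[, "B"] / v_plasma) * (1 - phys$hematocrit)
  curves <- cbind(
    plasma = A[, "B"],
    liver = A[, "H1"] + A[, "H2"] +
      phys$v_blood * (phys$v_liver * bw) * c_blood,
    gi = A[, "G"],
    kidney = A[, "R1"] + A[, "R2"] +
      phys$v_blood * (phys$v_kidney * bw) * c_blood,
    tissue = A[, "T1"] + A[, "T2"] + phys$v_blood * k$v_tissue * c_blood,
    urine = A[, "U"])
  out <- matrix(NA_real_, nrow(fg), ncol(curves),
                dimnames = list(NULL, colnames(curves)))
  for (i in seq_len(nrow(fg))) {
    sel <- which(tt >= fg[i, 1] - 1e-9 & tt <= fg[i, 2] + 1e-9)
    if (length(sel) < 2L)
      stop("observe: fewer than 2 trajectory points in frame ", i,
           "; use a denser time grid")
    for (j in seq_len(ncol(curves)))
      out[i, j] <- trapz_mean(tt[sel], curves[sel, j])
  }
  out
}

#' End-of-scan excretion bookkeeping
#'
#' Splits the excreted radioactivity at the end of the trajectory into the
#' renal route (urine amount), the cumulative hepatobiliary flux (H2 -> G),
#' the cumulative reabsorbed flux (G -> H1, enterohepatic recirculation) and
#' the cumulative transintestinal flux (B -> G).
#'
#' @param traj A \code{\link{simulate_pbpk}} trajectory.
#' @return Named list: \code{hepatobiliary}, \code{renal},
#'   \code{reabsorbed}, \code{transintestinal} (kBq, at the last time).
#' @export
excretion_split <- function(traj) {
  stopifnot(inherits(traj, "state_trajectory"))
  n <- length(traj$times)
  list(hepatobiliary = traj$cum_h2g[n],
       renal = traj$amounts[n, "U"][[1]],
       reabsorbed = traj$cum_gh1[n],
       transintestinal = traj$cum_bg[n])
}
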