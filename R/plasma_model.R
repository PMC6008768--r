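# Closed-form two-compartment model for plasma kinetics after a short
# zero-order infusion, its least-squares fit, and plasma-derived PK.

#' Parameters of the biexponential infusion plasma model
#'
#' The two-compartment disposition model with a zero-order infusion of
#' duration T has the plasma solution
#' C(t) = (A0/T) * sum_i (B_i/lambda_i) (1 - e^{-lambda_i tau}) e^{-lambda_i (t-T)+}
#' with tau = min(t, T), bolus coefficients
#' B_1 = lambda_1 (1/V_z - 1/V_1) / (lambda_z - lambda_1) and
#' B_z = (lambda_z/V_1 - lambda_1/V_z) / (lambda_z - lambda_1),
#' central volume V_1, terminal-phase volume V_z and rate constants
#' lambda_1 > lambda_z. B_1 + B_z = 1/V_1, so a bolus dilutes into V_1.
#'
#' @param v1 Central volume of distribution, ml (> 0).
#' @param vz Terminal-phase volume of distribution, ml (>= v1).
#' @param lambda1 Fast rate constant, 1/min.
#' @param lambdaz Terminal rate constant, 1/min (< lambda1).
#' @return An object of class \code{plasma_biexp_params}.
#' @export
plasma_biexp_params <- function(v1, vz, lambda1, lambdaz) {
  vals <- c(v1 = v1, vz = vz, lambda1 = lambda1, lambdaz = lambdaz)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("plasma_biexp_params: all parameters must be positive and finite")
  if (lambda1 <= lambdaz)
    stop("plasma_biexp_params: need lambda1 > lambdaz")
  if (vz < v1)
    stop("plasma_biexp_params: need vz >= v1")
  structure(list(v1 = v1, vz = vz, lambda1 = lambda1, lambdaz = lambdaz),
            class = "plasma_biexp_params")
}

#' @export
print.plasma_biexp_params <- function(x, ...) {
  cat(sprintf("Biexponential infusion model: V1 %.3g ml, Vz %.3g ml, lambda1 %.4g /min, lambdaz %.4g /min\n",
              x$v1, x$vz, x$lambda1, x$lambdaz))
  invisible(x)
}

.biexp_coefs <- function(p) {
  dl <- p$lambdaz - p$lambda1
  if (abs(dl) < 1e-12)
    stop("c_plasma_infusion: lambda1 == lambdaz is a degenerate parameter set")
  list(b1 = p$lambda1 * (1 / p$vz - 1 / p$v1) / dl,
       bz = (p$lambdaz / p$v1 - p$lambda1 / p$vz) / dl)
}

#' Plasma concentration under a zero-order infusion
#'
#' Evaluates the closed-form two-compartment infusion solution at times
#' \code{t}; C(0) = 0, C rises during the infusion and decays
#' biexponentially afterwards. For dose in MBq the result is in MBq/ml.
#'
#' @param t Time(s) post injection-start, min (>= 0).
#' @param p A \code{\link{plasma_biexp_params}} object.
#' @param dose Dose A(0) (MBq, or any activity unit).
#' @param T_inf Infusion duration, min (> 0).
#' @return Concentration(s), dose-unit per ml.
#' @export
c_plasma_infusion <- function(t, p, dose, T_inf) {
  stopifnot(inherits(p, "plasma_biexp_params"))
  if (any(t < 0)) stop("c_plasma_infusion: t must be >= 0")
  if (T_inf <= 0) stop("c_plasma_infusion: T_inf must be > 0")
  cf <- .biexp_coefs(p)
  tau <- pmin(t, T_inf)
  tp <- pmax(t - T_inf, 0)
  (dose / T_inf) *
    (cf$b1 / p$lambda1 * (1 - exp(-p$lambda1 * tau)) * exp(-p$lambda1 * tp) +
     cf$bz / p$lambdaz * (1 - exp(-p$lambdaz * tau)) * exp(-p$lambdaz * tp))
}

# Exact integral of c_plasma_infusion over [a, b]; used for frame averaging.
.c_plasma_integral <- function(a, b, p, dose, T_inf) {
  cf <- .biexp_coefs(p)
  s <- dose / T_inf
  one <- function(lam, B) {
    # antiderivative pieces on [0,T] and (T, Inf)
    pre <- function(a, b)   # a,b <= T
      (B / lam) * ((b - a) + (exp(-lam * b) - exp(-lam * a)) / lam)
    post <- function(a, b) { # a,b >= T
      C <- (B / lam) * (1 - exp(-lam * T_inf))
      C / lam * (exp(-lam * (a - T_inf)) - exp(-lam * (b - T_inf)))
    }
    if (b <= T_inf) pre(a, b)
    else if (a >= T_inf) post(a, b)
    else pre(a, T_inf) + post(T_inf, b)
  }
  s * (one(p$lambda1, cf$b1) + one(p$lambdaz, cf$bz))
}

#' Frame-averaged plasma model values
#'
#' Mean of the infusion model over each frame interval, by closed-form
#' integration. PET frames are time averages, so fits compare these means,
#' not point evaluations.
#'
#' @param frame_grid Two-column matrix of frame (start, end) times, min.
#' @inheritParams c_plasma_infusion
#' @return One mean concentration per frame.
#' @export
c_plasma_frame_avg <- function(frame_grid, p, dose, T_inf) {
  fg <- as.matrix(frame_grid)
  vapply(seq_len(nrow(fg)), function(i) {
    a <- fg[i, 1]; b <- fg[i, 2]
    .c_plasma_integral(a, b, p, dose, T_inf) / (b - a)
  }, numeric(1))
}

#' Fit the biexponential infusion model to a plasma concentration curve
#'
#' Unweighted least squares of the frame-averaged model against the
#' observed per-frame plasma concentrations, with a seeded multistart.
#' Internally the model is parameterised as (log V1, log (Vz - V1),
#' log lambda_z, log Delta) with lambda_1 = lambda_z + Delta, which
#' enforces lambda_1 > lambda_z and Vz >= V1 by construction. Starts draw
#' rate constants log-uniformly in [1e-3, 1] /min and volumes log-uniformly
#' in [0.1, 20] ml.
#'
#' @param c_plasma Observed per-frame plasma concentration, kBq/ml.
#' @param scan A \code{\link{scan_record}} supplying frames, dose and T.
#' @param n_starts Number of multistart draws (default 16).
#' @param seed RNG seed for the multistart (default 1).
#' @return A \code{plasma_biexp_params} object with attributes
#'   \code{ssr} (residual sum of squares) and \code{n_ok} (converged starts).
#' @export
fit_plasma <- function(c_plasma, scan, n_starts = 16, seed = 1) {
  validate_scan_record(scan)
  fg <- scan$frame_grid
  if (nrow(fg) < 5L || length(c_plasma) < 5L)
    stop("fit_plasma: at least 5 frames are required")
  if (length(c_plasma) != nrow(fg))
    stop("fit_plasma: c_plasma length must match the frame grid")
  dose_kBq <- scan$dose_a0 * 1000
  T_inf <- scan$infusion_duration_T

  unpack <- function(th) {
    v1 <- exp(th[1]); vz <- v1 + exp(th[2])
    lz <- exp(th[3]); l1 <- lz + exp(th[4])
    plasma_biexp_params(v1, vz, l1, lz)
  }
  obj <- function(th) {
    p <- tryCatch(unpack(th), error = function(e) NULL)
    if (is.null(p)) return(1e30)
    m <- tryCatch(c_plasma_frame_avg(fg, p, dose_kBq, T_inf),
                  error = function(e) NULL)
    if (is.null(m) || any(!is.finite(m))) return(1e30)
    sum((m - c_plasma)^2)
  }

  starts <- with_preserved_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      lams <- sort(exp(stats::runif(2, log(1e-3), log(1))))  # lz < l1
      vols <- sort(exp(stats::runif(2, log(0.1), log(20))))  # v1 <= vz
      c(log(vols[1]), log(max(vols[2] - vols[1], 1e-3)),
        log(lams[1]), log(max(lams[2] - lams[1], 1e-6)))
    })
  })
  best <- NULL; n_ok <- 0L
  for (th0 in starts) {
    fit <- tryCatch(stats::nlminb(th0, obj,
                                  control = list(eval.max = 2000, iter.max = 1000,
                                                 rel.tol = 1e-12)),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective) || fit$objective >= 1e30) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best))
    stop("fit_plasma: no multistart converged (", n_starts, " starts)")
  out <- unpack(best$par)
  attr(out, "ssr") <- best$objective
  attr(out, "n_ok") <- n_ok
  out
}

#' Plasma-derived pharmacokinetics: clearance and terminal half-life
#'
#' CL = lambda_z x V_z (reported in ul/min) and t_1/2 = ln(2)/lambda_z.
#'
#' @param p A \code{\link{plasma_biexp_params}} object.
#' @return List with \code{cl} (ul/min) and \code{t_half} (min).
#' @export
plasma_derived <- function(p) {
  stopifnot(inherits(p, "plasma_biexp_params"))
  list(cl = p$lambdaz * p$vz * 1000, t_half = log(2) / p$lambdaz)
}
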