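# Fitting protocol: weighted sum of squared residuals over all regional
# amount curves, bounded multistart local least squares, and the
# bounds-refinement rule applied across scans of the same tracer.

#' Fit configuration
#'
#' @param n_starts Number of random multistart initial parameter sets
#'   (default 128; desk-scale runs and the test-suite use fewer).
#' @param seed RNG seed for the start draws.
#' @param weight_factor Residual multiplier for the early frames of the
#'   weighted regions (default 5). The residual (not its square) is
#'   multiplied, so the squared contribution scales with its square.
#' @param weighted_regions Regions whose early frames are up-weighted
#'   (default plasma, liver, kidney).
#' @param weighted_frames How many leading frames are up-weighted (default 2).
#' @param lower_bounds,upper_bounds Optional named numeric vectors overriding
#'   individual entries of \code{\link{initial_bounds}}.
#' @param fit_k_bg Estimate the transintestinal rate k_bg (default FALSE:
#'   fixed at 0).
#' @param v_tissue_bounds Allowed peripheral-tissue volume range in
#'   cm^3 per g body weight (default c(0.2, 1.5)).
#' @param default_k_upper Upper bound for rate constants without a
#'   physiological cap, 1/min (default 10).
#' @return Object of class \code{fit_config}.
#' @export
fit_config <- function(n_starts = 128, seed = 1, weight_factor = 5,
                       weighted_regions = c("plasma", "liver", "kidney"),
                       weighted_frames = 2,
                       lower_bounds = NULL, upper_bounds = NULL,
                       fit_k_bg = FALSE,
                       v_tissue_bounds = c(0.2, 1.5),
                       default_k_upper = 10) {
  if (n_starts < 1) stop("fit_config: n_starts must be >= 1")
  if (weight_factor < 1) stop("fit_config: weight_factor must be >= 1")
  if (length(v_tissue_bounds) != 2L || v_tissue_bounds[1] > v_tissue_bounds[2])
    stop("fit_config: v_tissue_bounds must be an increasing pair")
  structure(list(n_starts = as.integer(n_starts), seed = seed,
                 weight_factor = weight_factor,
                 weighted_regions = weighted_regions,
                 weighted_frames = as.integer(weighted_frames),
                 lower_bounds = lower_bounds, upper_bounds = upper_bounds,
                 fit_k_bg = isTRUE(fit_k_bg),
                 v_tissue_bounds = v_tissue_bounds,
                 default_k_upper = default_k_upper),
            class = "fit_config")
}

# full parameter vector layout used by the optimiser
.par_names <- c(.rate_names, "f_bt1", "v_tissue")

#' Initial parameter bounds from physiology
#'
#' Lower bounds are 0 for every rate constant. The plasma-to-liver and
#' plasma-to-kidney uptake rates are capped by organ plasma flow divided by
#' plasma volume (Q_P / V_Plasma): uptake cannot exceed delivery. Other
#' rates get a permissive default cap; f_bt1 spans [0, 1]; v_tissue spans
#' the configured per-gram range times body weight. With
#' \code{fit_k_bg = FALSE} the k_bg bounds are degenerate [0, 0].
#'
#' @param phys A \code{\link{physiology_constants}} object.
#' @param bw Body weight, g.
#' @param cfg A \code{\link{fit_config}}.
#' @return List with named numeric vectors \code{lower} and \code{upper}.
#' @export
initial_bounds <- function(phys, bw, cfg = fit_config()) {
  v_plasma <- plasma_volume(bw, phys)
  lower <- stats::setNames(rep(0, length(.par_names)), .par_names)
  upper <- stats::setNames(rep(cfg$default_k_upper, length(.par_names)),
                           .par_names)
  upper["k_bh1"] <- phys$q_p_hepatic / v_plasma
  upper["k_br1"] <- phys$q_p_renal / v_plasma
  upper["f_bt1"] <- 1
  lower["v_tissue"] <- cfg$v_tissue_bounds[1] * bw
  upper["v_tissue"] <- cfg$v_tissue_bounds[2] * bw
  if (!cfg$fit_k_bg) upper["k_bg"] <- 0
  if (!is.null(cfg$lower_bounds))
    lower[names(cfg$lower_bounds)] <- cfg$lower_bounds
  if (!is.null(cfg$upper_bounds))
    upper[names(cfg$upper_bounds)] <- cfg$upper_bounds
  if (any(lower > upper))
    stop("initial_bounds: lower bound exceeds upper bound")
  list(lower = lower, upper = upper)
}

# weight matrix (n_frames x 5 regions) for the objective
.weight_matrix <- function(n_frames, cfg) {
  regions <- c("plasma", "liver", "gi", "kidney", "tissue")
  W <- matrix(1, n_frames, 5, dimnames = list(NULL, regions))
  wf <- min(cfg$weighted_frames, n_frames)
  if (wf > 0)
    W[seq_len(wf), intersect(cfg$weighted_regions, regions)] <- cfg$weight_factor
  W
}

# data matrix for the five fitted regions; tissue column needs v_tissue when
# the tissue curve is a concentration
.data_matrix <- function(prepared, v_tissue) {
  cbind(plasma = prepared$a_plasma,
        liver = prepared$a_liver,
        gi = prepared$a_gi,
        kidney = prepared$a_kidney,
        tissue = if (prepared$tissue_is_conc)
          prepared$tissue_values * v_tissue else prepared$a_tissue)
}

# weighted residual vector on a raw parameter vector (canonical .par_names
# order); NULL on simulation failure
.residuals_par <- function(par, prepared, W, phys, npts = 21, rtol = 1e-8) {
  scan <- prepared$scan
  dose_kBq <- scan$dose_a0 * 1000
  model <- tryCatch(
    .pbpk_frame_observed_cpp(par[seq_len(14L)], par[15L], par[16L],
                             scan$frame_grid, dose_kBq,
                             scan$infusion_duration_T, scan$body_weight,
                             phys$v_blood, phys$hematocrit,
                             phys$v_liver, phys$v_kidney,
                             npts, rtol, 1e-10 * dose_kBq),
    error = function(e) NULL)
  if (is.null(model) || any(!is.finite(model))) return(NULL)
  obs <- .data_matrix(prepared, par[16L])
  as.vector(W * (obs - model))
}

# fast objective on a raw parameter vector
.objective_par <- function(par, prepared, W, phys, npts = 21, rtol = 1e-8) {
  r <- .residuals_par(par, prepared, W, phys, npts, rtol)
  if (is.null(r)) return(Inf)
  sum(r^2)
}

# Bounded Levenberg-Marquardt least squares. Box constraints are removed by
# the sine transform par = lo + (up - lo) (sin th + 1)/2 (minpack style);
# the Jacobian is forward finite differences in th with a step large enough
# to dominate integrator noise. Returns par on the original scale.
.lm_bounded <- function(resid_fun, par0, lower, upper,
                        max_iter = 200, rel_tol = 1e-10, fd_step = 1e-6) {
  rng <- upper - lower
  to_par <- function(th) lower + rng * (sin(th) + 1) / 2
  th <- asin(pmin(pmax(2 * (par0 - lower) / rng - 1, -1), 1))
  r <- resid_fun(to_par(th))
  if (is.null(r)) return(NULL)
  ssr <- sum(r^2)
  lambda <- 1e-3
  n <- length(th)
  convergence <- "max iterations reached"
  for (it in seq_len(max_iter)) {
    J <- matrix(0, length(r), n)
    for (j in seq_len(n)) {
      thj <- th
      thj[j] <- thj[j] + fd_step
      rj <- resid_fun(to_par(thj))
      if (is.null(rj)) rj <- r # dead direction; zero column
      J[, j] <- (rj - r) / fd_step
    }
    g <- crossprod(J, r)
    A <- crossprod(J)
    dA <- diag(A) + 1e-12
    improved <- FALSE
    for (tries in 1:25) {
      delta <- tryCatch(solve(A + lambda * diag(dA, n), -g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        th_new <- th + as.vector(delta)
        r_new <- resid_fun(to_par(th_new))
        if (!is.null(r_new)) {
          ssr_new <- sum(r_new^2)
          if (is.finite(ssr_new) && ssr_new < ssr) {
            rel <- (ssr - ssr_new) / max(ssr, .Machine$double.xmin)
            th <- th_new; r <- r_new; ssr <- ssr_new
            lambda <- max(lambda / 3, 1e-12)
            improved <- TRUE
            if (rel < rel_tol) {
              convergence <- "relative tolerance reached"
              return(list(par = to_par(th), objective = ssr, iterations = it,
                          convergence = convergence))
            }
            break
          }
        }
      }
      lambda <- lambda * 10
    }
    if (!improved) {
      convergence <- "no further improvement"
      break
    }
  }
  list(par = to_par(th), objective = ssr, iterations = it,
       convergence = convergence)
}

#' Weighted sum-of-squares objective
#'
#' Simulates the compartment model at the given rate constants, applies the
#' observation model, and returns the weighted sum of squared residuals over
#' plasma, liver, gi, kidney and tissue amounts (urine, when present, is
#' never fitted). Residuals of the first \code{weighted_frames} frames of
#' the weighted regions are multiplied by \code{weight_factor} before
#' squaring. A failed simulation yields \code{Inf} so the multistart can
#' discard the start.
#'
#' @param k A \code{\link{rate_constant_set}}.
#' @param prepared A \code{\link{prepare_scan}} result.
#' @param cfg A \code{\link{fit_config}}.
#' @param phys A \code{\link{physiology_constants}} object.
#' @return The weighted SSR (kBq^2).
#' @export
objective <- function(k, prepared, cfg = fit_config(),
                      phys = physiology_constants()) {
  stopifnot(inherits(k, "rate_constant_set"), inherits(prepared, "prepared_scan"))
  W <- .weight_matrix(nrow(prepared$scan$frame_grid), cfg)
  .objective_par(c(.rate_vector(k), k$f_bt1, k$v_tissue), prepared, W, phys)
}

# draw n_starts parameter vectors within bounds: rates log-uniform above a
# floor of 1e-4 /min, f_bt1 and v_tissue uniform; fixed params sit at lower
.draw_starts <- function(n_starts, bounds, seed, v_tissue_hint = NULL) {
  lower <- bounds$lower; upper <- bounds$upper
  with_preserved_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      par <- lower
      for (nm in .rate_names) {
        if (upper[nm] > lower[nm]) {
          lo <- max(lower[nm], 1e-4)
          par[nm] <- exp(stats::runif(1, log(lo), log(upper[nm])))
        }
      }
      if (upper["f_bt1"] > lower["f_bt1"])
        par["f_bt1"] <- stats::runif(1, lower["f_bt1"], upper["f_bt1"])
      if (upper["v_tissue"] > lower["v_tissue"])
        par["v_tissue"] <- stats::runif(1, lower["v_tissue"], upper["v_tissue"])
      par
    })
  })
}

#' Bounded multistart least-squares fit of one prepared scan
#'
#' Draws \code{n_starts} random initial parameter sets within the bounds
#' (rates log-uniform above a 1e-4/min floor, f_bt1 and v_tissue uniform),
#' runs a bounded Levenberg-Marquardt least-squares minimisation from each
#' (box constraints via a sine reparameterisation) and keeps the best.
#' Fully reproducible given \code{cfg$seed}.
#'
#' @param prepared A \code{\link{prepare_scan}} result.
#' @param cfg A \code{\link{fit_config}}.
#' @param phys A \code{\link{physiology_constants}} object.
#' @param bounds Optional bounds list (default \code{\link{initial_bounds}}),
#'   e.g. the output of \code{\link{refine_bounds}}.
#' @param starts Optional list of start vectors overriding the random draws.
#' @return Object of class \code{pbpk_fit}: \code{best_params}
#'   (\code{rate_constant_set}), \code{objective}, \code{start_objectives},
#'   \code{residuals} (obs - model, n_frames x 5), \code{model} (fitted
#'   frame-averaged amounts), \code{bounds}, \code{n_failed},
#'   \code{convergence} message of the winning start.
#' @export
multistart_fit <- function(prepared, cfg = fit_config(),
                           phys = physiology_constants(),
                           bounds = NULL, starts = NULL) {
  stopifnot(inherits(prepared, "prepared_scan"), inherits(cfg, "fit_config"))
  scan <- prepared$scan
  if (is.null(bounds)) bounds <- initial_bounds(phys, scan$body_weight, cfg)
  lower <- bounds$lower[.par_names]; upper <- bounds$upper[.par_names]
  W <- .weight_matrix(nrow(scan$frame_grid), cfg)
  if (is.null(starts))
    starts <- .draw_starts(cfg$n_starts, list(lower = lower, upper = upper),
                           cfg$seed, prepared$v_tissue_hint)

  free <- which(upper > lower)
  if (!length(free)) stop("multistart_fit: all parameters are fixed")
  resid_free <- function(pf) {
    par <- lower
    par[free] <- pf
    .residuals_par(par, prepared, W, phys)
  }

  best <- NULL; objs <- numeric(0); n_failed <- 0L
  for (st in starts) {
    fit <- tryCatch(
      .lm_bounded(resid_free, st[free], lower[free], upper[free]),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) {
      n_failed <- n_failed + 1L
      objs <- c(objs, NA_real_)
      next
    }
    # the sine transform cannot represent a start sitting exactly on a
    # bound; keep the raw start too so a supplied optimum is never lost
    par0 <- lower; par0[free] <- st[free]
    obj0 <- .objective_par(par0, prepared, W, phys)
    if (is.finite(obj0) && obj0 < fit$objective)
      fit <- list(par = st[free], objective = obj0,
                  iterations = 0L, convergence = "start retained")
    objs <- c(objs, fit$objective)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best))
    stop("multistart_fit: all ", length(starts), " starts failed")

  par <- lower; par[free] <- best$par
  k <- rate_constant_set_from_vector(par)
  dose_kBq <- scan$dose_a0 * 1000
  model <- .pbpk_frame_observed_cpp(par[seq_len(14L)], par[15L], par[16L],
                                    scan$frame_grid, dose_kBq,
                                    scan$infusion_duration_T, scan$body_weight,
                                    phys$v_blood, phys$hematocrit,
                                    phys$v_liver, phys$v_kidney, 21, 1e-8,
                                    1e-10 * dose_kBq)
  obs <- .data_matrix(prepared, par[16L])
  structure(list(best_params = k,
                 objective = best$objective,
                 start_objectives = objs,
                 residuals = obs - model,
                 model = model,
                 observed = obs,
                 bounds = list(lower = lower, upper = upper),
                 n_failed = n_failed,
                 convergence = best$convergence,
                 scan_id = scan$scan_id,
                 group_label = scan$group_label),
            class = "pbpk_fit")
}

#' @export
print.pbpk_fit <- function(x, ...) {
  cat(sprintf("PBPK fit of scan '%s': weighted SSR %.4g (%d/%d starts converged)\n",
              x$scan_id, x$objective,
              sum(is.finite(x$start_objectives)), length(x$start_objectives)))
  invisible(x)
}

#' Refine parameter bounds from a set of fits
#'
#' Per parameter, the refined lower bound is 0.5 times the smallest best-fit
#' value across the scans and the refined upper bound 2 times the largest.
#' Parameters fixed at 0 (e.g. k_bg when not fitted) keep degenerate [0, 0]
#' bounds and stay fixed.
#'
#' @param results List of \code{pbpk_fit} objects from the same tracer group.
#' @param cfg A \code{\link{fit_config}} (unused slot kept for interface
#'   stability).
#' @return List with \code{lower} and \code{upper} named vectors.
#' @export
refine_bounds <- function(results, cfg = fit_config()) {
  if (inherits(results, "pbpk_fit")) results <- list(results)
  if (!length(results)) stop("refine_bounds: empty result list")
  stopifnot(all(vapply(results, inherits, TRUE, "pbpk_fit")))
  P <- vapply(results, function(r) {
    k <- r$best_params
    c(.rate_vector(k), k$f_bt1, k$v_tissue)
  }, numeric(length(.par_names)))
  P <- matrix(P, nrow = length(.par_names),
              dimnames = list(.par_names, NULL))
  lower <- 0.5 * apply(P, 1, min)
  upper <- 2 * apply(P, 1, max)
  # f_bt1 is a fraction; the 0.5x/2x rule must stay inside [0, 1]
  upper["f_bt1"] <- min(upper["f_bt1"], 1)
  lower["f_bt1"] <- min(lower["f_bt1"], upper["f_bt1"])
  list(lower = lower, upper = upper)
}
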