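# End-to-end orchestration: prepare -> plasma fit -> PBPK fit -> derived PK
# -> group summaries and pooled-variance t-tests, plus iterative bounds
# refinement across scans of the same tracer.

# quantities summarised and tested between groups
.report_quantities <- c("lambda_z", "v_z", "cl_plasma", "cl_h", "e_h",
                        "cl_r", "cl_r_over_gfr", "cl_h_over_cl_r",
                        "cl_total", "d_tissue")

.scan_quantities <- function(plasma_fit, derived) {
  pd <- plasma_derived(plasma_fit)
  c(lambda_z = plasma_fit$lambdaz, v_z = plasma_fit$vz,
    cl_plasma = pd$cl, t_half = pd$t_half,
    cl_h = derived$cl_h, e_h = derived$e_h,
    cl_r = derived$cl_r, cl_r_over_gfr = derived$cl_r_over_gfr,
    cl_h_over_cl_r = derived$cl_h_over_cl_r,
    cl_ti = derived$cl_ti, cl_total = derived$cl_total,
    d_tissue = derived$d_tissue)
}

.as_scan_list <- function(scans) {
  lapply(scans, function(s) {
    if (inherits(s, "scan_record")) s
    else if (is.character(s)) read_tac_table(s)
    else stop("run_study: each scan must be a scan_record or a file path")
  })
}

#' Run the full study pipeline over a set of scans
#'
#' For every scan: prepare the curves, fit the biexponential plasma model,
#' fit the whole-body compartment model by bounded multistart least squares,
#' and derive the clearance/distribution quantities. Scans sharing a group
#' label form a group; when exactly two groups with >= 2 scans each are
#' present, every reported quantity is compared by the homoscedastic
#' two-tailed t-test. Per-scan fit seeds are \code{cfg$seed + scan index},
#' so reruns with the same seeds reproduce the report numerically.
#'
#' @param scans List of \code{\link{scan_record}} objects and/or TAC file
#'   paths (sidecar configs resolved as in \code{\link{read_tac_table}}).
#' @param cfg A \code{\link{fit_config}}.
#' @param phys A \code{\link{physiology_constants}} object.
#' @param bounds Optional bounds list applied to every scan (default
#'   physiological \code{\link{initial_bounds}} per scan).
#' @return Object of class \code{study_report}: \code{per_scan} (prepared
#'   data, fits, derived quantities), \code{quantities} (data.frame, one row
#'   per scan), \code{group_summary} (mean/SD per group and quantity),
#'   \code{comparisons} (list of \code{group_comparison}), \code{table}
#'   (the two-group summary table with significance marks), and the
#'   configuration echo.
#' @export
run_study <- function(scans, cfg = fit_config(), phys = physiology_constants(),
                      bounds = NULL) {
  scans <- .as_scan_list(scans)
  if (!length(scans)) stop("run_study: at least one scan required")
  per_scan <- vector("list", length(scans))
  rows <- list()
  for (i in seq_along(scans)) {
    scan <- scans[[i]]
    prepared <- prepare_scan(scan, phys)
    scan_cfg <- cfg
    scan_cfg$seed <- cfg$seed + i
    plasma_fit <- fit_plasma(prepared$c_plasma, scan, seed = scan_cfg$seed)
    fit <- multistart_fit(prepared, scan_cfg, phys, bounds = bounds)
    derived <- derive_all(fit$best_params, scan, phys)
    per_scan[[i]] <- list(scan = scan, prepared = prepared,
                          plasma_fit = plasma_fit, fit = fit,
                          derived = derived)
    rows[[i]] <- data.frame(scan_id = scan$scan_id, group = scan$group_label,
                            tracer = scan$tracer_label,
                            objective = fit$objective,
                            t(.scan_quantities(plasma_fit, derived)))
  }
  quantities <- do.call(rbind, rows)
  report <- structure(list(per_scan = per_scan, quantities = quantities,
                           cfg = cfg, phys = phys),
                      class = "study_report")
  report$group_summary <- .summarise_groups(quantities)
  cmp <- .compare_two_groups(quantities)
  report$comparisons <- cmp$comparisons
  report$table <- cmp$table
  if (length(unique(quantities$group)) < 2L ||
      any(table(quantities$group) < 2L))
    warning("run_study: fewer than two groups with >= 2 scans; ",
            "no t-tests computed")
  report
}

.summarise_groups <- function(quantities) {
  qs <- intersect(.report_quantities, names(quantities))
  do.call(rbind, lapply(split(quantities, quantities$group), function(d) {
    out <- data.frame(group = d$group[1L], n = nrow(d))
    for (q in qs) {
      out[[paste0(q, "_mean")]] <- mean(d[[q]])
      out[[paste0(q, "_sd")]] <- stats::sd(d[[q]])
    }
    out
  }))
}

.compare_two_groups <- function(quantities) {
  groups <- unique(quantities$group)
  qs <- intersect(.report_quantities, names(quantities))
  if (length(groups) != 2L ||
      any(vapply(groups, function(g) sum(quantities$group == g), 1L) < 2L))
    return(list(comparisons = list(), table = NULL))
  a <- quantities[quantities$group == groups[1L], ]
  b <- quantities[quantities$group == groups[2L], ]
  comparisons <- list()
  tab <- data.frame(quantity = qs)
  for (j in seq_along(qs)) {
    q <- qs[j]
    cm <- compare_groups(a[[q]], b[[q]])
    comparisons[[q]] <- cm
    mark <- if (cm$p < 0.01) "**" else if (cm$p < 0.05) "*" else ""
    tab[[paste0(groups[1L], "_mean")]][j] <- cm$mean_a
    tab[[paste0(groups[1L], "_sd")]][j] <- cm$sd_a
    tab[[paste0(groups[2L], "_mean")]][j] <- cm$mean_b
    tab[[paste0(groups[2L], "_sd")]][j] <- cm$sd_b
    tab$p[j] <- cm$p
    tab$mark[j] <- mark
  }
  list(comparisons = comparisons, table = tab)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d scans, groups: %s\n",
              nrow(x$quantities),
              paste(unique(x$quantities$group), collapse = ", ")))
  if (!is.null(x$table)) {
    cat("\nGroup comparison (pooled-variance t-test):\n")
    print(cbind(x$table[, "quantity", drop = FALSE],
                round(x$table[, !(names(x$table) %in% c("quantity", "mark"))], 4),
                mark = x$table$mark), row.names = FALSE)
  }
  invisible(x)
}

#' Refine bounds per tracer and refit
#'
#' Applies the 0.5x/2x bounds-refinement rule (\code{\link{refine_bounds}})
#' per tracer group, refits every scan inside the refined bounds and
#' repeats for the given number of rounds. The previous best parameter set
#' of each scan is always injected as an extra start, so per-scan best
#' objectives are non-increasing across rounds.
#'
#' @param scans As in \code{\link{run_study}}.
#' @param cfg,phys As in \code{\link{run_study}}.
#' @param rounds Number of refinement rounds (0 returns the initial run).
#' @param report Optional initial \code{study_report} to refine (skips the
#'   initial fits).
#' @return A \code{study_report} with an extra element
#'   \code{objective_history}: matrix scans x (rounds + 1) of best
#'   objectives per round.
#' @export
refine_and_refit <- function(scans, cfg = fit_config(),
                             phys = physiology_constants(),
                             rounds = 1, report = NULL) {
  scans <- .as_scan_list(scans)
  if (is.null(report)) report <- run_study(scans, cfg, phys)
  history <- matrix(vapply(report$per_scan, function(s) s$fit$objective, 0),
                    ncol = 1)
  rownames(history) <- vapply(report$per_scan, function(s) s$scan$scan_id, "")
  if (rounds < 1) {
    report$objective_history <- history
    return(report)
  }
  for (r in seq_len(rounds)) {
    tracers <- vapply(report$per_scan, function(s) s$scan$tracer_label, "")
    new_per_scan <- report$per_scan
    for (tr in unique(tracers)) {
      idx <- which(tracers == tr)
      bounds <- refine_bounds(lapply(report$per_scan[idx], `[[`, "fit"), cfg)
      for (i in idx) {
        s <- report$per_scan[[i]]
        scan_cfg <- cfg
        scan_cfg$seed <- cfg$seed + i + r * 10000L
        prev <- s$fit$best_params
        prev_par <- stats::setNames(c(.rate_vector(prev), prev$f_bt1,
                                      prev$v_tissue), .par_names)
        # clamp the carried-over start into the refined box (it lies inside
        # by construction up to floating-point rounding)
        prev_par <- pmin(pmax(prev_par, bounds$lower), bounds$upper)
        starts <- c(.draw_starts(scan_cfg$n_starts, bounds, scan_cfg$seed),
                    list(prev_par))
        fit <- multistart_fit(s$prepared, scan_cfg, phys, bounds = bounds,
                              starts = starts)
        s$fit <- fit
        s$derived <- derive_all(fit$best_params, s$scan, phys)
        new_per_scan[[i]] <- s
      }
    }
    report$per_scan <- new_per_scan
    history <- cbind(history, vapply(report$per_scan,
                                     function(s) s$fit$objective, 0))
  }
  colnames(history) <- paste0("round_", seq_len(ncol(history)) - 1L)
  rows <- lapply(report$per_scan, function(s)
    data.frame(scan_id = s$scan$scan_id, group = s$scan$group_label,
               tracer = s$scan$tracer_label, objective = s$fit$objective,
               t(.scan_quantities(s$plasma_fit, s$derived))))
  report$quantities <- do.call(rbind, rows)
  report$group_summary <- .summarise_groups(report$quantities)
  cmp <- .compare_two_groups(report$quantities)
  report$comparisons <- cmp$comparisons
  report$table <- cmp$table
  report$objective_history <- history
  report
}

#' Write a study report to delimited files
#'
#' Emits \code{quantities.csv} (per-scan unrounded values),
#' \code{group_summary.csv}, \code{comparison.csv} (when available) and a
#' plain-text \code{study.log} with seeds and solver diagnostics.
#'
#' @param report A \code{study_report}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$quantities, file.path(dir, "quantities.csv"),
                   row.names = FALSE)
  utils::write.csv(report$group_summary, file.path(dir, "group_summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$table))
    utils::write.csv(report$table, file.path(dir, "comparison.csv"),
                     row.names = FALSE)
  log <- c(sprintf("petpbpk study report (%s)", format(Sys.time())),
           sprintf("seed: %s, n_starts: %d", format(report$cfg$seed),
                   report$cfg$n_starts),
           vapply(report$per_scan, function(s)
             sprintf("scan %s: objective %.6g, failed starts %d",
                     s$scan$scan_id, s$fit$objective, s$fit$n_failed), ""))
  writeLines(log, file.path(dir, "study.log"))
  invisible(dir)
}
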