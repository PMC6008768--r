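#' A single dynamic PET scan: frame grid, regional curves and metadata
#'
#' Container for one scan's decay-corrected time-activity data. Times are
#' stored internally in minutes post injection-start; curves are stored per
#' region together with their declared kind (\code{"conc"} in kBq/ml or
#' \code{"amount"} in kBq). The frame grid is a set of non-overlapping,
#' strictly increasing half-open intervals \code{[start, end)}; the first
#' frame must not start before the infusion has ended.
#'
#' @param scan_id Scan identifier (character).
#' @param body_weight Body weight in g.
#' @param dose_a0 Injected radioactivity dose A(0) in MBq.
#' @param frame_grid Two-column matrix (or data.frame) of frame start/end
#'   times in minutes post injection.
#' @param curves Named list, one entry per region (see
#'   \code{\link{region_kinds}}), each a list with elements \code{values}
#'   (numeric, one per frame, >= 0) and \code{kind} ("conc" or "amount").
#' @param infusion_duration_T Infusion duration in minutes (default 10 s).
#' @param group_label Treatment group label (e.g. "control", "cyclosporine").
#' @param tracer_label Tracer label.
#'
#' @return An object of class \code{scan_record}.
#' @export
scan_record <- function(scan_id, body_weight, dose_a0, frame_grid, curves,
                        infusion_duration_T = 10 / 60,
                        group_label = "control", tracer_label = "tracer") {
  fg <- as.matrix(frame_grid)
  if (ncol(fg) != 2L) stop("scan_record: frame_grid needs two columns (start, end)")
  storage.mode(fg) <- "double"
  colnames(fg) <- c("start", "end")
  x <- structure(list(scan_id = as.character(scan_id),
                      body_weight = body_weight,
                      dose_a0 = dose_a0,
                      infusion_duration_T = infusion_duration_T,
                      frame_grid = fg,
                      curves = curves,
                      group_label = as.character(group_label),
                      tracer_label = as.character(tracer_label)),
                 class = "scan_record")
  validate_scan_record(x)
}

#' Validate a scan_record's invariants
#'
#' Checks positivity of metadata, frame-grid monotonicity and
#' non-overlap, infusion/frame ordering, curve lengths, curve
#' non-negativity and amount-only regions.
#'
#' @param x A \code{scan_record}.
#' @return \code{x}, invisibly unchanged, or an error.
#' @export
validate_scan_record <- function(x) {
  stopifnot(inherits(x, "scan_record"))
  if (!is.finite(x$body_weight) || x$body_weight <= 0)
    stop("scan_record: body_weight must be positive (g)")
  if (!is.finite(x$dose_a0) || x$dose_a0 <= 0)
    stop("scan_record: dose_a0 must be positive (MBq)")
  if (!is.finite(x$infusion_duration_T) || x$infusion_duration_T <= 0)
    stop("scan_record: infusion_duration_T must be positive (min)")
  fg <- x$frame_grid
  n <- nrow(fg)
  if (n < 1L) stop("scan_record: at least one frame required")
  if (any(fg[, "end"] <= fg[, "start"]))
    stop("scan_record: every frame must satisfy end > start")
  if (n > 1L) {
    if (any(diff(fg[, "start"]) <= 0))
      stop("scan_record: frame starts must be strictly increasing")
    if (any(fg[-n, "end"] > fg[-1L, "start"] + 1e-9))
      stop("scan_record: frames overlap")
  }
  if (fg[1L, "start"] < x$infusion_duration_T - 1e-9)
    stop("scan_record: first frame must not start before the infusion ends")
  if (!is.list(x$curves) || is.null(names(x$curves)) || !length(x$curves))
    stop("scan_record: curves must be a non-empty named list")
  bad <- setdiff(names(x$curves), region_kinds())
  if (length(bad)) stop("scan_record: unknown region(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(x$curves)) {
    cv <- x$curves[[nm]]
    if (!is.list(cv) || is.null(cv$values) || is.null(cv$kind))
      stop("scan_record: curve '", nm, "' must have $values and $kind")
    if (!cv$kind %in% c("conc", "amount"))
      stop("scan_record: curve '", nm, "' has unknown kind '", cv$kind, "'")
    if (nm %in% .amount_only_regions && cv$kind != "amount")
      stop("scan_record: region '", nm, "' must be given as an amount (kBq)")
    if (length(cv$values) != n)
      stop("scan_record: curve '", nm, "' has ", length(cv$values),
           " values for ", n, " frames")
    neg <- which(cv$values < 0)
    if (length(neg))
      stop("scan_record: negative value in curve '", nm, "' at frame ", neg[1L])
  }
  invisible(x)
}

#' @export
print.scan_record <- function(x, ...) {
  fg <- x$frame_grid
  cat(sprintf("Scan '%s' (%s, %s): BW %.1f g, A(0) %.2f MBq, T %.3f min\n",
              x$scan_id, x$tracer_label, x$group_label,
              x$body_weight, x$dose_a0, x$infusion_duration_T))
  cat(sprintf("  %d frames, %.2f-%.2f min; regions: %s\n", nrow(fg),
              fg[1, "start"], fg[nrow(fg), "end"],
              paste(names(x$curves), collapse = ", ")))
  invisible(x)
}

# --- plain-text I/O ----------------------------------------------------------
# TAC tables are delimited text with columns frame_start_s, frame_end_s and one
# column per region named <region>_conc_kBq_per_ml or <region>_amount_kBq.
# Scan metadata lives in a sidecar "key: value" config file.

.curve_colname <- function(region, kind) {
  if (kind == "conc") paste0(region, "_conc_kBq_per_ml")
  else paste0(region, "_amount_kBq")
}

.parse_curve_colname <- function(nm) {
  if (grepl("_conc_kBq_per_ml$", nm))
    list(region = sub("_conc_kBq_per_ml$", "", nm), kind = "conc")
  else if (grepl("_amount_kBq$", nm))
    list(region = sub("_amount_kBq$", "", nm), kind = "amount")
  else NULL
}

#' Read a flat "key: value" scan configuration file
#'
#' Recognised keys: \code{scan_id}, \code{body_weight_g}, \code{dose_MBq},
#' \code{infusion_duration_s}, \code{group}, \code{tracer}. Lines starting
#' with \code{#} and blank lines are ignored.
#'
#' @param path Path to the config file.
#' @return Named list of character values (numbers not yet coerced).
#' @export
read_scan_config <- function(path) {
  if (!file.exists(path)) stop("read_scan_config: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("read_scan_config: unparseable line: ", lines[bad][1L])
  stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
}

#' Write a scan configuration file
#'
#' @param scan A \code{scan_record}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_scan_config <- function(scan, path) {
  stopifnot(inherits(scan, "scan_record"))
  lines <- c(paste0("scan_id: ", scan$scan_id),
             paste0("body_weight_g: ", format(scan$body_weight, digits = 10)),
             paste0("dose_MBq: ", format(scan$dose_a0, digits = 10)),
             paste0("infusion_duration_s: ",
                    format(scan$infusion_duration_T * 60, digits = 10)),
             paste0("group: ", scan$group_label),
             paste0("tracer: ", scan$tracer_label))
  writeLines(lines, path)
  invisible(path)
}

.default_config_path <- function(path) {
  sub("\\.(csv|tsv|txt)$", ".config", path)
}

#' Read a time-activity table plus sidecar config into a scan_record
#'
#' The table must contain \code{frame_start_s} and \code{frame_end_s}
#' (seconds post injection) plus at least a blood or plasma column, and the
#' liver, gi, kidney and tissue columns; an optional urine column is kept.
#' Field separator (comma or tab) is auto-detected. Times are converted to
#' minutes.
#'
#' @param path Path to the TAC table.
#' @param config Either a path to the sidecar config, a named list as
#'   returned by \code{\link{read_scan_config}}, or \code{NULL} to use
#'   \code{<path without extension>.config}.
#' @return A validated \code{\link{scan_record}}.
#' @export
read_tac_table <- function(path, config = NULL) {
  if (!file.exists(path)) stop("read_tac_table: no such file: ", path)
  if (is.null(config)) config <- .default_config_path(path)
  if (is.character(config)) config <- read_scan_config(config)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("frame_start_s", "frame_end_s"))
    if (!col %in% names(tab))
      stop("read_tac_table: missing mandatory column '", col, "'")
  curves <- list()
  for (nm in setdiff(names(tab), c("frame_start_s", "frame_end_s"))) {
    pc <- .parse_curve_colname(nm)
    if (is.null(pc))
      stop("read_tac_table: column '", nm, "' does not follow ",
           "<region>_conc_kBq_per_ml / <region>_amount_kBq naming")
    if (!pc$region %in% region_kinds())
      stop("read_tac_table: unknown region in column '", nm, "'")
    curves[[pc$region]] <- list(values = as.numeric(tab[[nm]]), kind = pc$kind)
  }
  if (!any(c("blood", "plasma") %in% names(curves)))
    stop("read_tac_table: missing mandatory column: blood or plasma curve")
  for (req in c("liver", "gi", "kidney", "tissue"))
    if (!req %in% names(curves))
      stop("read_tac_table: missing mandatory column for region '", req, "'")
  need <- c("scan_id", "body_weight_g", "dose_MBq", "infusion_duration_s")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("read_tac_table: config lacks key(s): ", paste(miss, collapse = ", "))
  scan_record(scan_id = config$scan_id,
              body_weight = as.numeric(config$body_weight_g),
              dose_a0 = as.numeric(config$dose_MBq),
              frame_grid = cbind(start = tab$frame_start_s / 60,
                                 end = tab$frame_end_s / 60),
              curves = curves,
              infusion_duration_T = as.numeric(config$infusion_duration_s) / 60,
              group_label = if (is.null(config$group)) "control" else config$group,
              tracer_label = if (is.null(config$tracer)) "tracer" else config$tracer)
}

#' Write a scan_record as a TAC table (plus sidecar config)
#'
#' Emits the same dialect \code{\link{read_tac_table}} consumes: times in
#' seconds, one column per region. The sidecar config is written next to the
#' table unless \code{write_config = FALSE}.
#'
#' @param scan A valid \code{scan_record}.
#' @param path Output path for the table (.csv or .tsv decides the separator).
#' @param write_config Also write \code{<path without extension>.config}.
#' @return \code{path}, invisibly.
#' @export
write_tac_table <- function(scan, path, write_config = TRUE) {
  validate_scan_record(scan)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- data.frame(frame_start_s = scan$frame_grid[, "start"] * 60,
                    frame_end_s = scan$frame_grid[, "end"] * 60,
                    check.names = FALSE)
  for (nm in names(scan$curves))
    tab[[.curve_colname(nm, scan$curves[[nm]]$kind)]] <- scan$curves[[nm]]$values
  utils::write.table(format(tab, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  if (write_config) write_scan_config(scan, .default_config_path(path))
  invisible(path)
}
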