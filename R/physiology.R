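#' Physiological constants for mouse whole-body PBPK modelling
#'
#' Bundles the literature-derived physiological constants used throughout the
#' pipeline: hematocrit, specific blood volume, specific liver and kidney
#' volumes, hepatic and renal plasma flows and the glomerular filtration rate.
#' Defaults are the standard mouse values used for image-derived amount
#' conversion and for the physiological upper bounds of the fit.
#'
#' @param hematocrit Blood volume fraction occupied by cells (dimensionless,
#'   default 0.44). Converts blood to plasma concentration.
#' @param v_blood Specific blood volume, ml blood per g body weight
#'   (default 0.0585).
#' @param v_liver Specific liver volume, cm^3 per g body weight (default 0.065).
#' @param v_kidney Specific kidney volume, cm^3 per g body weight
#'   (default 0.0164).
#' @param q_p_hepatic Hepatic plasma flow, ml plasma/min (default 1.0).
#' @param q_p_renal Renal plasma flow, ml plasma/min (default 0.73).
#' @param gfr Glomerular filtration rate, ul/min (default 160).
#'
#' @return An object of class \code{physiology_constants} (a named list).
#' @examples
#' phys <- physiology_constants()
#' plasma_volume(20, phys)
#' @export
physiology_constants <- function(hematocrit = 0.44,
                                 v_blood = 0.0585,
                                 v_liver = 0.065,
                                 v_kidney = 0.0164,
                                 q_p_hepatic = 1.0,
                                 q_p_renal = 0.73,
                                 gfr = 160) {
  vals <- list(hematocrit = hematocrit, v_blood = v_blood,
               v_liver = v_liver, v_kidney = v_kidney,
               q_p_hepatic = q_p_hepatic, q_p_renal = q_p_renal, gfr = gfr)
  for (nm in names(vals)) {
    x <- vals[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("physiology_constants: '", nm, "' must be a single positive number")
  }
  if (hematocrit >= 1)
    stop("physiology_constants: hematocrit must lie strictly between 0 and 1")
  structure(vals, class = "physiology_constants")
}

#' @export
print.physiology_constants <- function(x, ...) {
  cat("Physiological constants (mouse):\n")
  cat(sprintf("  hematocrit      %.3f\n", x$hematocrit))
  cat(sprintf("  v_blood         %.4f ml/g\n", x$v_blood))
  cat(sprintf("  v_liver         %.4f cm^3/g\n", x$v_liver))
  cat(sprintf("  v_kidney        %.4f cm^3/g\n", x$v_kidney))
  cat(sprintf("  Q_P,hepatic     %.2f ml/min\n", x$q_p_hepatic))
  cat(sprintf("  Q_P,renal       %.2f ml/min\n", x$q_p_renal))
  cat(sprintf("  GFR             %.0f ul/min\n", x$gfr))
  invisible(x)
}

#' Plasma volume from body weight
#'
#' V_Plasma = v_blood x (1 - hematocrit) x BW: the plasma fraction of the
#' theoretical blood volume. Used both to convert the image-derived blood
#' concentration to a total plasma amount and to express clearances as
#' rate constant x plasma volume.
#'
#' @param bw Body weight in g (> 0).
#' @param phys A \code{\link{physiology_constants}} object.
#' @return Plasma volume in ml.
#' @examples
#' plasma_volume(20) # 0.6552 ml with default constants
#' @export
plasma_volume <- function(bw, phys = physiology_constants()) {
  stopifnot(inherits(phys, "physiology_constants"))
  if (!is.numeric(bw) || length(bw) != 1L || !is.finite(bw) || bw <= 0)
    stop("plasma_volume: body weight must be a single positive number (g)")
  phys$v_blood * (1 - phys$hematocrit) * bw
}

#' Region names recognised in time-activity tables
#'
#' The modelled regions: blood plasma (or whole blood), liver,
#' combined gallbladder + intestine ("gi"), kidneys, peripheral tissue and
#' urinary bladder. \code{gi} and \code{urine} curves are always amounts
#' (kBq) because no meaningful reference volume exists for them; the other
#' regions may be given as concentration (kBq/ml) or amount (kBq).
#'
#' @return Character vector of region names.
#' @export
region_kinds <- function() {
  c("plasma", "blood", "liver", "gi", "kidney", "tissue", "urine")
}

# regions whose curves must be amounts
.amount_only_regions <- c("gi", "urine")
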