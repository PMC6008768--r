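#' Blood to plasma concentration
#'
#' C_Plasma = C_Blood / (1 - hematocrit): radioactivity is assumed confined
#' to plasma, so the whole-blood concentration is diluted by the cell
#' fraction.
#'
#' @param c_blood Whole-blood concentration(s), kBq/ml (>= 0).
#' @param phys A \code{\link{physiology_constants}} object.
#' @return Plasma concentration(s), kBq/ml.
#' @export
blood_to_plasma_conc <- function(c_blood, phys = physiology_constants()) {
  stopifnot(inherits(phys, "physiology_constants"))
  if (any(c_blood < 0)) stop("blood_to_plasma_conc: negative concentration")
  c_blood / (1 - phys$hematocrit)
}

#' Total plasma radioactivity amount from blood concentration
#'
#' A_Plasma = C_Blood x v_blood x BW: the image-derived blood concentration
#' times the theoretical blood volume. Algebraically identical to
#' C_Plasma x V_Plasma.
#'
#' @param c_blood Whole-blood concentration(s), kBq/ml (>= 0).
#' @param bw Body weight, g.
#' @param phys A \code{\link{physiology_constants}} object.
#' @return Amount(s) in kBq.
#' @export
total_plasma_amount <- function(c_blood, bw, phys = physiology_constants()) {
  stopifnot(inherits(phys, "physiology_constants"))
  if (any(c_blood < 0)) stop("total_plasma_amount: negative concentration")
  if (bw <= 0) stop("total_plasma_amount: body weight must be positive")
  c_blood * phys$v_blood * bw
}

#' Standardized uptake value
#'
#' SUV = C / (A(0)/BW), with C in kBq/ml, dose in MBq and body weight in g,
#' so the normaliser A(0)/BW is dose x 1000 / BW in kBq/g.
#'
#' @param c Concentration(s), kBq/ml.
#' @param dose Injected dose, MBq (> 0).
#' @param bw Body weight, g (> 0).
#' @return Dimensionless SUV value(s).
#' @export
suv <- function(c, dose, bw) {
  if (dose <= 0) stop("suv: dose must be positive")
  if (bw <= 0) stop("suv: body weight must be positive")
  c / (dose * 1000 / bw)
}

#' Prepare a scan for fitting: amount curves and plasma concentration
#'
#' Converts the regional curves of a \code{\link{scan_record}} into the
#' amount curves A(t) the compartment model is fitted against:
#' liver and kidney concentrations are multiplied by their physiological
#' organ volumes (v_liver x BW, v_kidney x BW); the plasma amount comes from
#' the blood concentration via the theoretical blood volume (or directly
#' from a plasma concentration times V_Plasma); gi and urine are passed
#' through as amounts. Peripheral tissue has no fixed volume: a
#' concentration curve is retained as-is and converted inside the fit with
#' the estimated V_Tissue; \code{v_tissue_hint} (default 0.74 cm^3/g x BW)
#' seeds that estimate. If both blood and plasma are present, plasma wins.
#'
#' @param scan A valid \code{scan_record}.
#' @param phys A \code{\link{physiology_constants}} object.
#' @param v_tissue_hint Optional prior for the peripheral-tissue volume, cm^3.
#' @return An object of class \code{prepared_scan} with per-frame amount
#'   vectors \code{a_plasma}, \code{a_liver}, \code{a_gi}, \code{a_kidney},
#'   \code{a_urine} (or NULL), tissue data (\code{a_tissue} or
#'   \code{c_tissue}), \code{c_plasma}, and the organ volumes.
#' @export
prepare_scan <- function(scan, phys = physiology_constants(),
                         v_tissue_hint = NULL) {
  validate_scan_record(scan)
  bw <- scan$body_weight
  v_plasma <- plasma_volume(bw, phys)
  cv <- scan$curves

  if (!is.null(cv$plasma)) {
    if (cv$plasma$kind == "conc") {
      c_plasma <- cv$plasma$values
      a_plasma <- c_plasma * v_plasma
    } else {
      a_plasma <- cv$plasma$values
      c_plasma <- a_plasma / v_plasma
    }
  } else if (!is.null(cv$blood)) {
    if (cv$blood$kind != "conc")
      stop("prepare_scan: blood curve must be a concentration")
    c_plasma <- blood_to_plasma_conc(cv$blood$values, phys)
    a_plasma <- total_plasma_amount(cv$blood$values, bw, phys)
  } else stop("prepare_scan: need a blood or plasma curve")

  organ_amount <- function(region, volume) {
    crv <- cv[[region]]
    if (is.null(crv)) stop("prepare_scan: missing region '", region, "'")
    if (crv$kind == "amount") crv$values else crv$values * volume
  }
  v_liver_organ <- phys$v_liver * bw
  v_kidney_organ <- phys$v_kidney * bw
  a_liver <- organ_amount("liver", v_liver_organ)
  a_kidney <- organ_amount("kidney", v_kidney_organ)
  if (is.null(cv$gi)) stop("prepare_scan: missing region 'gi'")
  a_gi <- cv$gi$values
  a_urine <- if (is.null(cv$urine)) NULL else cv$urine$values

  if (is.null(cv$tissue)) stop("prepare_scan: missing region 'tissue'")
  tissue_is_conc <- cv$tissue$kind == "conc"
  if (is.null(v_tissue_hint)) v_tissue_hint <- 0.74 * bw

  structure(list(scan = scan,
                 a_plasma = a_plasma, c_plasma = c_plasma,
                 a_liver = a_liver, a_gi = a_gi, a_kidney = a_kidney,
                 a_urine = a_urine,
                 tissue_values = cv$tissue$values,
                 tissue_is_conc = tissue_is_conc,
                 a_tissue = if (tissue_is_conc) NULL else cv$tissue$values,
                 v_plasma = v_plasma,
                 v_liver_organ = v_liver_organ,
                 v_kidney_organ = v_kidney_organ,
                 v_tissue_hint = v_tissue_hint),
            class = "prepared_scan")
}

#' @export
print.prepared_scan <- function(x, ...) {
  cat(sprintf("Prepared scan '%s': V_Plasma %.3f ml, liver %.2f cm^3, kidney %.2f cm^3, tissue %s\n",
              x$scan$scan_id, x$v_plasma, x$v_liver_organ, x$v_kidney_organ,
              if (x$tissue_is_conc) "concentration (V_Tissue fitted)" else "amount"))
  invisible(x)
}
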