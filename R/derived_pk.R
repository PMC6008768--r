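# Clearance and distribution functionals of the fitted rate constants, and
# group statistics. Clearances are rate constant x plasma volume scaled by
# the fraction of uptaken tracer that proceeds to irreversible elimination;
# they are reported in ul/min (plasma volume in ml x 1000).

#' Hepatobiliary clearance from rate constants
#'
#' CL_H = k_BH1 * k_H1H2 / (k_H1B + k_H1H2) * V_Plasma: plasma-to-liver
#' uptake times the probability that tracer in the reversible hepatic
#' compartment proceeds irreversibly (H1 -> H2) rather than refluxing to
#' plasma. At steady state this equals the flux into gallbladder/intestine
#' divided by the plasma concentration.
#'
#' @param k A \code{\link{rate_constant_set}}.
#' @param v_plasma Plasma volume, ml.
#' @return CL_H in ul/min.
#' @export
cl_hepatic <- function(k, v_plasma) {
  stopifnot(inherits(k, "rate_constant_set"))
  den <- k$k_h1b + k$k_h1h2
  if (den <= 0) {
    if (k$k_bh1 == 0) return(0)
    stop("cl_hepatic: k_h1b + k_h1h2 = 0 with nonzero hepatic uptake")
  }
  k$k_bh1 * k$k_h1h2 / den * v_plasma * 1000
}

#' Renal clearance from rate constants
#'
#' The two kidney compartments are treated as one: the effective urinary
#' rate is k_R1U / (1 + k_R1R2/k_R2R1), correcting for the mass fraction
#' residing in R1, and CL_R = k_BR1 * k_eff / (k_R1B + k_eff) * V_Plasma.
#'
#' @param k A \code{\link{rate_constant_set}}.
#' @param v_plasma Plasma volume, ml.
#' @return CL_R in ul/min.
#' @export
cl_renal <- function(k, v_plasma) {
  stopifnot(inherits(k, "rate_constant_set"))
  if (k$k_r1r2 > 0 && k$k_r2r1 == 0)
    stop("cl_renal: k_r1r2 > 0 with k_r2r1 = 0 (irreversible trap; ",
         "the one-compartment reduction is invalid)")
  keff <- if (k$k_r1r2 == 0) k$k_r1u
          else k$k_r1u / (1 + k$k_r1r2 / k$k_r2r1)
  den <- k$k_r1b + keff
  if (den <= 0) {
    if (k$k_br1 == 0) return(0)
    stop("cl_renal: k_r1b + effective urinary rate = 0 with nonzero renal uptake")
  }
  k$k_br1 * keff / den * v_plasma * 1000
}

#' Tissue-to-plasma distribution coefficient at equilibrium
#'
#' D_Tissue = [f_BT1 k_BT / k_TB1 + (1 - f_BT1) k_BT / k_TB2] *
#' V_Plasma / V_Tissue: the equilibrium amount ratio of the two tissue
#' sub-compartments to plasma, converted to a concentration ratio.
#'
#' @param k A \code{\link{rate_constant_set}}.
#' @param v_plasma Plasma volume, ml.
#' @return Dimensionless distribution coefficient.
#' @export
d_tissue <- function(k, v_plasma) {
  stopifnot(inherits(k, "rate_constant_set"))
  term <- function(frac, k_out) {
    influx <- frac * k$k_bt
    if (influx == 0) return(0)
    if (k_out <= 0)
      stop("d_tissue: zero tissue efflux with nonzero influx fraction")
    influx / k_out
  }
  (term(k$f_bt1, k$k_tb1) + term(1 - k$f_bt1, k$k_tb2)) *
    v_plasma / k$v_tissue
}

#' All derived pharmacokinetic quantities for one scan
#'
#' Assembles CL_H, CL_R, the transintestinal clearance CL_TI = k_BG x
#' V_Plasma, total CL = CL_H + CL_R + CL_TI, hepatic extraction ratio
#' E_H = CL_H / Q_P,H, CL_R/GFR, CL_H/CL_R and D_Tissue.
#'
#' @param k A \code{\link{rate_constant_set}}.
#' @param scan The \code{\link{scan_record}} (body weight).
#' @param phys A \code{\link{physiology_constants}} object.
#' @return Object of class \code{derived_pk}: named list of clearances
#'   (ul/min) and dimensionless ratios.
#' @export
derive_all <- function(k, scan, phys = physiology_constants()) {
  validate_scan_record(scan)
  v_plasma <- plasma_volume(scan$body_weight, phys)
  cl_h <- cl_hepatic(k, v_plasma)
  cl_r <- cl_renal(k, v_plasma)
  cl_ti <- k$k_bg * v_plasma * 1000
  structure(list(cl_h = cl_h,
                 cl_r = cl_r,
                 cl_ti = cl_ti,
                 cl_total = cl_h + cl_r + cl_ti,
                 e_h = cl_h / (phys$q_p_hepatic * 1000),
                 cl_r_over_gfr = cl_r / phys$gfr,
                 cl_h_over_cl_r = if (cl_r > 0) cl_h / cl_r else NA_real_,
                 d_tissue = d_tissue(k, v_plasma),
                 v_plasma = v_plasma),
            class = "derived_pk")
}

#' @export
print.derived_pk <- function(x, ...) {
  cat(sprintf("CL_H %.3g ul/min, CL_R %.3g ul/min, CL %.3g ul/min\n",
              x$cl_h, x$cl_r, x$cl_total))
  cat(sprintf("E_H %.2g, CL_R/GFR %.2g, CL_H/CL_R %.2g, D_Tissue %.2g\n",
              x$e_h, x$cl_r_over_gfr, x$cl_h_over_cl_r, x$d_tissue))
  invisible(x)
}

#' Homoscedastic two-tailed two-sample t-test
#'
#' Pooled-variance Student's t-test, the group comparison used throughout
#' the reporting layer; significance is declared at p < 0.05. Implemented
#' from the closed form (not delegated) so the statistic is available with
#' its degenerate-variance handling: equal means with zero pooled variance
#' give p = 1, unequal means give p = 0 with \code{degenerate = TRUE}.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @return Object of class \code{group_comparison}: means, SDs, n, the t
#'   statistic, df, two-sided p, and \code{significant} (p < 0.05).
#' @export
compare_groups <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L)
    stop("compare_groups: each group needs at least 2 values")
  ma <- mean(values_a); mb <- mean(values_b)
  va <- stats::var(values_a); vb <- stats::var(values_b)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  degenerate <- FALSE
  if (sp2 <= 0) {
    degenerate <- TRUE
    if (ma == mb) { tstat <- 0; p <- 1 }
    else { tstat <- sign(ma - mb) * Inf; p <- 0 }
  } else {
    tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  structure(list(mean_a = ma, sd_a = sqrt(va), n_a = na,
                 mean_b = mb, sd_b = sqrt(vb), n_b = nb,
                 t = tstat, df = df, p = p,
                 significant = p < 0.05, degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group A: %.4g +/- %.4g (n=%d); Group B: %.4g +/- %.4g (n=%d)\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("t = %.4g (df %d), p = %.4g%s\n", x$t, x$df, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}
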