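#' Isotope model constants for the 13C qSIP density model
#'
#' Parameters of the linear relationships linking DNA buoyant density, GC
#' content, and mean nucleotide molar mass that underlie excess atom fraction
#' (EAF) estimation. Defaults are the canonical constants of the qSIP method
#' of Hungate and co-workers, used by the standard qSIP workflows:
#'
#' * GC content from unlabeled ("light") buoyant density:
#'   `GC = (W_light - gc_intercept) / gc_slope`
#' * mean molar mass of an unlabeled nucleotide:
#'   `M_light = mw_slope * GC + mw_intercept` (g/mol)
#' * maximum possible mass gain under full 13C labeling:
#'   `M_heavymax - M_light = dmax_intercept + dmax_slope * GC` (g/mol);
#'   dAMP/dTMP/dGMP carry 10 carbon atoms and dCMP 9, so the mean number of
#'   carbons per nucleotide falls linearly with GC (10 - 0.5 GC), which is why
#'   `dmax_slope` is negative.
#' * `nat_13c` is the natural abundance atom fraction of 13C; EAF is reported
#'   in excess of it, so the saturation value of EAF is `1 - nat_13c`.
#'
#' All constants can be overridden, e.g. to propagate an independently
#' calibrated density-GC regression.
#'
#' @param gc_intercept Buoyant density at GC = 0 (g/ml).
#' @param gc_slope Density increase per unit GC fraction (g/ml).
#' @param mw_intercept Mean nucleotide molar mass at GC = 0 (g/mol).
#' @param mw_slope Molar mass increase per unit GC (g/mol).
#' @param dmax_intercept,dmax_slope Linear coefficients of the maximum 13C
#'   mass gain as a function of GC (g/mol).
#' @param nat_13c Natural 13C atom fraction (dimensionless).
#'
#' @return An object of class `qsip_constants`: a named list of the seven
#'   constants, validated.
#' @examples
#' qsip_constants()
#' qsip_constants(nat_13c = 0.0112)
#' @export
qsip_constants <- function(gc_intercept = 1.646057,
                           gc_slope = 0.083506,
                           mw_intercept = 307.691,
                           mw_slope = 0.496,
                           dmax_intercept = 9.974564,
                           dmax_slope = -0.4987282,
                           nat_13c = 0.01111233) {
  const <- list(
    gc_intercept = gc_intercept, gc_slope = gc_slope,
    mw_intercept = mw_intercept, mw_slope = mw_slope,
    dmax_intercept = dmax_intercept, dmax_slope = dmax_slope,
    nat_13c = nat_13c
  )
  if (!all(vapply(const, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1)))) {
    stop("all isotope constants must be finite numeric scalars", call. = FALSE)
  }
  if (gc_slope <= 0) stop("`gc_slope` must be positive", call. = FALSE)
  dmax <- dmax_intercept + dmax_slope * c(0, 1)
  if (any(dmax <= 0)) {
    stop("maximum 13C mass gain must be positive over GC in [0, 1]",
         call. = FALSE)
  }
  if (nat_13c <= 0 || nat_13c >= 0.02) {
    stop("`nat_13c` must lie in (0, 0.02)", call. = FALSE)
  }
  structure(const, class = "qsip_constants")
}

#' @export
print.qsip_constants <- function(x, ...) {
  cat("qSIP isotope model constants (13C):\n")
  cat(sprintf("  GC = (W_light - %.6f) / %.6f\n", x$gc_intercept, x$gc_slope))
  cat(sprintf("  M_light = %.3f + %.3f GC  [g/mol]\n",
              x$mw_intercept, x$mw_slope))
  cat(sprintf("  dM_max  = %.6f %+.7f GC  [g/mol]\n",
              x$dmax_intercept, x$dmax_slope))
  cat(sprintf("  natural 13C atom fraction = %.8f\n", x$nat_13c))
  invisible(x)
}

as_qsip_constants <- function(x) {
  if (inherits(x, "qsip_constants")) return(x)
  if (is.null(x)) return(qsip_constants())
  do.call(qsip_constants, as.list(x))
}
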