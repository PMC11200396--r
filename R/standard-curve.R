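# Linear calibration curves for analyte quantification (GSH, pNA/caspase-3).

#' Fit a straight-line standard curve
#'
#' Ordinary least squares of signal on known concentration,
#' `signal = slope * concentration + intercept`. Single-range assay
#' calibrations are treated as linear.
#'
#' @param concentration Known standard concentrations (>= 2 distinct values).
#' @param signal Measured signals at those concentrations.
#' @param analyte Optional analyte label.
#' @return An object of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared` and the calibration points.
#' @examples
#' sc <- fit_standard_curve(c(0, 5, 10), c(0.05, 1.05, 2.05))
#' sc$slope # 0.2
#' @export
fit_standard_curve <- function(concentration, signal, analyte = "analyte") {
  if (length(concentration) != length(signal)) {
    stop("concentration and signal lengths differ", call. = FALSE)
  }
  if (length(unique(concentration)) < 2) {
    stop("rank deficiency: need >= 2 distinct standard concentrations", call. = FALSE)
  }
  fit <- stats::lm(signal ~ concentration)
  slope <- unname(stats::coef(fit)[2])
  if (slope == 0 || stats::sd(signal) == 0) {
    stop("degenerate standard curve: fitted slope is zero", call. = FALSE)
  }
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((signal - mean(signal))^2)
  structure(
    list(analyte = analyte, slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         points = data.frame(known_concentration = concentration, signal = signal)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve for %s: signal = %.6g * conc + %.6g (r^2 = %.4f, %d points)\n",
              x$analyte, x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @export
predict.standard_curve <- function(object, concentration, ...) {
  object$slope * concentration + object$intercept
}

#' Invert a standard curve to quantify an unknown
#'
#' Returns `(signal - intercept) / slope`. Results below zero (signal under
#' the blank) are returned unclipped with a warning so extrapolation is
#' visible to the caller.
#'
#' @param curve A [fit_standard_curve()] object.
#' @param signal Measured signal(s) of the unknown(s).
#' @return Estimated concentration(s) in the units of the standards.
#' @export
quantify_from_curve <- function(curve, signal) {
  if (!inherits(curve, "standard_curve")) stop("curve must be a standard_curve", call. = FALSE)
  if (curve$slope == 0) stop("non-invertible curve: slope is zero", call. = FALSE)
  conc <- (signal - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning("quantified concentration below zero (signal under the blank); not clipped",
            call. = FALSE)
  }
  conc
}
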