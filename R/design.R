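# Fixed-ratio (ray) mixture design and dilution series.

#' Fixed-ratio mixture components from monotherapy EC50s
#'
#' A two-drug ray is parameterised by the EC50-fraction weight `f_a`:
#' component concentrations are `c_a = f_a * ec50_a` and
#' `c_b = (1 - f_a) * ec50_b`, so the total `c_a + c_b` is the additive-theory
#' EC50 of that ratio (`f_a * ec50_a + (1 - f_a) * ec50_b`). Ratio labels
#' such as "1:4" are metadata; the controlling parameter is `f_a`. Full
#' precision is retained; rounding for human-readable tables is a separate
#' formatting concern (see [format.mixture_design()]).
#'
#' @param ec50_a,ec50_b Monotherapy EC50s in micromolar (> 0).
#' @param f_a EC50-fraction weight of drug A, in `[0, 1]`.
#' @param label Optional ratio label (e.g. `"1:4"`).
#' @param drug_a,drug_b Drug labels.
#' @return An object of class `mixture_design` with fields `f_a`, `f_b`,
#'   `c_a`, `c_b`, `total`, `label`.
#' @examples
#' fixed_ratio_components(10.06, 0.07, 0.5, "1:1") # 5.03 + 0.035 = 5.065 uM
#' @export
fixed_ratio_components <- function(ec50_a, ec50_b, f_a, label = NULL,
                                   drug_a = "drug_a", drug_b = "drug_b") {
  if (!is.finite(ec50_a) || !is.finite(ec50_b) || ec50_a <= 0 || ec50_b <= 0) {
    stop("EC50s must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(f_a) || f_a < 0 || f_a > 1) {
    stop("f_a must lie in [0, 1]", call. = FALSE)
  }
  c_a <- f_a * ec50_a
  c_b <- (1 - f_a) * ec50_b
  structure(
    list(drug_a = drug_a, drug_b = drug_b,
         f_a = f_a, f_b = 1 - f_a,
         c_a = c_a, c_b = c_b, total = c_a + c_b,
         ec50_a = ec50_a, ec50_b = ec50_b,
         label = label %||% sprintf("f_a=%g", f_a)),
    class = "mixture_design"
  )
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Format a mixture design at reporting precision
#'
#' @param x A [fixed_ratio_components()] design.
#' @param digits_a,digits_b Decimal places for the component concentrations
#'   in the human-readable line (machine output stays full precision).
#' @param ... Unused.
#' @export
format.mixture_design <- function(x, digits_a = 2, digits_b = 3, ...) {
  c(sprintf("Fixed-ratio mixture %s (f_%s = %g, f_%s = %g)",
            x$label, x$drug_a, x$f_a, x$drug_b, x$f_b),
    sprintf("  %s %.*f uM + %s %.*f uM = %.4g uM total",
            x$drug_a, digits_a, x$c_a, x$drug_b, digits_b, x$c_b, x$total))
}

#' Geometric dilution series along a mixture ray
#'
#' Totals `center * factor^k` for `k = -n_each_side, ..., n_each_side`; the
#' center value itself is dropped when `exclude_center` (the design used to
#' bracket the most effective mixing concentration while omitting it).
#' Each total is split into components preserving the ray proportions
#' `c_a / total` and `c_b / total`.
#'
#' @param design A [fixed_ratio_components()] object.
#' @param center_total Center of the series in micromolar (> 0); defaults to
#'   the design total.
#' @param n_each_side Dilution steps on each side (>= 1, default 3).
#' @param factor Geometric step (> 1, default 2).
#' @param exclude_center Drop the center value itself? (default TRUE)
#' @return An object of class `dilution_series`: a data.frame with columns
#'   `level`, `total`, `c_a`, `c_b`, plus attributes `design`,
#'   `center_excluded`.
#' @export
dilution_series <- function(design, center_total = design$total, n_each_side = 3,
                            factor = 2, exclude_center = TRUE) {
  if (!inherits(design, "mixture_design")) stop("design must be a mixture_design", call. = FALSE)
  if (!is.finite(center_total) || center_total <= 0) stop("center_total must be > 0", call. = FALSE)
  if (!is.finite(factor) || factor <= 1) stop("dilution factor must be > 1", call. = FALSE)
  if (n_each_side < 1) stop("n_each_side must be >= 1", call. = FALSE)
  k <- if (exclude_center) c(-(n_each_side:1), 1:n_each_side) else
    (-n_each_side):n_each_side
  totals <- center_total * factor^k
  p_a <- design$c_a / design$total
  out <- data.frame(level = k, total = totals,
                    c_a = totals * p_a, c_b = totals * (1 - p_a))
  attr(out, "design") <- design
  attr(out, "center_excluded") <- exclude_center
  attr(out, "factor") <- factor
  class(out) <- c("dilution_series", "data.frame")
  out
}

#' Write design / dilution tables as CSV
#'
#' Design header: `label,f_a,c_a_uM,c_b_uM,total_uM`; the dilution CSV adds
#' a `level` column.
#'
#' @param x A `mixture_design`, a list of them, or a `dilution_series`.
#' @param path File path.
#' @export
write_design <- function(x, path) {
  if (inherits(x, "mixture_design")) x <- list(x)
  if (inherits(x, "dilution_series")) {
    d <- attr(x, "design")
    out <- data.frame(label = d$label, f_a = d$f_a, level = x$level,
                      c_a_uM = x$c_a, c_b_uM = x$c_b, total_uM = x$total)
  } else {
    out <- do.call(rbind, lapply(x, function(d) {
      data.frame(label = d$label, f_a = d$f_a, c_a_uM = d$c_a,
                 c_b_uM = d$c_b, total_uM = d$total)
    }))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
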