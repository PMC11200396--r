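# Loewe isobolographic synergy analysis: theoretical additive EC50,
# additivity/interaction indices, potency comparison and classification.

#' Theoretical additive EC50 of a fixed-ratio mixture
#'
#' Under Loewe additivity the mixture behaves as a dilution of its
#' components, so the 50%-effect total concentration of the ray with
#' EC50-fraction `f_a` is the weighted sum
#' `EC50T = f_a * EC50_A + (1 - f_a) * EC50_B`. Its SEM is propagated
#' assuming independent monotherapy errors,
#' `sqrt(f_a^2 * sem_A^2 + (1 - f_a)^2 * sem_B^2)`; pass `sem` to override
#' with an externally supplied value.
#'
#' @param est_a,est_b Monotherapy EC50s as [potency_estimate()] objects
#'   (or `list(value, sem)`).
#' @param f_a EC50-fraction weight of drug A, in `[0, 1]`.
#' @param sem Optional SEM override in micromolar.
#' @param n Replicates to carry for the downstream t-test.
#' @return A [potency_estimate()] of kind `"EC50T"`.
#' @examples
#' a <- potency_estimate(10.06, 0.22)
#' b <- potency_estimate(0.07, 0.004)
#' theoretical_additive_ec50(a, b, 0.25)
#' @export
theoretical_additive_ec50 <- function(est_a, est_b, f_a, sem = NULL, n = NULL) {
  est_a <- .as_potency(est_a, "est_a")
  est_b <- .as_potency(est_b, "est_b")
  if (!is.finite(f_a) || f_a < 0 || f_a > 1) stop("f_a must lie in [0, 1]", call. = FALSE)
  value <- f_a * est_a$value + (1 - f_a) * est_b$value
  sem <- sem %||% sqrt(f_a^2 * est_a$sem^2 + (1 - f_a)^2 * est_b$sem^2)
  n <- n %||% min(est_a$n, est_b$n)
  potency_estimate(value, sem, kind = "EC50T", n = n)
}

#' Additivity index of a combination point
#'
#' `i = c_a / EC50_A + c_b / EC50_B`: the sum of each component expressed as
#' a fraction of its own equieffective concentration. Points on the
#' additivity line have `i = 1`.
#'
#' @param c_a,c_b Component concentrations in micromolar (>= 0).
#' @param ec50_a,ec50_b Monotherapy EC50s in micromolar (> 0).
#' @return The dimensionless index.
#' @export
additivity_index <- function(c_a, c_b, ec50_a, ec50_b) {
  if (any(!is.finite(c(ec50_a, ec50_b))) || any(c(ec50_a, ec50_b) <= 0)) {
    stop("EC50s must be > 0", call. = FALSE)
  }
  if (any(c(c_a, c_b) < 0)) stop("concentrations must be >= 0", call. = FALSE)
  c_a / ec50_a + c_b / ec50_b
}

#' Interaction index
#'
#' `I = EC50E / EC50T`: experimentally fitted mixture potency over the
#' Loewe-additive prediction. `I < 1` indicates synergy (the mixture is more
#' potent than additivity predicts), `I = 1` additivity, `I > 1` antagonism.
#'
#' @param ec50_e Experimental mixture EC50 (total concentration, uM, > 0).
#' @param ec50_t Theoretical additive EC50 (uM, > 0).
#' @return The dimensionless index.
#' @examples
#' interaction_index(0.26, 2.55) # ~0.10
#' @export
interaction_index <- function(ec50_e, ec50_t) {
  if (any(!is.finite(c(ec50_e, ec50_t))) || any(c(ec50_e, ec50_t) <= 0)) {
    stop("potencies must be > 0", call. = FALSE)
  }
  ec50_e / ec50_t
}

#' Welch's t comparison of experimental vs theoretical potency
#'
#' With only (value, SEM, n) summaries available,
#' `t = (value_T - value_E) / sqrt(sem_T^2 + sem_E^2)` with
#' Welch-Satterthwaite degrees of freedom
#' `(sem_E^2 + sem_T^2)^2 / (sem_E^4/(n_E - 1) + sem_T^4/(n_T - 1))`
#' and a two-sided p-value.
#'
#' @param est_e,est_t [potency_estimate()] objects (SEMs must be > 0).
#' @param n_e,n_t Replicates behind each estimate (>= 2); defaults to the
#'   `n` stored on the estimates.
#' @return A list with `t_statistic`, `dof`, `p_value`.
#' @export
compare_potencies <- function(est_e, est_t, n_e = NULL, n_t = NULL) {
  est_e <- .as_potency(est_e, "est_e")
  est_t <- .as_potency(est_t, "est_t")
  n_e <- n_e %||% est_e$n
  n_t <- n_t %||% est_t$n
  if (est_e$sem <= 0 || est_t$sem <= 0) {
    stop("degenerate variance: both SEMs must be > 0", call. = FALSE)
  }
  if (is.na(n_e) || is.na(n_t) || n_e < 2 || n_t < 2) {
    stop("replicate counts n_e and n_t must be >= 2", call. = FALSE)
  }
  se2 <- est_e$sem^2 + est_t$sem^2
  t_stat <- (est_t$value - est_e$value) / sqrt(se2)
  dof <- se2^2 / (est_e$sem^4 / (n_e - 1) + est_t$sem^4 / (n_t - 1))
  list(t_statistic = t_stat, dof = dof,
       p_value = 2 * stats::pt(-abs(t_stat), dof))
}

#' Classify a drug-drug interaction
#'
#' Tallarida's index rule gated by significance: synergistic when `I < 1`
#' and the theoretical-vs-experimental comparison rejects at `alpha`;
#' antagonistic when `I > 1` and significant; otherwise additive
#' (statistically indistinguishable from the additivity line).
#'
#' @param I Interaction index (> 0).
#' @param p_value Two-sided p-value from [compare_potencies()].
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return `"synergistic"`, `"additive"` or `"antagonistic"`.
#' @export
classify_interaction <- function(I, p_value, alpha = 0.05) {
  if (!is.finite(I) || I <= 0) stop("I must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (p_value < alpha) {
    if (I < 1) "synergistic" else if (I > 1) "antagonistic" else "additive"
  } else {
    "additive"
  }
}

#' Full interaction assessment for one fixed-ratio mixture
#'
#' Assembles the theoretical additive EC50 (from the monotherapy estimates
#' and ray fraction, unless supplied directly), the interaction index
#' `I = EC50E / EC50T`, its reciprocal fold-reduction in equipotent
#' concentration, Welch's t comparison and the classification.
#'
#' @param ec50_e Experimental mixture EC50 ([potency_estimate()] or
#'   `list(value, sem)`), total concentration of the ray.
#' @param est_a,est_b Monotherapy EC50 estimates (needed when `ec50_t` is
#'   not supplied).
#' @param f_a Ray EC50-fraction of drug A.
#' @param ec50_t Optional theoretical EC50 supplied directly.
#' @param n_e,n_t Replicates behind each potency.
#' @param alpha Significance level for the classification.
#' @return An object of class `interaction_assessment` with fields `ec50_t`,
#'   `ec50_e`, `f_a`, `additivity_index_i`, `interaction_index_I`,
#'   `fold_reduction`, `t_statistic`, `dof`, `p_value`, `classification`.
#' @examples
#' assess_interaction(potency_estimate(0.26, 0.039, n = 9),
#'                    ec50_t = potency_estimate(2.55, 0.013, n = 9), f_a = 0.25)
#' @export
assess_interaction <- function(ec50_e, est_a = NULL, est_b = NULL, f_a = NULL,
                               ec50_t = NULL, n_e = NULL, n_t = NULL,
                               alpha = 0.05) {
  ec50_e <- .as_potency(ec50_e, "ec50_e")
  ec50_e$kind <- "EC50E"
  if (is.null(ec50_t)) {
    if (is.null(est_a) || is.null(est_b) || is.null(f_a)) {
      stop("supply either ec50_t or (est_a, est_b, f_a)", call. = FALSE)
    }
    ec50_t <- theoretical_additive_ec50(est_a, est_b, f_a)
  } else {
    ec50_t <- .as_potency(ec50_t, "ec50_t")
    ec50_t$kind <- "EC50T"
  }
  I <- interaction_index(ec50_e$value, ec50_t$value)
  i <- if (!is.null(est_a) && !is.null(est_b) && !is.null(f_a)) {
    d <- fixed_ratio_components(.as_potency(est_a)$value, .as_potency(est_b)$value, f_a)
    additivity_index(ec50_e$value * d$c_a / d$total, ec50_e$value * d$c_b / d$total,
                     d$ec50_a, d$ec50_b)
  } else I
  cmp <- compare_potencies(ec50_e, ec50_t, n_e = n_e, n_t = n_t)
  structure(
    list(ec50_t = ec50_t, ec50_e = ec50_e, f_a = f_a,
         additivity_index_i = i,
         interaction_index_I = I,
         fold_reduction = 1 / I,
         t_statistic = cmp$t_statistic, dof = cmp$dof, p_value = cmp$p_value,
         alpha = alpha,
         classification = classify_interaction(I, cmp$p_value, alpha)),
    class = "interaction_assessment"
  )
}

#' @export
print.interaction_assessment <- function(x, digits = 3, ...) {
  cat("Isobolographic interaction assessment",
      if (!is.null(x$f_a)) sprintf("(ray f_a = %g)", x$f_a) else "", "\n")
  cat(sprintf("  EC50T = %.4g +/- %.3g uM,  EC50E = %.4g +/- %.3g uM\n",
              x$ec50_t$value, x$ec50_t$sem, x$ec50_e$value, x$ec50_e$sem))
  cat(sprintf("  interaction index I = %.*g (fold reduction %.3g)\n",
              digits, x$interaction_index_I, x$fold_reduction))
  cat(sprintf("  Welch t = %.4g on %.3g df, p = %.3g  =>  %s\n",
              x$t_statistic, x$dof, x$p_value, toupper(x$classification)))
  invisible(x)
}

#' Isobologram coordinates for export
#'
#' The 50%-effect isobologram places drug A's EC50 on the y-axis and drug
#' B's on the x-axis; the additivity line joins `(0, EC50_A)` to
#' `(EC50_B, 0)`. The theoretical point is the ray design itself
#' (`(c_b, c_a)` at total EC50T) and the experimental point decomposes
#' EC50E along the same ray proportions.
#'
#' @param est_a,est_b Monotherapy EC50 estimates (drug A on y, drug B on x).
#' @param assessment An [assess_interaction()] result (for EC50E), optional.
#' @param design A [fixed_ratio_components()] design defining the ray.
#' @return A data.frame with columns
#'   `element, x_conc_b_uM, y_conc_a_uM, x_sem, y_sem`; elements are
#'   `axis_a`, `axis_b`, `line_start`, `line_end`, `theoretical_point` and
#'   (when an assessment is given) `experimental_point`.
#' @export
isobologram_coordinates <- function(est_a, est_b, assessment = NULL, design) {
  est_a <- .as_potency(est_a, "est_a")
  est_b <- .as_potency(est_b, "est_b")
  if (!inherits(design, "mixture_design")) stop("design must be a mixture_design", call. = FALSE)
  rows <- list(
    data.frame(element = "axis_a", x_conc_b_uM = 0, y_conc_a_uM = est_a$value,
               x_sem = 0, y_sem = est_a$sem),
    data.frame(element = "axis_b", x_conc_b_uM = est_b$value, y_conc_a_uM = 0,
               x_sem = est_b$sem, y_sem = 0),
    data.frame(element = "line_start", x_conc_b_uM = 0, y_conc_a_uM = est_a$value,
               x_sem = NA_real_, y_sem = NA_real_),
    data.frame(element = "line_end", x_conc_b_uM = est_b$value, y_conc_a_uM = 0,
               x_sem = NA_real_, y_sem = NA_real_),
    data.frame(element = "theoretical_point", x_conc_b_uM = design$c_b,
               y_conc_a_uM = design$c_a, x_sem = NA_real_, y_sem = NA_real_)
  )
  if (!is.null(assessment)) {
    tot <- assessment$ec50_e$value
    rows <- c(rows, list(
      data.frame(element = "experimental_point",
                 x_conc_b_uM = tot * design$c_b / design$total,
                 y_conc_a_uM = tot * design$c_a / design$total,
                 x_sem = NA_real_, y_sem = NA_real_)
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
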