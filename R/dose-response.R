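# Sigmoidal concentration-response fitting with probit/logit links and
# effective-concentration (ECp) estimation.

.clip_eps <- 1e-6

#' Map endpoint values onto a 0-1 effect fraction
#'
#' Rescales endpoint values (cytoprotection or lethality percentages) to the
#' unit interval for link-scale fitting:
#' `effect = clip((value - baseline) / (ceiling - baseline), 0, 1)`.
#' For lethality use `baseline = 0`, `ceiling = 100`; for cytoprotection the
#' baseline is the injured, untreated viability and the ceiling the control
#' viability.
#'
#' @param endpoints A data.frame with columns `concentration`, `value` and
#'   optionally `n` (replicates per cell, default 1).
#' @param effect_kind `"cytoprotection"` or `"lethality"` (metadata).
#' @param baseline,ceiling Endpoint values mapping to effect 0 and 1;
#'   `ceiling > baseline` required.
#' @param drug_id Optional label.
#' @return A data.frame with `concentration`, `effect_fraction`, `n` and
#'   attributes `effect_kind`, `drug_id`.
#' @export
build_curve_data <- function(endpoints, effect_kind = c("cytoprotection", "lethality"),
                             baseline = 0, ceiling = 100,
                             drug_id = endpoints$drug_id[1] %||% "drug") {
  effect_kind <- match.arg(effect_kind)
  if (!is.finite(baseline) || !is.finite(ceiling) || ceiling <= baseline) {
    stop("ceiling must exceed baseline", call. = FALSE)
  }
  e <- (endpoints$value - baseline) / (ceiling - baseline)
  out <- data.frame(
    concentration = endpoints$concentration,
    effect_fraction = pmin(pmax(e, 0), 1),
    n = if ("n" %in% names(endpoints)) endpoints$n else 1L
  )
  attr(out, "effect_kind") <- effect_kind
  attr(out, "drug_id") <- as.character(drug_id)
  out
}

#' Fit a probit or logit concentration-response model
#'
#' Maximum-likelihood fit of
#' `effect_fraction ~ linkinv(intercept + slope * log10(concentration))`,
#' treating each point as a binomial proportion with effective size `n`
#' (quasi-binomial weighting: point estimates are the weighted-binomial MLE;
#' the parameter covariance is the inverse information scaled by the
#' estimated dispersion, so over- or under-dispersion relative to the
#' nominal binomial is absorbed). The concentration metameter is log10
#' micromolar, which makes every ECp exactly equivariant under unit changes.
#' Zero-concentration control wells must not be entered here; they serve
#' normalisation only.
#'
#' @param data A data.frame with columns `concentration` (> 0, at least 4
#'   distinct values), `effect_fraction` (in `[0, 1]`; values are clipped to
#'   `[1e-6, 1 - 1e-6]` to keep the link finite) and optionally `n`.
#' @param link `"probit"` (default) or `"logit"`.
#' @return An object of class `potency_fit`: coefficients (intercept, slope
#'   per log10 uM), dispersion-scaled covariance, `log_ec50 = -intercept/slope`,
#'   the weighted-binomial log-likelihood, and convergence flag. Supports
#'   `coef`, `vcov`, `logLik`, `predict`, `residuals`, `summary`, `plot`.
#' @seealso [effective_concentration()]
#' @examples
#' d <- data.frame(concentration = c(2, 5, 10, 20, 50),
#'                 effect_fraction = c(0.05, 0.2, 0.5, 0.8, 0.97), n = 9)
#' fit <- fit_concentration_response(d)
#' effective_concentration(fit, 0.5)
#' @export
fit_concentration_response <- function(data, link = c("probit", "logit")) {
  link <- match.arg(link)
  if (!is.data.frame(data) ||
      !all(c("concentration", "effect_fraction") %in% names(data))) {
    stop("data needs columns 'concentration' and 'effect_fraction'", call. = FALSE)
  }
  conc <- data$concentration
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("concentrations must be finite and > 0 (zero-concentration controls are for normalisation, not fitting)",
         call. = FALSE)
  }
  if (length(unique(conc)) < 4) {
    stop("insufficient design: need >= 4 distinct concentrations", call. = FALSE)
  }
  y_raw <- data$effect_fraction
  if (any(!is.finite(y_raw)) || any(y_raw < 0) || any(y_raw > 1)) {
    stop("effect_fraction must lie in [0, 1]; use build_curve_data() to normalise",
         call. = FALSE)
  }
  n <- if ("n" %in% names(data)) data$n else rep(1L, nrow(data))
  if (any(n < 1)) stop("replicate counts n must be >= 1", call. = FALSE)
  y <- pmin(pmax(y_raw, .clip_eps), 1 - .clip_eps)
  if (all(y > 0.5) || all(y < 0.5)) {
    warning("design has no observation on both sides of 50% effect; ECp estimates extrapolate",
            call. = FALSE)
  }
  lc <- log10(conc)
  gfit <- suppressWarnings(stats::glm(
    y ~ lc,
    family = stats::quasibinomial(link = link),
    weights = n,
    control = stats::glm.control(epsilon = 1e-10, maxit = 200)
  ))
  if (!gfit$converged) {
    stop(sprintf("fit failure: IRLS did not converge in %d iterations (deviance %.6g)",
                 gfit$iter, gfit$deviance), call. = FALSE)
  }
  b <- stats::setNames(unname(stats::coef(gfit)), c("intercept", "slope"))
  if (b["slope"] < 0) {
    warning("fitted slope is negative (monotone-decreasing response); check the effect coding",
            call. = FALSE)
  }
  sm <- summary(gfit)
  V <- sm$cov.scaled
  dimnames(V) <- list(c("intercept", "slope"), c("intercept", "slope"))
  mu <- stats::fitted(gfit)
  ll <- sum(n * (y * log(mu) + (1 - y) * log(1 - mu)))
  structure(
    list(link = link,
         coefficients = b,
         covariance = V,
         converged = TRUE,
         log_ec50 = unname(-b["intercept"] / b["slope"]),
         loglik = ll,
         dispersion = sm$dispersion,
         df_residual = gfit$df.residual,
         drug_id = attr(data, "drug_id") %||% "drug",
         effect_kind = attr(data, "effect_kind") %||% NA_character_,
         data = data.frame(concentration = conc, effect_fraction = y, n = n),
         glm = gfit),
    class = "potency_fit"
  )
}

.link_quantile <- function(link, p) {
  switch(link, probit = stats::qnorm(p), logit = stats::qlogis(p))
}

.link_inv <- function(link, eta) {
  switch(link, probit = stats::pnorm(eta), logit = stats::plogis(eta))
}

#' @export
coef.potency_fit <- function(object, ...) object$coefficients

#' @export
vcov.potency_fit <- function(object, ...) object$covariance

#' @export
logLik.potency_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = nrow(object$data), class = "logLik")
}

#' @export
residuals.potency_fit <- function(object, type = "pearson", ...) {
  stats::residuals(object$glm, type = type)
}

#' @export
predict.potency_fit <- function(object, concentration = NULL, ...) {
  concentration <- concentration %||% object$data$concentration
  if (any(concentration <= 0)) stop("concentrations must be > 0", call. = FALSE)
  b <- object$coefficients
  .link_inv(object$link, b["intercept"] + b["slope"] * log10(concentration))
}

#' @export
print.potency_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s concentration-response fit for '%s'\n", x$link, x$drug_id))
  cat(sprintf("  intercept %.*g, slope %.*g per log10(uM)  (dispersion %.3g)\n",
              digits, x$coefficients["intercept"], digits, x$coefficients["slope"],
              x$dispersion))
  cat(sprintf("  EC50 = %.*g uM  (log10 EC50 = %.*g)\n",
              digits, 10^x$log_ec50, digits, x$log_ec50))
  invisible(x)
}

#' @export
summary.potency_fit <- function(object, ...) {
  se <- sqrt(diag(object$covariance))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = object$coefficients / se,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(object$coefficients / se)))
  out <- list(link = object$link, drug_id = object$drug_id, coefficients = tab,
              dispersion = object$dispersion, df_residual = object$df_residual,
              ec50 = effective_concentration(object, 0.5))
  class(out) <- "summary.potency_fit"
  out
}

#' @export
print.summary.potency_fit <- function(x, ...) {
  cat(sprintf("%s concentration-response fit for '%s'\n\n", x$link, x$drug_id))
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nDispersion %.4g on %d residual df\n", x$dispersion, x$df_residual))
  print(x$ec50)
  invisible(x)
}

#' @export
plot.potency_fit <- function(x, n_grid = 200, xlab = "concentration (uM)",
                             ylab = "effect fraction", ...) {
  d <- x$data
  rng <- range(d$concentration)
  cc <- 10^seq(log10(rng[1]) - 0.2, log10(rng[2]) + 0.2, length.out = n_grid)
  plot(d$concentration, d$effect_fraction, log = "x", xlab = xlab, ylab = ylab,
       ylim = c(0, 1), ...)
  graphics::lines(cc, predict(x, cc))
  graphics::abline(h = 0.5, lty = 3)
  graphics::abline(v = 10^x$log_ec50, lty = 3)
  invisible(x)
}

#' Construct a potency estimate directly
#'
#' Container for a potency value (LC50/EC50/ECp) with its SEM, used both by
#' [effective_concentration()] and for entering published values
#' (e.g. an EC50 of 10.06 +/- 0.22 uM) without raw data.
#'
#' @param value Potency in micromolar (> 0).
#' @param sem Standard error of the mean in micromolar (>= 0).
#' @param kind Label, e.g. `"EC50"`, `"LC50"`, `"EC90"`, `"EC50T"`, `"EC50E"`.
#' @param p_level Effect fraction the value refers to (in (0, 1)).
#' @param ci95 Optional length-2 confidence limits in micromolar.
#' @param n Replicates behind the estimate (used by [compare_potencies()]).
#' @return An object of class `potency_estimate`.
#' @export
potency_estimate <- function(value, sem, kind = "EC50", p_level = 0.5,
                             ci95 = NULL, n = NA_integer_) {
  if (!is.finite(value) || value <= 0) stop("potency value must be > 0", call. = FALSE)
  if (!is.finite(sem) || sem < 0) stop("sem must be >= 0", call. = FALSE)
  if (p_level <= 0 || p_level >= 1) stop("p_level must be in (0, 1)", call. = FALSE)
  if (!is.null(ci95)) {
    if (length(ci95) != 2 || any(!is.finite(ci95)) || ci95[1] >= ci95[2]) {
      stop("ci95 must be finite increasing limits", call. = FALSE)
    }
  }
  structure(list(kind = kind, p_level = p_level, value = value, sem = sem,
                 ci95 = ci95, n = n),
            class = "potency_estimate")
}

#' @export
print.potency_estimate <- function(x, digits = 4, ...) {
  ci <- if (is.null(x$ci95)) "" else
    sprintf(" (95%% CI %.*g-%.*g)", digits, x$ci95[1], digits, x$ci95[2])
  cat(sprintf("%s = %.*g +/- %.*g uM%s\n", x$kind, digits, x$value, digits, x$sem, ci))
  invisible(x)
}

# coerce potency_estimate / list / numeric to a (value, sem) pair
.as_potency <- function(x, what = "potency") {
  if (inherits(x, "potency_estimate")) return(x)
  if (is.list(x) && !is.null(x$value)) {
    return(potency_estimate(x$value, x$sem %||% 0, kind = x$kind %||% "EC50",
                            n = x$n %||% NA_integer_))
  }
  if (is.numeric(x) && length(x) >= 1) {
    return(potency_estimate(x[1], if (length(x) >= 2) x[2] else 0))
  }
  stop(what, " must be a potency_estimate, a list(value, sem) or a numeric",
       call. = FALSE)
}

#' Effective concentration at effect level p, with delta-method uncertainty
#'
#' `ECp = 10^((q_p - intercept) / slope)` where `q_p` is the link quantile of
#' `p`. The SEM is obtained by the delta method on the log10 scale from the
#' fit covariance and propagated to micromolar
#' (`sem_uM = ln(10) * ECp * se_log10`); the 95% CI is `+/- 1.96 * se` on the
#' log10 scale, then exponentiated, so it is always positive and asymmetric
#' in micromolar.
#'
#' @param fit A converged [fit_concentration_response()] object with
#'   positive slope.
#' @param p Effect fraction in (0, 1); 0.5 gives the EC50.
#' @param kind Optional label override (e.g. `"LC50"`, `"EC50E"`).
#' @param n Replicates per concentration backing the fit, stored for
#'   downstream t-tests (default: the modal `n` of the fitted data).
#' @return A [potency_estimate()].
#' @export
effective_concentration <- function(fit, p = 0.5, kind = NULL, n = NULL) {
  if (!inherits(fit, "potency_fit")) stop("fit must be a potency_fit", call. = FALSE)
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  b <- fit$coefficients
  if (b["slope"] <= 0) stop("slope must be > 0 to invert the curve", call. = FALSE)
  q <- .link_quantile(fit$link, p)
  lep <- unname((q - b["intercept"]) / b["slope"])
  grad <- c(-1 / b["slope"], -(q - b["intercept"]) / b["slope"]^2)
  v <- drop(t(grad) %*% fit$covariance %*% grad)
  se_l <- sqrt(max(v, 0))
  value <- 10^lep
  if (is.null(kind)) kind <- if (p == 0.5) "EC50" else sprintf("EC%g", 100 * p)
  if (is.null(n)) {
    tab <- table(fit$data$n)
    n <- as.integer(names(tab)[which.max(tab)])
  }
  potency_estimate(
    value = value,
    sem = log(10) * value * se_l,
    kind = kind, p_level = p,
    ci95 = 10^(lep + c(-1, 1) * 1.96 * se_l),
    n = n
  )
}
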