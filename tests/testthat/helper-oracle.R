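# Independent brute-force oracle: grid search over (slope, log_ec50)
# maximising the same weighted-binomial log-likelihood the fitter uses.
grid_loglik_oracle <- function(conc, effect, n, link = "probit",
                               slopes = seq(0.1, 10, length.out = 200),
                               log_ec50s = seq(-3, 3, length.out = 200)) {
  lc <- log10(conc)
  y <- pmin(pmax(effect, 1e-6), 1 - 1e-6)
  linkinv <- if (link == "probit") stats::pnorm else stats::plogis
  best <- -Inf
  best_par <- c(NA, NA)
  for (s in slopes) {
    eta <- s * outer(-log_ec50s, lc, `+`)        # s * (lc - log_ec50)
    mu <- linkinv(eta)
    ll <- drop(log(mu) %*% (n * y) + log1p(-mu) %*% (n * (1 - y)))
    j <- which.max(ll)
    if (ll[j] > best) {
      best <- ll[j]
      best_par <- c(slope = s, log_ec50 = log_ec50s[j])
    }
  }
  list(loglik = best, par = best_par)
}

# noiseless effect fractions from a probit-in-log10-concentration curve
probit_curve <- function(conc, log_ec50, slope) {
  stats::pnorm(slope * (log10(conc) - log_ec50))
}

# the study's 8-point monotherapy grids
dds_series <- c(6.04, 7.65, 9.66, 12.08, 15.30, 19.33, 24.16, 30.6)
cbd_series <- c(0.047, 0.06, 0.07, 0.09, 0.11, 0.15, 0.18, 0.24)

# quick monotherapy recovery experiment at the study design:
# Gaussian effect-fraction noise, sd `noise` per well, averaged over n reps
simulate_mono_fit <- function(ec50, hill, conc, n = 9, noise = 0.05,
                              link = "probit") {
  e_true <- conc^hill / (conc^hill + ec50^hill)
  e_obs <- pmin(pmax(e_true + stats::rnorm(length(conc), 0, noise / sqrt(n)), 0), 1)
  suppressWarnings(fit_concentration_response(
    data.frame(concentration = conc, effect_fraction = e_obs, n = n), link = link))
}
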