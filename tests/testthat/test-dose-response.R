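test_that("build_curve_data rescales endpoints onto the unit interval", {
  ep <- data.frame(concentration = c(1, 2, 3),
                   value = c(47.19, 89.37, 100), n = 9)
  cd <- build_curve_data(ep, "cytoprotection", baseline = 47.19, ceiling = 100)
  expect_equal(cd$effect_fraction[1], 0)
  expect_equal(cd$effect_fraction[3], 1)
  expect_equal(cd$effect_fraction[2], (89.37 - 47.19) / (100 - 47.19))
  expect_error(build_curve_data(ep, baseline = 100, ceiling = 47), "ceiling")
  # out-of-range values are clipped
  ep$value <- c(30, 120, 70)
  cd <- build_curve_data(ep, baseline = 47.19, ceiling = 100)
  expect_true(all(cd$effect_fraction >= 0 & cd$effect_fraction <= 1))
})

test_that("noiseless probit data are recovered to high precision", {
  conc <- 10^seq(0.4, 1.6, length.out = 8)
  d <- data.frame(concentration = conc,
                  effect_fraction = probit_curve(conc, 1, 2), n = 9)
  fit <- fit_concentration_response(d, "probit")
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["slope"]), 2, tolerance = 1e-6)
  expect_equal(10^fit$log_ec50, 10, tolerance = 1e-6)
  est <- effective_concentration(fit, 0.5)
  expect_equal(est$value, 10, tolerance = 1e-6)
})

test_that("the optimiser matches the brute-force likelihood grid", {
  set.seed(101)
  for (k in 1:5) {
    log_ec50 <- runif(1, -1, 1)
    slope <- runif(1, 0.5, 5)
    conc <- 10^seq(log_ec50 - 0.7, log_ec50 + 0.7, length.out = 8)
    e <- pmin(pmax(probit_curve(conc, log_ec50, slope) + rnorm(8, 0, 0.03), 0), 1)
    d <- data.frame(concentration = conc, effect_fraction = e, n = 9)
    fit <- suppressWarnings(fit_concentration_response(d, "probit"))
    oracle <- grid_loglik_oracle(conc, e, rep(9, 8), "probit")
    expect_gte(fit$loglik, oracle$loglik - 1e-6)
  }
})

test_that("fitting contracts: warnings and errors fire on bad designs", {
  conc <- c(1, 2, 4, 8)
  dec <- data.frame(concentration = conc,
                    effect_fraction = c(0.9, 0.7, 0.3, 0.1), n = 9)
  expect_warning(fit_concentration_response(dec), "negative")
  onesided <- data.frame(concentration = conc,
                         effect_fraction = c(0.55, 0.7, 0.8, 0.9), n = 9)
  expect_warning(fit_concentration_response(onesided), "50%")
  expect_error(
    fit_concentration_response(
      data.frame(concentration = c(1, 2, 2, 1),
                 effect_fraction = c(0.2, 0.8, 0.8, 0.2))),
    "insufficient design")
  expect_error(
    fit_concentration_response(
      data.frame(concentration = c(0, 1, 2, 4),
                 effect_fraction = c(0.1, 0.2, 0.5, 0.8))),
    "> 0")
})

test_that("ECp follows closed-form link quantile arithmetic", {
  conc <- 10^seq(0.4, 1.6, length.out = 8)
  fit <- fit_concentration_response(
    data.frame(concentration = conc,
               effect_fraction = probit_curve(conc, 1, 2), n = 9), "probit")
  ec90 <- effective_concentration(fit, 0.9)
  expect_equal(ec90$value, 10^(1 + qnorm(0.9) / 2), tolerance = 1e-6)
  ec50 <- effective_concentration(fit, 0.5)
  expect_equal(ec50$value, 10^fit$log_ec50)
  # monotone in p
  ps <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  vals <- vapply(ps, function(p) effective_concentration(fit, p)$value, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(effective_concentration(fit, 1.2), "p must be")
  # CI straddles the estimate when SEM is positive
  noisy <- suppressWarnings(fit_concentration_response(
    data.frame(concentration = conc,
               effect_fraction = pmin(pmax(probit_curve(conc, 1, 2) +
                                             c(0.02, -0.03, 0.01, 0.02, -0.02, 0.01, -0.01, 0.02), 0), 1),
               n = 9)))
  est <- effective_concentration(noisy, 0.5)
  expect_true(est$ci95[1] < est$value && est$value < est$ci95[2])
  expect_gte(est$sem, 0)
})

test_that("ECp estimates are equivariant under concentration rescaling", {
  set.seed(77)
  conc <- 10^seq(-0.5, 0.7, length.out = 8)
  e <- pmin(pmax(probit_curve(conc, 0, 1.5) + rnorm(8, 0, 0.02), 0), 1)
  for (k in c(0.001, 12.5, 1000)) {
    f1 <- suppressWarnings(fit_concentration_response(
      data.frame(concentration = conc, effect_fraction = e, n = 9)))
    f2 <- suppressWarnings(fit_concentration_response(
      data.frame(concentration = k * conc, effect_fraction = e, n = 9)))
    expect_equal(unname(coef(f2)["slope"]), unname(coef(f1)["slope"]), tolerance = 1e-8)
    for (p in c(0.2, 0.5, 0.9)) {
      expect_equal(effective_concentration(f2, p)$value,
                   k * effective_concentration(f1, p)$value, tolerance = 1e-8)
    }
  }
})

test_that("probit and logit agree at the median on symmetric noiseless data", {
  conc <- 10^seq(0.5, 1.5, length.out = 9) # log-symmetric around EC50 = 10
  e <- probit_curve(conc, 1, 2)
  d <- data.frame(concentration = conc, effect_fraction = e, n = 9)
  ec_p <- effective_concentration(fit_concentration_response(d, "probit"), 0.5)$value
  ec_l <- effective_concentration(fit_concentration_response(d, "logit"), 0.5)$value
  expect_equal(ec_l, ec_p, tolerance = 0.02)
})

test_that("potency_fit behaves like a fitted model object", {
  conc <- 10^seq(0.4, 1.6, length.out = 8)
  d <- data.frame(concentration = conc,
                  effect_fraction = probit_curve(conc, 1, 2), n = 9)
  fit <- fit_concentration_response(d)
  expect_named(coef(fit), c("intercept", "slope"))
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  expect_equal(vcov(fit), t(vcov(fit)))
  expect_true(all(eigen(vcov(fit), only.values = TRUE)$values > -1e-12))
  expect_equal(predict(fit, 10^fit$log_ec50), 0.5, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_length(residuals(fit), 8)
  expect_s3_class(summary(fit), "summary.potency_fit")
  expect_output(print(fit), "EC50")
  expect_equal(attr(logLik(fit), "df"), 2L)
})

test_that("potency_estimate validates and prints published values", {
  est <- potency_estimate(10.06, 0.22, n = 9)
  expect_output(print(est), "10.06")
  expect_error(potency_estimate(-1, 0.1), "> 0")
  expect_error(potency_estimate(1, -0.1), ">= 0")
  expect_error(potency_estimate(1, 0.1, ci95 = c(2, 1)), "ci95")
})
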