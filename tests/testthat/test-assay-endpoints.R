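test_that("viability, lethality and cytoprotection arithmetic is exact", {
  expect_equal(viability_percent(0.5, 0.5), 100)
  expect_equal(viability_percent(0, 0.5), 0)
  expect_equal(viability_percent(0.236, 0.5), 47.2)
  expect_error(viability_percent(0.2, 0), "invalid control")
  expect_error(viability_percent(0.2, -1), "invalid control")

  expect_equal(lethality_percent(100), 0)
  expect_equal(lethality_percent(0), 100)
  expect_equal(lethality_percent(88.18), 11.82)

  expect_equal(cytoprotection_percent(47.19, 47.19), 0)
  expect_equal(cytoprotection_percent(89.37, 47.19), 42.18)
  expect_equal(cytoprotection_percent(100, 47.19), 52.81)
})

test_that("viability and lethality are complementary for any signal (conservation)", {
  set.seed(42)
  v <- viability_percent(runif(50, 0, 2), runif(50, 0.1, 2))
  expect_equal(v + lethality_percent(v), rep(100, 50))
  # antisymmetry of cytoprotection
  a <- runif(20, 0, 120); b <- runif(20, 0, 120)
  expect_equal(cytoprotection_percent(a, b), -cytoprotection_percent(b, a))
})

test_that("LDH cytotoxicity hits its anchors and is affine-invariant", {
  expect_equal(ldh_cytotoxicity_percent(0.1, 0.1, 1.1), 0)
  expect_equal(ldh_cytotoxicity_percent(1.1, 0.1, 1.1), 100)
  expect_equal(ldh_cytotoxicity_percent(0.6, 0.1, 1.1), 50)
  expect_error(ldh_cytotoxicity_percent(0.5, 1, 1), "degenerate window")
  set.seed(7)
  for (shift in c(-0.05, 0.3, 2)) {
    expect_equal(ldh_cytotoxicity_percent(0.47 + shift, 0.1 + shift, 1.3 + shift),
                 ldh_cytotoxicity_percent(0.47, 0.1, 1.3))
  }
})

test_that("standard curves fit, invert, and reject degenerate designs", {
  sc <- fit_standard_curve(c(0, 1, 2), c(0, 2, 4))
  expect_equal(sc$slope, 2)
  expect_equal(sc$intercept, 0)
  expect_equal(sc$r_squared, 1)

  sc2 <- fit_standard_curve(c(0, 5, 10), c(0.05, 1.05, 2.05))
  expect_equal(sc2$slope, 0.2)
  expect_equal(sc2$intercept, 0.05)
  expect_equal(quantify_from_curve(sc2, 1.05), 5)

  expect_error(fit_standard_curve(c(0, 10), c(1, 1)), "slope is zero")
  expect_error(fit_standard_curve(c(3, 3, 3), c(1, 2, 3)), "rank deficiency")
  expect_warning(q <- quantify_from_curve(fit_standard_curve(c(0, 1), c(1, 3)), 0),
                 "below zero")
  expect_equal(q, -0.5)

  # round trip: quantify(predict(conc)) is the identity
  set.seed(3)
  conc <- sort(runif(6, 0, 10))
  sc3 <- fit_standard_curve(conc, 0.3 + 1.7 * conc + rnorm(6, 0, 0.01))
  x <- runif(10, 0, 10)
  expect_equal(quantify_from_curve(sc3, predict(sc3, x)), x)
})

test_that("percent_of_control normalises to the control mean", {
  ctrl <- c(98, 101, 102, 99)
  same <- percent_of_control(ctrl, ctrl)
  expect_equal(same$value, 100)
  expect_equal(same$n, 4L)
  expect_equal(percent_of_control(2 * mean(ctrl), ctrl)$value, 200)
  # OGD/R ROS at 1.737x the control mean reads 173.7%
  expect_equal(percent_of_control(1.737 * mean(ctrl), ctrl)$value, 173.7)
  expect_error(percent_of_control(1, numeric(0)), "empty control")
})

make_mtt_plate <- function() {
  grid <- expand.grid(replicate = 1:3, concentration = c(5, 10, 20, 40))
  rbind(
    data.frame(group = "control", drug_id = "none", concentration = 0,
               replicate = 1:3, assay = "mtt", signal = c(0.49, 0.50, 0.51)),
    data.frame(group = "ogdr", drug_id = "none", concentration = 0,
               replicate = 1:3, assay = "mtt", signal = c(0.24, 0.25, 0.23)),
    data.frame(group = "ogdr_treated", drug_id = "A",
               concentration = grid$concentration, replicate = grid$replicate,
               assay = "mtt", signal = 0.25 + 0.005 * grid$concentration)
  )
}

test_that("plate validation enforces groups, assays and LDH anchors", {
  plate <- make_mtt_plate()
  expect_s3_class(plate_table(plate), "plate_table")
  bad <- plate; bad$group[1] <- "mock"
  expect_error(plate_table(bad), "unknown group")
  bad <- plate; bad$assay[1] <- "xtt"
  expect_error(plate_table(bad), "unknown assay")
  bad <- plate; bad$signal[1] <- -1
  expect_error(plate_table(bad), "signals")
  ldh <- data.frame(group = "ogdr", drug_id = "none", concentration = 0,
                    replicate = 1, assay = "ldh", signal = 0.4)
  expect_error(plate_table(ldh), "blank")
})

test_that("plate_endpoints summarises cells with mean, SEM and n", {
  ep <- plate_endpoints(make_mtt_plate())
  ctrl <- ep[ep$group == "control", ]
  expect_equal(ctrl$value, 100)
  expect_equal(ctrl$n, 3L)
  ogdr <- ep[ep$group == "ogdr", ]
  expect_equal(ogdr$value, 100 * 0.24 / 0.5)
  expect_equal(ogdr$sem, sd(100 * c(0.24, 0.25, 0.23) / 0.5) / sqrt(3))
  trt <- ep[ep$group == "ogdr_treated", ]
  expect_equal(nrow(trt), 4L)
  expect_equal(trt$value, 100 * (0.25 + 0.005 * c(5, 10, 20, 40)) / 0.5)

  cp <- add_cytoprotection(ep)
  expect_equal(cp$endpoint, rep("cytoprotection_pct", 4))
  expect_equal(cp$value, trt$value - ogdr$value)
})

test_that("LDH and percent-of-control assays run through plate_endpoints", {
  plate <- rbind(
    data.frame(group = "blank", drug_id = "none", concentration = 0,
               replicate = 1:2, assay = "ldh", signal = c(0.1, 0.1)),
    data.frame(group = "maximum_release", drug_id = "none", concentration = 0,
               replicate = 1:2, assay = "ldh", signal = c(1.1, 1.1)),
    data.frame(group = "ogdr", drug_id = "none", concentration = 0,
               replicate = 1:2, assay = "ldh", signal = c(0.6, 0.6)),
    data.frame(group = "control", drug_id = "none", concentration = 0,
               replicate = 1:2, assay = "ros", signal = c(100, 100)),
    data.frame(group = "ogdr", drug_id = "none", concentration = 0,
               replicate = 1:2, assay = "ros", signal = c(173, 174.4))
  )
  ep <- plate_endpoints(plate)
  expect_equal(ep$value[ep$endpoint == "ldh_cytotoxicity_pct"], 50)
  ros <- ep[ep$endpoint == "pct_of_control" & ep$group == "ogdr", ]
  expect_equal(ros$value, 173.7)
})

test_that("plate CSV round-trips through the documented dialect", {
  plate <- plate_table(make_mtt_plate())
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_table(plate, path)
  header <- readLines(path, n = 1)
  expect_equal(header, "group,drug_id,concentration_uM,replicate,assay,signal")
  back <- read_plate_table(path)
  expect_equal(back$signal, plate$signal)
  expect_equal(back$concentration, plate$concentration)
})
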