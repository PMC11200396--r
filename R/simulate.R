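# Synthetic OGD/R plate experiments: Hill monotherapy curves, a Loewe
# combination model with interaction parameter psi, and replicate noise.

#' Configuration for a synthetic OGD/R experiment
#'
#' Defaults mirror the study conditions the analysis targets: monotherapy
#' EC50s of 10.06 and 0.07 uM, an injured (OGD/R) baseline of 47.19% of
#' control viability, 8-point concentration series per drug, nine replicates
#' per group, and Gaussian well noise with sd 5% of the control signal.
#' Hill slopes default to 2 (a modelling choice; the steepness is not
#' identifiable from published summaries). `psi` is the Loewe interaction
#' parameter: 1 = additive, < 1 = synergistic, > 1 = antagonistic; with
#' equal Hill slopes the true interaction index of the simulated ray equals
#' `psi` exactly.
#'
#' @param ec50_a,ec50_b True monotherapy EC50s (uM).
#' @param hill_a,hill_b Hill slopes (> 0).
#' @param psi Loewe interaction parameter (> 0).
#' @param viability_control,viability_ogdr Control and injured-baseline
#'   viability (%); control must exceed baseline.
#' @param max_protection Fraction of the control-baseline gap a saturating
#'   treatment can restore (default 1).
#' @param noise_sd Well noise sd as percent of the control signal.
#' @param n_replicates Replicates per group (default 9).
#' @param conc_a,conc_b Monotherapy concentration series (uM).
#' @param f_a Candidate ray fraction(s) of drug A (EC50-fraction weights).
#' @param dilution_factor,n_each_side Geometric dilution design for each
#'   mixture ray around its design total. The default (factor 2, 4 steps
#'   each side) spans center/16 to center*16 so that a strongly synergistic
#'   ray (mixture EC50 near a tenth of the additive prediction) is still
#'   bracketed by assayed concentrations rather than extrapolated.
#' @param control_signal Mean control-well signal (OD units).
#' @param drug_a,drug_b Drug labels.
#' @param seed Integer root seed; per-arm child seeds are derived from it
#'   deterministically.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(ec50_a = 10.06, ec50_b = 0.07,
                              hill_a = 2, hill_b = 2, psi = 1,
                              viability_control = 100, viability_ogdr = 47.19,
                              max_protection = 1, noise_sd = 5,
                              n_replicates = 9L,
                              conc_a = c(6.04, 7.65, 9.66, 12.08, 15.30, 19.33, 24.16, 30.6),
                              conc_b = c(0.047, 0.06, 0.07, 0.09, 0.11, 0.15, 0.18, 0.24),
                              f_a = 0.25,
                              dilution_factor = 2, n_each_side = 4,
                              control_signal = 0.5,
                              drug_a = "DDS", drug_b = "CBD",
                              seed = 1L) {
  stopifnot(ec50_a > 0, ec50_b > 0, hill_a > 0, hill_b > 0, psi > 0,
            viability_control > viability_ogdr,
            max_protection > 0, max_protection <= 1,
            noise_sd >= 0, n_replicates >= 1,
            all(conc_a > 0), all(conc_b > 0),
            all(f_a >= 0), all(f_a <= 1),
            dilution_factor > 1, n_each_side >= 1, control_signal > 0)
  structure(
    list(ec50_a = ec50_a, ec50_b = ec50_b, hill_a = hill_a, hill_b = hill_b,
         psi = psi, viability_control = viability_control,
         viability_ogdr = viability_ogdr, max_protection = max_protection,
         noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
         conc_a = conc_a, conc_b = conc_b, f_a = f_a,
         dilution_factor = dilution_factor, n_each_side = n_each_side,
         control_signal = control_signal, drug_a = drug_a, drug_b = drug_b,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Hill monotherapy effect fraction
#'
#' `e = c^h / (c^h + ec50^h)`, the standard sigmoid on the concentration
#' scale; `e = 0.5` at `c = ec50` for any Hill slope.
#'
#' @param concentration Concentration(s) in uM (>= 0).
#' @param ec50 Half-maximal concentration (> 0).
#' @param hill Hill slope (> 0).
#' @return Effect fraction(s) in `[0, 1)`.
#' @export
monotherapy_effect <- function(concentration, ec50, hill) {
  stopifnot(ec50 > 0, hill > 0, all(concentration >= 0))
  ch <- concentration^hill
  ch / (ch + ec50^hill)
}

# inverse Hill: concentration producing effect e as monotherapy
.inverse_hill <- function(e, ec50, hill) ec50 * (e / (1 - e))^(1 / hill)

#' Loewe combination effect with interaction parameter psi
#'
#' The mixture effect `e` solves
#' `c_a / ECe_a + c_b / ECe_b = psi`, where `ECe_x` is the inverse Hill
#' curve of drug x at effect `e`. `psi = 1` is exact Loewe additivity (the
#' model reduces to the monotherapy curve when one concentration is zero);
#' `psi < 1` shifts the whole combination surface to lower concentrations
#' (synergy). Solved by bisection on `e` in `(1e-9, 1 - 1e-9)`; if the root
#' lies outside, the boundary value is returned with attribute
#' `boundary = TRUE`.
#'
#' @param c_a,c_b Component concentrations (uM, >= 0); both zero gives 0.
#' @param config A [simulation_config()] supplying EC50s, Hill slopes and
#'   `psi`.
#' @return Effect fraction(s).
#' @export
loewe_combination_effect <- function(c_a, c_b, config) {
  stopifnot(inherits(config, "simulation_config"),
            all(c_a >= 0), all(c_b >= 0))
  m <- max(length(c_a), length(c_b))
  c_a <- rep_len(c_a, m); c_b <- rep_len(c_b, m)
  eps <- 1e-9
  # occupancy sum minus psi; strictly decreasing in e
  gap <- function(e, i) {
    c_a[i] / .inverse_hill(e, config$ec50_a, config$hill_a) +
      c_b[i] / .inverse_hill(e, config$ec50_b, config$hill_b) - config$psi
  }
  out <- numeric(m)
  boundary <- logical(m)
  for (i in seq_len(m)) {
    if (c_a[i] == 0 && c_b[i] == 0) { out[i] <- 0; next }
    lo <- eps; hi <- 1 - eps
    if (gap(hi, i) > 0) { out[i] <- hi; boundary[i] <- TRUE; next }
    if (gap(lo, i) < 0) { out[i] <- lo; boundary[i] <- TRUE; next }
    for (it in 1:100) {
      mid <- (lo + hi) / 2
      if (gap(mid, i) > 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-12) break
    }
    out[i] <- (lo + hi) / 2
  }
  attr(out, "boundary") <- boundary
  out
}

# effect fraction -> viability percent under the config's endpoint model
.effect_to_viability <- function(e, config) {
  config$viability_ogdr +
    e * config$max_protection * (config$viability_control - config$viability_ogdr)
}

.child_seed <- function(root, k) as.integer((as.numeric(root) * 1009 + 7919 * k) %% 2147483647)

# one arm of wells: viability vector per concentration, replicated with noise
.simulate_arm <- function(group, drug_id, conc, viability, config, arm_index) {
  set.seed(.child_seed(config$seed, arm_index))
  nrep <- config$n_replicates
  n <- length(conc) * nrep
  v <- rep(viability, each = nrep)
  s0 <- config$control_signal
  signal <- pmax(0, v / 100 * s0 + stats::rnorm(n, 0, config$noise_sd / 100 * s0))
  data.frame(group = group, drug_id = drug_id,
             concentration = rep(conc, each = nrep),
             replicate = rep(seq_len(nrep), times = length(conc)),
             assay = "mtt", signal = signal, stringsAsFactors = FALSE)
}

#' Simulate a full OGD/R plate experiment
#'
#' Emits an MTT plate with control and untreated-OGD/R wells, both
#' monotherapy concentration series, and one fixed-ratio mixture ray per
#' `config$f_a`: the design-point (screening) wells plus a geometric
#' dilution series bracketing it (center excluded, as in a bracketing
#' design). Well signal is
#' `(viability / 100) * control_signal + N(0, noise_sd% * control_signal)`,
#' truncated at zero. Mixture drug ids encode the ray fraction as
#' `mix_fa<f_a>`. Deterministic given `config$seed` (each arm has its own
#' derived child seed, so arms can be regenerated independently).
#'
#' @param config A [simulation_config()].
#' @return An object of class `simulated_experiment`: `plate` (a
#'   [plate_table()]), `truth` (the config) and `derived_truth` with
#'   `ec50t_true`, `ec50e_true` and `I_true` per ray (with equal Hill
#'   slopes, `ec50e_true = psi * ec50t_true` and `I_true = psi` in closed
#'   form).
#' @export
simulate_ogdr_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  arms <- list()
  arm_index <- 0L
  add_arm <- function(group, drug_id, conc, viability) {
    arm_index <<- arm_index + 1L
    arms[[length(arms) + 1L]] <<-
      .simulate_arm(group, drug_id, conc, viability, config, arm_index)
  }
  add_arm("control", "none", 0, config$viability_control)
  add_arm("ogdr", "none", 0, config$viability_ogdr)
  e_a <- monotherapy_effect(config$conc_a, config$ec50_a, config$hill_a)
  add_arm("ogdr_treated", config$drug_a, config$conc_a, .effect_to_viability(e_a, config))
  e_b <- monotherapy_effect(config$conc_b, config$ec50_b, config$hill_b)
  add_arm("ogdr_treated", config$drug_b, config$conc_b, .effect_to_viability(e_b, config))

  derived <- list()
  for (f in config$f_a) {
    design <- fixed_ratio_components(config$ec50_a, config$ec50_b, f,
                                     drug_a = config$drug_a, drug_b = config$drug_b)
    series <- dilution_series(design, n_each_side = config$n_each_side,
                              factor = config$dilution_factor, exclude_center = TRUE)
    totals <- c(series$total, design$total) # series + screening design point
    ca <- totals * design$c_a / design$total
    cb <- totals * design$c_b / design$total
    e_mix <- loewe_combination_effect(ca, cb, config)
    add_arm("ogdr_treated", sprintf("mix_fa%g", f), totals,
            .effect_to_viability(as.numeric(e_mix), config))
    equal_hills <- isTRUE(all.equal(config$hill_a, config$hill_b))
    derived[[sprintf("mix_fa%g", f)]] <- list(
      f_a = f,
      ec50t_true = design$total,
      ec50e_true = if (equal_hills) config$psi * design$total else NA_real_,
      I_true = if (equal_hills) config$psi else NA_real_
    )
  }
  plate <- plate_table(do.call(rbind, arms))
  structure(list(plate = plate, truth = config, derived_truth = derived),
            class = "simulated_experiment")
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf("Simulated OGD/R experiment: %d wells, psi = %g, seed = %d\n",
              nrow(x$plate), x$truth$psi, x$truth$seed))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Writes the plate CSV (same dialect as [read_plate_table()]) and a truth
#' sidecar JSON carrying the generating parameters and derived closed-form
#' truths.
#'
#' @param config A [simulation_config()].
#' @param output_dir Directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
run_simulation <- function(config, output_dir) {
  sim <- simulate_ogdr_experiment(config)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  plate_path <- file.path(output_dir, "plate.csv")
  truth_path <- file.path(output_dir, "truth.json")
  write_plate_table(sim$plate, plate_path)
  jsonlite::write_json(list(truth = unclass(sim$truth),
                            derived_truth = sim$derived_truth),
                       truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(plate = plate_path, truth = truth_path))
}
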