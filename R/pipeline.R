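# Orchestration: plate table -> endpoints -> potency fits -> ray design ->
# isobolographic assessment -> report.

#' Analysis run configuration
#'
#' Either a plate path/table (full pipeline) or pre-computed potencies
#' (shortcut: straight to the interaction assessment).
#'
#' @param plate A [plate_table()], data.frame, or path to a plate CSV.
#' @param potencies Optional shortcut input: a list (or path to a JSON file)
#'   with `ec50_t = list(value, sem)`, `ec50_e = list(value, sem)`,
#'   optionally `est_a`, `est_b`, `f_a`, `n`.
#' @param link Link function for all concentration-response fits.
#' @param f_a Candidate ray fractions to tabulate (Table-1-style output);
#'   rays actually fitted are those present in the plate.
#' @param alpha Significance level for the synergy call.
#' @param n_replicates Replicates per group, used for t-test sizes.
#' @param drug_a,drug_b Monotherapy drug ids expected in the plate.
#' @param rays Optional named numeric vector mapping mixture `drug_id`s to
#'   their `f_a`; by default ids of the form `mix_fa<f>` are parsed.
#' @param out_dir Optional output directory for report files.
#' @param seed Seed recorded in provenance (the analysis itself is
#'   deterministic).
#' @return An object of class `run_config`.
#' @export
run_config <- function(plate = NULL, potencies = NULL,
                       link = c("probit", "logit"),
                       f_a = c(0.5, 0.25, 0.75), alpha = 0.05,
                       n_replicates = 9L, drug_a = "DDS", drug_b = "CBD",
                       rays = NULL, out_dir = NULL, seed = NA_integer_) {
  link <- match.arg(link)
  if (is.null(plate) && is.null(potencies)) {
    stop("supply a plate table/CSV or a potencies shortcut", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (any(f_a < 0 | f_a > 1)) stop("f_a values must lie in [0, 1]", call. = FALSE)
  structure(list(plate = plate, potencies = potencies, link = link, f_a = f_a,
                 alpha = alpha, n_replicates = as.integer(n_replicates),
                 drug_a = drug_a, drug_b = drug_b, rays = rays,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

.parse_ray_fraction <- function(drug_id, rays = NULL) {
  if (!is.null(rays) && drug_id %in% names(rays)) return(unname(rays[[drug_id]]))
  if (grepl("^mix_fa", drug_id)) {
    f <- suppressWarnings(as.numeric(sub("^mix_fa", "", drug_id)))
    if (is.finite(f) && f >= 0 && f <= 1) return(f)
  }
  NA_real_
}

# scalar summary of a potency fit for the report JSON
.fit_summary <- function(fit, est) {
  list(drug_id = fit$drug_id,
       value_uM = est$value, sem_uM = est$sem, ci95 = est$ci95,
       kind = est$kind, p_level = est$p_level, link = fit$link,
       slope = unname(fit$coefficients["slope"]),
       intercept = unname(fit$coefficients["intercept"]),
       converged = fit$converged)
}

# routine group statistics on the screening wells: one-way ANOVA across
# groups plus Dunnett-type contrasts vs the untreated OGD/R group. These
# are descriptive companions; they never gate the synergy call.
.group_statistics <- function(viab_df) {
  viab_df$grp <- factor(viab_df$grp)
  viab_df$grp <- stats::relevel(viab_df$grp, ref = "ogdr")
  fit <- stats::aov(viability ~ grp, data = viab_df)
  p_overall <- summary(fit)[[1]][["Pr(>F)"]][1]
  dunnett <- NULL
  if (requireNamespace("multcomp", quietly = TRUE)) {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett"))
    sm <- summary(gl)
    dunnett <- data.frame(contrast = names(sm$test$coefficients),
                          estimate = unname(sm$test$coefficients),
                          p_adj = unname(sm$test$pvalues))
  }
  list(anova_p = p_overall, dunnett_vs_ogdr = dunnett)
}

#' Run the full isobolographic analysis
#'
#' Stages: endpoint derivation (viability % per cell), monotherapy
#' concentration-response fits and EC50s, candidate fixed-ratio design
#' table, best-ray selection (maximal mean cytoprotection at each ray's
#' design concentration), mixture-ray fit for EC50E (total concentration)
#' and EC90E, theoretical additive EC50T with propagated SEM, interaction
#' index, Welch's t-test, classification, and isobologram coordinates.
#' With a `potencies` shortcut config, only the assessment stage runs.
#'
#' @param config A [run_config()].
#' @return An object of class `analysis_report`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$potencies)) {
    return(.run_shortcut(config))
  }
  plate <- config$plate
  if (is.character(plate)) plate <- read_plate_table(plate)
  plate <- plate_table(as.data.frame(plate))

  ep <- plate_endpoints(plate, assays = "mtt")
  v_ogdr <- ep$value[ep$group == "ogdr" & ep$endpoint == "viability_pct"]
  if (length(v_ogdr) != 1) stop("stage endpoints: expected exactly one ogdr baseline cell",
                                call. = FALSE)
  v_ctrl <- ep$value[ep$group == "control" & ep$endpoint == "viability_pct"]

  fit_drug <- function(id) {
    rows <- ep[ep$group == "ogdr_treated" & ep$drug_id == id, , drop = FALSE]
    if (nrow(rows) < 4) stop("stage fit: too few concentrations for ", id, call. = FALSE)
    cd <- build_curve_data(rows, "cytoprotection", baseline = v_ogdr, ceiling = 100,
                           drug_id = id)
    fit_concentration_response(cd, link = config$link)
  }
  fit_a <- fit_drug(config$drug_a)
  fit_b <- fit_drug(config$drug_b)
  est_a <- effective_concentration(fit_a, 0.5, n = config$n_replicates)
  est_b <- effective_concentration(fit_b, 0.5, n = config$n_replicates)

  # Table-1 analogue over the candidate fractions, from the fitted EC50s
  designs <- lapply(config$f_a, function(f)
    fixed_ratio_components(est_a$value, est_b$value, f,
                           drug_a = config$drug_a, drug_b = config$drug_b))

  # rays present in the plate
  mix_ids <- setdiff(unique(ep$drug_id[ep$group == "ogdr_treated"]),
                     c(config$drug_a, config$drug_b))
  ray_f <- vapply(mix_ids, .parse_ray_fraction, numeric(1), rays = config$rays)
  mix_ids <- mix_ids[is.finite(ray_f)]
  ray_f <- ray_f[is.finite(ray_f)]
  if (length(mix_ids) == 0) stop("stage design: no mixture rays found in the plate",
                                 call. = FALSE)

  # screening: mean cytoprotection at each ray's design concentration
  screening <- data.frame(drug_id = mix_ids, f_a = ray_f,
                          cytoprotection = NA_real_, design_total = NA_real_)
  for (k in seq_along(mix_ids)) {
    d <- fixed_ratio_components(est_a$value, est_b$value, ray_f[k])
    rows <- ep[ep$group == "ogdr_treated" & ep$drug_id == mix_ids[k], , drop = FALSE]
    j <- which.min(abs(log(rows$concentration) - log(d$total)))
    screening$design_total[k] <- rows$concentration[j]
    screening$cytoprotection[k] <- cytoprotection_percent(rows$value[j], v_ogdr)
  }
  best <- which.max(screening$cytoprotection)
  best_id <- screening$drug_id[best]
  best_f <- screening$f_a[best]

  rows <- ep[ep$group == "ogdr_treated" & ep$drug_id == best_id, , drop = FALSE]
  cd_mix <- build_curve_data(rows, "cytoprotection", baseline = v_ogdr, ceiling = 100,
                             drug_id = best_id)
  fit_mix <- fit_concentration_response(cd_mix, link = config$link)
  ec50_e <- effective_concentration(fit_mix, 0.5, kind = "EC50E", n = config$n_replicates)
  ec90_e <- effective_concentration(fit_mix, 0.9, kind = "EC90E", n = config$n_replicates)

  assessment <- assess_interaction(ec50_e, est_a = est_a, est_b = est_b,
                                   f_a = best_f, alpha = config$alpha)
  best_design <- fixed_ratio_components(est_a$value, est_b$value, best_f,
                                        drug_a = config$drug_a, drug_b = config$drug_b)
  iso <- isobologram_coordinates(est_a, est_b, assessment, best_design)
  ec90_components <- list(
    total_uM = ec90_e$value,
    c_a_uM = ec90_e$value * best_design$c_a / best_design$total,
    c_b_uM = ec90_e$value * best_design$c_b / best_design$total
  )

  # screening-group statistics (control / ogdr / each ray design point)
  group_tests <- tryCatch({
    ctrl <- plate[plate$group == "control" & plate$assay == "mtt", ]
    base <- plate[plate$group == "ogdr" & plate$assay == "mtt", ]
    ctrl_mean <- mean(ctrl$signal)
    pieces <- list(
      data.frame(grp = "control", viability = viability_percent(ctrl$signal, ctrl_mean)),
      data.frame(grp = "ogdr", viability = viability_percent(base$signal, ctrl_mean))
    )
    for (k in seq_along(mix_ids)) {
      w <- plate[plate$group == "ogdr_treated" & plate$drug_id == mix_ids[k] &
                   plate$concentration == screening$design_total[k], ]
      if (nrow(w)) pieces[[length(pieces) + 1L]] <-
          data.frame(grp = mix_ids[k], viability = viability_percent(w$signal, ctrl_mean))
    }
    .group_statistics(do.call(rbind, pieces))
  }, error = function(e) NULL)

  report <- structure(
    list(potencies = list(
           drug_a = .fit_summary(fit_a, est_a),
           drug_b = .fit_summary(fit_b, est_b),
           mixture = .fit_summary(fit_mix, ec50_e)),
         fits = list(drug_a = fit_a, drug_b = fit_b, mixture = fit_mix),
         designs = designs,
         screening = screening,
         chosen_ray = list(drug_id = best_id, f_a = best_f),
         assessment = assessment,
         ec90_components = ec90_components,
         isobologram = iso,
         group_tests = group_tests,
         baseline = list(viability_ogdr = v_ogdr, viability_control = v_ctrl),
         provenance = list(package = "isobolr",
                           version = as.character(utils::packageVersion("isobolr")),
                           link = config$link, alpha = config$alpha,
                           seed = config$seed)),
    class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

.run_shortcut <- function(config) {
  pot <- config$potencies
  if (is.character(pot)) pot <- jsonlite::read_json(pot, simplifyVector = TRUE)
  est_a <- if (!is.null(pot$est_a)) .as_potency(pot$est_a) else NULL
  est_b <- if (!is.null(pot$est_b)) .as_potency(pot$est_b) else NULL
  n <- pot$n %||% config$n_replicates
  ec50_e <- .as_potency(pot$ec50_e)
  ec50_t <- if (!is.null(pot$ec50_t)) .as_potency(pot$ec50_t) else NULL
  assessment <- assess_interaction(ec50_e, est_a = est_a, est_b = est_b,
                                   f_a = pot$f_a %||% NULL, ec50_t = ec50_t,
                                   n_e = n, n_t = n, alpha = config$alpha)
  designs <- NULL
  iso <- NULL
  if (!is.null(est_a) && !is.null(est_b)) {
    designs <- lapply(config$f_a, function(f)
      fixed_ratio_components(est_a$value, est_b$value, f,
                             drug_a = config$drug_a, drug_b = config$drug_b))
    if (!is.null(pot$f_a)) {
      d <- fixed_ratio_components(est_a$value, est_b$value, pot$f_a,
                                  drug_a = config$drug_a, drug_b = config$drug_b)
      iso <- isobologram_coordinates(est_a, est_b, assessment, d)
    }
  }
  report <- structure(
    list(potencies = pot, fits = NULL, designs = designs, screening = NULL,
         chosen_ray = list(drug_id = NA_character_, f_a = pot$f_a %||% NA_real_),
         assessment = assessment, ec90_components = NULL, isobologram = iso,
         group_tests = NULL, baseline = NULL,
         provenance = list(package = "isobolr",
                           version = as.character(utils::packageVersion("isobolr")),
                           link = config$link, alpha = config$alpha,
                           seed = config$seed)),
    class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Isobolographic analysis report\n")
  if (!is.null(x$baseline)) {
    cat(sprintf("  OGD/R baseline viability: %.2f%% of control\n",
                x$baseline$viability_ogdr))
  }
  if (!is.null(x$fits)) {
    cat(sprintf("  EC50 (%s link): %s = %.4g +/- %.3g uM, %s = %.4g +/- %.3g uM\n",
                x$provenance$link %||% "?",
                x$potencies$drug_a$drug_id %||% "drug A",
                x$potencies$drug_a$value_uM, x$potencies$drug_a$sem_uM,
                x$potencies$drug_b$drug_id %||% "drug B",
                x$potencies$drug_b$value_uM, x$potencies$drug_b$sem_uM))
  }
  if (!is.na(x$chosen_ray$f_a %||% NA)) {
    cat(sprintf("  chosen ray: f_a = %g\n", x$chosen_ray$f_a))
  }
  print(x$assessment)
  invisible(x)
}

# serialisable view of the report (no glm objects / environments)
.report_json <- function(report) {
  a <- report$assessment
  list(
    potencies = report$potencies,
    designs = if (!is.null(report$designs))
      lapply(report$designs, function(d) d[c("label", "f_a", "c_a", "c_b", "total")]),
    chosen_ray = report$chosen_ray,
    assessment = list(
      f_a = a$f_a,
      ec50_t = list(value = a$ec50_t$value, sem = a$ec50_t$sem),
      ec50_e = list(value = a$ec50_e$value, sem = a$ec50_e$sem),
      interaction_index = a$interaction_index_I,
      fold_reduction = a$fold_reduction,
      t = a$t_statistic, dof = a$dof, p_value = a$p_value,
      classification = a$classification),
    ec90_components = report$ec90_components,
    baseline = report$baseline,
    provenance = report$provenance
  )
}

#' Write an analysis report to disk
#'
#' Emits `report.json`, a Table-1-style design CSV, a Table-2-style
#' assessment CSV and the isobologram coordinates CSV.
#'
#' @param report An [run_analysis()] result.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(.report_json(report), p, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, p)
  if (!is.null(report$designs)) {
    p <- file.path(out_dir, "design_table.csv")
    write_design(report$designs, p)
    paths <- c(paths, p)
  }
  a <- report$assessment
  p <- file.path(out_dir, "assessment_table.csv")
  utils::write.csv(data.frame(
    f_a = a$f_a %||% NA_real_,
    ec50_t_uM = a$ec50_t$value, ec50_t_sem = a$ec50_t$sem,
    ec50_e_uM = a$ec50_e$value, ec50_e_sem = a$ec50_e$sem,
    interaction_index = a$interaction_index_I,
    fold_reduction = a$fold_reduction,
    t = a$t_statistic, dof = a$dof, p_value = a$p_value,
    classification = a$classification), p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$isobologram)) {
    p <- file.path(out_dir, "isobologram.csv")
    utils::write.csv(report$isobologram, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
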