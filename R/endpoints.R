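# Assay-endpoint arithmetic: raw plate signals -> derived percentages.

.plate_groups <- c("control", "ogdr", "ogdr_treated", "blank", "maximum_release")
.plate_assays <- c("mtt", "ldh", "ros", "gsh", "caspase3")

#' Cell viability as a percentage of the untreated control
#'
#' Viability is the treated-group signal (mean formazan OD for an MTT assay)
#' expressed relative to the control-group signal. Values above 100% are
#' returned as-is; clipping, where needed, happens at the curve-fitting
#' stage so that raw information is preserved.
#'
#' @param signal_treatment Numeric signal(s) for the experimental group
#'   (OD or fluorescence, arbitrary units, `>= 0`).
#' @param signal_control Positive numeric signal(s) for the control group.
#' @return Viability in percent, `100 * signal_treatment / signal_control`.
#' @examples
#' viability_percent(0.236, 0.5) # 47.2
#' @export
viability_percent <- function(signal_treatment, signal_control) {
  if (any(!is.finite(signal_control)) || any(signal_control <= 0)) {
    stop("invalid control: control signal must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(signal_treatment)) || any(signal_treatment < 0)) {
    stop("treatment signal must be finite and >= 0", call. = FALSE)
  }
  100 * signal_treatment / signal_control
}

#' Lethality as the complement of viability
#'
#' @param viability Viability in percent.
#' @return `100 - viability`.
#' @examples
#' lethality_percent(88.18) # 11.82
#' @export
lethality_percent <- function(viability) {
  if (any(!is.finite(viability))) stop("viability must be finite", call. = FALSE)
  100 - viability
}

#' Cytoprotection index
#'
#' The gain in viability of a treated, injured culture over the injured,
#' untreated baseline (the OGD/R group). Negative values (treatment worse
#' than no treatment) are allowed.
#'
#' @param viability_treatment Viability (%) of the treated injured group.
#' @param viability_ogdr Viability (%) of the untreated injured group.
#' @return `viability_treatment - viability_ogdr`, in percentage points.
#' @examples
#' cytoprotection_percent(89.37, 47.19) # 42.18
#' @export
cytoprotection_percent <- function(viability_treatment, viability_ogdr) {
  if (any(!is.finite(viability_treatment)) || any(!is.finite(viability_ogdr))) {
    stop("viabilities must be finite", call. = FALSE)
  }
  viability_treatment - viability_ogdr
}

#' LDH-release cytotoxicity
#'
#' Fractional position of the treatment OD between the blank (no-cell or
#' no-lysis background) and the maximum-release (fully lysed) wells:
#' `100 * (od_treatment - od_blank) / (od_maximum - od_blank)`.
#' The result is invariant to adding a constant to all three ODs.
#'
#' @param od_treatment Treatment-well OD.
#' @param od_blank Blank-well OD (averaged upstream if several wells).
#' @param od_maximum Maximum-release OD; must exceed `od_blank`.
#' @return Cytotoxicity in percent.
#' @export
ldh_cytotoxicity_percent <- function(od_treatment, od_blank, od_maximum) {
  if (any(!is.finite(c(od_treatment, od_blank, od_maximum)))) {
    stop("ODs must be finite", call. = FALSE)
  }
  if (any(od_maximum <= od_blank)) {
    stop("degenerate window: od_maximum must exceed od_blank", call. = FALSE)
  }
  100 * (od_treatment - od_blank) / (od_maximum - od_blank)
}

#' Express replicate measurements as a percentage of the control group
#'
#' Each value is scaled by the control-group mean; the group mean and SEM of
#' the scaled values are returned. The control group itself maps to
#' 100 +/- its own SEM.
#'
#' @param values Replicate measurements for one group.
#' @param control_values Replicate measurements for the control group.
#' @return A list with `value` (mean %), `sem` and `n`.
#' @export
percent_of_control <- function(values, control_values) {
  if (length(control_values) == 0) stop("empty control group", call. = FALSE)
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) stop("control mean must be > 0", call. = FALSE)
  p <- 100 * values / m
  n <- length(p)
  list(value = mean(p), sem = if (n > 1) stats::sd(p) / sqrt(n) else NA_real_, n = n)
}

#' Validate a long-format plate measurement table
#'
#' One row per well: experimental group, drug (or mixture) identifier,
#' concentration in micromolar, replicate index, assay type and raw signal.
#'
#' @param x A data.frame with columns `group`, `drug_id`, `concentration`,
#'   `replicate`, `assay`, `signal`.
#' @return `x` with class `plate_table`, after validation.
#' @export
plate_table <- function(x) {
  need <- c("group", "drug_id", "concentration", "replicate", "assay", "signal")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("plate table is missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  x$group <- as.character(x$group)
  x$drug_id <- as.character(x$drug_id)
  x$assay <- as.character(x$assay)
  if (!all(x$group %in% .plate_groups)) {
    stop("unknown group(s): ", paste(setdiff(unique(x$group), .plate_groups), collapse = ", "),
         call. = FALSE)
  }
  if (!all(x$assay %in% .plate_assays)) {
    stop("unknown assay(s): ", paste(setdiff(unique(x$assay), .plate_assays), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(x$concentration)) || any(x$concentration < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(x$signal)) || any(x$signal < 0)) {
    stop("signals must be finite and >= 0", call. = FALSE)
  }
  if ("ldh" %in% x$assay) {
    sub <- x[x$assay == "ldh", ]
    if (!any(sub$group == "blank") || !any(sub$group == "maximum_release")) {
      stop("an LDH assay needs at least one blank and one maximum_release row",
           call. = FALSE)
    }
  }
  class(x) <- unique(c("plate_table", class(x)))
  x
}

#' Read / write a plate table CSV
#'
#' The on-disk dialect is UTF-8 CSV with a `.` decimal separator and header
#' `group,drug_id,concentration_uM,replicate,assay,signal`, one well per row.
#'
#' @param path File path.
#' @return For `read_plate_table`, a validated [plate_table()].
#' @export
read_plate_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("concentration_uM" %in% names(x)) {
    names(x)[names(x) == "concentration_uM"] <- "concentration"
  }
  plate_table(x)
}

#' @rdname read_plate_table
#' @param plate A [plate_table()].
#' @export
write_plate_table <- function(plate, path) {
  out <- as.data.frame(plate)[, c("group", "drug_id", "concentration",
                                  "replicate", "assay", "signal")]
  names(out)[names(out) == "concentration"] <- "concentration_uM"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# mean/sem/n per (group, drug_id, concentration) cell
.summarise_cells <- function(sub, value, endpoint) {
  key <- paste(sub$group, sub$drug_id, sub$concentration, sep = "\r")
  idx <- split(seq_along(value), key)
  rows <- lapply(idx, function(i) {
    n <- length(i)
    data.frame(
      group = sub$group[i[1]], drug_id = sub$drug_id[i[1]],
      concentration = sub$concentration[i[1]], endpoint = endpoint,
      value = mean(value[i]),
      sem = if (n > 1) stats::sd(value[i]) / sqrt(n) else NA_real_,
      n = n, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, out$drug_id, out$concentration), , drop = FALSE]
}

#' Derive endpoint summaries from a raw plate table
#'
#' Converts raw well signals into per-cell (group x drug x concentration)
#' endpoint means with SEMs: viability % for MTT, LDH cytotoxicity % for LDH
#' (using the mean blank and maximum-release wells), and percent-of-control
#' for ROS/GSH/caspase-3 readouts. Normalisation is per plate.
#'
#' @param plate A [plate_table()] (or data.frame coercible to one).
#' @param assays Which assays to summarise (default: all present).
#' @return A data.frame with columns
#'   `group, drug_id, concentration, endpoint, value, sem, n`.
#' @export
plate_endpoints <- function(plate, assays = unique(plate$assay)) {
  plate <- plate_table(as.data.frame(plate))
  out <- list()
  for (a in assays) {
    sub <- plate[plate$assay == a, , drop = FALSE]
    if (nrow(sub) == 0) next
    if (a == "mtt") {
      ctrl <- mean(sub$signal[sub$group == "control"])
      val <- viability_percent(sub$signal, ctrl)
      out[[a]] <- .summarise_cells(sub, val, "viability_pct")
    } else if (a == "ldh") {
      blank <- mean(sub$signal[sub$group == "blank"])
      mx <- mean(sub$signal[sub$group == "maximum_release"])
      keep <- !(sub$group %in% c("blank", "maximum_release"))
      sub <- sub[keep, , drop = FALSE]
      val <- ldh_cytotoxicity_percent(sub$signal, blank, mx)
      out[[a]] <- .summarise_cells(sub, val, "ldh_cytotoxicity_pct")
    } else {
      ctrl <- sub$signal[sub$group == "control"]
      if (length(ctrl) == 0) stop("empty control group for assay ", a, call. = FALSE)
      m <- mean(ctrl)
      if (!is.finite(m) || m <= 0) stop("control mean must be > 0", call. = FALSE)
      val <- 100 * sub$signal / m
      out[[a]] <- .summarise_cells(sub, val, "pct_of_control")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Add cytoprotection rows to a viability endpoint table
#'
#' For every treated cell, cytoprotection = viability - viability(OGD/R);
#' the SEM combines both terms by independent-error propagation.
#'
#' @param endpoints Output of [plate_endpoints()] containing `viability_pct`
#'   rows for the `ogdr` and `ogdr_treated` groups.
#' @return The treated rows re-expressed as `cytoprotection_pct`.
#' @export
add_cytoprotection <- function(endpoints) {
  v <- endpoints[endpoints$endpoint == "viability_pct", , drop = FALSE]
  base <- v[v$group == "ogdr", , drop = FALSE]
  if (nrow(base) == 0) stop("no ogdr baseline rows found", call. = FALSE)
  b_val <- mean(base$value)
  b_sem <- mean(base$sem)
  trt <- v[v$group == "ogdr_treated", , drop = FALSE]
  trt$endpoint <- "cytoprotection_pct"
  trt$value <- cytoprotection_percent(trt$value, b_val)
  trt$sem <- sqrt(trt$sem^2 + b_sem^2)
  rownames(trt) <- NULL
  trt
}

#' Write an endpoint table CSV
#'
#' Header: `group,drug_id,concentration_uM,endpoint,value,sem,n`.
#'
#' @param endpoints Output of [plate_endpoints()].
#' @param path File path.
#' @export
write_endpoints <- function(endpoints, path) {
  out <- endpoints
  names(out)[names(out) == "concentration"] <- "concentration_uM"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
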