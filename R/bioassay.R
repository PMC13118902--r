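#' Net optical density
#'
#' Reference-wavelength subtraction: measurement absorbance minus the
#' reference-wavelength absorbance for the same well (e.g. 550 nm minus
#' 680 nm for an MTT read).
#'
#' @param a_measure Absorbance at the measurement wavelength.
#' @param a_reference Absorbance at the reference wavelength.
#' @return Net absorbance (vectorised).
#' @export
net_od <- function(a_measure, a_reference) {
  if (any(is.na(a_measure)) || any(is.na(a_reference)) ||
      any(!is.finite(a_measure)) || any(!is.finite(a_reference))) {
    stop_validation("missing or non-finite absorbance reading")
  }
  a_measure - a_reference
}

#' MTT cell viability
#'
#' Viability as percent of the untreated (negative) control, anchored at the
#' lysed (positive) control:
#' 100 (OD_sample − OD_pos) / (OD_neg − OD_pos).
#' Equals 100 at the negative-control mean and 0 at the positive-control mean
#' by construction. Values outside [0, 100] are mathematically possible and
#' are returned as computed, with a warning.
#'
#' @param od_sample Net OD of the sample well(s).
#' @param od_neg_mean Mean net OD of the negative (untreated) controls.
#' @param od_pos_mean Mean net OD of the positive (lysed/dead) controls.
#' @return Viability in percent (vectorised over `od_sample`).
#' @export
viability_mtt <- function(od_sample, od_neg_mean, od_pos_mean) {
  if (od_neg_mean == od_pos_mean) {
    stop_validation("degenerate controls: negative and positive control ODs are equal")
  }
  v <- 100 * (od_sample - od_pos_mean) / (od_neg_mean - od_pos_mean)
  if (any(v < 0 | v > 100)) {
    warning("viability outside [0, 100]% reported as computed (not clipped)")
  }
  v
}

#' LDH cytotoxicity
#'
#' Cytotoxicity as percent of the full-lysis (positive) control:
#' 100 (OD_sample − OD_neg) / (OD_pos − OD_neg).
#' Equals 0 at the negative-control mean and 100 at the positive-control
#' mean. Out-of-range values are returned as computed, with a warning.
#'
#' @inheritParams viability_mtt
#' @return Cytotoxicity in percent (vectorised over `od_sample`).
#' @export
cytotoxicity_ldh <- function(od_sample, od_neg_mean, od_pos_mean) {
  if (od_neg_mean == od_pos_mean) {
    stop_validation("degenerate controls: negative and positive control ODs are equal")
  }
  ct <- 100 * (od_sample - od_neg_mean) / (od_pos_mean - od_neg_mean)
  if (any(ct < 0 | ct > 100)) {
    warning("cytotoxicity outside [0, 100]% reported as computed (not clipped)")
  }
  ct
}

#' Classify a condition against viability/cytotoxicity thresholds
#'
#' A condition fails if cytotoxicity strictly exceeds the cytotoxicity
#' threshold (default 20%) or viability falls strictly below the viability
#' threshold (default 80%); boundary values pass. Either metric may be NULL
#' if not measured.
#'
#' @param viability Viability in percent, or NULL.
#' @param cytotoxicity Cytotoxicity in percent, or NULL.
#' @param viability_threshold Pass floor for viability, percent.
#' @param cytotoxicity_threshold Pass ceiling for cytotoxicity, percent.
#' @return List with logical `pass`, and flags `reduced_viability`,
#'   `cytotoxic`.
#' @export
classify_condition <- function(viability = NULL, cytotoxicity = NULL,
                               viability_threshold = 80,
                               cytotoxicity_threshold = 20) {
  for (m in c(viability, cytotoxicity)) {
    if (!is.null(m) && (m < -50 || m > 200)) {
      warning(sprintf("assay metric %.1f%% is outside the plausible range [-50, 200]", m))
    }
  }
  reduced <- !is.null(viability) && viability < viability_threshold
  toxic <- !is.null(cytotoxicity) && cytotoxicity > cytotoxicity_threshold
  list(pass = !(reduced || toxic),
       reduced_viability = reduced, cytotoxic = toxic)
}

#' A plate-reader assay
#'
#' Tidy per-well table for an MTT or LDH plate: absorbances at the
#' measurement and reference wavelengths, well role (sample, negative
#' control, positive control, blank) and for sample wells a condition
#' identifier (e.g. the dose). At least one negative and one positive control
#' are required.
#'
#' @param wells Data frame with columns `well`, `role`
#'   (sample/negative_control/positive_control/blank), `condition`,
#'   `a_measure`, `a_reference`.
#' @param assay "MTT" or "LDH".
#' @return Object of class `plate_assay`.
#' @export
plate_assay <- function(wells, assay = c("MTT", "LDH")) {
  assay <- match.arg(assay)
  need <- c("well", "role", "condition", "a_measure", "a_reference")
  if (!is.data.frame(wells) || !all(need %in% names(wells))) {
    stop_validation("plate table must have columns: %s", paste(need, collapse = ", "))
  }
  ok_roles <- c("sample", "negative_control", "positive_control", "blank")
  if (!all(wells$role %in% ok_roles)) {
    stop_validation("unknown well role(s): %s",
                    paste(unique(setdiff(wells$role, ok_roles)), collapse = ", "))
  }
  if (!any(wells$role == "negative_control") || !any(wells$role == "positive_control")) {
    stop_validation("plate needs at least one negative and one positive control well")
  }
  if (any(!is.finite(wells$a_measure)) || any(!is.finite(wells$a_reference))) {
    stop_validation("absorbances must be finite")
  }
  structure(list(wells = wells, assay = assay), class = "plate_assay")
}

#' Read a plate assay from CSV
#'
#' Expects the `well,role,condition,a_measure,a_reference` schema.
#'
#' @param path CSV path.
#' @param assay "MTT" or "LDH".
#' @return A [plate_assay()].
#' @export
read_plate_csv <- function(path, assay = c("MTT", "LDH")) {
  plate_assay(utils::read.csv(path, stringsAsFactors = FALSE), assay)
}

#' Reduce a plate assay to per-condition metrics
#'
#' Computes net ODs, averages the controls on this plate (arithmetic mean of
#' net OD; no cross-plate pooling), then evaluates viability (MTT plates) or
#' cytotoxicity (LDH plates) per well and summarises mean ± SD per condition,
#' with the threshold classification.
#'
#' @param plate A [plate_assay()].
#' @param viability_threshold,cytotoxicity_threshold Passed to
#'   [classify_condition()].
#' @return Data frame with one row per condition: `condition`, `metric`
#'   ("viability" or "cytotoxicity"), `mean`, `sd`, `n`, `pass`.
#' @export
reduce_plate <- function(plate, viability_threshold = 80,
                         cytotoxicity_threshold = 20) {
  stopifnot(inherits(plate, "plate_assay"))
  w <- plate$wells
  w$net <- net_od(w$a_measure, w$a_reference)
  neg <- mean(w$net[w$role == "negative_control"])
  pos <- mean(w$net[w$role == "positive_control"])
  s <- w[w$role == "sample", ]
  metric_fun <- if (plate$assay == "MTT") viability_mtt else cytotoxicity_ldh
  s$value <- suppressWarnings(metric_fun(s$net, neg, pos))
  agg <- do.call(rbind, lapply(split(s, s$condition), function(g) {
    m <- mean(g$value)
    cls <- if (plate$assay == "MTT") {
      classify_condition(viability = m,
                         viability_threshold = viability_threshold)
    } else {
      classify_condition(cytotoxicity = m,
                         cytotoxicity_threshold = cytotoxicity_threshold)
    }
    data.frame(condition = g$condition[1L],
               metric = if (plate$assay == "MTT") "viability" else "cytotoxicity",
               mean = m, sd = stats::sd(g$value), n = nrow(g),
               pass = cls$pass)
  }))
  rownames(agg) <- NULL
  agg[order(agg$condition), , drop = FALSE]
}

#' Disintegration time series
#'
#' Object counts per batch over time, with reference counts measured at t = 0
#' for independently prepared batches in water. Remaining fractions are
#' expressed relative to the mean reference count.
#'
#' @param counts Data frame with columns `batch`, `time_min`, `count`,
#'   `is_reference` (logical; reference rows carry the t = 0 water counts).
#' @return Object of class `disintegration_series`.
#' @export
disintegration_series <- function(counts) {
  need <- c("batch", "time_min", "count", "is_reference")
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    stop_validation("disintegration table must have columns: %s",
                    paste(need, collapse = ", "))
  }
  check_nonnegative(counts$count, "count")
  ref <- counts$count[as.logical(counts$is_reference)]
  if (length(ref) == 0L || mean(ref) <= 0) {
    stop_validation("reference counts are missing or their mean is zero")
  }
  structure(list(counts = counts, reference_mean = mean(ref)),
            class = "disintegration_series")
}

#' Read a disintegration series from CSV
#'
#' Expects the `batch,time_min,count,is_reference` schema.
#'
#' @param path CSV path.
#' @return A [disintegration_series()].
#' @export
read_disintegration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$is_reference <- as.logical(df$is_reference)
  disintegration_series(df)
}

#' Remaining and disintegrated fractions over time
#'
#' For each timepoint, the percentage of particles remaining relative to the
#' mean reference (t = 0, water) count — mean ± SD over batches — and its
#' complement, the percentage disintegrated.
#'
#' @param series A [disintegration_series()].
#' @return Data frame with `time_min`, `remaining_pct_mean`,
#'   `remaining_pct_sd`, `disintegrated_pct_mean`, `n_batches`.
#' @export
remaining_fraction <- function(series) {
  stopifnot(inherits(series, "disintegration_series"))
  df <- series$counts[!as.logical(series$counts$is_reference), , drop = FALSE]
  df$remaining <- 100 * df$count / series$reference_mean
  out <- do.call(rbind, lapply(split(df, df$time_min), function(g) {
    data.frame(time_min = g$time_min[1L],
               remaining_pct_mean = mean(g$remaining),
               remaining_pct_sd = stats::sd(g$remaining),
               disintegrated_pct_mean = 100 - mean(g$remaining),
               n_batches = nrow(g))
  }))
  rownames(out) <- NULL
  out[order(out$time_min), , drop = FALSE]
}

#' Empirical size-distribution summary
#'
#' d10/d50/d90 percentiles (linear-interpolation empirical quantiles,
#' type 7), mean, and the span (d90 − d10)/d50 — a dimensionless width
#' measure that is invariant under rescaling of the sample.
#'
#' @param values_um Numeric vector of sizes (µm); at least 10 values.
#' @return List of class `size_summary` with `d10`, `d50`, `d90`, `mean`,
#'   `span`, `n`.
#' @export
size_summary <- function(values_um) {
  if (!is.numeric(values_um) || length(values_um) < 10L) {
    stop_validation("size summary needs at least 10 values, got %d",
                    length(values_um))
  }
  check_nonnegative(values_um, "values_um")
  q <- stats::quantile(values_um, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  if (q[2L] <= 0) stop_validation("median size is zero; span undefined")
  structure(list(d10 = q[1L], d50 = q[2L], d90 = q[3L],
                 mean = mean(values_um),
                 span = (q[3L] - q[1L]) / q[2L],
                 n = length(values_um)),
            class = "size_summary")
}

#' @export
print.size_summary <- function(x, ...) {
  cat(sprintf("d10/d50/d90 = %.2f/%.2f/%.2f um, mean %.2f um, span %.2f (n = %d)\n",
              x$d10, x$d50, x$d90, x$mean, x$span, x$n))
  invisible(x)
}
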