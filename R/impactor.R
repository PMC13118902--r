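#' Impactor stage cutoff table
#'
#' An ordered table of effective cutoff diameters (D50) for the sizing stages
#' of a cascade impactor at a given flow rate, plus a terminal collector
#' (micro-orifice collector or back-up filter) that has no cutoff and catches
#' everything finer than the last stage.
#'
#' @param flow_rate_lpm Operating flow rate, L/min.
#' @param stage_labels Character labels of the sizing stages, coarsest first.
#' @param cutoffs_um Strictly decreasing cutoff diameters, µm, one per stage.
#' @param terminal_label Label of the terminal collector (default "moc").
#' @return An object of class `cutoff_table`.
#' @seealso [ngi_cutoffs()] for the shipped NGI table at 60 L/min.
#' @export
cutoff_table <- function(flow_rate_lpm, stage_labels, cutoffs_um,
                         terminal_label = "moc") {
  check_positive(flow_rate_lpm, "flow_rate_lpm")
  if (length(stage_labels) != length(cutoffs_um)) {
    stop_validation("stage_labels and cutoffs_um must have equal length")
  }
  check_positive(min(cutoffs_um), "cutoffs_um")
  if (any(diff(cutoffs_um) >= 0)) {
    stop_validation("stage cutoffs must be strictly decreasing")
  }
  structure(list(flow_rate_lpm = flow_rate_lpm,
                 stage_labels = as.character(stage_labels),
                 cutoffs_um = as.numeric(cutoffs_um),
                 terminal_label = terminal_label),
            class = "cutoff_table")
}

#' Next-Generation Impactor cutoffs
#'
#' Stage D50 cutoff diameters of the Next-Generation Impactor at 60 L/min,
#' from the archival calibration of Marple et al. (2003), J Aerosol Med
#' 16(3):283-299: stages 1-7 at 8.06, 4.46, 2.82, 1.66, 0.94, 0.55 and
#' 0.34 µm, followed by the micro-orifice collector (MOC). Only the 60 L/min
#' calibration is shipped; build a [cutoff_table()] by hand for other flow
#' rates or impactors.
#'
#' @param flow_rate_lpm Flow rate; only 60 is supported by the shipped table.
#' @return A [cutoff_table()].
#' @export
ngi_cutoffs <- function(flow_rate_lpm = 60) {
  if (!isTRUE(all.equal(flow_rate_lpm, 60))) {
    stop_validation(
      "only the 60 L/min NGI calibration is shipped; supply a cutoff_table() for %g L/min",
      flow_rate_lpm)
  }
  cutoff_table(60, paste0("stage", 1:7),
               c(8.06, 4.46, 2.82, 1.66, 0.94, 0.55, 0.34))
}

#' A single cascade-impactor run
#'
#' Per-stage deposited masses plus the accounting masses recovered from the
#' capsule, the inhaler device, the induction port (inlet/throat) and the
#' pre-separator. Stage masses must match the cutoff table's stages followed
#' by its terminal collector.
#'
#' @param stage_masses_ug Named numeric vector of deposited masses (µg) for
#'   each sizing stage and the terminal collector, in cutoff-table order.
#' @param capsule_ug,device_ug,inlet_ug,preseparator_ug Accounting masses, µg.
#' @param cutoffs A [cutoff_table()].
#' @param loaded_dose_ug Optional nominal loaded dose, µg.
#' @return An object of class `impactor_run`.
#' @export
impactor_run <- function(stage_masses_ug, capsule_ug = 0, device_ug = 0,
                         inlet_ug = 0, preseparator_ug = 0,
                         cutoffs = ngi_cutoffs(), loaded_dose_ug = NULL) {
  stopifnot(inherits(cutoffs, "cutoff_table"))
  expected <- c(cutoffs$stage_labels, cutoffs$terminal_label)
  if (length(stage_masses_ug) == 0L) stop_validation("stage masses are empty")
  if (is.null(names(stage_masses_ug))) {
    if (length(stage_masses_ug) != length(expected)) {
      stop_validation("expected %d stage masses (stages + terminal collector), got %d",
                      length(expected), length(stage_masses_ug))
    }
    names(stage_masses_ug) <- expected
  }
  if (!identical(names(stage_masses_ug), expected)) {
    stop_validation("stage mass labels must be: %s", paste(expected, collapse = ", "))
  }
  check_nonnegative(stage_masses_ug, "stage_masses_ug")
  check_nonnegative(capsule_ug, "capsule_ug")
  check_nonnegative(device_ug, "device_ug")
  check_nonnegative(inlet_ug, "inlet_ug")
  check_nonnegative(preseparator_ug, "preseparator_ug")
  structure(list(stage_masses_ug = stage_masses_ug,
                 capsule_ug = capsule_ug, device_ug = device_ug,
                 inlet_ug = inlet_ug, preseparator_ug = preseparator_ug,
                 cutoffs = cutoffs, loaded_dose_ug = loaded_dose_ug),
            class = "impactor_run")
}

#' Read an impactor run from CSV
#'
#' Expects columns `fraction,label,mass_ug` where `fraction` is one of
#' `stage` or `accounting`; accounting labels are capsule, device, inlet,
#' preseparator; stage labels must match the cutoff table (stage1..stage7,
#' moc for the shipped NGI table).
#'
#' @param path CSV file path.
#' @param cutoffs A [cutoff_table()].
#' @return An [impactor_run()].
#' @export
read_impactor_csv <- function(path, cutoffs = ngi_cutoffs()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fraction", "label", "mass_ug")
  if (!all(need %in% names(df))) {
    stop_validation("impactor CSV must have columns: %s", paste(need, collapse = ", "))
  }
  acc <- df[df$fraction == "accounting", ]
  getacc <- function(lbl) {
    m <- acc$mass_ug[acc$label == lbl]
    if (length(m) == 0L) 0 else sum(m)
  }
  st <- df[df$fraction == "stage", ]
  masses <- stats::setNames(st$mass_ug, st$label)
  expected <- c(cutoffs$stage_labels, cutoffs$terminal_label)
  if (!all(expected %in% names(masses))) {
    stop_validation("missing stage rows: %s",
                    paste(setdiff(expected, names(masses)), collapse = ", "))
  }
  impactor_run(masses[expected],
               capsule_ug = getacc("capsule"), device_ug = getacc("device"),
               inlet_ug = getacc("inlet"), preseparator_ug = getacc("preseparator"),
               cutoffs = cutoffs)
}

#' Write an impactor run to CSV
#'
#' Inverse of [read_impactor_csv()]; writes the `fraction,label,mass_ug`
#' schema.
#'
#' @param run An [impactor_run()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_impactor_csv <- function(run, path) {
  stopifnot(inherits(run, "impactor_run"))
  df <- rbind(
    data.frame(fraction = "stage", label = names(run$stage_masses_ug),
               mass_ug = as.numeric(run$stage_masses_ug)),
    data.frame(fraction = "accounting",
               label = c("capsule", "device", "inlet", "preseparator"),
               mass_ug = c(run$capsule_ug, run$device_ug, run$inlet_ug,
                           run$preseparator_ug)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mass balance of an impactor run
#'
#' Conventional cascade-impactor accounting: the recovered dose is everything
#' rinsed from the system including the capsule; the emitted (ex-device) dose
#' excludes capsule and device residues; the impactor-sized mass is the mass
#' on the sizing stages plus the terminal collector — the inlet and
#' pre-separator deposits have no cutoff and are excluded from the size
#' distribution although they count towards the emitted dose.
#'
#' @param run An [impactor_run()].
#' @return List with `recovered_dose`, `emitted_dose`, `impactor_sized_mass`
#'   (all µg).
#' @export
mass_balance <- function(run) {
  stopifnot(inherits(run, "impactor_run"))
  sized <- sum(run$stage_masses_ug)
  recovered <- sized + run$capsule_ug + run$device_ug + run$inlet_ug +
    run$preseparator_ug
  list(recovered_dose = recovered,
       emitted_dose = recovered - run$capsule_ug - run$device_ug,
       impactor_sized_mass = sized)
}

#' Cumulative undersize distribution
#'
#' For each stage cutoff, the percentage of the impactor-sized mass deposited
#' on all finer stages plus the terminal collector — i.e. the mass fraction
#' with aerodynamic diameter below that cutoff.
#'
#' @param run An [impactor_run()].
#' @return Data frame with columns `cutoff_um` (decreasing) and
#'   `cum_pct_under` (nonincreasing down the table).
#' @export
cumulative_undersize <- function(run) {
  stopifnot(inherits(run, "impactor_run"))
  bal <- mass_balance(run)
  if (bal$impactor_sized_mass <= 0) {
    stop_validation("impactor-sized mass is zero; no size distribution")
  }
  m <- run$stage_masses_ug
  n_stage <- length(run$cutoffs$cutoffs_um)
  # mass below cutoff i = everything deposited past stage i
  below <- rev(cumsum(rev(m)))[-1L][seq_len(n_stage)]
  data.frame(cutoff_um = run$cutoffs$cutoffs_um,
             cum_pct_under = 100 * below / bal$impactor_sized_mass)
}

# Two-point log-probit interpolation: given the cumulative-undersize table,
# find the diameter at which the cumulative fraction crosses `target_pct`.
# Interpolates qnorm(fraction) linearly in log10(diameter) between the two
# bracketing stages (standard pharmacopoeial practice).
interp_diameter_at <- function(undersize, target_pct) {
  d <- undersize$cutoff_um
  p <- undersize$cum_pct_under
  ord <- order(d)           # ascending diameter, ascending cumulative %
  d <- d[ord]; p <- p[ord]
  usable <- p > 0 & p < 100 # probit undefined at the extremes
  d <- d[usable]; p <- p[usable]
  if (length(d) < 2L || min(p) > target_pct || max(p) < target_pct) {
    stop_validation("distribution not bracketed at %.2f%% undersize", target_pct)
  }
  hi <- which(p >= target_pct)[1L]
  if (p[hi] == target_pct) return(d[hi])
  lo <- hi - 1L
  z <- stats::qnorm(c(p[lo], p[hi]) / 100)
  zt <- stats::qnorm(target_pct / 100)
  logd <- log10(d[lo]) + (zt - z[1L]) / (z[2L] - z[1L]) *
    (log10(d[hi]) - log10(d[lo]))
  10^logd
}

#' Mass median aerodynamic diameter and geometric standard deviation
#'
#' MMAD is the diameter at 50% cumulative undersize, found by linear
#' interpolation of probit(cumulative fraction) against log10(cutoff)
#' between the two bracketing stages. GSD = sqrt(D84.13 / D15.87), the
#' geometric standard deviation of the (assumed lognormal) mass distribution.
#'
#' @param undersize A cumulative-undersize table from [cumulative_undersize()],
#'   or an [impactor_run()] (reduced internally).
#' @return List with `MMAD` (µm) and `GSD` (dimensionless).
#' @export
mmad_gsd <- function(undersize) {
  if (inherits(undersize, "impactor_run")) {
    undersize <- cumulative_undersize(undersize)
  }
  mmad <- interp_diameter_at(undersize, 50)
  d84 <- interp_diameter_at(undersize, 84.13)
  d16 <- interp_diameter_at(undersize, 15.87)
  list(MMAD = mmad, GSD = sqrt(d84 / d16))
}

#' Fine particle fraction
#'
#' Percentage of dose with aerodynamic diameter below `size_limit_um`
#' (default 5 µm). The sized mass below the limit is obtained by the same
#' log-probit interpolation used for the MMAD, applied to the cumulative mass
#' curve; the denominator is configurable because conventions differ: the
#' emitted (ex-device) dose, the total recovered dose, or the impactor-sized
#' mass alone.
#'
#' @param run An [impactor_run()].
#' @param size_limit_um Fine-particle size limit, µm.
#' @param denominator One of "emitted", "recovered", "sized".
#' @return List with `FPF` (percent), `fine_mass_ug`, `denominator_used`.
#' @export
fine_particle_fraction <- function(run, size_limit_um = 5.0,
                                   denominator = c("emitted", "recovered", "sized")) {
  stopifnot(inherits(run, "impactor_run"))
  denominator <- match.arg(denominator)
  bal <- mass_balance(run)
  und <- cumulative_undersize(run)
  pct_under_limit <-
    if (all(und$cum_pct_under <= 0)) 0
    else if (all(und$cum_pct_under >= 100 - 1e-12)) 100
    else interp_pct_at(und, size_limit_um)
  fine_mass <- pct_under_limit / 100 * bal$impactor_sized_mass
  denom <- switch(denominator,
                  emitted = bal$emitted_dose,
                  recovered = bal$recovered_dose,
                  sized = bal$impactor_sized_mass)
  if (denom <= 0) stop_validation("FPF denominator (%s) is zero", denominator)
  list(FPF = 100 * fine_mass / denom,
       fine_mass_ug = fine_mass,
       denominator_used = denominator)
}

# Cumulative % undersize at an arbitrary diameter. Within the stage range the
# two bracketing stages are interpolated on the probit/log10 scale when both
# carry informative (0 < % < 100) values; saturated brackets (both 0% or both
# 100%) pass through unchanged, and a mixed bracket falls back to linear
# interpolation in log10(d). Outside the stage range the value is clamped to
# the nearest stage's cumulative percentage.
interp_pct_at <- function(undersize, diameter_um) {
  d <- undersize$cutoff_um
  p <- undersize$cum_pct_under
  ord <- order(d)
  d <- d[ord]; p <- p[ord]
  if (diameter_um <= d[1L]) return(p[1L])
  n <- length(d)
  if (diameter_um >= d[n]) return(p[n])
  i <- findInterval(diameter_um, d)
  p_lo <- p[i]; p_hi <- p[i + 1L]
  if (p_lo == p_hi) return(p_lo)
  frac <- (log10(diameter_um) - log10(d[i])) / (log10(d[i + 1L]) - log10(d[i]))
  if (p_lo > 0 && p_lo < 100 && p_hi > 0 && p_hi < 100) {
    z <- stats::qnorm(c(p_lo, p_hi) / 100)
    return(100 * stats::pnorm(z[1L] + frac * (z[2L] - z[1L])))
  }
  p_lo + frac * (p_hi - p_lo)
}

#' Full aerosol summary for an impactor run
#'
#' Mass balance, MMAD, GSD and fine particle fraction in one call.
#'
#' @inheritParams fine_particle_fraction
#' @return List of class `aerosol_summary` with MMAD, GSD, FPF,
#'   emitted_dose, recovered_dose, impactor_sized_mass, denominator_used.
#' @export
aerosol_summary <- function(run, size_limit_um = 5.0, denominator = "emitted") {
  bal <- mass_balance(run)
  mg <- mmad_gsd(run)
  fpf <- fine_particle_fraction(run, size_limit_um, denominator)
  structure(c(mg, list(FPF = fpf$FPF), bal,
              list(denominator_used = fpf$denominator_used)),
            class = "aerosol_summary")
}

#' @export
print.aerosol_summary <- function(x, ...) {
  cat(sprintf("MMAD = %.2f um, GSD = %.2f, FPF = %.1f%% (of %s dose)\n",
              x$MMAD, x$GSD, x$FPF, x$denominator_used))
  cat(sprintf("recovered %.1f ug, emitted %.1f ug, sized %.1f ug\n",
              x$recovered_dose, x$emitted_dose, x$impactor_sized_mass))
  invisible(x)
}
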