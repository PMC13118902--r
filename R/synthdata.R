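# Seeded synthetic-data generators. Each generator produces the exact object
# its consumer module takes, from a known ground truth, so every pipeline
# stage is testable without instrument output. Same seed + parameters give
# identical output (set.seed at entry; no other RNG use inside).

#' Simulate a cascade-impactor run from a lognormal aerosol
#'
#' Generates per-stage deposited masses by discretizing a lognormal
#' aerodynamic mass distribution (median `mmad_true`, geometric SD
#' `gsd_true`) onto the cutoff table: the mass on stage i is the lognormal
#' CDF increment between the cutoffs bracketing that stage, the terminal
#' collector takes the tail below the last cutoff, and anything above the
#' first cutoff lands on stage 1. `noise = "none"` is the exact
#' discretization; `noise = "multinomial"` resamples `n_particles` mass
#' quanta multinomially across the stage bins. Losses (capsule, device,
#' inlet, pre-separator) are fixed fractions of the sized mass.
#'
#' @param mmad_true True mass median aerodynamic diameter, µm.
#' @param gsd_true True geometric standard deviation (≥ 1).
#' @param total_sized_mass_ug Mass reaching the sizing stages, µg.
#' @param loss_fractions Named list/vector with `capsule`, `device`, `inlet`,
#'   `preseparator`: each loss mass = fraction × total_sized_mass_ug.
#' @param noise "none" or "multinomial".
#' @param n_particles Number of mass quanta for multinomial noise.
#' @param cutoffs A [cutoff_table()].
#' @param seed Integer seed (used only for multinomial noise).
#' @return An [impactor_run()].
#' @export
gen_impactor_run <- function(mmad_true = 4.76, gsd_true = 1.38,
                             total_sized_mass_ug = 1000,
                             loss_fractions = c(capsule = 0.15, device = 0.05,
                                                inlet = 0.20, preseparator = 0.25),
                             noise = c("none", "multinomial"),
                             n_particles = 1e5,
                             cutoffs = ngi_cutoffs(), seed = 1L) {
  noise <- match.arg(noise)
  check_positive(mmad_true, "mmad_true")
  if (!is.numeric(gsd_true) || gsd_true < 1) {
    stop_validation("gsd_true must be >= 1, got %s", format(gsd_true))
  }
  check_positive(total_sized_mass_ug, "total_sized_mass_ug")
  lf <- as.list(loss_fractions)
  for (k in c("capsule", "device", "inlet", "preseparator")) {
    if (is.null(lf[[k]])) lf[[k]] <- 0
    check_nonnegative(lf[[k]], paste0("loss_fractions$", k))
  }

  mu <- log(mmad_true)
  sdlog <- if (gsd_true == 1) 1e-12 else log(gsd_true)
  # cumulative mass fraction below each cutoff (coarse -> fine)
  p_under <- stats::plnorm(cutoffs$cutoffs_um, mu, sdlog)
  # bin probabilities: stage1 = above c1; stage i = between c_{i-1} and c_i;
  # terminal collector = below the last cutoff
  probs <- c(diff(c(1, p_under)) * -1, p_under[length(p_under)])
  probs <- pmax(probs, 0)

  masses <- if (noise == "none") {
    total_sized_mass_ug * probs
  } else {
    set.seed(as.integer(seed))
    counts <- as.numeric(stats::rmultinom(1, size = n_particles, prob = probs))
    total_sized_mass_ug * counts / n_particles
  }
  names(masses) <- c(cutoffs$stage_labels, cutoffs$terminal_label)

  impactor_run(masses,
               capsule_ug = lf$capsule * total_sized_mass_ug,
               device_ug = lf$device * total_sized_mass_ug,
               inlet_ug = lf$inlet * total_sized_mass_ug,
               preseparator_ug = lf$preseparator * total_sized_mass_ug,
               cutoffs = cutoffs)
}

#' Simulate a microrod population with fragments
#'
#' Mixture of intact rods and fragments, emulating imaging-flow summary
#' output of a template-grown rod batch. Intact rod lengths are normal
#' (truncated to (0, template_length]: rods cannot exceed the template pore
#' length); fragment lengths are uniform on (0, length_mean × fragment_scale];
#' widths are normal truncated at zero.
#'
#' @param n Number of particles (> 0).
#' @param length_mean,length_sd Intact rod length distribution, µm.
#' @param width_mean,width_sd Rod width distribution, µm.
#' @param fragment_fraction Fraction of particles that are fragments, [0, 1].
#' @param fragment_scale Upper fragment length as a fraction of `length_mean`,
#'   in (0, 1).
#' @param template_length Maximum possible rod length (template pore length), µm.
#' @param seed Integer seed.
#' @return Data frame with columns `length_um`, `width_um`, `is_fragment`.
#' @export
gen_rod_population <- function(n, length_mean = 12.12, length_sd = 1.5,
                               width_mean = 3.41, width_sd = 0.4,
                               fragment_fraction = 0.1, fragment_scale = 0.5,
                               template_length = 13.0, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop_validation("n must be a positive count, got %s", format(n))
  }
  check_positive(length_mean, "length_mean"); check_nonnegative(length_sd, "length_sd")
  check_positive(width_mean, "width_mean"); check_nonnegative(width_sd, "width_sd")
  if (fragment_fraction < 0 || fragment_fraction > 1) {
    stop_validation("fragment_fraction must be in [0, 1]")
  }
  if (fragment_scale <= 0 || fragment_scale >= 1) {
    stop_validation("fragment_scale must be in (0, 1)")
  }
  check_positive(template_length, "template_length")

  set.seed(as.integer(seed))
  n <- as.integer(n)
  is_frag <- stats::runif(n) < fragment_fraction
  n_frag <- sum(is_frag)

  rtruncnorm <- function(k, mean, sd, lo = 0, hi = Inf) {
    out <- stats::rnorm(k, mean, sd)
    bad <- out <= lo | out > hi
    while (any(bad)) {  # rejection; tails are tiny for realistic moments
      out[bad] <- stats::rnorm(sum(bad), mean, sd)
      bad <- out <= lo | out > hi
    }
    out
  }

  len <- numeric(n)
  len[!is_frag] <- rtruncnorm(n - n_frag, length_mean, length_sd,
                              hi = template_length)
  len[is_frag] <- length_mean * fragment_scale * stats::runif(n_frag)
  wid <- rtruncnorm(n, width_mean, width_sd)

  data.frame(length_um = len, width_um = wid, is_fragment = is_frag)
}

#' Simulate an MTT/LDH plate from a dose-response curve
#'
#' Generates per-well net ODs by inverting the viability definition through a
#' four-parameter logistic viability curve
#' V(dose) = v_min + (v_max − v_min) / (1 + (dose/ec50)^hill),
#' so that running the plate back through the viability pipeline recovers the
#' curve exactly when `noise_sd = 0`. Gaussian noise of SD `noise_sd` is
#' added to the sample-well net ODs. The reference-wavelength channel is a
#' constant baseline so net OD equals `a_measure − a_reference`.
#'
#' @param dose_levels Numeric vector of doses (condition identifiers), e.g.
#'   mg/mL concentrations.
#' @param v_max,v_min Viability asymptotes at zero and saturating dose, percent.
#' @param ec50 Dose at half-maximal effect (same units as `dose_levels`).
#' @param hill Hill slope (> 0).
#' @param od_neg,od_pos Net OD of the negative and positive controls.
#' @param noise_sd Gaussian noise SD on sample net ODs (OD units).
#' @param replicates Sample wells per dose.
#' @param n_controls Wells per control type.
#' @param assay "MTT" or "LDH" (controls and schema are identical; the label
#'   selects the downstream metric).
#' @param seed Integer seed.
#' @return A [plate_assay()]. The generating viability per dose is attached
#'   as attribute `true_viability`.
#' @export
gen_plate <- function(dose_levels = c(0.025, 0.05, 0.1, 0.2, 0.4),
                      v_max = 100, v_min = 20, ec50 = 0.2, hill = 2,
                      od_neg = 0.8, od_pos = 0.1, noise_sd = 0.02,
                      replicates = 3, n_controls = 6,
                      assay = c("MTT", "LDH"), seed = 1L) {
  assay <- match.arg(assay)
  if (od_neg == od_pos) stop_validation("degenerate controls: od_neg == od_pos")
  check_nonnegative(noise_sd, "noise_sd")
  check_positive(ec50, "ec50"); check_positive(hill, "hill")
  check_nonnegative(dose_levels, "dose_levels")

  set.seed(as.integer(seed))
  viab <- v_min + (v_max - v_min) / (1 + (dose_levels / ec50)^hill)
  # invert the viability definition: od = od_pos + V/100 (od_neg - od_pos)
  od_true <- od_pos + viab / 100 * (od_neg - od_pos)

  a_ref <- 0.05
  rows <- list()
  for (i in seq_along(dose_levels)) {
    net <- od_true[i] + stats::rnorm(replicates, 0, noise_sd)
    rows[[length(rows) + 1L]] <- data.frame(
      well = sprintf("S%d_%d", i, seq_len(replicates)),
      role = "sample", condition = dose_levels[i],
      a_measure = net + a_ref, a_reference = a_ref)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    well = sprintf("NC%d", seq_len(n_controls)), role = "negative_control",
    condition = NA_real_, a_measure = od_neg + a_ref, a_reference = a_ref)
  rows[[length(rows) + 1L]] <- data.frame(
    well = sprintf("PC%d", seq_len(n_controls)), role = "positive_control",
    condition = NA_real_, a_measure = od_pos + a_ref, a_reference = a_ref)

  plate <- plate_assay(do.call(rbind, rows), assay)
  attr(plate, "true_viability") <- stats::setNames(viab, dose_levels)
  plate
}

#' Simulate a disintegration time series
#'
#' First-order decay with Poisson counting noise: per-batch counts at time t
#' are Poisson(n0 exp(−rate t)), with reference batches measured at t = 0.
#' The decay law is a testing device emulating dissolution-driven rod
#' disintegration (fast in acidic simulant fluid, slow near neutral pH), not
#' a kinetic claim.
#'
#' @param series_type "acidic_fast" (default rate 0.05/min) or "neutral_slow"
#'   (default rate 0.0005/min); explicit `rate_per_min` overrides the preset.
#' @param rate_per_min First-order disintegration rate, 1/min (≥ 0).
#' @param t_points Measurement timepoints, minutes.
#' @param n0 Mean reference object count.
#' @param batches Number of independent batches.
#' @param seed Integer seed.
#' @return A [disintegration_series()].
#' @export
gen_disintegration <- function(series_type = c("acidic_fast", "neutral_slow"),
                               rate_per_min = NULL,
                               t_points = c(10, 20, 30, 70, 180, 360),
                               n0 = 1000, batches = 3, seed = 1L) {
  series_type <- match.arg(series_type)
  if (is.null(rate_per_min)) {
    rate_per_min <- switch(series_type, acidic_fast = 0.05, neutral_slow = 5e-4)
  }
  if (!is.numeric(rate_per_min) || rate_per_min < 0) {
    stop_validation("rate_per_min must be >= 0")
  }
  check_positive(n0, "n0"); check_positive(batches, "batches")

  set.seed(as.integer(seed))
  ref <- data.frame(batch = sprintf("ref%d", seq_len(batches)),
                    time_min = 0,
                    count = stats::rpois(batches, n0),
                    is_reference = TRUE)
  obs <- do.call(rbind, lapply(seq_len(batches), function(b) {
    data.frame(batch = sprintf("batch%d", b),
               time_min = t_points,
               count = stats::rpois(length(t_points),
                                    n0 * exp(-rate_per_min * t_points)),
               is_reference = FALSE)
  }))
  disintegration_series(rbind(ref, obs))
}
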