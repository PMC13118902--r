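# Synthetic-data generators: determinism, ground-truth recovery, validity.

test_that("generators are deterministic under a fixed seed", {
  expect_identical(gen_impactor_run(noise = "multinomial", seed = 9),
                   gen_impactor_run(noise = "multinomial", seed = 9))
  expect_identical(gen_rod_population(500, seed = 9),
                   gen_rod_population(500, seed = 9))
  p1 <- gen_plate(seed = 9); p2 <- gen_plate(seed = 9)
  expect_identical(p1$wells, p2$wells)
  expect_identical(gen_disintegration(seed = 9)$counts,
                   gen_disintegration(seed = 9)$counts)
  # and actually depend on the seed
  expect_false(identical(gen_plate(seed = 1)$wells, gen_plate(seed = 2)$wells))
})

test_that("impactor generator: exact discretization and degenerate width", {
  run <- gen_impactor_run(4.76, 1.38, total_sized_mass_ug = 1000, noise = "none")
  expect_equal(sum(run$stage_masses_ug), 1000, tolerance = 1e-9)
  # stage masses equal analytic lognormal CDF increments
  p <- plnorm(ngi_cutoffs()$cutoffs_um, log(4.76), log(1.38))
  expect_equal(unname(run$stage_masses_ug),
               1000 * c(1 - p[1], -diff(p), p[7]), tolerance = 1e-12)
  # near-degenerate GSD puts all mass on the stages bracketing the median
  tight <- gen_impactor_run(4.76, 1 + 1e-9, noise = "none")
  on_bracket <- tight$stage_masses_ug[c("stage2", "stage3")]
  expect_equal(sum(on_bracket), sum(tight$stage_masses_ug), tolerance = 1e-9)
  expect_error(gen_impactor_run(gsd_true = 0.9), class = "rodaero_validation_error")
})

test_that("multinomial noise converges to the exact discretization", {
  exact <- gen_impactor_run(noise = "none")
  noisy <- gen_impactor_run(noise = "multinomial", n_particles = 1e6, seed = 2)
  expect_equal(unname(noisy$stage_masses_ug), unname(exact$stage_masses_ug),
               tolerance = 0.02)
})

test_that("rod population: fragment-free median near length mean, span grows with fragments", {
  pop0 <- gen_rod_population(5000, length_mean = 12.12, length_sd = 1.5,
                             fragment_fraction = 0, template_length = 13,
                             seed = 3)
  ss0 <- size_summary(pop0$length_um)
  # truncated-normal median oracle: qnorm at half the truncated mass
  alpha <- pnorm((13 - 12.12) / 1.5)
  med_oracle <- 12.12 + 1.5 * qnorm(alpha / 2)
  expect_equal(ss0$d50, med_oracle, tolerance = 0.02)
  expect_true(all(pop0$length_um <= 13))
  expect_true(all(pop0$width_um > 0))
  # more fragments -> wider span, across independent seeds
  spans <- sapply(1:20, function(s) {
    lo <- size_summary(gen_rod_population(2000, fragment_fraction = 0.05,
                                          seed = s)$length_um)$span
    hi <- size_summary(gen_rod_population(2000, fragment_fraction = 0.4,
                                          seed = s)$length_um)$span
    hi - lo
  })
  expect_true(all(spans > 0))
  expect_error(gen_rod_population(0), class = "rodaero_validation_error")
  expect_error(gen_rod_population(10, fragment_fraction = 1.5),
               class = "rodaero_validation_error")
})

test_that("plate generator inverts the viability definition exactly", {
  plate <- gen_plate(dose_levels = c(0, 0.2), noise_sd = 0, v_max = 100,
                     v_min = 20, ec50 = 0.2, hill = 2, seed = 1)
  res <- reduce_plate(plate)
  # dose 0 -> v_max; dose = ec50 -> midpoint of the asymptotes
  expect_equal(res$mean[res$condition == 0], 100, tolerance = 1e-9)
  expect_equal(res$mean[res$condition == 0.2], (100 + 20) / 2, tolerance = 1e-9)
  expect_error(gen_plate(od_neg = 0.5, od_pos = 0.5),
               class = "rodaero_validation_error")
})

test_that("noisy plates recover the generating dose-response within 2 noise SD", {
  noise_sd <- 0.02
  plate <- gen_plate(noise_sd = noise_sd, replicates = 6, seed = 4)
  res <- reduce_plate(plate)
  truth <- attr(plate, "true_viability")
  truth <- truth[order(as.numeric(names(truth)))]
  # 2*noise_sd in OD units maps to viability through the control span
  tol_pct <- 2 * noise_sd / (0.8 - 0.1) * 100
  expect_true(all(abs(res$mean - unname(truth)) <= tol_pct))
})

test_that("disintegration generator matches exponential-decay oracles", {
  # rate 0: remaining ~100% at every timepoint (within Poisson noise)
  flat <- gen_disintegration(rate_per_min = 0, n0 = 5000, batches = 5, seed = 6)
  rf <- remaining_fraction(flat)
  se <- 100 * sqrt(5000) / 5000 / sqrt(5)  # Poisson SE of the batch mean, in %
  expect_true(all(abs(rf$remaining_pct_mean - 100) < 4 * se))
  # half-life: mean remaining at t = ln2/rate is ~50% within 3 SE
  rate <- 0.02
  t_half <- log(2) / rate
  dec <- gen_disintegration(rate_per_min = rate, t_points = c(10, t_half, 100),
                            n0 = 2000, batches = 6, seed = 7)
  rfd <- remaining_fraction(dec)
  at_half <- rfd[rfd$time_min == t_half, ]
  se_half <- 100 * sqrt(1000) / 2000 / sqrt(6)
  expect_lt(abs(at_half$remaining_pct_mean - 50), 3 * se_half)
  # monotone decay of the mean over seeds
  mono <- sapply(1:10, function(s) {
    r <- remaining_fraction(gen_disintegration(rate_per_min = 0.01, n0 = 5000,
                                               batches = 3, seed = s))
    all(diff(r$remaining_pct_mean) < 0)
  })
  expect_true(all(mono))
  expect_error(gen_disintegration(rate_per_min = -1),
               class = "rodaero_validation_error")
})

test_that("generator outputs satisfy their consumers' invariants", {
  run <- gen_impactor_run(noise = "multinomial", seed = 10)
  expect_s3_class(run, "impactor_run")
  u <- cumulative_undersize(run)
  expect_true(all(u$cum_pct_under >= 0 & u$cum_pct_under <= 100))
  plate <- gen_plate(seed = 10)
  expect_s3_class(plate, "plate_assay")
  series <- gen_disintegration(seed = 10)
  expect_s3_class(series, "disintegration_series")
  expect_gt(series$reference_mean, 0)
})
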