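# Cascade-impactor data reduction.

make_run <- function(stage_masses, ...) {
  impactor_run(stats::setNames(stage_masses, c(paste0("stage", 1:7), "moc")), ...)
}

test_that("mass balance accounting", {
  run <- make_run(c(rep(100 / 7, 7), 0), capsule_ug = 20, device_ug = 5,
                  inlet_ug = 10, preseparator_ug = 15)
  bal <- mass_balance(run)
  expect_equal(bal$recovered_dose, 150)
  expect_equal(bal$emitted_dose, 125)
  expect_equal(bal$impactor_sized_mass, 100)
  # single-stage deposition, no losses: emitted equals that stage
  solo <- make_run(c(0, 0, 42, 0, 0, 0, 0, 0))
  expect_equal(mass_balance(solo)$emitted_dose, 42)
  expect_error(make_run(c(-1, rep(1, 7))), class = "rodaero_validation_error")
})

test_that("cumulative undersize: extremes and equal-mass steps", {
  all_moc <- make_run(c(rep(0, 7), 50))
  expect_true(all(cumulative_undersize(all_moc)$cum_pct_under == 100))
  all_s1 <- make_run(c(50, rep(0, 7)))
  expect_true(all(cumulative_undersize(all_s1)$cum_pct_under == 0))
  equal <- make_run(rep(10, 8))
  u <- cumulative_undersize(equal)
  # brute force: below cutoff i lies (8 - i)/8 of the mass
  expect_equal(u$cum_pct_under, 100 * (7:1) / 8)
  expect_true(all(diff(u$cum_pct_under) <= 0))      # decreasing cutoff order
  expect_true(all(u$cum_pct_under >= 0 & u$cum_pct_under <= 100))
  expect_error(cumulative_undersize(make_run(rep(0, 8))),
               class = "rodaero_validation_error")
})

test_that("MMAD/GSD recover a discretized lognormal", {
  run <- gen_impactor_run(mmad_true = 4.76, gsd_true = 1.38, noise = "none")
  mg <- mmad_gsd(run)
  expect_lt(abs(mg$MMAD - 4.76) / 4.76, 0.05)
  expect_lt(abs(mg$GSD - 1.38) / 1.38, 0.05)
  expect_gte(mg$GSD, 1)
})

test_that("MMAD equals a cutoff hit exactly at 50%", {
  # exactly half the sized mass lies below stage 3's cutoff (2.82 um)
  run <- make_run(c(10, 40, 0, 30, 10, 5, 3, 2))
  expect_equal(mmad_gsd(run)$MMAD, 2.82)
})

test_that("monodisperse-ish mass between two cutoffs gives small GSD, bracketed MMAD", {
  run <- make_run(c(1e-4, 1e-4, 49, 49, 1e-4, 1e-4, 1e-4, 1e-4))
  mg <- mmad_gsd(run)
  expect_gt(mg$MMAD, 1.66)
  expect_lt(mg$MMAD, 4.46)
  expect_lt(mg$GSD, 1.5)
  expect_error(mmad_gsd(make_run(c(100, rep(0, 7)))), "not bracketed")
})

test_that("fine particle fraction: extremes, analytic oracle, invariances", {
  # everything below 5 um (on fine stages), sized denominator
  fine <- make_run(c(0, 0, 30, 30, 30, 5, 3, 2))
  expect_equal(fine_particle_fraction(fine, denominator = "sized")$FPF, 100)
  # nothing below the 5 um region
  coarse <- make_run(c(60, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(fine_particle_fraction(coarse, denominator = "sized")$FPF, 0)
  # analytic lognormal CDF oracle at 5 um
  run <- gen_impactor_run(4.76, 1.38, noise = "none",
                          loss_fractions = c(capsule = 0, device = 0,
                                             inlet = 0, preseparator = 0))
  fpf <- fine_particle_fraction(run, 5, "sized")$FPF
  analytic <- 100 * plnorm(5, log(4.76), log(1.38))
  expect_lt(abs(fpf - analytic) / analytic, 0.05)
  # scale invariance
  run10 <- gen_impactor_run(4.76, 1.38, total_sized_mass_ug = 1e4, noise = "none",
                            loss_fractions = c(capsule = 0, device = 0,
                                               inlet = 0, preseparator = 0))
  expect_equal(fine_particle_fraction(run10, 5, "sized")$FPF, fpf, tolerance = 1e-9)
  # emitted -> recovered denominator never increases FPF
  lossy <- gen_impactor_run(4.76, 1.38, noise = "none")
  expect_gte(fine_particle_fraction(lossy, 5, "emitted")$FPF,
             fine_particle_fraction(lossy, 5, "recovered")$FPF)
})

test_that("log-probit reduction is exact for lognormal aerosols on any grid", {
  # probit(cumulative %) is linear in log(d) for a lognormal, so two-point
  # interpolation recovers the generating parameters up to floating error,
  # independently of the cutoff grid
  fine_grid <- cutoff_table(60, paste0("s", 1:30),
                            10^seq(log10(20), log10(0.2), length.out = 30))
  for (run in list(gen_impactor_run(4.76, 1.38, noise = "none"),
                   gen_impactor_run(4.76, 1.38, noise = "none", cutoffs = fine_grid))) {
    mg <- mmad_gsd(run)
    expect_equal(mg$MMAD, 4.76, tolerance = 1e-9)
    # the conventional 84.13/15.87 percentiles round 100*pnorm(+/-1), leaving
    # a ~1e-4 relative offset in GSD even on an exact lognormal
    expect_equal(mg$GSD, 1.38, tolerance = 1e-3)
  }
})

test_that("impactor CSV round-trips", {
  run <- gen_impactor_run(noise = "multinomial", seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_impactor_csv(run, path)
  back <- read_impactor_csv(path)
  expect_equal(back$stage_masses_ug, run$stage_masses_ug, tolerance = 1e-9)
  expect_equal(back$capsule_ug, run$capsule_ug)
  expect_equal(aerosol_summary(back)$MMAD, aerosol_summary(run)$MMAD,
               tolerance = 1e-9)
})

test_that("cutoff table validation and NGI fixture", {
  ngi <- ngi_cutoffs()
  expect_equal(ngi$cutoffs_um, c(8.06, 4.46, 2.82, 1.66, 0.94, 0.55, 0.34))
  expect_error(ngi_cutoffs(30), "60 L/min")
  expect_error(cutoff_table(60, c("a", "b"), c(1, 2)),
               class = "rodaero_validation_error")
})
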