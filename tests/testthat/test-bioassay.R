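# Plate-reader metrics, classification, disintegration and size summaries.

test_that("net OD is reference-wavelength subtraction", {
  expect_equal(net_od(0.80, 0.05), 0.75)
  expect_equal(net_od(0.3, 0.3), 0)
  expect_error(net_od(NA, 0.05), class = "rodaero_validation_error")
})

test_that("viability and cytotoxicity hit their control anchors exactly", {
  expect_equal(viability_mtt(0.8, 0.8, 0.1), 100)
  expect_equal(viability_mtt(0.1, 0.8, 0.1), 0)
  expect_equal(viability_mtt(0.5, 0.8, 0.1), 57.142857, tolerance = 1e-6)
  expect_equal(cytotoxicity_ldh(0.1, 0.1, 0.9), 0)
  expect_equal(cytotoxicity_ldh(0.9, 0.1, 0.9), 100)
  expect_equal(cytotoxicity_ldh(0.3, 0.1, 0.9), 25)
  expect_error(viability_mtt(0.5, 0.4, 0.4), "degenerate")
  expect_error(cytotoxicity_ldh(0.5, 0.4, 0.4), "degenerate")
})

test_that("both metrics are affine in the sample OD", {
  od <- seq(0, 1, by = 0.1)
  v <- suppressWarnings(viability_mtt(od, 0.8, 0.1))
  ct <- suppressWarnings(cytotoxicity_ldh(od, 0.1, 0.9))
  expect_equal(diff(v), rep(diff(v)[1], length(v) - 1L))
  expect_equal(diff(ct), rep(diff(ct)[1], length(ct) - 1L))
})

test_that("out-of-range metrics warn but are not clipped", {
  expect_warning(v <- viability_mtt(0.9, 0.8, 0.1), "not clipped")
  expect_gt(v, 100)
})

test_that("threshold classification is strict at the boundary", {
  expect_true(classify_condition(cytotoxicity = 19.9)$pass)
  expect_true(classify_condition(cytotoxicity = 20)$pass)
  expect_false(classify_condition(cytotoxicity = 20.1)$pass)
  expect_true(classify_condition(viability = 80)$pass)
  expect_false(classify_condition(viability = 79.9)$pass)
  both <- classify_condition(viability = 50, cytotoxicity = 50)
  expect_false(both$pass)
  expect_true(both$reduced_viability)
  expect_true(both$cytotoxic)
  expect_warning(classify_condition(viability = 300), "plausible range")
})

test_that("remaining fraction: anchors, arithmetic, batch relabeling invariance", {
  mk <- function(counts, ref = c(1000, 1000, 1000), batches = "b1") {
    disintegration_series(rbind(
      data.frame(batch = paste0("r", seq_along(ref)), time_min = 0,
                 count = ref, is_reference = TRUE),
      data.frame(batch = batches, time_min = seq_along(counts) * 10,
                 count = counts, is_reference = FALSE)))
  }
  rf <- remaining_fraction(mk(c(800, 900, 1000)))
  expect_equal(rf$remaining_pct_mean, c(80, 90, 100))
  expect_equal(rf$disintegrated_pct_mean, c(20, 10, 0))
  expect_equal(remaining_fraction(mk(c(1000)))$remaining_pct_mean, 100)
  expect_equal(remaining_fraction(mk(c(0)))$disintegrated_pct_mean, 100)
  # linear in counts
  expect_equal(remaining_fraction(mk(c(400, 450, 500)))$remaining_pct_mean,
               c(40, 45, 50))
  # batch relabeling does not change the summary
  a <- mk(c(800, 900, 1000), batches = "x")
  b <- mk(c(800, 900, 1000), batches = "y")
  expect_equal(remaining_fraction(a)$remaining_pct_mean,
               remaining_fraction(b)$remaining_pct_mean)
  expect_error(disintegration_series(
    data.frame(batch = "b", time_min = 0, count = 0, is_reference = TRUE)),
    class = "rodaero_validation_error")
})

test_that("size summary: quantiles, span, scale invariance", {
  expect_equal(size_summary(rep(5, 20))$span, 0)
  set.seed(1)
  u <- runif(2e4)
  ss <- size_summary(u)
  expect_equal(ss$span, (0.9 - 0.1) / 0.5, tolerance = 0.02)
  expect_equal(ss$d50, 0.5, tolerance = 0.02)
  # multiplicative rescaling leaves span unchanged
  expect_equal(size_summary(7.3 * u)$span, ss$span, tolerance = 1e-9)
  expect_true(ss$d10 <= ss$d50 && ss$d50 <= ss$d90)
  expect_error(size_summary(1:5), "at least 10")
})

test_that("plate reduction pipeline computes per-condition means and flags", {
  plate <- gen_plate(noise_sd = 0, v_min = 20, ec50 = 0.2, hill = 2,
                     assay = "MTT", seed = 1)
  res <- reduce_plate(plate)
  truth <- attr(plate, "true_viability")
  expect_equal(res$mean, unname(truth[order(as.numeric(names(truth)))]),
               tolerance = 1e-9)
  expect_equal(res$metric, rep("viability", nrow(res)))
  expect_identical(res$pass, res$mean >= 80)
})

test_that("plate CSV round-trips", {
  plate <- gen_plate(assay = "LDH", seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(plate$wells, path, row.names = FALSE)
  back <- read_plate_csv(path, "LDH")
  expect_equal(reduce_plate(back)$mean, reduce_plate(plate)$mean, tolerance = 1e-12)
})

test_that("plate validation requires controls", {
  wells <- data.frame(well = "a", role = "sample", condition = 1,
                      a_measure = 0.5, a_reference = 0.05)
  expect_error(plate_assay(wells, "MTT"), "control")
})
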