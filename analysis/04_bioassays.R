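#!/usr/bin/env Rscript
# MTT viability and LDH cytotoxicity on synthetic plates.
#
# Generates plates from a known logistic dose-response over the study's
# concentration series (0.025-0.4 mg/mL), reduces them to per-condition
# mean +/- SD, and classifies each condition against the 80% viability and
# 20% cytotoxicity thresholds.

suppressPackageStartupMessages(library(rodaero))
dir.create("results", showWarnings = FALSE)

doses <- c(0.025, 0.05, 0.1, 0.2, 0.4)

mtt <- gen_plate(dose_levels = doses, v_max = 100, v_min = 60, ec50 = 0.3,
                 hill = 1.5, noise_sd = 0.02, replicates = 3,
                 assay = "MTT", seed = 1)
mtt_res <- reduce_plate(mtt)
cat("MTT viability (% of untreated control):\n")
print(mtt_res, row.names = FALSE)

# LDH plate: mild membrane damage only (v_min high -> low cytotoxicity)
ldh <- gen_plate(dose_levels = doses, v_max = 100, v_min = 85, ec50 = 0.2,
                 hill = 2, noise_sd = 0.02, replicates = 3,
                 assay = "LDH", seed = 2)
ldh_res <- reduce_plate(ldh)
cat("\nLDH cytotoxicity (% of full lysis):\n")
print(ldh_res, row.names = FALSE)

out <- rbind(mtt_res, ldh_res)
write.csv(out, "results/bioassay_summary.csv", row.names = FALSE)
cat(sprintf("\n%d of %d conditions pass both thresholds\n",
            sum(out$pass), nrow(out)))
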