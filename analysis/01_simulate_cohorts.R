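#!/usr/bin/env Rscript
# Generate the two synthetic seroconverter cohorts every later stage uses:
# a cART-era cohort (threshold-driven treatment initiation from 1996 on) and
# a pre-cART-era cohort (untreated follow-up 1989-1995).  Writes CSVs plus
# the ground-truth table under results/data/.

library(cd4slope)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# trajectories from the integrated-OU process with fast mean reversion:
# within-patient slopes wander around the population slope, the regime the
# outcome analysis should face
cart_cfg <- simulation_config(n_patients = 2000, seed = 20260101,
                              trajectory = "iou", alpha = 40, tau = 60)
cart <- simulate_cohort(cart_cfg)
write_cohort(cart$cohort, file.path(out, "cart_era"))
write.csv(cart$truth, file.path(out, "cart_era", "truth.csv"),
          row.names = FALSE)

pre_cfg <- simulation_config(n_patients = 1500, seed = 20260102,
                             era = "pre_cart", baseline_hazard = 0.10,
                             outcome = c(cd4_per100 = -0.30, log10_vl = 0,
                                         age_per10 = 0.30, prior_aids = 0.80,
                                         slope_per10 = -0.04))
pre <- simulate_cohort(pre_cfg)
write_cohort(pre$cohort, file.path(out, "pre_cart_era"))
write.csv(pre$truth, file.path(out, "pre_cart_era", "truth.csv"),
          row.names = FALSE)

w <- as.numeric(cart$cohort$patients$first_positive_date -
                  cart$cohort$patients$last_negative_date) / 365.25
cat(sprintf(paste0(
  "cART-era cohort: %d patients, %d CD4 measurements, %d initiated cART\n",
  "  median test window %.2f y (target 0.82)\n",
  "pre-cART cohort: %d patients, %d CD4 measurements\n"),
  nrow(cart$cohort$patients), nrow(cart$cohort$measurements),
  sum(!is.na(cart$cohort$patients$cart_date)), median(w),
  nrow(pre$cohort$patients), nrow(pre$cohort$measurements)))
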