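#!/usr/bin/env Rscript
# The prognostic question: does the pre-treatment CD4 slope predict AIDS or
# death after cART initiation, beyond the established baseline predictors?
# Stratified Cox models with discrimination of 5-year predictions, for all
# eligible patients and the >350 cells/ul subgroup.

library(cd4slope)

co <- read_cohort("results/data/cart_era/patients.csv",
                  "results/data/cart_era/measurements.csv")

for (sub in c("all", "cd4_gt_350")) {
  res <- run_main_analysis(co, analysis_config(
    subgroup = sub, out_dir = file.path("results", paste0("outcome_", sub))))
  b <- res$outcomes[[1]]
  cat(sprintf(paste0("\n[%s] n = %d, events = %d (%.0f%%), rate %.2f ",
                     "(%.2f-%.2f) /100 py\n",
                     "  unadjusted HR per +10 cells/ul/yr: %.2f (%.2f-%.2f), ",
                     "c = %.2f\n",
                     "  adjusted HR: %.2f (%.2f-%.2f), p = %.2f\n",
                     "  c index without/with slope: %.3f / %.3f\n",
                     "  events by slope quartile: %s\n"),
              sub, b$n, b$n_events, b$pct_events,
              b$event_rate$rate_per_100py, b$event_rate$ci[["lower"]],
              b$event_rate$ci[["upper"]],
              b$hr_unadjusted[["hr"]], b$hr_unadjusted[["lower"]],
              b$hr_unadjusted[["upper"]], b$c_slope_alone,
              b$hr_adjusted[["hr"]], b$hr_adjusted[["lower"]],
              b$hr_adjusted[["upper"]], b$hr_adjusted[["p"]],
              b$c_without_slope, b$c_with_slope,
              if (is.null(res$quartile_events)) "(slopes degenerate)"
              else paste(res$quartile_events$events, collapse = "/")))
}
cat("\nUnder the null generator the full-cohort adjusted slope HR hugs 1\n",
    "and the c index is unchanged by adding the slope: knowing how fast a\n",
    "patient declined to a given CD4 adds nothing to knowing where they\n",
    "are now.  The >350 subgroup is noisier: its single open-ended CD4\n",
    "stratum leaves residual baseline-CD4 confounding that the slope can\n",
    "partly absorb.\n")
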