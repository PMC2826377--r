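#!/usr/bin/env Rscript
# Compare the three per-patient CD4-slope estimators on the eligible
# cART-era cohort: two-point interpolation, per-patient least squares, and
# mixed-model BLUPs.  The substantive point is the shrinkage hierarchy —
# the fraction of apparent "rapid decliners" (>100 cells/ul/yr) collapses
# as estimators borrow more strength.

library(cd4slope)

co <- read_cohort("results/data/cart_era/patients.csv",
                  "results/data/cart_era/measurements.csv")
el <- apply_eligibility(co)
print(el$report)
write_eligibility_report(el$report, "results/eligibility.tsv")

rows <- lapply(c("two_point", "ols", "blup"), function(m) {
  sl <- estimate_slopes(el$cohort, method = m)
  s <- summarize_slopes(sl)
  write.csv(sl, sprintf("results/slopes_%s.csv", m), row.names = FALSE)
  data.frame(method = m, n = s$n, median = s$median,
             q1 = s$iqr[["q1"]], q3 = s$iqr[["q3"]],
             pct_rapid = 100 * s$prop_rapid)
})
tab <- do.call(rbind, rows)
write.table(tab, "results/slope_summaries.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tab, digits = 3)
cat("\nRapid-decliner prevalence falls two_point -> ols -> blup, the\n",
    "shrinkage ordering behind the published 54%/38%/13% spread.\n")
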