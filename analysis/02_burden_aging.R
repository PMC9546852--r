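#!/usr/bin/env Rscript
# 02: mutation burden vs age. Fits the donor random-intercept LMM on the
# untreated samples, builds the bootstrap expected-burden null, and scans
# every treated donor for excess SBS burden over the aging expectation.

suppressPackageStartupMessages(library(therasig))
set.seed(20220602L)

meta <- read_sample_meta("results/meta.tsv")
ctx <- read_context_matrix("results/context_SBS96.tsv")
bt <- burden_table(list(SBS96 = ctx), meta)

fit <- fit_aging_lmm(bt[!bt$treated, ])
print(fit)

null <- bootstrap_expected_burden(bt[!bt$treated, ], B = 1000)
scan <- excess_burden_scan(bt[bt$treated, ], null, mut_type = "SBS96")
print(scan)

write.table(bt, "results/burden_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(scan, "results/excess_burden_scan.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(c(
  sprintf("aging_rate_per_year\t%.6g", fit$slope),
  sprintf("aging_rate_ci95\t%.6g\t%.6g", fit$slope_ci95[1], fit$slope_ci95[2]),
  sprintf("intercept\t%.6g", fit$intercept),
  sprintf("donor_intercept_sd\t%.6g", fit$donor_intercept_sd),
  sprintf("residual_sd\t%.6g", fit$residual_sd)
), "results/aging_fit.tsv")
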