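#!/usr/bin/env Rscript
# 04: treatment mutagenesis. Platinum dose-response (SBS35 vs CAPOX
# cycles), the SBS:DBS coupling of platinum damage, the bimodal 5-FU
# signature (SBS17), and the aging rate recovered from exposures.
# Quantitative regressions use the NNLS exposures from driver 03.

suppressPackageStartupMessages(library(therasig))
set.seed(20220604L)

meta <- read_sample_meta("results/meta.tsv")
read_expo <- function(tag) {
  d <- read.delim(sprintf("results/exposures_%s.tsv", tag), check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE]); rownames(m) <- d$sample_id; m
}
fx <- read_expo("SBS96_nnls")
dx <- read_expo("DBS78_nnls")

tr <- meta$received_platinum
dr <- dose_response(fx[tr, "SBS35"], meta$capox_cycles[tr], meta$donor_id[tr])
print(dr)

treated <- meta$received_platinum | meta$received_5fu
rt <- sbs_dbs_ratio(fx[treated, "SBS35"], dx[treated, "DBS5"])
print(rt)

expo17 <- fx[meta$received_5fu, "SBS17"]
active <- expo17 >= 100
wil <- compare_groups(fx[meta$received_5fu, "SBS17"],
                      fx[!meta$received_5fu, "SBS17"], alternative = "greater")
cat(sprintf("5-FU: %d/%d exposed clones active (>= 100 SBS17), mean active %.0f, Wilcoxon p = %.3g\n",
            sum(active), length(active),
            if (any(active)) mean(expo17[active]) else 0, wil))

ar <- suppressWarnings(aging_rate(fx, meta))
print(ar)

writeLines(c(
  sprintf("platinum_sbs_per_cycle\t%.6g", dr$slope),
  sprintf("platinum_sbs_per_cycle_se\t%.6g", dr$slope_se),
  sprintf("platinum_dose_response_p\t%.6g", dr$p_value),
  sprintf("sbs_per_dbs_ratio\t%.6g", rt$ratio_sbs_per_dbs),
  sprintf("sbs_dbs_pearson_r\t%.6g", rt$pearson_r),
  sprintf("fivefu_active_fraction\t%.6g", mean(active)),
  sprintf("fivefu_mean_active_sbs\t%.6g",
          if (any(active)) mean(expo17[active]) else 0),
  sprintf("fivefu_wilcoxon_p\t%.6g", wil),
  sprintf("aging_rate_from_exposures\t%.6g", ar$slope)
), "results/treatment_effects.tsv")
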