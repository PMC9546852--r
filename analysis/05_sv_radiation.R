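#!/usr/bin/env Rscript
# 05: structural variation and the radiotherapy footprint. Classifies SVs
# into simple (DEL/DUP by length bin) and complex per-cluster events, and
# tests the coupling between the radiation indel signature (ID8) and
# [50 bp, 10 kb) simple structural deletions.

suppressPackageStartupMessages(library(therasig))
set.seed(20220605L)

meta <- read_sample_meta("results/meta.tsv")
sv <- read_sv("results/sv.tsv")
d <- read.delim("results/exposures_ID83_nnls.tsv", check.names = FALSE)
ix <- as.matrix(d[, -1, drop = FALSE]); rownames(ix) <- d$sample_id

prof <- classify_sv_profile(sv, sample_ids = meta$sample_id)
write.table(prof$simple, "results/sv_simple_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(prof$complex, "results/sv_complex_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

fp <- radiation_footprint(ix[, "ID8"], sv, meta)
cat(sprintf("ID8 vs structural deletions: r = %.3f (95%% CI %.3f-%.3f), fit slope %.3f del/ID8\n",
            fp$correlation$r, fp$correlation$ci[1], fp$correlation$ci[2],
            unname(coef(fp$fit)[2])))
cat(sprintf("ID8 radiotherapy-vs-not Wilcoxon p = %.3g\n", fp$wilcoxon_p))
cat(sprintf("low-microhomology fraction of radiation-window deletions: %.3f\n",
            fp$mh_low_fraction))

write.table(fp$per_sample, "results/radiation_per_sample.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(c(
  sprintf("id8_deletion_pearson_r\t%.6g", fp$correlation$r),
  sprintf("id8_deletion_r_ci95\t%.6g\t%.6g",
          fp$correlation$ci[1], fp$correlation$ci[2]),
  sprintf("deletions_per_id8\t%.6g", unname(coef(fp$fit)[2])),
  sprintf("id8_wilcoxon_p\t%.6g", fp$wilcoxon_p),
  sprintf("mh_low_fraction\t%.6g", fp$mh_low_fraction),
  sprintf("n_simple_sv\t%d", sum(prof$burden$sv_burden))
), "results/sv_radiation.tsv")
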