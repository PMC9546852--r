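#!/usr/bin/env Rscript
# 01: simulate the default (colon-like) cohort and persist the shared
# inputs for the downstream drivers: sample metadata, per-sample context
# matrices (SBS96/DBS78/ID83), SV records and the generator ground truth.
# Full per-mutation records are regenerated on demand (records = TRUE)
# rather than stored; the context matrices are the analysis substrate.

suppressPackageStartupMessages(library(therasig))

seed <- 20220601L
out <- "results"
dir.create(out, showWarnings = FALSE)

co <- simulate_cohort(seed = seed)
print(co)

write.table(co$meta, file.path(out, "meta.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(co$ground_truth, file.path(out, "ground_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(co$sv, file.path(out, "sv.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (mt in names(co$context)) {
  write_context_matrix(co$context[[mt]],
                       file.path(out, sprintf("context_%s.tsv", mt)))
}
cat("cohort seed:", seed, "\n")
cat("samples:", nrow(co$meta), " donors:",
    length(unique(co$meta$donor_id)), "\n")
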