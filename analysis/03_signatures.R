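#!/usr/bin/env Rscript
# 03: signature analysis. De novo NMF extraction with reference-guided
# rank selection, then strict refitting of the tissue signature set to
# every sample. Exposure matrices feed drivers 04 and 05.
#
# Quantitative exposures are also written from plain NNLS (max_delta = 0):
# the strict elimination step censors genuinely small exposures to zero,
# which biases downstream dose-response regression (see vignette).

suppressPackageStartupMessages(library(therasig))
set.seed(20220603L)

ctx_sbs <- read_context_matrix("results/context_SBS96.tsv")
ctx_dbs <- read_context_matrix("results/context_DBS78.tsv")
ctx_id  <- read_context_matrix("results/context_ID83.tsv")

ref_sbs <- merge_signatures(synthetic_reference_signatures("SBS96"),
                            c("SBS17a", "SBS17b"), "SBS17")
rk <- select_rank(ctx_sbs, ref_sbs, ranks = 2:6, n_restarts = 20)
cat("selected rank:", rk$rank, "\n")
write.table(rk$report, "results/rank_selection.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# 10% inclusion rule: optional reference signatures are retained only if
# their de novo counterpart reaches >= 10% relative contribution somewhere
ext <- rk$results[[as.character(rk$rank)]]
rep_k <- rk$report[rk$report$rank == rk$rank, ]
rel <- relative_contribution(ext$contributions)
matched <- !is.na(rep_k$best_reference) & rep_k$matched
contrib <- apply(rel[, matched, drop = FALSE], 2, max)
names(contrib) <- rep_k$best_reference[matched]
sbs_names <- signature_set("colon", "SBS96", denovo_contrib = contrib)
cat("SBS refit set:", paste(sbs_names, collapse = ", "), "\n")
sig_sbs <- ref_sbs[, sbs_names]
sig_dbs <- synthetic_reference_signatures("DBS78")[, signature_set("colon", "DBS78")]
sig_id  <- synthetic_reference_signatures("ID83")[, signature_set("colon", "ID83")]

write_exposures <- function(mat, sigs, tag, max_delta) {
  fx <- fit_exposures(mat, sigs, max_delta = max_delta)
  write.table(data.frame(sample_id = rownames(fx$exposures),
                         fx$exposures, check.names = FALSE),
              sprintf("results/exposures_%s.tsv", tag), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fx
}
fx_strict <- write_exposures(ctx_sbs, sig_sbs, "SBS96_strict", 0.004)
fx_nnls   <- write_exposures(ctx_sbs, sig_sbs, "SBS96_nnls", 0)
dx <- write_exposures(ctx_dbs, sig_dbs, "DBS78_nnls", 0)
ix <- write_exposures(ctx_id,  sig_id,  "ID83_nnls", 0)

cat(sprintf("mean reconstruction cosine (strict): %.4f\n",
            mean(fx_strict$cosine)))
cat(sprintf("mean reconstruction cosine (NNLS):   %.4f\n",
            mean(fx_nnls$cosine)))
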