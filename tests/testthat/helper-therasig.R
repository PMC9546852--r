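# Shared helpers for the therasig test suite.

# Complement/reverse-complement maps used by strand-symmetry checks,
# independent of the package's own revcomp().
.comp <- c(A = "T", C = "G", G = "C", T = "A")

# A minimal mutation-record data.frame in the shape read_mutations() emits.
make_records <- function(n, sample_id = "s1", chrom = "1", vaf = 0.5,
                         ref = "C", alt = "T", flank5 = "A", flank3 = "A") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = seq_len(n),
             ref = ref, alt = alt, mut_class = "SBS", vaf = vaf,
             flank5 = flank5, flank3 = flank3,
             local_seq = NA_character_, offset = NA_integer_,
             stringsAsFactors = FALSE)
}

# A minimal valid sample-metadata table.
make_meta <- function(sample_id, donor_id = sample_id, age = 50,
                      tissue = "colon", capox_cycles = 0,
                      received_platinum = FALSE, received_5fu = FALSE,
                      received_radiotherapy = FALSE) {
  data.frame(sample_id = sample_id, donor_id = donor_id, age = age,
             tissue = tissue, capox_cycles = capox_cycles,
             received_platinum = received_platinum,
             received_5fu = received_5fu,
             received_radiotherapy = received_radiotherapy,
             stringsAsFactors = FALSE)
}

# Burden rows for fit_aging_lmm-style inputs.
make_burden <- function(burden, age, donor_id) {
  data.frame(burden = burden, age = age, donor_id = donor_id,
             stringsAsFactors = FALSE)
}

# Two near-orthogonal toy signatures over 8 channels for NNLS oracles.
toy_signatures <- function() {
  sigA <- c(0.45, 0.45, 0.04, 0.02, 0.02, 0.01, 0.005, 0.005)
  sigB <- c(0.005, 0.005, 0.01, 0.02, 0.02, 0.04, 0.45, 0.45)
  m <- cbind(sigA = sigA, sigB = sigB)
  rownames(m) <- paste0("ch", 1:8)
  m
}

# Exhaustive grid-search least-squares oracle for exposures on a small
# signature matrix: returns the grid point minimising the residual sum of
# squares over [0, upper]^k with the given step.
grid_nnls_oracle <- function(catalog, signatures, upper, step = 1) {
  grid <- seq(0, upper, by = step)
  k <- ncol(signatures)
  stopifnot(k %in% c(2, 3))
  if (k == 2) {
    best <- c(NA, NA); best_rss <- Inf
    for (a in grid) {
      # vectorise the inner loop over b
      resid0 <- catalog - a * signatures[, 1]
      rec <- outer(signatures[, 2], grid)
      rss <- colSums((resid0 - rec)^2)
      j <- which.min(rss)
      if (rss[j] < best_rss) { best_rss <- rss[j]; best <- c(a, grid[j]) }
    }
    names(best) <- colnames(signatures)
    best
  } else {
    best <- c(NA, NA, NA); best_rss <- Inf
    for (a in grid) for (b in grid) {
      resid0 <- catalog - a * signatures[, 1] - b * signatures[, 2]
      rec <- outer(signatures[, 3], grid)
      rss <- colSums((resid0 - rec)^2)
      j <- which.min(rss)
      if (rss[j] < best_rss) { best_rss <- rss[j]; best <- c(a, b, grid[j]) }
    }
    names(best) <- colnames(signatures)
    best
  }
}

# Exact Wilcoxon rank-sum p by full enumeration of group assignments
# (one-sided, "greater": first group shifted above the second).
wilcox_enum_oracle <- function(a, b) {
  x <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(x), n)
  r <- rank(x)
  w_obs <- sum(r[seq_len(n)]) # rank sum of group a in the combined ranking
  w_all <- apply(idx, 2, function(i) sum(r[i]))
  mean(w_all >= w_obs)
}
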