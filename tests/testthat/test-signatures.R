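test_that("cosine similarity matches hand values and rejects zero vectors", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(cosine_similarity(c(1, 1), c(10, 10)), 1)  # scale invariance
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
})

test_that("cosine_matrix computes all column pairs", {
  A <- cbind(c(1, 0), c(1, 1))
  B <- cbind(c(0, 1))
  cm <- cosine_matrix(A, B)
  expect_equal(dim(cm), c(2L, 1L))
  expect_equal(cm[2, 1], 1 / sqrt(2))
})

test_that("NMF reconstructs an exact low-rank factorisation", {
  set.seed(21)
  S <- matrix(runif(96 * 2), 96, 2)
  S <- sweep(S, 2, colSums(S), "/")
  C <- matrix(runif(10 * 2, 50, 400), 10, 2)
  V <- C %*% t(S)  # samples x channels
  colnames(V) <- paste0("ch", 1:96); rownames(V) <- paste0("s", 1:10)
  res <- extract_denovo(V, rank = 2, n_restarts = 10, seed = 4)
  rec <- res$contributions %*% t(res$signatures)
  per_sample <- vapply(1:10, function(i) cosine_similarity(V[i, ], rec[i, ]),
                       numeric(1))
  expect_true(all(per_sample > 0.99))
  expect_true(all(abs(colSums(res$signatures) - 1) < 1e-8))
})

test_that("rank-1 NMF recovers the single generating profile", {
  set.seed(22)
  p <- runif(96); p <- p / sum(p)
  V <- t(sapply(1:8, function(i) rmultinom(1, 3000, p)[, 1]))
  colnames(V) <- paste0("ch", 1:96)
  res <- extract_denovo(V, rank = 1, n_restarts = 5, seed = 1)
  expect_gt(cosine_similarity(res$signatures[, 1], p), 0.99)
})

test_that("NMF is deterministic under a fixed seed and validates input", {
  set.seed(23)
  V <- matrix(rpois(5 * 20, 40), 5, 20)
  r1 <- extract_denovo(V, 2, n_restarts = 3, seed = 7)
  r2 <- extract_denovo(V, 2, n_restarts = 3, seed = 7)
  expect_identical(r1$signatures, r2$signatures)
  expect_identical(r1$contributions, r2$contributions)
  expect_error(extract_denovo(V, 5), "rank")
  expect_error(extract_denovo(matrix(0, 4, 8), 2), "zero")
  expect_error(extract_denovo(-V, 2), "non-negative")
})

test_that("select_rank finds the generating rank on a 2-signature cohort", {
  set.seed(24)
  ref <- synthetic_reference_signatures("SBS96")
  # samples with independently varying exposures on two reference signatures
  expo <- cbind(SBS1 = runif(12, 100, 2000), SBS35 = runif(12, 100, 2000))
  V <- t(sapply(1:12, function(i) {
    rmultinom(1, 3000, ref[, "SBS1"] * expo[i, 1] / sum(expo[i, ]) +
                ref[, "SBS35"] * expo[i, 2] / sum(expo[i, ]))[, 1]
  }))
  colnames(V) <- rownames(ref)
  sel <- select_rank(V, ref, ranks = 1:4, n_restarts = 10, seed = 5)
  expect_identical(sel$rank, 2L)
  rep2 <- sel$report[sel$report$rank == 2, ]
  expect_setequal(rep2$best_reference, c("SBS1", "SBS35"))
  expect_true(all(rep2$cosine >= 0.8))
})

test_that("min_cosine = 0 makes the rank constraint vacuous", {
  set.seed(25)
  V <- matrix(rpois(6 * 96, 30), 6, 96)
  colnames(V) <- rownames(synthetic_reference_signatures("SBS96"))
  sel <- select_rank(V, synthetic_reference_signatures("SBS96"),
                     ranks = 1:3, min_cosine = 0, n_restarts = 3, seed = 6)
  expect_identical(sel$rank, 3L)
})

test_that("merge_signatures merges disjoint profiles to their renormalised sum", {
  m <- cbind(a = c(1, 0, 0, 0), b = c(0, 1, 0, 0), c = c(0, 0, 0.5, 0.5))
  rownames(m) <- paste0("ch", 1:4)
  merged <- merge_signatures(m, c("a", "b"), "ab")
  expect_identical(colnames(merged), c("ab", "c"))
  expect_equal(unname(merged[, "ab"]), c(0.5, 0.5, 0, 0))
  # merging identical columns leaves the profile unchanged
  m2 <- cbind(x = c(0.25, 0.75), y = c(0.25, 0.75))
  expect_equal(unname(merge_signatures(m2, c("x", "y"), "xy")[, 1]),
               c(0.25, 0.75))
  expect_error(merge_signatures(m, c("a", "zzz"), "n"), "zzz|unknown")
})

test_that("refit_strict recovers exact single-signature membership", {
  sigs <- toy_signatures()
  fit <- refit_strict(100 * sigs[, "sigA"], sigs)
  expect_equal(unname(fit$exposures["sigA"]), 100, tolerance = 1e-6)
  expect_equal(unname(fit$exposures["sigB"]), 0, tolerance = 1e-6)
  expect_gt(fit$reconstructed_cosine, 0.9999)
})

test_that("refit_strict is scale-equivariant and handles all-zero catalogs", {
  sigs <- toy_signatures()
  catalog <- 300 * sigs[, 1] + 200 * sigs[, 2]
  f1 <- refit_strict(catalog, sigs)
  f2 <- refit_strict(2 * catalog, sigs)
  expect_equal(unname(f2$exposures), unname(2 * f1$exposures), tolerance = 1e-6)
  f0 <- refit_strict(numeric(8) + 0, sigs)
  expect_true(all(f0$exposures == 0))
  expect_true(f0$all_zero)
  expect_true(is.na(f0$reconstructed_cosine))
})

test_that("strict elimination zeroes signatures that explain nothing", {
  set.seed(26)
  ref <- synthetic_reference_signatures("SBS96")
  sigs <- ref[, c("SBS1", "SBS5", "SBS35")]
  # catalog simulated without platinum
  catalog <- rmultinom(1, 4000, 0.4 * sigs[, "SBS1"] + 0.6 * sigs[, "SBS5"])[, 1]
  fit <- refit_strict(catalog, sigs)
  expect_identical(unname(fit$exposures["SBS35"]), 0)
  expect_true("SBS35" %in% fit$removed)
})

test_that("fit_exposures maps refit over samples and conserves shape", {
  set.seed(27)
  sigs <- toy_signatures()
  truth <- rbind(c(300, 200), c(50, 400))
  V <- truth %*% t(sigs)
  rownames(V) <- c("s1", "s2")
  fx <- fit_exposures(V, sigs)
  expect_identical(dim(fx$exposures), c(2L, 2L))
  expect_equal(unname(fx$exposures), unname(truth), tolerance = 1e-4)
  expect_true(all(fx$cosine > 0.999))
})

test_that("relative_contribution divides by per-sample burden", {
  expos <- rbind(s1 = c(a = 30, b = 70), s2 = c(a = 0, b = 50))
  rc <- relative_contribution(expos, burdens = c(s1 = 100, s2 = 50))
  expect_equal(unname(rc["s1", ]), c(0.3, 0.7))
  expect_equal(unname(rc["s2", "b"]), 1)
})

test_that("signature_set applies the 10% de novo inclusion rule", {
  base <- signature_set("colon", "SBS96")
  expect_length(base, 6)
  expect_setequal(base, c("SBS1", "SBS5", "SBS18", "SBS17", "SBS35", "SBS88"))
  expect_length(signature_set("colon", "ID83"), 5)
  # SBS88 below 10% in every sample -> excluded; treatment sigs retained
  contrib <- rbind(s1 = c(SBS88 = 0.05), s2 = c(SBS88 = 0.09))
  reduced <- signature_set("colon", "SBS96", denovo_contrib = contrib)
  expect_false("SBS88" %in% reduced)
  expect_true(all(c("SBS17", "SBS35") %in% reduced))
  # at 10% in one sample -> included
  contrib2 <- rbind(s1 = c(SBS88 = 0.12), s2 = c(SBS88 = 0.01))
  expect_true("SBS88" %in% signature_set("colon", "SBS96", denovo_contrib = contrib2))
  # liver set omits colibactin signatures and, untreated, treatment signatures
  expect_false("SBS88" %in% signature_set("liver", "SBS96"))
  expect_false("SBS35" %in% signature_set("liver", "SBS96", treated = FALSE))
})

test_that("synthetic reference signatures are valid near-orthogonal profiles", {
  for (mt in c("SBS96", "DBS78", "ID83")) {
    ref <- synthetic_reference_signatures(mt)
    expect_true(all(ref >= 0))
    expect_true(all(abs(colSums(ref) - 1) < 1e-8))
    cm <- cosine_matrix(ref, ref)
    off <- cm[upper.tri(cm)]
    # the flat clock-like profile overlaps every block profile by
    # construction (cosine up to ~sqrt(block/channels)), hence 0.5
    expect_true(all(off < 0.5), info = mt)
  }
  expect_identical(nrow(synthetic_reference_signatures("SBS96")), 96L)
  expect_identical(nrow(synthetic_reference_signatures("DBS78")), 78L)
  expect_identical(nrow(synthetic_reference_signatures("ID83")), 83L)
})
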