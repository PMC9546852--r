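test_that("burden_table joins burdens with metadata and flags treatment", {
  ctx <- matrix(1L, 2, 96, dimnames = list(c("a", "b"), sbs96_channels()))
  meta <- make_meta(c("a", "b"), donor_id = c("d1", "d2"), age = c(30, 60),
                    received_platinum = c(FALSE, TRUE))
  bt <- burden_table(list(SBS96 = ctx), meta)
  expect_identical(bt$burden, c(96L, 96L))
  expect_identical(bt$treated, c(FALSE, TRUE))
  expect_identical(bt$mut_type, c("SBS96", "SBS96"))
})

test_that("noise-free linear burdens give the exact OLS slope", {
  d <- make_burden(40 * (20:29), 20:29, paste0("d", 1:10))
  fit <- suppressWarnings(fit_aging_lmm(d))
  expect_equal(fit$slope, 40, tolerance = 1e-8)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_identical(fit$donor_intercept_sd, 0)
})

test_that("constant burdens give slope 0 with CI spanning (or touching) 0", {
  d <- make_burden(rep(500, 9), rep(c(20, 40, 60), each = 3),
                   rep(c("d1", "d2", "d3"), each = 3))
  fit <- suppressWarnings(fit_aging_lmm(d))
  expect_equal(fit$slope, 0, tolerance = 1e-8)
  expect_true(fit$slope_ci95[1] <= 0 && fit$slope_ci95[2] >= 0)
})

test_that("aging LMM recovers the generating slope (REML, donor intercepts)", {
  set.seed(101)
  ages <- rep(seq(15, 75, length.out = 12), each = 3)
  donors <- rep(paste0("d", 1:12), each = 3)
  u <- rnorm(12, 0, 100)[rep(1:12, each = 3)]
  d <- make_burden(round(100 + 43 * ages + u + rnorm(36, 0, 150)), ages, donors)
  fit <- fit_aging_lmm(d)
  expect_identical(fit$method, "lme_reml")
  expect_true(fit$slope_ci95[1] < 43 && 43 < fit$slope_ci95[2])
  expect_identical(fit$n_donors, 12L)
})

test_that("few-donor designs warn", {
  d <- make_burden(c(100, 200, 300, 400), c(20, 20, 40, 40),
                   c("d1", "d1", "d2", "d2"))
  expect_warning(fit_aging_lmm(d), "donors")
})

test_that("bootstrap null is reproducible under a fixed seed", {
  set.seed(1)
  d <- make_burden(round(100 + 43 * rep(c(20, 40, 60, 80), each = 3) +
                           rnorm(12, 0, 100)),
                   rep(c(20, 40, 60, 80), each = 3),
                   rep(paste0("d", 1:4), each = 3))
  n1 <- suppressWarnings(bootstrap_expected_burden(d, B = 5, seed = 9))
  n2 <- suppressWarnings(bootstrap_expected_burden(d, B = 5, seed = 9))
  expect_identical(n1$expected, n2$expected)
  expect_identical(dim(n1$expected), c(5L, 76L))
  expect_identical(colnames(n1$expected), as.character(5:80))
})

test_that("frac = 1 on noise-free data reproduces the full fit in every row", {
  d <- make_burden(40 * (20:27), 20:27, paste0("d", 1:8))
  null <- suppressWarnings(bootstrap_expected_burden(d, B = 4, frac = 1, seed = 2))
  expect_equal(unname(null$expected[1, ]), 40 * (5:80), tolerance = 1e-6)
  expect_true(all(apply(null$expected, 2, function(col) diff(range(col)) < 1e-6)))
})

test_that("bootstrap column means track the full-data fixed-effect line", {
  set.seed(77)
  ages <- rep(seq(10, 78, length.out = 10), each = 3)
  donors <- rep(paste0("d", 1:10), each = 3)
  u <- rnorm(10, 0, 100)[rep(1:10, each = 3)]
  d <- make_burden(round(100 + 43 * ages + u + rnorm(30, 0, 150)), ages, donors)
  full <- fit_aging_lmm(d)
  null <- suppressWarnings(bootstrap_expected_burden(d, B = 300, seed = 5))
  for (a in c(20, 50, 80)) {
    col <- null$expected[, as.character(a)]
    pred <- full$intercept + full$slope * a
    expect_lt(abs(mean(col) - pred), 2 * sd(col))
  }
})

test_that("excess test boundary p-values follow the add-one rule", {
  null <- structure(list(ages = 5:80,
                         expected = matrix(rep(100, 76 * 9), 9, 76,
                                           dimnames = list(NULL, as.character(5:80))),
                         B = 9L, frac = 0.7, seed = NULL, n_dropped = 0L),
                    class = "aging_null")
  hi <- excess_burden_test(200, 40, null)   # above every expectation
  lo <- excess_burden_test(50, 40, null)    # below every expectation
  expect_equal(hi$empirical_p, 1 / 10)
  expect_equal(lo$empirical_p, 10 / 10)
  expect_true(hi$significant == FALSE)      # 0.1 is not < 0.01 with B = 9
  expect_equal(hi$excess, 100)
})

test_that("empirical p is monotone non-increasing in the observed mean", {
  set.seed(8)
  null <- structure(list(ages = 5:80,
                         expected = matrix(rnorm(76 * 50, 100, 10), 50, 76,
                                           dimnames = list(NULL, as.character(5:80))),
                         B = 50L, frac = 0.7, seed = NULL, n_dropped = 0L),
                    class = "aging_null")
  ps <- vapply(seq(60, 140, by = 5),
               function(m) excess_burden_test(m, 30, null)$empirical_p,
               numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("ages outside the 5-80 grid are refused", {
  null <- structure(list(ages = 5:80,
                         expected = matrix(100, 2, 76,
                                           dimnames = list(NULL, as.character(5:80))),
                         B = 2L, frac = 0.7, seed = NULL, n_dropped = 0L),
                    class = "aging_null")
  expect_error(excess_burden_test(100, 92, null), "grid")
  expect_silent(excess_burden_test(100, 80.4, null))  # rounds into the grid
})

test_that("excess_burden_scan tests each donor once and sorts by p", {
  set.seed(2)
  null <- structure(list(ages = 5:80,
                         expected = matrix(rnorm(76 * 20, 1000, 50), 20, 76,
                                           dimnames = list(NULL, as.character(5:80))),
                         B = 20L, frac = 0.7, seed = NULL, n_dropped = 0L),
                    class = "aging_null")
  bt <- data.frame(donor_id = rep(c("t1", "t2"), each = 3),
                   age = rep(c(40, 60), each = 3),
                   burden = c(2000, 2100, 1900, 900, 950, 1000))
  res <- excess_burden_scan(bt, null, mut_type = "SBS96")
  expect_identical(nrow(res), 2L)
  expect_true(!is.unsorted(res$empirical_p))
  expect_identical(res$donor_id[1], "t1")
})
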