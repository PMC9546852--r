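#' Assemble a long-format mutation burden table
#'
#' One row per sample x mutation type, joining per-sample burdens (context
#' matrix row sums: the autosomal, clonal-filtered count) with the clinical
#' metadata. A sample is `treated` if it received platinum, 5-FU or
#' radiotherapy.
#'
#' @param context Named list of context matrices, e.g.
#'   `list(SBS96 = ..., DBS78 = ..., ID83 = ...)`; names are used as the
#'   `mut_type`.
#' @param meta Sample metadata table.
#' @return A data.frame with columns `sample_id`, `donor_id`, `age`,
#'   `tissue`, `treated`, `mut_type`, `burden`.
#' @export
burden_table <- function(context, meta) {
  validate_sample_meta(meta)
  if (is.matrix(context)) context <- list(burden = context)
  out <- do.call(rbind, lapply(names(context), function(mt) {
    m <- context[[mt]]
    i <- match(rownames(m), meta$sample_id)
    if (anyNA(i)) stop("context matrix rows not in metadata", call. = FALSE)
    data.frame(sample_id = rownames(m), donor_id = meta$donor_id[i],
               age = meta$age[i], tissue = meta$tissue[i],
               treated = meta$received_platinum[i] | meta$received_5fu[i] |
                 meta$received_radiotherapy[i],
               mut_type = mt, burden = as.integer(rowSums(m)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.lmm_fallback <- function(d) {
  fit <- stats::lm(burden ~ age, data = d)
  sm <- summary(fit)
  ci <- suppressWarnings(stats::confint(fit))
  slope <- unname(stats::coef(fit)[["age"]])
  ci_slope <- ci["age", ]
  if (anyNA(ci_slope)) ci_slope <- c(slope, slope)  # exact (zero-residual) fit
  structure(list(
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    slope = slope,
    slope_se = unname(sm$coefficients["age", "Std. Error"]),
    slope_ci95 = unname(ci_slope),
    donor_intercept_sd = 0,
    residual_sd = sm$sigma,
    n_samples = nrow(d),
    n_donors = length(unique(d$donor_id)),
    method = "ols_fallback"
  ), class = "aging_fit")
}

#' Fit the linear mixed-effects aging model for mutation burden
#'
#' Burden is regressed on age with a fixed intercept and slope and a
#' donor-level random intercept (REML), correcting for multiple clones per
#' donor. The 95% CI on the slope is Wald-type. When the random-effect
#' structure is degenerate (a single clone per donor, or a noise-free exact
#' fit) the model reduces to ordinary least squares with a warning and a
#' donor-intercept SD of 0.
#'
#' @param burden A data.frame with columns `burden`, `age`, `donor_id`
#'   (e.g. one mutation type's rows of [burden_table()]).
#' @param mut_type Optional filter applied to a `mut_type` column.
#' @return An object of class `aging_fit`: intercept, slope
#'   (mutations/year), `slope_se`, `slope_ci95`, `donor_intercept_sd`,
#'   `residual_sd`, `n_samples`, `n_donors`.
#' @export
fit_aging_lmm <- function(burden, mut_type = NULL) {
  d <- burden
  if (!is.null(mut_type) && "mut_type" %in% names(d)) d <- d[d$mut_type == mut_type, ]
  stopifnot(all(c("burden", "age", "donor_id") %in% names(d)))
  d <- d[, c("burden", "age", "donor_id")]
  n_donors <- length(unique(d$donor_id))
  if (n_donors < 3) warning("fewer than 3 donors; aging fit is unreliable", call. = FALSE)
  multi <- sum(table(d$donor_id) > 1)
  if (multi < 2) warning("fewer than 2 donors with multiple clones; donor variance weakly identified", call. = FALSE)
  fit <- tryCatch(
    nlme::lme(burden ~ age, random = ~ 1 | donor_id, data = d, method = "REML"),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    # Degenerate designs (one clone per donor, zero residual variance) are
    # legitimate inputs with an exact OLS answer; anything else is a real
    # convergence failure.
    ols <- stats::lm(burden ~ age, data = d)
    degenerate <- multi == 0 || summary(ols)$sigma < 1e-8 ||
      stats::var(d$burden) == 0
    if (degenerate) {
      warning("random-effect variance not estimable; falling back to OLS (donor SD reported as 0)",
              call. = FALSE)
      return(.lmm_fallback(d))
    }
    stop("aging LMM did not converge: ", conditionMessage(fit), call. = FALSE)
  }
  fe <- nlme::fixef(fit)
  # nlme warns (NaN p-value) when the between-group DF is 0; the CI below
  # uses its own df fallback, so the internal p-value is not consumed
  tt <- suppressWarnings(summary(fit)$tTable)
  se <- tt["age", "Std.Error"]
  df <- tt["age", "DF"]
  if (!is.finite(df) || df < 1) df <- max(1L, nrow(d) - 2L)
  slope <- unname(fe[["age"]])
  ci <- slope + c(-1, 1) * stats::qt(0.975, df) * se
  vc <- suppressWarnings(nlme::VarCorr(fit))
  donor_sd <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
  resid_sd <- suppressWarnings(as.numeric(vc["Residual", "StdDev"]))
  if (is.na(donor_sd)) { warning("singular random-effect variance; reporting 0", call. = FALSE); donor_sd <- 0 }
  structure(list(
    intercept = unname(fe[["(Intercept)"]]),
    slope = slope, slope_se = unname(se), slope_ci95 = ci,
    donor_intercept_sd = donor_sd, residual_sd = resid_sd,
    n_samples = nrow(d), n_donors = n_donors,
    method = "lme_reml"
  ), class = "aging_fit")
}

#' @export
print.aging_fit <- function(x, ...) {
  cat(sprintf("Aging model (%s): burden = %.1f + %.2f * age\n", x$method, x$intercept, x$slope))
  cat(sprintf("  slope 95%% CI [%.2f, %.2f] mutations/year; donor SD %.1f, residual SD %.1f\n",
              x$slope_ci95[1], x$slope_ci95[2], x$donor_intercept_sd, x$residual_sd))
  cat(sprintf("  n = %d samples, %d donors\n", x$n_samples, x$n_donors))
  invisible(x)
}

#' Bootstrap null distribution of expected burden across ages
#'
#' Repeatedly subsamples a fraction of the untreated samples (without
#' replacement, sampling unit = sample), refits the aging LMM, and records
#' the fixed-effect prediction (intercept + slope x age) at every integer
#' age of the grid. Iterations whose fit fails are dropped and counted.
#'
#' @param burden Untreated burden table rows (one mutation type).
#' @param B Number of bootstrap iterations.
#' @param frac Subsampling fraction in (0, 1].
#' @param ages Integer age grid (default 5:80).
#' @param seed Optional RNG seed for reproducibility.
#' @return An object of class `aging_null`: `ages`, `expected` (B_kept x
#'   length(ages) matrix), `B`, `frac`, `seed`, `n_dropped`.
#' @export
bootstrap_expected_burden <- function(burden, B = 10000, frac = 0.70,
                                      ages = 5:80, seed = NULL) {
  stopifnot(frac > 0, frac <= 1, nrow(burden) > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(burden)
  m <- max(2L, floor(frac * n))
  rows <- vector("list", B)
  dropped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, m)
    fit <- tryCatch(
      suppressWarnings(fit_aging_lmm(burden[idx, , drop = FALSE])),
      error = function(e) NULL
    )
    if (is.null(fit)) { dropped <- dropped + 1L; next }
    rows[[b]] <- fit$intercept + fit$slope * ages
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("all bootstrap iterations failed to converge", call. = FALSE)
  if (dropped > 0.10 * B) {
    warning(sprintf("%d/%d bootstrap iterations dropped (non-convergence)", dropped, B),
            call. = FALSE)
  }
  expected <- do.call(rbind, rows)
  colnames(expected) <- as.character(ages)
  structure(list(ages = ages, expected = expected, B = nrow(expected),
                 frac = frac, seed = seed, n_dropped = dropped),
            class = "aging_null")
}

#' @export
print.aging_null <- function(x, ...) {
  cat(sprintf("Bootstrap aging null: %d retained fits (%d dropped), %.0f%% subsampling, ages %d-%d\n",
              x$B, x$n_dropped, 100 * x$frac, min(x$ages), max(x$ages)))
  invisible(x)
}

#' Test one treated donor for excess mutation burden
#'
#' Compares the donor's mean clone burden with the bootstrap distribution
#' of expected burdens at the donor's (rounded) age. The one-sided
#' empirical p uses add-one smoothing:
#' p = (1 + #\{b : expected_b >= observed mean\}) / (B + 1),
#' so p is never exactly 0; significance is called at p < 0.01.
#'
#' @param burdens Numeric vector of the donor's per-clone burdens.
#' @param age Donor age in years; must round into the null's age grid.
#' @param null An `aging_null` from [bootstrap_expected_burden()].
#' @param donor_id,mut_type Optional labels carried into the result.
#' @return A one-row data.frame: `donor_id`, `mut_type`, `age`,
#'   `observed_mean`, `expected_mean`, `excess`, `empirical_p`, `significant`.
#' @export
excess_burden_test <- function(burdens, age, null, donor_id = NA_character_,
                               mut_type = NA_character_) {
  stopifnot(inherits(null, "aging_null"), length(burdens) >= 1)
  a <- as.integer(round(age))
  j <- match(a, null$ages)
  if (is.na(j)) {
    stop(sprintf("age %d outside the null grid [%d, %d]; no extrapolation",
                 a, min(null$ages), max(null$ages)), call. = FALSE)
  }
  obs <- mean(burdens)
  col <- null$expected[, j]
  p <- (1 + sum(col >= obs)) / (nrow(null$expected) + 1)
  data.frame(donor_id = donor_id, mut_type = mut_type, age = age,
             observed_mean = obs, expected_mean = mean(col),
             excess = obs - mean(col), empirical_p = p,
             significant = p < 0.01, stringsAsFactors = FALSE)
}

#' Excess-burden scan over all treated donors
#'
#' @param burden Burden table rows for treated samples of one mutation type
#'   (columns `donor_id`, `age`, `burden`).
#' @param null An `aging_null` for the same mutation type.
#' @param mut_type Optional label.
#' @return A data.frame with one row per donor, as [excess_burden_test()].
#' @export
excess_burden_scan <- function(burden, null, mut_type = NA_character_) {
  out <- lapply(split(burden, burden$donor_id), function(d) {
    excess_burden_test(d$burden, d$age[1], null, donor_id = d$donor_id[1],
                       mut_type = mut_type)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$empirical_p), ]
}
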