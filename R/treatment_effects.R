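#' Per-cycle treatment dose-response
#'
#' Regresses a per-sample signature exposure on the number of treatment
#' cycles in a linear mixed-effects model with a donor-level random
#' intercept (REML). The slope is the additional mutations per cycle; the
#' two-tailed p uses a t statistic with n_samples - 2 degrees of freedom.
#' Degenerate designs (one clone per donor with noise-free exposures) fall
#' back to ordinary least squares with a warning.
#'
#' @param exposure Numeric vector of per-sample exposures.
#' @param cycles Numeric vector of treatment cycle counts (>= 2 distinct
#'   values required).
#' @param donor_id Donor grouping factor.
#' @return A list of class `dose_response_fit`: `slope`, `slope_se`,
#'   `p_value`, `intercept`, `n_samples`, `n_donors`.
#' @export
dose_response <- function(exposure, cycles, donor_id) {
  stopifnot(length(exposure) == length(cycles), length(cycles) == length(donor_id))
  if (length(unique(cycles)) < 2) stop("no dose contrast: a single cycle value", call. = FALSE)
  d <- data.frame(exposure = exposure, cycles = cycles, donor_id = donor_id)
  fit <- tryCatch(
    nlme::lme(exposure ~ cycles, random = ~ 1 | donor_id, data = d, method = "REML"),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    warning("mixed model degenerate; falling back to OLS (donor variance 0)", call. = FALSE)
    ols <- stats::lm(exposure ~ cycles, data = d)
    sm <- summary(ols)$coefficients
    slope <- unname(sm["cycles", "Estimate"]); se <- unname(sm["cycles", "Std. Error"])
  } else {
    tt <- summary(fit)$tTable
    slope <- unname(tt["cycles", "Value"]); se <- unname(tt["cycles", "Std.Error"])
  }
  df <- length(exposure) - 2L
  tval <- if (se > 0) slope / se else Inf * sign(slope)
  p <- if (is.finite(tval)) 2 * stats::pt(-abs(tval), df) else 0
  if (slope == 0 && se == 0) p <- 1
  structure(list(slope = slope, slope_se = se, p_value = p,
                 n_samples = length(exposure),
                 n_donors = length(unique(donor_id))),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Dose-response: %.1f (+/- %.1f SE) mutations per cycle, p = %.3g (n = %d samples, %d donors)\n",
              x$slope, x$slope_se, x$p_value, x$n_samples, x$n_donors))
  invisible(x)
}

#' SBS:DBS coupling of platinum mutations
#'
#' Ordinary least squares of per-sample DBS exposure on SBS exposure (with
#' intercept). The mutation ratio is reported as SBS per DBS, i.e. the
#' reciprocal of the fitted slope, with a delta-method standard error.
#'
#' @param sbs,dbs Paired per-sample exposure vectors (n >= 3).
#' @return A list of class `ratio_fit`: `slope_dbs_per_sbs`, `slope_se`,
#'   `ratio_sbs_per_dbs`, `ratio_se`, `pearson_r`, `n`, `reliable` (FALSE
#'   when the slope CI spans 0).
#' @export
sbs_dbs_ratio <- function(sbs, dbs) {
  stopifnot(length(sbs) == length(dbs), length(sbs) >= 3)
  if (stats::var(sbs) == 0) stop("zero variance in SBS exposures", call. = FALSE)
  fit <- stats::lm(dbs ~ sbs)
  # noise-free proportional data is a legitimate input; lm's "essentially
  # perfect fit" warning is expected there
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(sm["sbs", "Estimate"]); se <- unname(sm["sbs", "Std. Error"])
  ci <- slope + c(-1, 1) * stats::qt(0.975, length(sbs) - 2) * se
  reliable <- slope > 0 && (ci[1] > 0)
  ratio <- if (slope > 0) 1 / slope else NA_real_
  ratio_se <- if (slope > 0) se / slope^2 else NA_real_
  r <- if (stats::var(dbs) > 0) stats::cor(sbs, dbs) else NA_real_
  structure(list(slope_dbs_per_sbs = slope, slope_se = se,
                 ratio_sbs_per_dbs = ratio, ratio_se = ratio_se,
                 pearson_r = r, n = length(sbs), reliable = reliable),
            class = "ratio_fit")
}

#' @export
print.ratio_fit <- function(x, ...) {
  cat(sprintf("1 DBS per %.1f (+/- %.1f SE) SBS mutations (slope %.4f, Pearson r = %.2f, n = %d)%s\n",
              x$ratio_sbs_per_dbs, x$ratio_se, x$slope_dbs_per_sbs,
              x$pearson_r, x$n, if (!x$reliable) " [unreliable: slope CI spans 0]" else ""))
  invisible(x)
}

#' Age-related mutation rate from aging-signature exposures
#'
#' Sums the aging-signature exposures per sample and fits the aging LMM,
#' giving the annual clock-like mutation rate for a (sub)cohort.
#'
#' @param exposures Samples x signatures exposure matrix.
#' @param meta Sample metadata (must cover all exposure rows).
#' @param aging_signatures Columns to sum (default SBS1 + SBS5 + SBS18).
#' @return An `aging_fit` (see [fit_aging_lmm()]).
#' @export
aging_rate <- function(exposures, meta, aging_signatures = c("SBS1", "SBS5", "SBS18")) {
  use <- intersect(aging_signatures, colnames(exposures))
  if (!length(use)) stop("none of the aging signatures present in exposures", call. = FALSE)
  i <- match(rownames(exposures), meta$sample_id)
  if (anyNA(i)) stop("exposure rows missing from metadata", call. = FALSE)
  d <- data.frame(burden = rowSums(exposures[, use, drop = FALSE]),
                  age = meta$age[i], donor_id = meta$donor_id[i])
  fit_aging_lmm(d)
}

#' One-sided Wilcoxon rank-sum comparison of two groups
#'
#' Exact enumeration when the smaller group has at most 10 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param values_a,values_b Numeric vectors.
#' @param alternative `"greater"` (default; a shifted above b), `"less"` or
#'   `"two.sided"`.
#' @return The p value.
#' @export
compare_groups <- function(values_a, values_b, alternative = "greater") {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- min(length(values_a), length(values_b)) <= 10 && !ties
  suppressWarnings(stats::wilcox.test(values_a, values_b, alternative = alternative,
                                      exact = exact, correct = !exact)$p.value)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors (n >= 3, finite variance).
#' @return A list: `r`, `p` (two-sided), `ci` (95%, Fisher z), `n`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       ci = as.numeric(ct$conf.int), n = length(x))
}
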