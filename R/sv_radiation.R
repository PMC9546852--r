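SV_COMPLEX_TYPES <- c("COMPLEX_SV", "COMPLEX_DEL", "RECIP_INV", "RECIP_TRANS")

#' Structural variant length bins
#'
#' Half-open bins `[low, high)`. The reported aggregates use 1-10 kb,
#' 10-100 kb, 100 kb-1 Mb, 1-10 Mb and >=10 Mb; a sub-kilobase bin
#' [50 bp, 1 kb) is added because radiation-associated simple deletions
#' concentrate between 50 bp and 10 kb.
#'
#' @return Named numeric vector of bin lower edges; names are bin labels.
#' @export
sv_length_bins <- function() {
  stats::setNames(c(50, 1e3, 1e4, 1e5, 1e6, 1e7),
                  c("50bp-1kb", "1kb-10kb", "10kb-100kb", "100kb-1Mb",
                    "1Mb-10Mb", ">=10Mb"))
}

.sv_bin <- function(len) {
  edges <- c(unname(sv_length_bins()), Inf)
  labs <- names(sv_length_bins())
  cut(len, breaks = edges, labels = labs, right = FALSE)
}

#' Classify structural variants into simple and complex profiles
#'
#' Simple events are single-breakpoint clusters (cluster_size 1) resolved
#' as DEL or DUP, stratified by half-open length bin; everything in a
#' multi-breakpoint cluster, or resolved as a complex/reciprocal type, is a
#' complex event. Complex events are counted per cluster (one cluster = one
#' event): via distinct `cluster_id` when present, otherwise each record
#' contributes 1/cluster_size. SV load (`sv_burden`) is the number of
#' simple events.
#'
#' @param sv SV records data.frame (columns `sample_id`, `sv_type`,
#'   `length`, `cluster_size`, `resolved_type`, optionally `cluster_id`).
#' @param sample_ids Optional sample universe (defaults to the samples
#'   present); samples without SVs get zero rows.
#' @return A list: `simple` (sample_id x sv_type x length_bin counts,
#'   long), `complex` (sample_id x category counts, long), `burden`
#'   (sample_id, sv_burden).
#' @export
classify_sv_profile <- function(sv, sample_ids = NULL) {
  sample_ids <- sample_ids %||% unique(sv$sample_id)
  sv$resolved_type <- toupper(as.character(sv$resolved_type))
  sv$length <- as.numeric(sv$length)  # an all-NA column parses as logical
  is_complex <- sv$cluster_size > 1 | sv$resolved_type %in% SV_COMPLEX_TYPES
  simple <- sv[!is_complex & sv$resolved_type %in% c("DEL", "DUP"), , drop = FALSE]
  if (nrow(simple)) {
    bad <- is.na(simple$length) | simple$length < 0
    if (any(bad)) {
      stop("missing or negative length on simple DEL/DUP record (sample ",
           simple$sample_id[bad][1], ")", call. = FALSE)
    }
  }
  bins <- names(sv_length_bins())
  simple_counts <- as.data.frame(table(
    sample_id = factor(simple$sample_id, levels = sample_ids),
    sv_type = factor(simple$resolved_type, levels = c("DEL", "DUP")),
    length_bin = .sv_bin(simple$length) |> factor(levels = bins)),
    responseName = "count", stringsAsFactors = FALSE)
  cx <- sv[is_complex, , drop = FALSE]
  if (nrow(cx)) {
    cat_of <- ifelse(cx$resolved_type %in% SV_COMPLEX_TYPES, cx$resolved_type, "COMPLEX_SV")
    if ("cluster_id" %in% names(cx) && !anyNA(cx$cluster_id)) {
      u <- !duplicated(paste(cx$sample_id, cx$cluster_id))
      w <- as.numeric(u)
    } else {
      w <- 1 / pmax(cx$cluster_size, 1)
    }
    complex_counts <- stats::aggregate(
      w, by = list(sample_id = factor(cx$sample_id, levels = sample_ids),
                   category = factor(cat_of, levels = SV_COMPLEX_TYPES)),
      FUN = sum, drop = FALSE)
    names(complex_counts)[3] <- "count"
    complex_counts$count[is.na(complex_counts$count)] <- 0
    complex_counts$sample_id <- as.character(complex_counts$sample_id)
    complex_counts$category <- as.character(complex_counts$category)
  } else {
    complex_counts <- expand.grid(sample_id = sample_ids,
                                  category = SV_COMPLEX_TYPES,
                                  stringsAsFactors = FALSE)
    complex_counts$count <- 0
  }
  burden <- as.data.frame(table(sample_id = factor(simple$sample_id, levels = sample_ids)),
                          responseName = "sv_burden", stringsAsFactors = FALSE)
  list(simple = simple_counts, complex = complex_counts, burden = burden)
}

#' Per-sample count of radiation-window simple structural deletions
#'
#' Simple DEL events with length in [50 bp, 10 kb), the window where
#' radiotherapy-associated deletions concentrate.
#'
#' @param sv SV records data.frame.
#' @param sample_ids Sample universe.
#' @return Named integer vector per sample.
#' @export
structural_deletion_count <- function(sv, sample_ids = NULL) {
  sample_ids <- sample_ids %||% unique(sv$sample_id)
  sv$resolved_type <- toupper(as.character(sv$resolved_type))
  simple_del <- sv$cluster_size == 1 & sv$resolved_type == "DEL" &
    !sv$resolved_type %in% SV_COMPLEX_TYPES
  win <- simple_del & !is.na(sv$length) & sv$length >= 50 & sv$length < 1e4
  tab <- table(factor(sv$sample_id[win], levels = sample_ids))
  stats::setNames(as.integer(tab), sample_ids)
}

#' Radiotherapy footprint: ID-8 indels and structural deletions
#'
#' Per-sample summary of the radiation-associated ID-8 exposure and the
#' [50 bp, 10 kb) simple structural deletion count, their Pearson
#' correlation with least-squares fit, a one-sided Wilcoxon rank-sum test
#' of ID-8 exposure between radiotherapy-exposed and unexposed samples,
#' and the fraction of radiation-window deletions in exposed samples with
#' little or no breakpoint microhomology (<= 1 bp).
#'
#' @param id8_exposures Named numeric vector (or 1-column matrix) of ID-8
#'   exposures per sample.
#' @param sv SV records data.frame with `microhomology_len`.
#' @param meta Sample metadata with `received_radiotherapy`.
#' @return A list: `per_sample` data.frame, `correlation` (see
#'   [correlate()]), `fit` (lm deletions ~ ID8), `wilcoxon_p`,
#'   `mh_low_fraction`.
#' @export
radiation_footprint <- function(id8_exposures, sv, meta) {
  if (is.matrix(id8_exposures)) {
    id8_exposures <- stats::setNames(id8_exposures[, "ID8"], rownames(id8_exposures))
  }
  samples <- meta$sample_id
  id8 <- id8_exposures[samples]
  if (anyNA(id8)) stop("ID8 exposure missing for some samples", call. = FALSE)
  dels <- structural_deletion_count(sv, samples)
  if (length(samples) < 3) stop("need >= 3 samples for the correlation", call. = FALSE)
  corr <- correlate(unname(id8), unname(dels))
  fit <- stats::lm(dels ~ id8)
  radio <- meta$received_radiotherapy
  wp <- if (any(radio) && any(!radio)) {
    compare_groups(id8[radio], id8[!radio], alternative = "greater")
  } else NA_real_
  sv$resolved_type <- toupper(as.character(sv$resolved_type))
  win <- sv$cluster_size == 1 & sv$resolved_type == "DEL" &
    !is.na(sv$length) & sv$length >= 50 & sv$length < 1e4 &
    sv$sample_id %in% samples[radio]
  mh_frac <- if (any(win)) mean(sv$microhomology_len[win] <= 1, na.rm = TRUE) else NA_real_
  list(per_sample = data.frame(sample_id = samples, id8 = unname(id8),
                               structural_deletions = unname(dels),
                               radiotherapy = radio, stringsAsFactors = FALSE),
       correlation = corr, fit = fit, wilcoxon_p = wp,
       mh_low_fraction = mh_frac)
}
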