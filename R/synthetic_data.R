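.default_treated_design <- function(tissue) {
  if (tissue == "colon") {
    # Seven treated colorectal donors: six CapOx-exposed (one with a single
    # cycle), one 5-FU-only; three received local pelvic radiotherapy.
    data.frame(
      donor_id = paste0("T", 1:7),
      age = c(24, 52, 58, 66, 71, 76, 77),
      capox_cycles = c(4, 4, 2, 0, 3, 1, 5),
      received_platinum = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
      received_5fu = TRUE,
      received_radiotherapy = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
      months_since_treatment = c(1.5, 1, 2, 1.5, 2.5, 1, 0.5),
      stringsAsFactors = FALSE)
  } else {
    # Liver donors: more cycles on average, longer treatment-to-biopsy gap.
    data.frame(
      donor_id = paste0("T", 1:7),
      age = c(40, 48, 55, 60, 63, 68, 72),
      capox_cycles = c(9, 8, 6, 5, 4, 3, 6),
      received_platinum = TRUE,
      received_5fu = TRUE,
      received_radiotherapy = FALSE,
      months_since_treatment = c(30, 1, 12, 1, 20, 8, 34),
      stringsAsFactors = FALSE)
  }
}

#' Configuration of a synthetic organoid cohort
#'
#' Defines the generative law of a synthetic cohort of clonally expanded
#' stem cells: linear age-related mutation accumulation with a donor-level
#' random intercept, per-cycle platinum SBS with binomially coupled DBS,
#' all-or-none per-clone 5-FU activation, radiotherapy ID-8 indels with
#' correlated 50 bp-10 kb simple structural deletions, and clonal versus
#' in-vitro subclonal VAF distributions. Defaults encode the study
#' conditions the analysis is designed for: 43 aging SBS/year, 105
#' platinum SBS per CapOx cycle, 1 platinum DBS per 26 platinum SBS,
#' 265 +/- 195 5-FU SBS in clones where the process activates, and ~80
#' ID-8 indels per irradiated colon clone. The liver preset keeps the
#' aging clock and zeroes every treatment effect (systemic therapy leaves
#' the liver epithelium unmutagenised).
#'
#' @param tissue `"colon"` or `"liver"`.
#' @param n_donors_untreated,clones_per_donor Cohort layout.
#' @param age_range Untreated donor ages are drawn uniformly in this range.
#' @param aging_rate_mean Aging SBS per year (fixed-effect slope).
#' @param aging_intercept Aging SBS at age 0.
#' @param donor_sd,residual_sd Donor-level and clone-level SD of the aging
#'   SBS burden (mutations).
#' @param aging_mix,aging_dbs_mix,aging_id_mix Signature mixes of the aging
#'   processes (proportions summing to 1).
#' @param aging_dbs_rate,aging_id_rate Aging DBS / indel burden per year
#'   (Poisson).
#' @param treated_design Data.frame describing the treated donors; columns
#'   `donor_id`, `age`, `capox_cycles`, `received_platinum`,
#'   `received_5fu`, `received_radiotherapy`, `months_since_treatment`.
#' @param platinum_per_cycle_mean,platinum_per_cycle_sd Platinum SBS per
#'   CapOx cycle; the per-clone SD scales with sqrt(cycles).
#' @param dbs_per_sbs Platinum DBS per platinum SBS (binomial thinning).
#' @param fiveFU_activation_prob Per-clone probability that the 5-FU
#'   process activates; the observed heterogeneity is both inter- and
#'   intra-donor, so the draw is per clone, not per donor.
#' @param fiveFU_mean,fiveFU_sd 5-FU SBS count when active.
#' @param fiveFU_mix Mix over the two 5-FU signature components.
#' @param radio_id8_mean,radio_id8_sd ID-8 indels per irradiated clone.
#' @param sv_del_per_id8 Expected simple structural deletions per ID-8
#'   indel (Poisson thinning).
#' @param complex_sv_rate Expected complex SV events per irradiated clone.
#' @param background_sv_rate Expected background simple SVs per clone.
#' @param vaf_clonal,vaf_subclonal Beta(shape1, shape2) parameters of the
#'   clonal (mode ~0.5) and in-vitro subclonal VAF distributions; the
#'   subclonal 95th percentile must fall below the 0.3 clonality cutoff.
#' @param n_invitro_subclonal In-vitro subclonal SBS appended per clone
#'   when records are expanded (removed again by clonal filtering).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(tissue = c("colon", "liver"),
                          n_donors_untreated = 7,
                          clones_per_donor = 3,
                          age_range = c(10, 80),
                          aging_rate_mean = 43,
                          aging_intercept = 100,
                          donor_sd = 100,
                          residual_sd = 150,
                          aging_mix = c(SBS1 = 0.25, SBS5 = 0.55, SBS18 = 0.20),
                          aging_dbs_rate = 0.5,
                          aging_dbs_mix = c(DBS2 = 0.3, DBS4 = 0.25, DBS6 = 0.2,
                                            DBS9 = 0.15, DBS11 = 0.1),
                          aging_id_rate = 2.5,
                          aging_id_mix = c(ID1 = 0.4, ID2 = 0.35, ID5 = 0.25),
                          treated_design = NULL,
                          platinum_per_cycle_mean = 105,
                          platinum_per_cycle_sd = 40,
                          dbs_per_sbs = 1 / 26,
                          fiveFU_activation_prob = 0.2,
                          fiveFU_mean = 265,
                          fiveFU_sd = 195,
                          fiveFU_mix = c(SBS17a = 0.5, SBS17b = 0.5),
                          radio_id8_mean = 80,
                          radio_id8_sd = 15,
                          sv_del_per_id8 = 0.18,
                          complex_sv_rate = 1.0,
                          background_sv_rate = 0.2,
                          vaf_clonal = c(60, 60),
                          vaf_subclonal = c(4, 26),
                          n_invitro_subclonal = 50) {
  tissue <- match.arg(tissue)
  if (tissue == "liver") {
    # systemic-treatment effects absent in liver unless explicitly overridden
    if (missing(platinum_per_cycle_mean)) platinum_per_cycle_mean <- 0
    if (missing(fiveFU_activation_prob)) fiveFU_activation_prob <- 0
    if (missing(radio_id8_mean)) radio_id8_mean <- 0
    if (missing(sv_del_per_id8)) sv_del_per_id8 <- 0
    if (missing(complex_sv_rate)) complex_sv_rate <- 0
  }
  treated_design <- treated_design %||% .default_treated_design(tissue)
  cfg <- list(tissue = tissue, n_donors_untreated = n_donors_untreated,
              clones_per_donor = clones_per_donor, age_range = age_range,
              aging_rate_mean = aging_rate_mean, aging_intercept = aging_intercept,
              donor_sd = donor_sd, residual_sd = residual_sd,
              aging_mix = aging_mix, aging_dbs_rate = aging_dbs_rate,
              aging_dbs_mix = aging_dbs_mix, aging_id_rate = aging_id_rate,
              aging_id_mix = aging_id_mix, treated_design = treated_design,
              platinum_per_cycle_mean = platinum_per_cycle_mean,
              platinum_per_cycle_sd = platinum_per_cycle_sd,
              dbs_per_sbs = dbs_per_sbs,
              fiveFU_activation_prob = fiveFU_activation_prob,
              fiveFU_mean = fiveFU_mean, fiveFU_sd = fiveFU_sd,
              fiveFU_mix = fiveFU_mix,
              radio_id8_mean = radio_id8_mean, radio_id8_sd = radio_id8_sd,
              sv_del_per_id8 = sv_del_per_id8, complex_sv_rate = complex_sv_rate,
              background_sv_rate = background_sv_rate,
              vaf_clonal = vaf_clonal, vaf_subclonal = vaf_subclonal,
              n_invitro_subclonal = n_invitro_subclonal)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Validate a cohort configuration
#'
#' @param cfg A list as built by [cohort_config()].
#' @return `cfg` invisibly, or an error describing the inconsistency.
#' @export
validate_cohort_config <- function(cfg) {
  rates <- c(cfg$aging_rate_mean, cfg$aging_dbs_rate, cfg$aging_id_rate,
             cfg$platinum_per_cycle_mean, cfg$fiveFU_mean, cfg$radio_id8_mean,
             cfg$sv_del_per_id8, cfg$background_sv_rate, cfg$complex_sv_rate)
  if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  for (mx in list(cfg$aging_mix, cfg$aging_dbs_mix, cfg$aging_id_mix,
                  cfg$fiveFU_mix)) {
    if (abs(sum(mx) - 1) > 1e-8 || any(mx < 0)) {
      stop("signature mixes must be proportions summing to 1", call. = FALSE)
    }
  }
  if (cfg$fiveFU_activation_prob < 0 || cfg$fiveFU_activation_prob > 1) {
    stop("fiveFU_activation_prob must be in [0, 1]", call. = FALSE)
  }
  q95 <- stats::qbeta(0.95, cfg$vaf_subclonal[1], cfg$vaf_subclonal[2])
  if (q95 >= 0.3) {
    stop("subclonal VAF 95th percentile must be < 0.3 (got ",
         round(q95, 3), ")", call. = FALSE)
  }
  td <- cfg$treated_design
  need <- c("donor_id", "age", "capox_cycles", "received_platinum",
            "received_5fu", "received_radiotherapy", "months_since_treatment")
  miss <- setdiff(need, names(td))
  if (length(miss)) stop("treated_design lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- td$received_platinum & td$capox_cycles == 0
  if (any(bad)) {
    stop("inconsistent config: platinum-treated donor with zero cycles (",
         td$donor_id[bad][1], ")", call. = FALSE)
  }
  bad2 <- td$capox_cycles > 0 & !(td$received_platinum & td$received_5fu)
  if (any(bad2)) {
    stop("capox_cycles > 0 requires received_platinum and received_5fu (",
         td$donor_id[bad2][1], ")", call. = FALSE)
  }
  invisible(cfg)
}

.rcount <- function(n, mean, sd) {
  pmax(0L, as.integer(round(stats::rnorm(n, mean, sd))))
}

.draw_channels <- function(n, profile) {
  # one multinomial draw -> per-channel integer counts
  if (n == 0) return(stats::setNames(integer(length(profile)), names(profile)))
  stats::setNames(as.integer(stats::rmultinom(1, n, profile)), names(profile))
}

.expand_records <- function(sample_id, counts_by_channel, mut_type, origin,
                            clonal, cfg) {
  total <- sum(counts_by_channel)
  if (total == 0) return(NULL)
  ch <- rep(names(counts_by_channel), counts_by_channel)
  vaf_par <- if (clonal) cfg$vaf_clonal else cfg$vaf_subclonal
  vaf <- stats::rbeta(total, vaf_par[1], vaf_par[2])
  chrom <- as.character(sample.int(22, total, replace = TRUE))
  pos <- sample.int(2e8, total, replace = TRUE)
  if (mut_type == "SBS96") {
    p <- parse_sbs96(ch)
    df <- data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
                     ref = p$ref, alt = p$alt, mut_class = "SBS", vaf = vaf,
                     flank5 = p$flank5, flank3 = p$flank3,
                     local_seq = NA_character_, offset = NA_integer_,
                     channel = ch, stringsAsFactors = FALSE)
  } else if (mut_type == "DBS78") {
    p <- parse_dbs78(ch)
    df <- data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
                     ref = p$ref2, alt = p$alt2, mut_class = "DBS", vaf = vaf,
                     flank5 = NA_character_, flank3 = NA_character_,
                     local_seq = NA_character_, offset = NA_integer_,
                     channel = ch, stringsAsFactors = FALSE)
  } else {
    real <- lapply(ch, realize_id83)
    df <- data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
                     ref = vapply(real, `[[`, character(1), "ref"),
                     alt = vapply(real, `[[`, character(1), "alt"),
                     mut_class = "INDEL", vaf = vaf,
                     flank5 = NA_character_, flank3 = NA_character_,
                     local_seq = vapply(real, `[[`, character(1), "local_seq"),
                     offset = vapply(real, function(r) as.integer(r$offset),
                                     integer(1)),
                     channel = ch, stringsAsFactors = FALSE)
  }
  df$origin <- origin
  df$clonal <- clonal
  df
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Generates per-clone mutation counts under the configured generative law,
#' draws channels multinomially from reference signature profiles, and
#' assembles the sample metadata, context matrices (clonal mutations only),
#' SV table and per-clone ground truth. With `records = TRUE` the
#' individual mutation records are also expanded, including the in-vitro
#' subclonal spike-ins that clonal filtering must remove, so the full
#' read / filter / classify / count pipeline can be exercised end to end.
#'
#' @param config A [cohort_config()].
#' @param reference Optional named list of reference signature matrices
#'   (`SBS96`, `DBS78`, `ID83`; channels x signatures); defaults to
#'   [synthetic_reference_signatures()].
#' @param records Expand individual mutation records (slower).
#' @param seed Optional RNG seed; a fixed seed gives identical output.
#' @return A list of class `synthetic_cohort`: `meta`, `ground_truth`
#'   (per-clone process totals), `context` (list of SBS96 / DBS78 / ID83
#'   sample x channel matrices), `sv`, `records` (or `NULL`), `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), reference = NULL,
                            records = FALSE, seed = NULL) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  reference <- reference %||%
    list(SBS96 = synthetic_reference_signatures("SBS96"),
         DBS78 = synthetic_reference_signatures("DBS78"),
         ID83 = synthetic_reference_signatures("ID83"))
  cfg <- config
  for (mt in c("SBS96", "DBS78", "ID83")) {
    need <- switch(mt,
                   SBS96 = c(names(cfg$aging_mix), names(cfg$fiveFU_mix), "SBS35"),
                   DBS78 = c(names(cfg$aging_dbs_mix), "DBS5"),
                   ID83 = c(names(cfg$aging_id_mix), "ID8"))
    miss <- setdiff(need, colnames(reference[[mt]]))
    if (length(miss)) {
      stop("reference lacks signature(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  td <- cfg$treated_design
  untreated <- data.frame(
    donor_id = paste0("U", seq_len(cfg$n_donors_untreated)),
    age = stats::runif(cfg$n_donors_untreated, cfg$age_range[1], cfg$age_range[2]),
    capox_cycles = 0L, received_platinum = FALSE, received_5fu = FALSE,
    received_radiotherapy = FALSE, months_since_treatment = NA_real_,
    stringsAsFactors = FALSE)
  donors <- rbind(untreated, td[, names(untreated)])
  donors$u <- stats::rnorm(nrow(donors), 0, cfg$donor_sd)
  k <- cfg$clones_per_donor
  meta <- do.call(rbind, lapply(seq_len(nrow(donors)), function(i) {
    data.frame(sample_id = paste0(donors$donor_id[i], "_c", seq_len(k)),
               donor_id = donors$donor_id[i], tissue = cfg$tissue,
               age = donors$age[i], capox_cycles = donors$capox_cycles[i],
               received_platinum = donors$received_platinum[i],
               received_5fu = donors$received_5fu[i],
               received_radiotherapy = donors$received_radiotherapy[i],
               months_since_treatment = donors$months_since_treatment[i],
               stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  n <- nrow(meta)
  u <- donors$u[match(meta$donor_id, donors$donor_id)]

  gt <- data.frame(sample_id = meta$sample_id, donor_id = meta$donor_id,
                   stringsAsFactors = FALSE)
  gt$aging_sbs <- .rcount(n, cfg$aging_intercept + cfg$aging_rate_mean * meta$age + u,
                          cfg$residual_sd)
  plat_mean <- cfg$platinum_per_cycle_mean * meta$capox_cycles
  plat_sd <- cfg$platinum_per_cycle_sd * sqrt(pmax(meta$capox_cycles, 1))
  gt$platinum_sbs <- ifelse(meta$received_platinum & plat_mean > 0,
                            .rcount(n, plat_mean, plat_sd), 0L)
  gt$platinum_dbs <- stats::rbinom(n, gt$platinum_sbs, cfg$dbs_per_sbs)
  active <- meta$received_5fu & cfg$fiveFU_mean > 0 &
    stats::runif(n) < cfg$fiveFU_activation_prob
  gt$fiveFU_active <- active
  gt$fiveFU_sbs <- ifelse(active, .rcount(n, cfg$fiveFU_mean, cfg$fiveFU_sd), 0L)
  irradiated <- meta$received_radiotherapy & cfg$radio_id8_mean > 0
  gt$radio_id8 <- ifelse(irradiated,
                         .rcount(n, cfg$radio_id8_mean, cfg$radio_id8_sd), 0L)
  gt$radio_sv_del <- stats::rpois(n, cfg$sv_del_per_id8 * gt$radio_id8)
  gt$aging_dbs <- stats::rpois(n, cfg$aging_dbs_rate * meta$age)
  gt$aging_id <- stats::rpois(n, cfg$aging_id_rate * meta$age)

  ref <- reference
  sbs_ch <- rownames(ref$SBS96)
  dbs_ch <- rownames(ref$DBS78)
  id_ch <- rownames(ref$ID83)
  ctx_sbs <- matrix(0L, n, length(sbs_ch), dimnames = list(meta$sample_id, sbs_ch))
  ctx_dbs <- matrix(0L, n, length(dbs_ch), dimnames = list(meta$sample_id, dbs_ch))
  ctx_id <- matrix(0L, n, length(id_ch), dimnames = list(meta$sample_id, id_ch))
  rec_list <- if (records) vector("list", n) else NULL
  sv_list <- vector("list", n)
  sub_profile <- as.vector(ref$SBS96[, names(cfg$aging_mix), drop = FALSE] %*%
                             cfg$aging_mix)

  for (i in seq_len(n)) {
    sid <- meta$sample_id[i]
    # process totals -> per-signature splits -> per-channel multinomial draws
    sbs_counts <- stats::setNames(integer(length(sbs_ch)), sbs_ch)
    aging_split <- if (gt$aging_sbs[i] > 0) {
      as.integer(stats::rmultinom(1, gt$aging_sbs[i], cfg$aging_mix))
    } else integer(length(cfg$aging_mix))
    for (j in seq_along(cfg$aging_mix)) {
      sbs_counts <- sbs_counts +
        .draw_channels(aging_split[j], ref$SBS96[, names(cfg$aging_mix)[j]])
    }
    ffu_split <- if (gt$fiveFU_sbs[i] > 0) {
      as.integer(stats::rmultinom(1, gt$fiveFU_sbs[i], cfg$fiveFU_mix))
    } else integer(length(cfg$fiveFU_mix))
    for (j in seq_along(cfg$fiveFU_mix)) {
      sbs_counts <- sbs_counts +
        .draw_channels(ffu_split[j], ref$SBS96[, names(cfg$fiveFU_mix)[j]])
    }
    sbs_counts <- sbs_counts +
      .draw_channels(gt$platinum_sbs[i], ref$SBS96[, "SBS35"])
    ctx_sbs[i, ] <- sbs_counts

    dbs_counts <- stats::setNames(integer(length(dbs_ch)), dbs_ch)
    dbs_split <- if (gt$aging_dbs[i] > 0) {
      as.integer(stats::rmultinom(1, gt$aging_dbs[i], cfg$aging_dbs_mix))
    } else integer(length(cfg$aging_dbs_mix))
    for (j in seq_along(cfg$aging_dbs_mix)) {
      dbs_counts <- dbs_counts +
        .draw_channels(dbs_split[j], ref$DBS78[, names(cfg$aging_dbs_mix)[j]])
    }
    dbs_counts <- dbs_counts +
      .draw_channels(gt$platinum_dbs[i], ref$DBS78[, "DBS5"])
    ctx_dbs[i, ] <- dbs_counts

    id_counts <- stats::setNames(integer(length(id_ch)), id_ch)
    id_split <- if (gt$aging_id[i] > 0) {
      as.integer(stats::rmultinom(1, gt$aging_id[i], cfg$aging_id_mix))
    } else integer(length(cfg$aging_id_mix))
    for (j in seq_along(cfg$aging_id_mix)) {
      id_counts <- id_counts +
        .draw_channels(id_split[j], ref$ID83[, names(cfg$aging_id_mix)[j]])
    }
    id_counts <- id_counts + .draw_channels(gt$radio_id8[i], ref$ID83[, "ID8"])
    ctx_id[i, ] <- id_counts

    svs <- list()
    if (gt$radio_sv_del[i] > 0) {
      nd <- gt$radio_sv_del[i]
      svs$radio <- data.frame(
        sample_id = sid, chrom = as.character(sample.int(22, nd, TRUE)),
        pos = sample.int(2e8, nd, TRUE), sv_type = "DEL",
        length = round(10^stats::runif(nd, log10(50), 4)),
        cluster_size = 1L, resolved_type = "DEL", microhomology_len = 0L,
        origin = "radio_sv", stringsAsFactors = FALSE)
    }
    nb <- stats::rpois(1, cfg$background_sv_rate)
    if (nb > 0) {
      bg_type <- sample(c("DEL", "DUP"), nb, TRUE)
      svs$bg <- data.frame(
        sample_id = sid, chrom = as.character(sample.int(22, nb, TRUE)),
        pos = sample.int(2e8, nb, TRUE), sv_type = bg_type,
        length = round(10^stats::runif(nb, 3, 7)),
        cluster_size = 1L, resolved_type = bg_type,
        microhomology_len = sample(0:3, nb, TRUE),
        origin = "background_sv", stringsAsFactors = FALSE)
    }
    if (irradiated[i] && cfg$complex_sv_rate > 0) {
      ncx <- stats::rpois(1, cfg$complex_sv_rate)
      if (ncx > 0) {
        cat_cx <- sample(SV_COMPLEX_TYPES, ncx, TRUE)
        cs <- sample(2:5, ncx, TRUE)
        svs$cx <- do.call(rbind, lapply(seq_len(ncx), function(e) {
          data.frame(
            sample_id = sid, chrom = as.character(sample.int(22, cs[e], TRUE)),
            pos = sample.int(2e8, cs[e], TRUE), sv_type = "BND",
            length = NA_real_, cluster_size = cs[e],
            resolved_type = cat_cx[e], microhomology_len = NA_integer_,
            origin = "radio_complex", stringsAsFactors = FALSE)
        }))
      }
    }
    if (length(svs)) sv_list[[i]] <- do.call(rbind, svs)

    if (records) {
      parts <- list(
        .expand_records(sid, sbs_counts, "SBS96", "clonal_sbs", TRUE, cfg),
        .expand_records(sid, dbs_counts, "DBS78", "clonal_dbs", TRUE, cfg),
        .expand_records(sid, id_counts, "ID83", "clonal_indel", TRUE, cfg))
      if (cfg$n_invitro_subclonal > 0) {
        sub_counts <- .draw_channels(cfg$n_invitro_subclonal, sub_profile)
        names(sub_counts) <- sbs_ch
        parts <- c(parts, list(
          .expand_records(sid, sub_counts, "SBS96", "invitro_subclonal",
                          FALSE, cfg)))
      }
      rec_list[[i]] <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    }
  }
  sv <- do.call(rbind, sv_list[!vapply(sv_list, is.null, logical(1))])
  if (is.null(sv)) {
    sv <- data.frame(sample_id = character(0), chrom = character(0),
                     pos = integer(0), sv_type = character(0),
                     length = numeric(0), cluster_size = integer(0),
                     resolved_type = character(0),
                     microhomology_len = integer(0), origin = character(0),
                     stringsAsFactors = FALSE)
  }
  rownames(sv) <- NULL
  recs <- if (records) {
    do.call(rbind, rec_list[!vapply(rec_list, is.null, logical(1))])
  } else NULL
  if (!is.null(recs)) rownames(recs) <- NULL
  structure(list(meta = meta, ground_truth = gt,
                 context = list(SBS96 = ctx_sbs, DBS78 = ctx_dbs, ID83 = ctx_id),
                 sv = sv, records = recs, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  treated <- unique(x$meta$donor_id[x$meta$received_platinum |
                                      x$meta$received_5fu |
                                      x$meta$received_radiotherapy])
  cat(sprintf("Synthetic %s cohort: %d clones from %d donors (%d treated)\n",
              x$config$tissue, nrow(x$meta), length(unique(x$meta$donor_id)),
              length(treated)))
  cat(sprintf("  clonal mutations: %d SBS, %d DBS, %d indels; %d SV records%s\n",
              sum(x$context$SBS96), sum(x$context$DBS78), sum(x$context$ID83),
              nrow(x$sv),
              if (is.null(x$records)) ""
              else sprintf("; %d expanded records", nrow(x$records))))
  invisible(x)
}

.vcf_header <- function() {
  c("##fileformat=VCFv4.2",
    "##source=therasig_synthetic_cohort",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Pre-annotated mutation channel\">",
    "##INFO=<ID=FL5,Number=1,Type=String,Description=\"5-prime flanking base\">",
    "##INFO=<ID=FL3,Number=1,Type=String,Description=\"3-prime flanking base\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO"), collapse = "\t")))
}

#' Write a synthetic cohort in the pipeline's input formats
#'
#' Emits `meta.tsv`, `sv.tsv` and either a single `mutations.tsv` (with
#' pre-annotated context columns) or one VCF 4.2 per clone. VCF records
#' carry the VAF and channel as INFO tags `AF` / `CTX` and SBS flanking
#' bases as `FL5` / `FL3`, so the output round-trips losslessly through
#' [read_mutations()].
#'
#' @param cohort A `synthetic_cohort` simulated with `records = TRUE`.
#' @param out_dir Output directory (created if missing).
#' @param format `"tsv"` or `"vcf"`.
#' @return Character vector of written file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (is.null(cohort$records)) {
    stop("cohort was simulated without records; rerun simulate_cohort(records = TRUE)",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta_path <- file.path(out_dir, "meta.tsv")
  utils::write.table(cohort$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sv_path <- file.path(out_dir, "sv.tsv")
  utils::write.table(cohort$sv, sv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(meta_path, sv_path)
  rec <- cohort$records
  if (format == "tsv") {
    mut_path <- file.path(out_dir, "mutations.tsv")
    utils::write.table(rec[, setdiff(names(rec), c("origin", "clonal"))],
                       mut_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, mut_path)
  } else {
    for (sid in unique(rec$sample_id)) {
      r <- rec[rec$sample_id == sid, ]
      info <- paste0("AF=", formatC(r$vaf, digits = 6, format = "f"),
                     ";CTX=", r$channel,
                     ifelse(is.na(r$flank5), "",
                            paste0(";FL5=", r$flank5, ";FL3=", r$flank3)))
      body <- paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", info,
                    sep = "\t")
      p <- file.path(out_dir, paste0(sid, ".vcf"))
      writeLines(c(.vcf_header(), body), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
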