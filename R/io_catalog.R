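#' Read somatic mutation calls from VCF or TSV
#'
#' Builds a mutation table (one row per somatic call) from either a
#' per-clone VCF 4.x file or a pre-tabulated TSV. VCF records must carry a
#' variant-allele-frequency annotation; the INFO tag is looked up along a
#' configurable ladder (default `PURPLE_AF`, `AF`, `VAF`). Records with
#' malformed alleles (symbolic, multi-allelic or non-ACGT) are skipped with
#' a warning reporting how many were dropped; a record without any VAF
#' annotation is a hard error naming the record.
#'
#' Optional annotation columns/INFO tags are propagated when present:
#' `flank5`/`flank3` (`FL5`/`FL3`) for SBS trinucleotide context,
#' `channel` (`CTX`) for a pre-computed mutation-type channel, and
#' `local_seq`/`offset` for indel context.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param sample_id Sample identifier for VCF input (defaults to the file
#'   name without extension). TSV input carries its own `sample_id` column.
#' @param vaf_tag Character vector of INFO tags tried in order for the VAF.
#' @return A data.frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `mut_class`, `vaf` plus any context columns present.
#' @export
read_mutations <- function(path, format = c("auto", "vcf", "tsv"),
                           sample_id = NULL,
                           vaf_tag = c("PURPLE_AF", "AF", "VAF")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    # force sequence columns to character: a column of "T" alleles would
    # otherwise be read as logical TRUE
    hdr <- names(utils::read.delim(path, nrows = 1))
    chr_cols <- intersect(c("sample_id", "chrom", "ref", "alt", "flank5",
                            "flank3", "local_seq", "channel"), hdr)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = stats::setNames(
                               rep("character", length(chr_cols)), chr_cols))
    req <- c("sample_id", "chrom", "pos", "ref", "alt", "vaf")
    miss <- setdiff(req, names(tab))
    if (length(miss)) stop("TSV is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
    tab$chrom <- as.character(tab$chrom)
    bad <- grepl("[^ACGT]", tab$ref) | grepl("[^ACGT]", tab$alt) | tab$ref == tab$alt
    if (any(bad)) {
      warning(sum(bad), " record(s) with malformed alleles skipped", call. = FALSE)
      tab <- tab[!bad, , drop = FALSE]
    }
    if (nrow(tab) == 0) {
      tab$mut_class <- character(0)
    } else {
      tab$mut_class <- mutation_class(tab$ref, tab$alt)
    }
    rownames(tab) <- NULL
    return(tab)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) {
    # single-record VCFs come back as a bare named vector
    fx <- matrix(fx, nrow = length(fx) %/% 7, byrow = FALSE,
                 dimnames = list(NULL, names(fx)))
  }
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      mut_class = character(0), vaf = numeric(0),
                      stringsAsFactors = FALSE))
  }
  sid <- sample_id %||% sub("\\.vcf(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  vaf <- rep(NA_real_, nrow(fix))
  for (tag in vaf_tag) {
    v <- suppressWarnings(vcfR::extract.info(vcf, element = tag, as.numeric = TRUE))
    if (!is.null(v)) vaf[is.na(vaf)] <- v[is.na(vaf)]
    if (!anyNA(vaf)) break
  }
  if (anyNA(vaf)) {
    i <- which(is.na(vaf))[1]
    stop(sprintf("no VAF annotation (tried %s) for record %s:%s %s>%s",
                 paste(vaf_tag, collapse = "/"),
                 fix$CHROM[i], fix$POS[i], fix$REF[i], fix$ALT[i]), call. = FALSE)
  }
  out <- data.frame(sample_id = sid, chrom = as.character(fix$CHROM),
                    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                    vaf = vaf, stringsAsFactors = FALSE)
  opt_tags <- c(flank5 = "FL5", flank3 = "FL3", channel = "CTX")
  for (col in names(opt_tags)) {
    v <- suppressWarnings(vcfR::extract.info(vcf, element = opt_tags[[col]]))
    if (!is.null(v) && !all(is.na(v))) out[[col]] <- v
  }
  bad <- is.na(out$ref) | is.na(out$alt) | grepl("[^ACGT]", out$ref) |
    grepl("[^ACGT]", out$alt) | out$ref == out$alt
  if (any(bad)) {
    warning(sum(bad), " record(s) with malformed alleles skipped", call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out$mut_class <- if (nrow(out)) mutation_class(out$ref, out$alt) else character(0)
  rownames(out) <- NULL
  out[, c("sample_id", "chrom", "pos", "ref", "alt", "mut_class", "vaf",
          intersect(c("flank5", "flank3", "channel"), names(out)))]
}

#' Read the per-sample metadata table
#'
#' @param path TSV with columns `sample_id`, `donor_id`, `tissue`, `age`,
#'   `capox_cycles`, `received_platinum`, `received_5fu`,
#'   `received_radiotherapy` and optionally `months_since_treatment`.
#' @return A validated data.frame.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_meta(meta)
}

#' Validate a sample metadata table
#'
#' Checks the invariants of the clinical metadata: every sample maps to
#' exactly one donor, ages are positive, and CapOx cycles > 0 imply both
#' platinum and 5-FU exposure.
#'
#' @param meta A data.frame of per-sample metadata.
#' @return `meta`, invisibly unchanged, or an error.
#' @export
validate_sample_meta <- function(meta) {
  req <- c("sample_id", "donor_id", "tissue", "age", "capox_cycles",
           "received_platinum", "received_5fu", "received_radiotherapy")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata", call. = FALSE)
  if (any(meta$age <= 0)) stop("ages must be positive", call. = FALSE)
  if (any(meta$capox_cycles < 0)) stop("capox_cycles must be >= 0", call. = FALSE)
  bad <- meta$capox_cycles > 0 & !(meta$received_platinum & meta$received_5fu)
  if (any(bad)) {
    stop("capox_cycles > 0 requires received_platinum and received_5fu (sample ",
         meta$sample_id[bad][1], ")", call. = FALSE)
  }
  meta
}

#' Clonal filtering of somatic mutations
#'
#' Retains mutations with VAF strictly above `vaf_min` (default 0.30):
#' calls at or below the threshold are treated as having arisen in vitro
#' after the clonal step and are discarded. Optionally restricts to
#' autosomes (the mutation burden is defined on the autosomal genome).
#'
#' @param records Mutation table as returned by [read_mutations()].
#' @param vaf_min VAF threshold in (0, 1); retention is strict (`vaf > vaf_min`).
#' @param autosomes_only Drop chrX/chrY/chrM records.
#' @return The filtered mutation table, input order preserved.
#' @export
filter_clonal <- function(records, vaf_min = 0.30, autosomes_only = TRUE) {
  stopifnot(is.numeric(vaf_min), vaf_min > 0, vaf_min < 1)
  keep <- records$vaf > vaf_min
  if (autosomes_only) keep <- keep & .norm_chrom(records$chrom) %in% AUTOSOMES
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute the signature channel of each mutation record
#'
#' For `SBS96` the trinucleotide flanks must be available (columns
#' `flank5`/`flank3`, or a pre-annotated `channel` column); for `DBS78` the
#' alleles suffice; for `ID83` a pre-annotated `channel` column or
#' `local_seq`/`offset` columns are required.
#'
#' @param records Mutation table restricted or not to one class; only rows
#'   of the class matching `mut_type` are used.
#' @param mut_type One of `"SBS96"`, `"DBS78"`, `"ID83"`.
#' @return Character vector of channels for the matching rows, with the row
#'   indices of those records as the `idx` attribute.
#' @export
mutation_channels <- function(records, mut_type = c("SBS96", "DBS78", "ID83")) {
  mut_type <- match.arg(mut_type)
  cls <- c(SBS96 = "SBS", DBS78 = "DBS", ID83 = "INDEL")[[mut_type]]
  idx <- which(records$mut_class == cls)
  rec <- records[idx, , drop = FALSE]
  ch <- rep(NA_character_, nrow(rec))
  if ("channel" %in% names(rec)) {
    pre <- !is.na(rec$channel) & nzchar(rec$channel)
    ch[pre] <- rec$channel[pre]
  }
  todo <- which(is.na(ch))
  if (length(todo)) {
    if (mut_type == "SBS96") {
      if (!all(c("flank5", "flank3") %in% names(rec))) {
        stop("SBS96 classification needs flank5/flank3 columns or a channel column; ",
             "annotate flanks from a reference FASTA or supply pre-annotated context",
             call. = FALSE)
      }
      ch[todo] <- classify_sbs96(rec$ref[todo], rec$alt[todo],
                                 rec$flank5[todo], rec$flank3[todo])
    } else if (mut_type == "DBS78") {
      ch[todo] <- classify_dbs78(rec$ref[todo], rec$alt[todo])
    } else {
      if (!all(c("local_seq", "offset") %in% names(rec))) {
        stop("ID83 classification needs local_seq/offset columns or a channel column",
             call. = FALSE)
      }
      ch[todo] <- vapply(todo, function(i) {
        classify_id83(rec$ref[i], rec$alt[i], rec$local_seq[i], rec$offset[i])
      }, character(1))
    }
  }
  structure(ch, idx = idx)
}

#' Build a samples x channels mutation context matrix
#'
#' Counts clonal-filtered mutations of one class into the canonical channel
#' set, with one row per sample in metadata order. Counts are conserved:
#' each row sums to the sample's filtered burden of that mutation type.
#'
#' @param records Clonal-filtered mutation table.
#' @param meta Sample metadata (defines row order; every sample present in
#'   `records` must appear here).
#' @param mut_type One of `"SBS96"`, `"DBS78"`, `"ID83"`.
#' @return Integer matrix, `rownames` = sample ids, `colnames` = channels.
#' @export
build_context_matrix <- function(records, meta, mut_type = c("SBS96", "DBS78", "ID83")) {
  mut_type <- match.arg(mut_type)
  channels <- switch(mut_type, SBS96 = sbs96_channels(),
                     DBS78 = dbs78_channels(), ID83 = id83_channels())
  unknown <- setdiff(unique(records$sample_id), meta$sample_id)
  if (length(unknown)) {
    stop("sample(s) absent from metadata: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  ch <- mutation_channels(records, mut_type)
  idx <- attr(ch, "idx")
  bad <- !ch %in% channels
  if (any(bad)) stop("unrecognised ", mut_type, " channel: ", ch[bad][1], call. = FALSE)
  tab <- table(factor(records$sample_id[idx], levels = meta$sample_id),
               factor(ch, levels = channels))
  mat <- matrix(as.integer(tab), nrow = nrow(meta),
                dimnames = list(meta$sample_id, channels))
  mat
}

#' Write / read a context matrix as TSV
#'
#' Channels as columns in canonical order, samples as rows.
#'
#' @param mat Context matrix from [build_context_matrix()].
#' @param path Output path.
#' @return `write_context_matrix` returns `path` invisibly;
#'   `read_context_matrix` returns the matrix.
#' @export
write_context_matrix <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_context_matrix
#' @export
read_context_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "integer"
  m
}

#' Read structural variant calls from TSV
#'
#' @param path TSV with columns `sample_id`, `chrom`, `pos`, `sv_type`,
#'   `length`, `cluster_size`, `resolved_type`, `microhomology_len` and
#'   optionally `cluster_id`.
#' @return A data.frame of SV records.
#' @export
read_sv <- function(path) {
  sv <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "chrom", "pos", "sv_type", "length", "cluster_size",
           "resolved_type", "microhomology_len")
  miss <- setdiff(req, names(sv))
  if (length(miss)) stop("SV table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  sv
}
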