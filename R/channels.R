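BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  flipped <- vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(s) {
    paste(rev(s), collapse = "")
  }, character(1))
  unname(flipped)
}

.check_bases <- function(x, what, len = 1L) {
  ok <- !is.na(x) & nchar(x) == len & !grepl("[^ACGT]", x)
  if (!all(ok)) {
    stop(sprintf("invalid %s: %s", what,
                 paste(utils::head(x[!ok], 3), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Canonical SBS96 channel labels
#'
#' The 96 trinucleotide-context single-base-substitution classes in COSMIC
#' order: six pyrimidine-strand substitutions (C>A, C>G, C>T, T>A, T>C, T>G),
#' each in 16 flanking contexts ordered alphabetically by 5' then 3' base.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(BASES, BASES, function(f5, f3) {
      paste0(f5, "[", s, "]", f3)
    })))
  }))
}

#' Classify a single-base substitution into its SBS96 channel
#'
#' Applies the pyrimidine-strand convention: substitutions reported from a
#' purine reference base are reverse-complemented (flanks swapped and
#' complemented) before labelling, so a mutation and its reverse-strand
#' representation map to the same channel.
#'
#' @param ref,alt Reference and alternate base (single A/C/G/T; vectorised).
#' @param flank5,flank3 The bases immediately 5' and 3' of the mutated base
#'   on the reported strand.
#' @return Character vector of channel labels of the form `"X[R>A]Y"`.
#' @examples
#' classify_sbs96("G", "A", "T", "C")  # -> "G[C>T]A"
#' @export
classify_sbs96 <- function(ref, alt, flank5, flank3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(flank5) == n, length(flank3) == n)
  .check_bases(ref, "ref"); .check_bases(alt, "alt")
  .check_bases(flank5, "flank5"); .check_bases(flank3, "flank3")
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  purine <- !(ref %in% PYRIMIDINES)
  out_ref <- ifelse(purine, comp[ref], ref)
  out_alt <- ifelse(purine, comp[alt], alt)
  out_f5 <- ifelse(purine, comp[flank3], flank5)
  out_f3 <- ifelse(purine, comp[flank5], flank3)
  paste0(out_f5, "[", out_ref, ">", out_alt, "]", out_f3)
}

# Canonical DBS reference doublets: the 10 that survive reverse-complement
# collapapsing in COSMIC's DBS78 scheme.
DBS_CANONICAL_REF <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")

.dbs_canonical <- function(ref2, alt2) {
  if (!(ref2 %in% DBS_CANONICAL_REF)) {
    ref2 <- revcomp(ref2)
    alt2 <- revcomp(alt2)
  }
  if (ref2 == revcomp(ref2)) {
    rc_alt <- revcomp(alt2)
    if (rc_alt < alt2) alt2 <- rc_alt
  }
  paste0(ref2, ">", alt2)
}

#' Canonical DBS78 channel labels
#'
#' @return Character vector of the 78 doublet-base-substitution channels in
#'   alphabetical (reference doublet, alternate doublet) order.
#' @export
dbs78_channels <- function() {
  refs <- as.vector(outer(BASES, BASES, paste0))
  labs <- character(0)
  for (r in refs) {
    r1 <- substr(r, 1, 1); r2 <- substr(r, 2, 2)
    for (a1 in setdiff(BASES, r1)) for (a2 in setdiff(BASES, r2)) {
      labs <- c(labs, .dbs_canonical(r, paste0(a1, a2)))
    }
  }
  sort(unique(labs))
}

#' Classify a doublet-base substitution into its DBS78 channel
#'
#' Collapses reverse-complement-equivalent doublet substitutions onto the 10
#' canonical reference doublets; for palindromic reference doublets the
#' alternate doublet is likewise collapsed.
#'
#' @param ref2,alt2 Reference and alternate doublets (length-2 A/C/G/T
#'   strings, differing at both positions; vectorised).
#' @return Character vector of channel labels of the form `"CT>AA"`.
#' @examples
#' classify_dbs78("AG", "TT")  # -> "CT>AA"
#' @export
classify_dbs78 <- function(ref2, alt2) {
  n <- length(ref2)
  stopifnot(length(alt2) == n)
  .check_bases(ref2, "ref2", len = 2L)
  .check_bases(alt2, "alt2", len = 2L)
  if (any(ref2 == alt2)) stop("ref2 and alt2 must differ", call. = FALSE)
  same1 <- substr(ref2, 1, 1) == substr(alt2, 1, 1)
  same2 <- substr(ref2, 2, 2) == substr(alt2, 2, 2)
  if (any(same1 | same2)) {
    stop("doublet substitution must differ at both positions; got ",
         paste(ref2[same1 | same2], ">", alt2[same1 | same2])[1], call. = FALSE)
  }
  vapply(seq_len(n), function(i) .dbs_canonical(ref2[i], alt2[i]), character(1))
}

#' Canonical ID83 channel labels
#'
#' The 83 small insertion/deletion classes: 1-bp C/T deletions by homopolymer
#' length (1..6+), 1-bp C/T insertions by pre-existing run length (0..5+),
#' 2/3/4/5+ bp deletions and insertions at repeats by number of additional
#' motif copies (0..5+), and microhomology-flanked deletions by deletion
#' length and microhomology length.
#'
#' @return Character vector of length 83, e.g. `"DEL.T.1.4"`,
#'   `"DEL.rep.5+.0"`, `"DEL.mh.3.2"`.
#' @export
id83_channels <- function() {
  del1 <- paste0("DEL.", rep(c("C", "T"), each = 6), ".1.",
                 c("1", "2", "3", "4", "5", "6+"))
  ins1 <- paste0("INS.", rep(c("C", "T"), each = 6), ".1.",
                 c("0", "1", "2", "3", "4", "5+"))
  lens <- c("2", "3", "4", "5+")
  reps <- c("0", "1", "2", "3", "4", "5+")
  delr <- paste0("DEL.rep.", rep(lens, each = 6), ".", reps)
  insr <- paste0("INS.rep.", rep(lens, each = 6), ".", reps)
  mh <- c("DEL.mh.2.1",
          paste0("DEL.mh.3.", 1:2),
          paste0("DEL.mh.4.", 1:3),
          paste0("DEL.mh.5+.", c("1", "2", "3", "4", "5+")))
  c(del1, ins1, delr, insr, mh)
}

.count_copies_right <- function(seq_chars, start, motif_chars) {
  L <- length(motif_chars)
  n <- length(seq_chars)
  k <- 0L
  while (start + L - 1L <= n &&
         all(seq_chars[start:(start + L - 1L)] == motif_chars)) {
    k <- k + 1L
    start <- start + L
  }
  k
}

.count_copies_left <- function(seq_chars, end, motif_chars) {
  L <- length(motif_chars)
  k <- 0L
  while (end - L + 1L >= 1L &&
         all(seq_chars[(end - L + 1L):end] == motif_chars)) {
    k <- k + 1L
    end <- end - L
  }
  k
}

#' Classify a small insertion/deletion into its ID83 channel
#'
#' Indels are given VCF-style (`ref`/`alt` share a leading anchor base)
#' together with the local reference sequence and the 1-based position of
#' the anchor base within it. Repeat copies of the indel motif are counted
#' outward in both directions; microhomology is evaluated only for
#' deletions of >= 2 bp with no additional repeat copy, per the COSMIC
#' scheme. 1-bp indels of A/G are complemented to the T/C classes.
#'
#' @param ref,alt VCF-style reference and alternate alleles (one a strict
#'   prefix of the other).
#' @param local_seq Reference sequence surrounding the indel; must cover at
#'   least 6 motif lengths of flank on each side.
#' @param offset 1-based position of the anchor base within `local_seq`.
#' @return A single channel label from [id83_channels()].
#' @examples
#' # 1-bp deletion of T inside a TTTT run:
#' classify_id83("GT", "G", paste0(strrep("G", 8), "TTTT", strrep("A", 8)), 8)
#' @export
classify_id83 <- function(ref, alt, local_seq, offset) {
  stopifnot(length(ref) == 1, length(alt) == 1, length(local_seq) == 1)
  if (nchar(ref) == nchar(alt)) stop("not an indel: ref and alt have equal length", call. = FALSE)
  if (substr(ref, 1, 1) != substr(alt, 1, 1)) {
    stop("ref and alt must share a leading anchor base (VCF convention)", call. = FALSE)
  }
  is_del <- nchar(ref) > nchar(alt)
  motif <- if (is_del) substr(ref, 2, nchar(ref)) else substr(alt, 2, nchar(alt))
  if (grepl("[^ACGT]", motif) || nchar(motif) == 0) stop("invalid indel allele", call. = FALSE)
  L <- nchar(motif)
  chars <- strsplit(local_seq, "")[[1]]
  n <- length(chars)
  offset <- as.integer(offset)
  if (offset < 1 || offset > n) stop("offset outside local_seq", call. = FALSE)
  if (chars[offset] != substr(ref, 1, 1)) {
    stop("anchor base mismatch between ref and local_seq at offset", call. = FALSE)
  }
  need <- 6L * L
  left_avail <- offset
  right_start <- if (is_del) offset + L + 1L else offset + 1L
  right_avail <- n - right_start + 1L
  if (left_avail < need || right_avail < need) {
    stop(sprintf(
      "insufficient flank in local_seq: need >= %d bases on each side of the indel (have %d left, %d right)",
      need, left_avail, right_avail), call. = FALSE)
  }
  mchars <- strsplit(motif, "")[[1]]
  if (is_del) {
    if (!all(chars[(offset + 1L):(offset + L)] == mchars)) {
      stop("deleted sequence does not match local_seq at offset", call. = FALSE)
    }
    k_right <- .count_copies_right(chars, offset + L + 1L, mchars)
    k_left <- .count_copies_left(chars, offset, mchars)
    total <- 1L + k_left + k_right
    if (L == 1L) {
      base <- if (mchars %in% c("A", "G")) c(A = "T", G = "C")[[mchars]] else mchars
      cls <- if (total >= 6L) "6+" else as.character(total)
      return(paste0("DEL.", base, ".1.", cls))
    }
    len_cls <- if (L >= 5L) "5+" else as.character(L)
    if (total == 1L) {
      # no full extra copy: check breakpoint microhomology
      mh_r <- 0L
      while (mh_r < L - 1L && chars[offset + L + 1L + mh_r] == mchars[mh_r + 1L]) mh_r <- mh_r + 1L
      mh_l <- 0L
      while (mh_l < L - 1L && chars[offset - mh_l] == mchars[L - mh_l]) mh_l <- mh_l + 1L
      mh <- max(mh_r, mh_l)
      if (mh >= 1L) {
        mh_cls <- if (len_cls == "5+" && mh >= 5L) "5+" else as.character(min(mh, L - 1L))
        return(paste0("DEL.mh.", len_cls, ".", mh_cls))
      }
    }
    extra <- total - 1L
    rep_cls <- if (extra >= 5L) "5+" else as.character(extra)
    return(paste0("DEL.rep.", len_cls, ".", rep_cls))
  }
  # insertion
  k_right <- .count_copies_right(chars, offset + 1L, mchars)
  k_left <- .count_copies_left(chars, offset, mchars)
  k <- k_left + k_right
  if (L == 1L) {
    base <- if (mchars %in% c("A", "G")) c(A = "T", G = "C")[[mchars]] else mchars
    cls <- if (k >= 5L) "5+" else as.character(k)
    return(paste0("INS.", base, ".1.", cls))
  }
  len_cls <- if (L >= 5L) "5+" else as.character(L)
  rep_cls <- if (k >= 5L) "5+" else as.character(k)
  paste0("INS.rep.", len_cls, ".", rep_cls)
}

#' Construct a concrete indel realising an ID83 channel
#'
#' Builds a minimal (ref, alt, local_seq, offset) tuple whose
#' [classify_id83()] classification is exactly `channel`. Used by the
#' synthetic cohort generator and for exhaustive round-trip testing of the
#' indel classifier.
#'
#' @param channel A label from [id83_channels()].
#' @return A list with elements `ref`, `alt`, `local_seq`, `offset`.
#' @export
realize_id83 <- function(channel) {
  stopifnot(length(channel) == 1)
  if (!channel %in% id83_channels()) stop("unknown ID83 channel: ", channel, call. = FALSE)
  parts <- strsplit(channel, ".", fixed = TRUE)[[1]]
  kind <- parts[1]; sub <- parts[2]; len <- parts[3]; cls <- parts[4]
  num <- function(x) if (grepl("\\+$", x)) as.integer(sub("\\+$", "", x)) else as.integer(x)
  if (sub %in% c("C", "T")) {  # 1-bp homopolymer classes
    B <- sub
    pad_l <- strrep("G", 8); pad_r <- strrep("A", 8)
    if (kind == "DEL") {
      h <- num(cls)
      local_seq <- paste0(pad_l, strrep(B, h), pad_r)
      return(list(ref = paste0("G", B), alt = "G", local_seq = local_seq, offset = 8L))
    }
    k <- num(cls)
    local_seq <- paste0(pad_l, strrep(B, k), pad_r)
    return(list(ref = "G", alt = paste0("G", B), local_seq = local_seq, offset = 8L))
  }
  L <- if (len == "5+" && kind == "DEL" && sub == "mh" && cls == "5+") 6L else if (len == "5+") 5L else num(len)
  motif <- substr("ACGTAC", 1, L)
  m1 <- substr(motif, 1, 1); mL <- substr(motif, L, L)
  pad <- 6L * L
  if (sub == "rep") {
    k <- num(cls)
    p_l <- setdiff(BASES, c(mL, m1))[1]
    p_r <- setdiff(BASES, c(m1, mL))[1]
    if (kind == "DEL") {
      local_seq <- paste0(strrep(p_l, pad), strrep(motif, 1L + k), strrep(p_r, pad))
      return(list(ref = paste0(p_l, motif), alt = p_l, local_seq = local_seq, offset = pad))
    }
    local_seq <- paste0(strrep(p_l, pad), strrep(motif, k), strrep(p_r, pad))
    return(list(ref = p_l, alt = paste0(p_l, motif), local_seq = local_seq, offset = pad))
  }
  # microhomology deletion
  h <- num(cls)
  stopifnot(h <= L - 1L)
  p_l <- setdiff(BASES, c(mL, m1))[1]
  next_base <- substr(motif, h + 1L, h + 1L)
  x <- setdiff(BASES, c(next_base, p_l))[1]
  right <- paste0(substr(motif, 1, h), x, strrep(p_l, pad))
  local_seq <- paste0(strrep(p_l, pad), motif, right)
  list(ref = paste0(p_l, motif), alt = p_l, local_seq = local_seq, offset = pad)
}

#' Parse an SBS96 channel label into its components
#'
#' @param channel Character vector of SBS96 labels, e.g. `"A[C>T]G"`.
#' @return A data.frame with columns `flank5`, `ref`, `alt`, `flank3`.
#' @export
parse_sbs96 <- function(channel) {
  m <- regmatches(channel, regexec("^([ACGT])\\[([CT])>([ACGT])\\]([ACGT])$", channel))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) stop("malformed SBS96 label: ", channel[bad][1], call. = FALSE)
  out <- do.call(rbind, m)
  data.frame(flank5 = out[, 2], ref = out[, 3], alt = out[, 4], flank3 = out[, 5],
             stringsAsFactors = FALSE)
}

#' Parse a DBS78 channel label into reference and alternate doublets
#'
#' @param channel Character vector of DBS78 labels, e.g. `"CT>AA"`.
#' @return A data.frame with columns `ref2`, `alt2`.
#' @export
parse_dbs78 <- function(channel) {
  parts <- strsplit(channel, ">", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) stop("malformed DBS78 label: ", channel[bad][1], call. = FALSE)
  data.frame(ref2 = vapply(parts, `[`, character(1), 1),
             alt2 = vapply(parts, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}
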