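`%||%` <- function(a, b) if (is.null(a)) b else a

.norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

AUTOSOMES <- as.character(1:22)

#' Derive the mutation class from reference and alternate alleles
#'
#' @param ref,alt Allele strings (VCF convention for indels).
#' @return Character vector with values `"SBS"`, `"DBS"` or `"INDEL"`.
#' @export
mutation_class <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  cls <- ifelse(nr == 1 & na == 1, "SBS",
                ifelse(nr == 2 & na == 2, "DBS",
                       ifelse(nr != na, "INDEL", NA_character_)))
  if (anyNA(cls)) {
    stop("cannot classify alleles (equal-length block substitution?): ",
         ref[is.na(cls)][1], ">", alt[is.na(cls)][1], call. = FALSE)
  }
  cls
}
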