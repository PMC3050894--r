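#' Translate DNA in a fixed frame
#'
#' Standard-genetic-code translation starting `offset` bases into the
#' sequence (offset 0/1/2, matching GFF phase). Stop codons are rendered as
#' `"*"`, codons containing an ambiguous base as `"X"`, and a trailing
#' partial codon is dropped.
#'
#' @param dna DNA string
#' @param offset frame offset in 0..2 (bases skipped before the first codon)
#' @return amino-acid string (possibly empty)
#' @export
translate_dna <- function(dna, offset = 0L) {
  stopifnot(is_scalar_string(dna))
  offset <- as.integer(offset)
  if (!offset %in% 0:2) stop_altexon("offset must be 0, 1 or 2")
  dna <- toupper(dna)
  n <- nchar(dna) - offset
  n_codons <- n %/% 3L
  if (n_codons <= 0L) return("")
  starts <- offset + 1L + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- GENETIC_CODE_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Codons of a coding sequence
#' @param cds in-frame DNA string, length divisible by 3
#' @return character vector of codons
#' @export
split_codons <- function(cds) {
  stopifnot(is_scalar_string(cds))
  if (nchar(cds) %% 3L != 0L) {
    stop_altexon("CDS length ", nchar(cds), " is not divisible by 3")
  }
  if (nchar(cds) == 0L) return(character())
  starts <- seq(1L, nchar(cds), by = 3L)
  substring(toupper(cds), starts, starts + 2L)
}

#' Back-translate a peptide with seeded uniform codon choice
#'
#' Each residue is encoded by one of its synonymous codons chosen uniformly
#' at random (no codon-usage weighting); the draw is governed by the current
#' RNG state, so callers seed for reproducibility.
#'
#' @param peptide amino-acid string without gaps or stops
#' @return DNA string of length `3 * nchar(peptide)`
#' @export
back_translate <- function(peptide) {
  stopifnot(is_scalar_string(peptide), nzchar(peptide))
  aas <- strsplit(peptide, "")[[1]]
  if (any(aas == "*")) stop_altexon("peptide contains a stop character")
  codons_by_aa <- split(names(GENETIC_CODE_TABLE), GENETIC_CODE_TABLE)
  out <- vapply(aas, function(a) {
    cods <- codons_by_aa[[a]]
    if (is.null(cods)) stop_altexon("no codon for residue '", a, "'")
    cods[sample.int(length(cods), 1L)]
  }, character(1))
  paste(out, collapse = "")
}
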