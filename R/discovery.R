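#' Scan a region for minimal splice-site signals
#'
#' Finds every acceptor (AG immediately 5' of the reported boundary) and
#' donor (GT immediately 3' of the boundary) inside `region`. The splice
#' model is deliberately minimal — the canonical dinucleotide consensus plus
#' a reported polypyrimidine context score — because the conserved AG
#' acceptor is the evidence the discovery logic rests on; no position weight
#' matrix is used.
#'
#' @param locus a `genomic_locus`
#' @param region integer vector `c(start, end)`, 0-based half-open; the
#'   boundary of every reported hit lies in this interval
#' @return data.frame with columns `position` (0-based boundary offset),
#'   `kind` ("acceptor"/"donor") and `context_score` (for acceptors, the
#'   count of pyrimidines in the 15 nt upstream of the AG; `NA` for donors),
#'   sorted by position
#' @export
scan_splice_sites <- function(locus, region) {
  seq <- locus$sequence
  L <- nchar(seq)
  stopifnot(length(region) == 2L)
  rs <- as.integer(region[1]); re <- as.integer(region[2])
  if (rs < 0L || re > L || rs > re) {
    stop_altexon("region [", rs, ",", re, ") outside locus bounds [0,", L, ")")
  }
  empty <- data.frame(position = integer(), kind = character(),
                      context_score = integer())
  if (re - rs == 0L) return(empty)

  chars <- strsplit(seq, "")[[1]]
  cand_p <- rs:(re - 1L)
  # acceptor boundary p: 0-based p-2, p-1 hold A,G (1-based chars p-1, p)
  pa <- cand_p[cand_p >= 2L]
  acc <- pa[chars[pa - 1L] == "A" & chars[pa] == "G"]
  # donor boundary p: 0-based p, p+1 hold G,T (1-based chars p+1, p+2)
  pd <- cand_p[cand_p <= L - 2L]
  don <- pd[chars[pd + 1L] == "G" & chars[pd + 2L] == "T"]

  ctx <- vapply(acc, function(p) {
    win_start <- max(0L, p - 17L)          # 15 nt 5' of the AG dinucleotide
    win <- chars[seq_len(p - 2L - win_start) + win_start]
    sum(win %in% c("C", "T"))
  }, integer(1))

  out <- rbind(
    if (length(acc)) data.frame(position = acc, kind = "acceptor",
                                context_score = ctx) else empty,
    if (length(don)) data.frame(position = don, kind = "donor",
                                context_score = NA_integer_) else empty
  )
  out <- out[order(out$position, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find candidate unannotated coding exons inside an intron
#'
#' For every splice-acceptor boundary in the chosen intron, translation is
#' started at the boundary in the reading frame that continues the upstream
#' exons' coding phase (the candidate splices onto the upstream exons
#' in-frame; no independent ATG is required) and extended to the first
#' in-frame stop codon or the intron end. Candidates shorter than `min_aa`,
#' containing an ambiguous base inside the ORF, or lacking a stop when
#' `require_stop` is set, are discarded; discard counts are attached as the
#' `"discarded"` attribute.
#'
#' @param locus an annotated `genomic_locus` with at least 2 exons
#' @param intron_index which intron to search (1 = between exons 1 and 2)
#' @param min_aa minimum peptide length to report (default 100)
#' @param require_stop discard candidates whose frame reaches the intron end
#'   without a stop codon
#' @return data.frame of candidates sorted by `aa_length` decreasing then
#'   genomic position increasing, with columns `start`, `end` (0-based
#'   half-open, the end includes the stop codon when present), `phase`,
#'   `aa_length`, `peptide`, `acceptor_pos`, `acceptor_context`,
#'   `stop_at_end`
#' @export
find_candidate_exons <- function(locus, intron_index, min_aa = 100L,
                                 require_stop = FALSE) {
  if (nrow(locus$exons) < 2L) {
    stop_altexon("locus has fewer than 2 annotated exons; no introns to search")
  }
  intr <- introns(locus)
  if (!intron_index %in% intr$index) {
    stop_altexon("intron_index ", intron_index, " out of range 1..", nrow(intr))
  }
  if (min_aa < 1L) stop_altexon("min_aa must be >= 1")
  is <- intr$start[intr$index == intron_index]
  ie <- intr$end[intr$index == intron_index]

  # coding phase entering the intron: GFF-style phase of a hypothetical
  # exon following the upstream exons
  ex <- locus$exons
  cum <- sum(ex$end[seq_len(intron_index)] - ex$start[seq_len(intron_index)])
  q <- (3L - cum %% 3L) %% 3L

  sites <- scan_splice_sites(locus, c(is, ie))
  acc <- sites[sites$kind == "acceptor" & sites$position >= is + 2L, ,
               drop = FALSE]

  n_min_aa <- 0L; n_ambig <- 0L; n_no_stop <- 0L
  rows <- lapply(seq_len(nrow(acc)), function(k) {
    p <- acc$position[k]
    dna <- substr(locus$sequence, p + 1L, ie)  # 1-based substring of [p, ie)
    pep_full <- translate_dna(dna, offset = q)
    if (!nzchar(pep_full)) return(NULL)
    stop_idx <- regexpr("*", pep_full, fixed = TRUE)
    if (stop_idx > 0L) {
      peptide <- substr(pep_full, 1L, stop_idx - 1L)
      cand_end <- p + q + 3L * stop_idx      # stop codon included in interval
      stop_at_end <- TRUE
    } else {
      peptide <- pep_full
      cand_end <- ie
      stop_at_end <- FALSE
    }
    aa_len <- nchar(peptide)
    if (aa_len < min_aa) { n_min_aa <<- n_min_aa + 1L; return(NULL) }
    if (grepl("X", peptide, fixed = TRUE)) { n_ambig <<- n_ambig + 1L; return(NULL) }
    if (require_stop && !stop_at_end) { n_no_stop <<- n_no_stop + 1L; return(NULL) }
    data.frame(start = p, end = cand_end, phase = q, aa_length = aa_len,
               peptide = peptide, acceptor_pos = p,
               acceptor_context = acc$context_score[k],
               stop_at_end = stop_at_end)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(), phase = integer(),
                      aa_length = integer(), peptide = character(),
                      acceptor_pos = integer(), acceptor_context = integer(),
                      stop_at_end = logical())
  }
  out <- out[order(-out$aa_length, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded") <- list(min_aa = n_min_aa, ambiguous = n_ambig,
                                 no_stop = n_no_stop)
  out
}
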