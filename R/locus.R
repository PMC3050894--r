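#' Construct a genomic locus with exon annotations
#'
#' A locus couples a contig DNA sequence with an ordered table of exon
#' annotations and is the substrate of intronic exon discovery. Internally
#' all coordinates are 0-based half-open on the coding strand; minus-strand
#' input is reverse-complemented on construction so downstream code sees a
#' single orientation (the original strand is retained for reporting).
#'
#' @param id locus label (scalar character)
#' @param sequence DNA string over A,C,G,T,N (lower case accepted)
#' @param strand "+" or "-"; minus-strand sequences are reverse-complemented
#'   and exon coordinates flipped on construction
#' @param exons data.frame with columns `start`, `end` (0-based half-open),
#'   optional `phase` (0/1/2, GFF convention: bases to skip at exon start to
#'   reach the first complete codon; `NA` values are filled from cumulative
#'   coding length) and optional `role` (one of "catalytic", "cam", "tail",
#'   "alternative", "other")
#' @return an object of class `genomic_locus`
#' @export
genomic_locus <- function(id, sequence, strand = "+", exons = NULL) {
  if (!is_scalar_string(id) || !nzchar(id)) {
    stop_altexon("locus id must be a non-empty string")
  }
  if (!is_scalar_string(sequence) || !nzchar(sequence)) {
    stop_altexon("locus sequence must be a non-empty string")
  }
  sequence <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    stop_altexon("locus sequence contains invalid characters: ",
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  if (!strand %in% c("+", "-")) stop_altexon("strand must be '+' or '-'")

  if (is.null(exons)) {
    exons <- data.frame(start = integer(), end = integer(),
                        phase = integer(), role = character())
  }
  exons <- as.data.frame(exons)
  if (!all(c("start", "end") %in% names(exons))) {
    stop_altexon("exons must have columns 'start' and 'end'")
  }
  if (is.null(exons$phase)) exons$phase <- NA_integer_
  if (is.null(exons$role)) exons$role <- "other"

  if (strand == "-") {
    L <- nchar(sequence)
    sequence <- revcomp(sequence)
    if (nrow(exons)) {
      new_start <- L - exons$end
      new_end <- L - exons$start
      exons$start <- new_start
      exons$end <- new_end
    }
  }

  locus <- structure(
    list(id = id, sequence = sequence, strand = strand, exons = exons),
    class = "genomic_locus"
  )
  validate_locus(locus)
}

#' @noRd
validate_locus <- function(locus) {
  ex <- locus$exons
  L <- nchar(locus$sequence)
  if (nrow(ex)) {
    ex <- ex[order(ex$start), , drop = FALSE]
    rownames(ex) <- NULL
    if (any(ex$end <= ex$start)) {
      stop_altexon("exon intervals must satisfy end > start")
    }
    if (any(ex$start < 0L) || any(ex$end > L)) {
      stop_altexon("exon interval outside sequence bounds [0, ", L, ")")
    }
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
      stop_altexon("exon intervals overlap")
    }
    ex$phase <- fill_phases(ex)
    locus$exons <- ex
  }
  locus
}

# GFF-convention phase from cumulative coding length of preceding exons;
# keeps explicitly provided phases.
#' @noRd
fill_phases <- function(ex) {
  phase <- as.integer(ex$phase)
  cum <- 0L
  for (i in seq_len(nrow(ex))) {
    expected <- (3L - cum %% 3L) %% 3L
    if (is.na(phase[i])) phase[i] <- expected
    cum <- cum + (ex$end[i] - ex$start[i])
  }
  phase
}

#' @export
print.genomic_locus <- function(x, ...) {
  cat(sprintf("<genomic_locus> %s (%s strand, %d nt, %d exons)\n",
              x$id, x$strand, nchar(x$sequence), nrow(x$exons)))
  if (nrow(x$exons)) {
    ex <- x$exons
    cat(sprintf("  exon %2d: %7d-%7d  phase %d  %s\n",
                seq_len(nrow(ex)), ex$start + 1L, ex$end, ex$phase, ex$role),
        sep = "")
  }
  invisible(x)
}

#' Intron intervals of a locus
#'
#' Introns are the gaps between consecutive annotated exons, 0-based
#' half-open, indexed from 1 (intron k lies between exons k and k+1).
#'
#' @param locus a `genomic_locus`
#' @return data.frame with columns `index`, `start`, `end`
#' @export
introns <- function(locus) {
  ex <- locus$exons
  if (nrow(ex) < 2L) {
    return(data.frame(index = integer(), start = integer(), end = integer()))
  }
  data.frame(index = seq_len(nrow(ex) - 1L),
             start = ex$end[-nrow(ex)],
             end = ex$start[-1L])
}

#' Reverse complement of a DNA string
#' @param dna character scalar over A,C,G,T,N
#' @return character scalar
#' @export
revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Classify the 3' architecture of a DRP-1-like locus
#'
#' Vertebrate DRP-1 (DAPK2) loci carry two alternative 3' module sets
#' downstream of the catalytic-domain exons: a single ZIPk-like alternative
#' exon and the CaM-regulatory plus dimerization-tail exons. Teleost genomes
#' contain duplicated loci that retain only one of the two modules; this
#' classifier labels a locus by which modules its annotation carries.
#'
#' @param locus a `genomic_locus` whose exons carry `role` labels
#' @return list with `label` ("full", "zip_only" or "cam_only") and
#'   `evidence`, the role labels supporting it
#' @export
classify_locus <- function(locus) {
  roles <- locus$exons$role
  has_alt <- "alternative" %in% roles
  has_cam_tail <- "cam" %in% roles && "tail" %in% roles
  if (!has_alt && !has_cam_tail) {
    stop_altexon("not a DRP-1-like locus: neither an alternative exon nor ",
                 "cam+tail exons are annotated")
  }
  label <- if (has_alt && has_cam_tail) "full"
           else if (has_alt) "zip_only"
           else "cam_only"
  list(label = label,
       evidence = sort(unique(roles[roles %in% c("alternative", "cam", "tail")])))
}
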