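#' @noRd
codon_aa <- function(codon) {
  aa <- GENETIC_CODE_TABLE[codon]
  ifelse(is.na(aa), "X", aa)
}

# Expected synonymous site count of a sense codon (NG86). At each of the 3
# positions the synonymous fraction is taken over the changes that do not
# create a stop codon, so that syn + nonsyn fractions sum to 1 per position
# and N_sites + S_sites = 3 holds exactly per codon.
#' @noRd
codon_syn_sites <- function(codon) {
  aa0 <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(NT_BASES, substr(codon, pos, pos))
    muts <- vapply(alts, function(nt) {
      x <- codon
      substr(x, pos, pos) <- nt
      x
    }, character(1))
    aa <- codon_aa(muts)
    valid <- aa != "*"
    if (any(valid)) s <- s + sum(aa[valid] == aa0) / sum(valid)
  }
  s
}

# per-codon synonymous site table, built at install time
SYN_SITES <- local({
  sense <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
  stats::setNames(vapply(sense, codon_syn_sites, numeric(1)), sense)
})

#' @noRd
permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# Synonymous/nonsynonymous difference counts between two sense codons,
# averaged over all minimal mutational pathways (orderings of the differing
# positions). Pathways passing through a stop codon are excluded; if every
# ordering is blocked, all orderings are used with steps to/from stops
# counted as nonsynonymous.
#' @noRd
codon_diff_counts <- function(a, b) {
  diffpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diffpos) == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- permutations_of(diffpos)
  tally <- function(order, allow_stop) {
    cur <- a
    syn <- 0; nonsyn <- 0
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      aa_cur <- codon_aa(cur); aa_nxt <- codon_aa(nxt)
      if (!allow_stop && (aa_nxt == "*" || aa_cur == "*")) return(NULL)
      if (aa_cur == aa_nxt) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  counts <- Filter(Negate(is.null), lapply(paths, tally, allow_stop = FALSE))
  if (length(counts) == 0L) counts <- lapply(paths, tally, allow_stop = TRUE)
  Reduce(`+`, counts) / length(counts)
}

#' @noRd
is_countable_codon <- function(codon) {
  !grepl("[^ACGT]", codon) & codon_aa(codon) != "*" & codon != "---"
}

#' Nei-Gojobori dN/dS between two aligned codon sequences
#'
#' The 1986 counting method: expected synonymous/nonsynonymous site counts
#' from the standard genetic code, observed differences averaged over all
#' minimal mutational pathways per codon, and Jukes-Cantor correction
#' d = -3/4 ln(1 - 4p/3). Codon pairs containing a gap codon, an ambiguous
#' base or a stop codon are skipped pairwise. omega is flagged undefined
#' when dS = 0; proportions at or beyond 3/4 are flagged saturated and the
#' corresponding rate is `NA`.
#'
#' @param codon_row_a,codon_row_b equal-length codon vectors (or in-frame
#'   DNA strings, split internally)
#' @return object of class `dnds`: list with `N_sites`, `S_sites`, `Nd`,
#'   `Sd`, `pN`, `pS`, `dN`, `dS`, `omega`, `omega_defined`, `saturated`,
#'   `n_codons` (compared codons)
#' @export
nei_gojobori <- function(codon_row_a, codon_row_b) {
  if (length(codon_row_a) == 1L && nchar(codon_row_a[1]) > 3L) {
    codon_row_a <- split_codons(codon_row_a)
  }
  if (length(codon_row_b) == 1L && nchar(codon_row_b[1]) > 3L) {
    codon_row_b <- split_codons(codon_row_b)
  }
  if (length(codon_row_a) != length(codon_row_b)) {
    stop_altexon("codon rows differ in length")
  }
  keep <- is_countable_codon(codon_row_a) & is_countable_codon(codon_row_b)
  a <- codon_row_a[keep]
  b <- codon_row_b[keep]
  n_codons <- length(a)
  if (n_codons == 0L) stop_altexon("no comparable codon pairs")

  S <- (sum(SYN_SITES[a]) + sum(SYN_SITES[b])) / 2
  N <- 3 * n_codons - S
  Sd <- 0; Nd <- 0
  for (k in seq_len(n_codons)) {
    if (a[k] != b[k]) {
      cnt <- codon_diff_counts(a[k], b[k])
      Sd <- Sd + cnt[["syn"]]
      Nd <- Nd + cnt[["nonsyn"]]
    }
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  dS <- jc(pS)
  dN <- jc(pN)
  saturated <- pS >= 0.75 || pN >= 0.75
  omega_defined <- !saturated && !is.na(dS) && dS > 0 && !is.na(dN)
  omega <- if (omega_defined) dN / dS else NA_real_
  structure(list(N_sites = N, S_sites = S, Nd = Nd, Sd = Sd, pN = pN,
                 pS = pS, dN = dN, dS = dS, omega = omega,
                 omega_defined = omega_defined, saturated = saturated,
                 n_codons = n_codons),
            class = "dnds")
}

#' @export
print.dnds <- function(x, ...) {
  cat(sprintf("<dnds> %d codons: dN=%.4f dS=%.4f omega=%s\n", x$n_codons,
              x$dN, x$dS,
              if (x$omega_defined) sprintf("%.3f", x$omega) else "NA"))
  invisible(x)
}

#' Thread coding sequences onto a protein MSA
#'
#' Replaces each aligned residue by its source codon and each gap by
#' `"---"`, producing the codon alignment that the dN/dS screen runs on. A
#' terminal stop codon on a CDS is stripped; each CDS must otherwise
#' translate exactly to its ungapped protein row.
#'
#' @param protein_msa an `msa` object (or named aligned character vector)
#' @param cds_records named character vector of in-frame CDS, names matching
#'   the MSA rows
#' @return object of class `codon_alignment`: list with `codons` (named list
#'   of per-row codon vectors, all the MSA length)
#' @export
thread_codons <- function(protein_msa, cds_records) {
  aligned <- if (inherits(protein_msa, "msa")) protein_msa$sequences
             else protein_msa
  out <- vector("list", length(aligned))
  names(out) <- names(aligned)
  for (nm in names(aligned)) {
    cds <- cds_records[[nm]]
    if (is.null(cds)) stop_altexon("no CDS for MSA row '", nm, "'")
    codons <- split_codons(cds)
    aa <- codon_aa(codons)
    if (length(aa) && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    if (any(aa == "*")) {
      stop_altexon("internal stop codon in CDS '", nm, "' at codon ",
                   which(aa == "*")[1])
    }
    prot <- strsplit(gsub("-", "", aligned[[nm]]), "")[[1]]
    if (length(prot) != length(aa) || any(prot != aa)) {
      bad <- if (length(prot) != length(aa)) min(length(prot), length(aa)) + 1L
             else which(prot != aa)[1]
      stop_altexon("CDS '", nm, "' does not translate to its protein row ",
                   "(first mismatch at residue ", bad, ")")
    }
    row <- strsplit(aligned[[nm]], "")[[1]]
    threaded <- rep("---", length(row))
    threaded[row != "-"] <- codons
    out[[nm]] <- threaded
  }
  structure(list(codons = out), class = "codon_alignment")
}

#' Sliding-window mean dN/dS along a codon alignment
#'
#' Computes the mean of the defined pairwise omega values in each window of
#' `window_codons` codon columns, advancing by `step`. Windows in which no
#' pair has a defined omega (for example identical sequences, dS = 0) are
#' flagged.
#'
#' @param codon_alignment a `codon_alignment` from [thread_codons()]
#' @param window_codons window width in codons (>= 10)
#' @param step step in codons
#' @return data.frame with `start_codon`, `end_codon` (1-based inclusive),
#'   `mean_omega`, `n_defined` and `flagged`
#' @export
sliding_omega <- function(codon_alignment, window_codons = 30L, step = 10L) {
  stopifnot(inherits(codon_alignment, "codon_alignment"))
  rows <- codon_alignment$codons
  nc <- length(rows[[1]])
  if (window_codons < 10L) stop_altexon("window must be >= 10 codons")
  if (window_codons > nc) {
    stop_altexon("window (", window_codons, ") longer than alignment (", nc, ")")
  }
  starts <- seq(1L, nc - window_codons + 1L, by = step)
  res <- lapply(starts, function(s) {
    idx <- s:(s + window_codons - 1L)
    omegas <- c()
    nseq <- length(rows)
    for (i in seq_len(nseq - 1L)) {
      for (j in (i + 1L):nseq) {
        r <- tryCatch(nei_gojobori(rows[[i]][idx], rows[[j]][idx]),
                      error = function(e) NULL)
        if (!is.null(r) && r$omega_defined) omegas <- c(omegas, r$omega)
      }
    }
    data.frame(start_codon = s, end_codon = s + window_codons - 1L,
               mean_omega = if (length(omegas)) mean(omegas) else NA_real_,
               n_defined = length(omegas),
               flagged = length(omegas) == 0L)
  })
  do.call(rbind, res)
}
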