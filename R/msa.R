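#' Progressive multiple sequence alignment
#'
#' Aligns protein sequences progressively along a UPGMA guide tree built
#' from pairwise p-distances (1 - fractional identity of global pairwise
#' alignments). Profile-profile steps use mean-frequency profiles scored by
#' the substitution matrix with the same affine gap costs as the pairwise
#' aligner. The procedure is deterministic for a given input order; guide
#' tree ties are resolved by input index.
#'
#' @param records named character vector of >= 2 non-empty peptides
#' @param matrix substitution matrix, default [blosum62()]
#' @param gap_open,gap_extend affine gap costs
#' @return an object of class `msa`: list with `sequences` (named, aligned,
#'   equal length) and `weights` (Henikoff position-based, summing to 1)
#' @export
build_msa <- function(records, matrix = blosum62(), gap_open = 11,
                      gap_extend = 1) {
  n <- length(records)
  if (n < 2L) stop_altexon("need at least 2 sequences for an MSA")
  if (is.null(names(records)) || anyDuplicated(names(records))) {
    stop_altexon("records must have unique names")
  }
  if (any(!nzchar(records))) {
    stop_altexon("empty record: ", names(records)[!nzchar(records)][1])
  }

  if (n == 2L) {
    al <- align_global(records[[1]], records[[2]], matrix, gap_open, gap_extend)
    aligned <- stats::setNames(c(al$aligned_a, al$aligned_b), names(records))
    return(new_msa(aligned))
  }

  # guide tree from pairwise p-distances
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- align_global(records[[i]], records[[j]], matrix, gap_open,
                         gap_extend)
      D[i, j] <- D[j, i] <- 1 - percent_identity(al) / 100
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")  # UPGMA

  alpha <- rownames(matrix)
  profile_freq <- function(rows) {
    # rows: character matrix (sequences x columns); mean residue frequency,
    # gaps carry zero weight in the match score
    apply(rows, 2, function(col) {
      f <- tabulate(match(col, alpha), nbins = length(alpha))
      f / nrow(rows)
    })
  }

  clusters <- lapply(seq_len(n), function(i) {
    m <- matrix(strsplit(records[[i]], "")[[1]], nrow = 1)
    rownames(m) <- names(records)[i]
    m
  })
  merged <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    pick <- function(idx) if (idx < 0) clusters[[-idx]] else merged[[idx]]
    A <- pick(hc$merge[k, 1]); B <- pick(hc$merge[k, 2])
    fa <- profile_freq(A); fb <- profile_freq(B)
    scores <- t(fa) %*% matrix %*% fb
    res <- .gotoh_dp(scores, gap_open, gap_extend, FALSE)
    ops <- res$ops
    newA <- matrix("-", nrow(A), length(ops), dimnames = list(rownames(A), NULL))
    newB <- matrix("-", nrow(B), length(ops), dimnames = list(rownames(B), NULL))
    newA[, ops != 2L] <- A
    newB[, ops != 3L] <- B
    merged[[k]] <- rbind(newA, newB)
  }
  final <- merged[[n - 1L]]
  final <- final[names(records), , drop = FALSE]  # restore input order
  aligned <- stats::setNames(apply(final, 1, paste, collapse = ""),
                             names(records))
  new_msa(aligned)
}

#' @noRd
new_msa <- function(aligned) {
  stopifnot(length(unique(nchar(aligned))) == 1L)
  structure(list(sequences = aligned, weights = henikoff_weights(aligned)),
            class = "msa")
}

#' Construct an `msa` object from pre-aligned sequences
#'
#' @param aligned named character vector of equal-length gapped sequences
#' @return an `msa` object with Henikoff weights
#' @export
as_msa <- function(aligned) {
  if (length(aligned) < 2L) stop_altexon("an MSA needs >= 2 sequences")
  if (length(unique(nchar(aligned))) != 1L) {
    stop_altexon("aligned sequences must have equal length")
  }
  new_msa(aligned)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n",
              length(x$sequences), nchar(x$sequences[[1]])))
  invisible(x)
}

#' @noRd
msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unname(msa$sequences), ""))
}

#' Henikoff position-based sequence weights
#'
#' Each column contributes 1/(r * s) to every sequence, where r is the
#' number of distinct symbols in the column and s the count of the
#' sequence's own symbol (gaps are treated as a symbol type). Weights are
#' normalized to sum to 1, so adding a duplicated sequence redistributes
#' weight without changing weighted frequencies.
#'
#' @param aligned character vector of equal-length aligned sequences
#' @return numeric weights summing to 1
#' @export
henikoff_weights <- function(aligned) {
  m <- do.call(rbind, strsplit(unname(aligned), ""))
  w <- numeric(nrow(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    counts <- table(col)
    r <- length(counts)
    w <- w + 1 / (r * as.numeric(counts[col]))
  }
  stats::setNames(w / sum(w), names(aligned))
}

#' Weighted conservation profile of an MSA
#'
#' Per-column Henikoff-weighted residue frequencies (residues plus gap,
#' summing to 1) and information content in bits, computed as log2(20) minus
#' the Shannon entropy of the gap-excluded, renormalized residue
#' distribution — the quantity a sequence logo displays. The gap fraction is
#' reported separately; all-gap columns get `NA` information content.
#'
#' @param msa an `msa` object
#' @return list with `frequencies` (21 x n_columns matrix, rows are the 20
#'   residues plus `"-"`), `information` (bits, in \[0, log2(20)\]) and
#'   `gap_fraction`
#' @export
conservation_profile <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  m <- msa_matrix(msa)
  w <- msa$weights
  alpha <- c(rownames(blosum62()), "-")
  nc <- ncol(m)
  freq <- matrix(0, length(alpha), nc, dimnames = list(alpha, NULL))
  for (j in seq_len(nc)) {
    f <- vapply(alpha, function(a) sum(w[m[, j] == a]), numeric(1))
    freq[, j] <- f / sum(f)
  }
  gap_fraction <- freq["-", ]
  information <- vapply(seq_len(nc), function(j) {
    p <- freq[seq_len(20), j]
    if (sum(p) <= 0) return(NA_real_)
    p <- p / sum(p)
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  }, numeric(1))
  list(frequencies = freq, information = information,
       gap_fraction = gap_fraction)
}
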