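# Independent oracles: deliberately different algorithms/implementations
# from the package code they check.

# --- exhaustive affine-gap DP without Gotoh's three-state decomposition ---
# A gap of length k costs gap_open + k * gap_extend; gaps are closed in one
# step by looking back over every possible gap length.
oracle_global_score <- function(a, b, S, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  D <- matrix(-Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in 0:n) {
    for (j in 0:m) {
      if (i == 0 && j == 0) next
      best <- -Inf
      if (i > 0 && j > 0) best <- D[i, j] + S[ca[i], cb[j]]
      if (j > 0) {
        k <- 1:j
        best <- max(best, max(D[i + 1, j + 1 - k] - (gap_open + k * gap_extend)))
      }
      if (i > 0) {
        k <- 1:i
        best <- max(best, max(D[i + 1 - k, j + 1] - (gap_open + k * gap_extend)))
      }
      D[i + 1, j + 1] <- best
    }
  }
  D[n + 1, m + 1]
}

oracle_local_score <- function(a, b, S, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  D <- matrix(0, n + 1, m + 1)
  for (i in 1:n) {
    for (j in 1:m) {
      best <- D[i, j] + S[ca[i], cb[j]]
      k <- 1:j
      best <- max(best, max(D[i + 1, j + 1 - k] - (gap_open + k * gap_extend)))
      k <- 1:i
      best <- max(best, max(D[i + 1 - k, j + 1] - (gap_open + k * gap_extend)))
      D[i + 1, j + 1] <- max(0, best)
    }
  }
  max(D)
}

# --- brute-force splice-site scan: test every dinucleotide directly ---
oracle_splice_sites <- function(sequence, region_start, region_end) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  acc <- c(); don <- c()
  for (p in region_start:(region_end - 1)) {
    if (p >= 2 && substr(sequence, p - 1, p) == "AG") acc <- c(acc, p)
    if (p <= L - 2 && substr(sequence, p + 1, p + 2) == "GT") don <- c(don, p)
  }
  list(acceptors = acc, donors = don)
}

# --- candidate-exon enumeration with seqinr translation ---
oracle_candidates <- function(locus, intron_index, min_aa, require_stop) {
  ex <- locus$exons
  intr <- altexon::introns(locus)
  is <- intr$start[intron_index]; ie <- intr$end[intron_index]
  q <- (3 - sum(ex$end[1:intron_index] - ex$start[1:intron_index]) %% 3) %% 3
  seqc <- strsplit(locus$sequence, "")[[1]]
  out <- list()
  for (p in (is + 2):(ie - 1)) {
    if (!(seqc[p - 1] == "A" && seqc[p] == "G")) next
    cds_chars <- seqc[(p + q + 1):ie]
    n_cod <- length(cds_chars) %/% 3
    if (n_cod == 0) next
    aa <- seqinr::translate(cds_chars[1:(3 * n_cod)])
    stop_i <- which(aa == "*")[1]
    if (!is.na(stop_i)) {
      pep <- paste(aa[seq_len(stop_i - 1)], collapse = "")
      cand_end <- p + q + 3 * stop_i
      has_stop <- TRUE
    } else {
      pep <- paste(aa, collapse = "")
      cand_end <- ie
      has_stop <- FALSE
    }
    if (nchar(pep) < min_aa) next
    if (grepl("X", pep)) next
    if (require_stop && !has_stop) next
    out[[length(out) + 1]] <- data.frame(start = p, end = cand_end,
                                         aa_length = nchar(pep),
                                         peptide = pep,
                                         stop_at_end = has_stop)
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      aa_length = integer(), peptide = character(),
                      stop_at_end = logical()))
  }
  df <- do.call(rbind, out)
  df[order(-df$aa_length, df$start), ]
}

# --- brute-force heptad-run enumeration over all (start, length) pairs ---
oracle_heptads <- function(peptide, hydro, min_repeats, max_mismatch) {
  chars <- strsplit(peptide, "")[[1]]
  L <- length(chars)
  is_h <- chars %in% hydro
  budget_ok <- function(pos) sum(!is_h[pos]) <= max_mismatch
  out <- list()
  for (start in seq_len(L)) {
    len <- min_repeats
    repeat {
      pos <- start + 7 * (seq_len(len) - 1)
      if (pos[len] > L) break
      if (budget_ok(pos)) {
        left <- start - 7
        right <- pos[len] + 7
        maximal <- !(left >= 1 && budget_ok(c(left, pos))) &&
          !(right <= L && budget_ok(c(pos, right)))
        if (maximal) out[[length(out) + 1]] <- pos
      }
      len <- len + 1
    }
  }
  unique(out)
}

# --- pathway counting with hardcoded orderings and seqinr translation ---
oracle_codon_counts <- function(a, b) {
  aa_of <- function(codon) seqinr::translate(strsplit(codon, "")[[1]])
  dp <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(dp) == 0) return(c(syn = 0, nonsyn = 0))
  orderings <- switch(as.character(length(dp)),
    "1" = list(dp),
    "2" = list(dp, rev(dp)),
    "3" = list(dp[c(1, 2, 3)], dp[c(1, 3, 2)], dp[c(2, 1, 3)],
               dp[c(2, 3, 1)], dp[c(3, 1, 2)], dp[c(3, 2, 1)]))
  walk <- function(ord, allow_stop) {
    cur <- a; syn <- 0; nonsyn <- 0
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (!allow_stop && (aa_of(nxt) == "*" || aa_of(cur) == "*")) return(NULL)
      if (aa_of(cur) == aa_of(nxt)) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  res <- Filter(Negate(is.null), lapply(orderings, walk, allow_stop = FALSE))
  if (!length(res)) res <- lapply(orderings, walk, allow_stop = TRUE)
  Reduce(`+`, res) / length(res)
}

# random test sequences
random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

random_sense_codon <- function() {
  repeat {
    cod <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                 collapse = "")
    if (seqinr::translate(strsplit(cod, "")[[1]]) != "*") return(cod)
  }
}
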