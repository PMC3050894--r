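#' Scan a peptide for leucine-zipper-like heptad repeats
#'
#' A zipper interface is a run of hydrophobic residues spaced exactly 7
#' apart (the "d" positions of the coiled-coil abcdefg repeat). The scan
#' reports every maximal run of positions p, p+7, p+14, ... of length at
#' least `min_repeats` in which at most `max_mismatch` positions fall
#' outside the hydrophobic set. Only the d register is scored; runs in
#' different registers are reported separately. Alanine is deliberately not
#' in the default hydrophobic set, so a d-to-A mutant abolishes detection.
#'
#' @param peptide amino-acid string
#' @param hydrophobic_set residues accepted at d positions (default
#'   L, I, V, M, F)
#' @param min_repeats minimum number of d positions in a run (>= 2)
#' @param max_mismatch maximum non-hydrophobic d positions tolerated
#' @return list of hits, each with `d_positions` (1-based, step 7),
#'   `residues_at_d`, `n_repeats` and `score` (hydrophobic fraction);
#'   sorted by start position. Empty list if the peptide is too short.
#' @export
scan_heptads <- function(peptide, hydrophobic_set = c("L", "I", "V", "M", "F"),
                         min_repeats = 3L, max_mismatch = 0L) {
  stopifnot(is_scalar_string(peptide))
  if (min_repeats < 2L) stop_altexon("min_repeats must be >= 2")
  if (length(hydrophobic_set) == 0L) {
    stop_altexon("hydrophobic_set must be non-empty")
  }
  chars <- strsplit(peptide, "")[[1]]
  L <- length(chars)
  hits <- list()
  if (L < (min_repeats - 1L) * 7L + 1L) return(hits)
  hydro <- chars %in% hydrophobic_set

  for (reg in 1:7) {
    pos <- seq(reg, L, by = 7L)
    if (length(pos) < min_repeats) next
    ok <- hydro[pos]
    np <- length(pos)
    for (i in seq_len(np)) {
      for (j in i:np) {
        len <- j - i + 1L
        if (len < min_repeats) next
        mm <- sum(!ok[i:j])
        if (mm > max_mismatch) next
        # maximality: no extension left or right stays within budget
        ext_left <- i > 1L && (mm + !ok[i - 1L]) <= max_mismatch
        ext_right <- j < np && (mm + !ok[j + 1L]) <= max_mismatch
        if (ext_left || ext_right) next
        d_pos <- pos[i:j]
        hits[[length(hits) + 1L]] <- list(
          d_positions = d_pos,
          residues_at_d = chars[d_pos],
          n_repeats = len,
          score = sum(ok[i:j]) / len)
      }
    }
  }
  if (length(hits)) {
    hits <- hits[order(vapply(hits, function(h) h$d_positions[1], numeric(1)))]
  }
  hits
}

#' Model a d-position alanine mutant
#'
#' Replaces every d-position residue of a heptad hit with alanine — the in
#' silico counterpart of the loss-of-function zipper mutant in which the
#' hydrophobic interface residues are substituted to A. Re-scanning the
#' mutant with the default hydrophobic set finds no hit at that register.
#'
#' @param peptide amino-acid string
#' @param hit a hit from [scan_heptads()]
#' @return the mutated peptide
#' @export
mutate_d_positions <- function(peptide, hit) {
  stopifnot(is_scalar_string(peptide), is.list(hit),
            !is.null(hit$d_positions))
  pos <- hit$d_positions
  if (any(pos < 1L) || any(pos > nchar(peptide))) {
    stop_altexon("d position out of range 1..", nchar(peptide))
  }
  chars <- strsplit(peptide, "")[[1]]
  chars[pos] <- "A"
  paste(chars, collapse = "")
}
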