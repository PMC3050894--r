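#!/usr/bin/env Rscript
# Look for leucine-zipper-like heptad repeats (hydrophobic d positions every
# 7 residues) in the candidate peptide, and verify that substituting the d
# positions to alanine abolishes detection — the in silico analogue of a
# zipper loss-of-function mutant.

suppressPackageStartupMessages(library(altexon))

cand <- readLines("results/candidate_peptide.txt")
hits <- scan_heptads(cand, min_repeats = 3)
cat(sprintf("heptad hits (>= 3 repeats): %d\n", length(hits)))

if (length(hits)) {
  tab <- do.call(rbind, lapply(hits, function(h) {
    data.frame(d_positions = paste(h$d_positions, collapse = ","),
               residues = paste(h$residues_at_d, collapse = ""),
               n_repeats = h$n_repeats, score = h$score)
  }))
  write.table(tab, "results/heptads.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  best <- hits[[which.max(vapply(hits, `[[`, numeric(1), "n_repeats"))]]
  cat(sprintf("strongest register: d at %s (%s)\n",
              paste(best$d_positions, collapse = "/"),
              paste(best$residues_at_d, collapse = "/")))
  mut <- mutate_d_positions(cand, best)
  still <- Filter(function(h) any(h$d_positions %in% best$d_positions),
                  scan_heptads(mut, min_repeats = 3))
  cat(sprintf("after d-to-A substitution: %d hit(s) at that register (expect 0)\n",
              length(still)))
} else {
  cat("no heptad repeat in this candidate (zipper-less implant)\n")
  write.table(data.frame(), "results/heptads.tsv", row.names = FALSE)
}
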