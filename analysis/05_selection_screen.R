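#!/usr/bin/env Rscript
# Test whether the exon's cross-species conservation looks protein-coding:
# thread the ortholog CDS onto the protein MSA and estimate Nei-Gojobori
# dN/dS pairwise and in sliding windows.

suppressPackageStartupMessages(library(altexon))

data_dir <- "results/data"
cds <- read_fasta(file.path(data_dir, "orthologs_cds.fasta"), type = "dna")
prots <- vapply(cds, function(s) sub("\\*$", "", translate_dna(s)),
                character(1))
msa <- build_msa(prots)
aln <- thread_codons(msa, cds)

nms <- names(aln$codons)
pairs <- t(combn(nms, 2))
pw <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
  r <- nei_gojobori(aln$codons[[pairs[k, 1]]], aln$codons[[pairs[k, 2]]])
  data.frame(a = pairs[k, 1], b = pairs[k, 2],
             N_sites = round(r$N_sites, 2), S_sites = round(r$S_sites, 2),
             pN = round(r$pN, 4), pS = round(r$pS, 4),
             dN = round(r$dN, 4), dS = round(r$dS, 4),
             omega = ifelse(r$omega_defined, round(r$omega, 4), NA))
}))
write.table(pw, "results/selection_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("mean pairwise omega: %.3f over %d pairs\n",
            mean(pw$omega, na.rm = TRUE), nrow(pw)))

win <- sliding_omega(aln, window_codons = 30, step = 10)
write.table(win, "results/selection_windows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
frac <- mean(win$mean_omega[!win$flagged] < 1)
cat(sprintf("%d windows; %.0f%% with omega < 1 (purifying); window means %.2f-%.2f\n",
            nrow(win), 100 * frac, min(win$mean_omega, na.rm = TRUE),
            max(win$mean_omega, na.rm = TRUE)))
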