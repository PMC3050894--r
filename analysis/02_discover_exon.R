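#!/usr/bin/env Rscript
# Scan the intron downstream of the catalytic exons for splice-acceptor-led
# open reading frames and compare the candidates against the simulator's
# hidden truth.

suppressPackageStartupMessages(library(altexon))

data_dir <- "results/data"
locus_seq <- read_fasta(file.path(data_dir, "locus.fasta"), type = "dna")
locus <- read_gff_exons(file.path(data_dir, "locus.gff"),
                        genomic_locus(names(locus_seq)[1], locus_seq[[1]]))
truth <- jsonlite::read_json(file.path(data_dir, "truth.json"))

cands <- find_candidate_exons(locus, truth$intron_index, min_aa = 100)
disc <- attr(cands, "discarded")
cat(sprintf("intron %d: %d candidate(s) >= 100 aa (discarded: %d short, %d ambiguous)\n",
            truth$intron_index, nrow(cands), disc$min_aa, disc$ambiguous))

tab <- data.frame(start_1based = cands$start + 1L, end_1based = cands$end,
                  phase = cands$phase, aa_length = cands$aa_length,
                  acceptor_context = cands$acceptor_context,
                  stop_at_end = cands$stop_at_end)
write.table(tab, "results/candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

hit <- cands$start[1] == truth$exon_start && cands$end[1] == truth$exon_end
cat(sprintf("top candidate %d-%d (%d aa): %s the hidden implant\n",
            tab$start_1based[1], tab$end_1based[1], tab$aa_length[1],
            if (hit) "matches" else "MISSES"))
writeLines(cands$peptide[1], "results/candidate_peptide.txt")
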