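#!/usr/bin/env Rscript
# Quantify the candidate exon's homology to the paralog domain (percent
# identity and similarity, BLOSUM62) and build the ortholog MSA with its
# Henikoff-weighted conservation profile.

suppressPackageStartupMessages(library(altexon))

data_dir <- "results/data"
cand <- readLines("results/candidate_peptide.txt")
paralog <- read_fasta(file.path(data_dir, "paralog.fasta"), type = "protein")

gl <- align_global(cand, paralog[[1]])
cat(sprintf("candidate vs paralog (global): %d%% identity, %d%% similarity, score %.0f\n",
            round(percent_identity(gl)), round(percent_similarity(gl)),
            gl$score))
lo <- align_local(cand, paralog[[1]])
cat(sprintf("best local block: candidate %d-%d vs paralog %d-%d (%d%% identity)\n",
            lo$a_range[1], lo$a_range[2], lo$b_range[1], lo$b_range[2],
            round(percent_identity(lo))))

# conservation of the ortholog set (translated from the CDS records)
cds <- read_fasta(file.path(data_dir, "orthologs_cds.fasta"), type = "dna")
prots <- vapply(cds, function(s) sub("\\*$", "", translate_dna(s)),
                character(1))
msa <- build_msa(prots)
prof <- conservation_profile(msa)
consensus <- rownames(prof$frequencies)[apply(prof$frequencies, 2, which.max)]
out <- data.frame(column = seq_along(prof$information),
                  information_bits = round(prof$information, 4),
                  gap_fraction = round(prof$gap_fraction, 4),
                  consensus = consensus)
write.table(out, "results/conservation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_fasta(msa$sequences, "results/orthologs_msa.fasta")
cat(sprintf("ortholog MSA: %d x %d; mean information %.2f bits (max %.2f)\n",
            length(msa$sequences), nchar(msa$sequences[[1]]),
            mean(prof$information), log2(20)))
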