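#!/usr/bin/env Rscript
# Generate the ground-truthed study inputs: a DRP-1-like genomic locus with
# a hidden ZIPk-like intronic exon, an ortholog CDS set for the selection
# screen, and a clade-structured kinase-domain family for the phylogeny.
# Everything downstream (02-07) reads from results/data/.

suppressPackageStartupMessages(library(altexon))

data_dir <- "results/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 2026L

# locus: 8 catalytic exons, CaM + tail exons downstream, implant at 70%
# identity to the paralog domain (the ZIPk-like extra-catalytic region)
sim <- simulate_locus(target_identity_pct = 70, exon_aa_length = 200,
                      seed = seed)
paths <- write_locus_bundle(sim, data_dir)
cat(sprintf("locus: %d nt, %d annotated exons; implant hidden at %d-%d (phase %d)\n",
            nchar(sim$locus$sequence), nrow(sim$locus$exons),
            sim$truth$exon_start + 1, sim$truth$exon_end, sim$truth$phase))

# orthologs of the implanted exon: 5 vertebrate-like taxa, purifying
# selection (omega 0.15) over most codons with a neutral C-terminal patch
# emulating the Ser/Thr-rich unconstrained tail
tree <- ape::read.tree(
  text = "(((human:0.04,mouse:0.04):0.03,cow:0.06):0.05,(chicken:0.10,fish:0.16):0.05);")
n_cod <- nchar(sim$truth$cds) / 3
omega <- rep(0.15, n_cod)
omega[(n_cod - 36):n_cod] <- 1
orth <- evolve_cds(sim$truth$cds, tree, omega_profile = omega, kappa = 2,
                   seed = seed + 1)
write_fasta(orth, file.path(data_dir, "orthologs_cds.fasta"))
ape::write.tree(tree, file.path(data_dir, "ortholog_tree.nwk"))
cat(sprintf("orthologs: %d taxa, %d codons, purifying omega 0.15 with a %d-codon neutral tail\n",
            length(orth), n_cod, 37))

# kinase-domain family: three ingroup clades (DAPk-, DRP-1- and ZIPk-like)
# plus a distant DRAK-like outgroup clade
fam <- make_clade_family(n_clades = 4, taxa_per_clade = 4,
                         within_div = 0.08, between_div = 0.35,
                         length = 280, seed = seed + 2)
nm <- names(fam$proteins)
names(fam$proteins) <- sub("clade1", "DAPk", nm)
names(fam$proteins) <- sub("clade2", "DRP1", names(fam$proteins))
names(fam$proteins) <- sub("clade3", "ZIPk", names(fam$proteins))
names(fam$proteins) <- sub("clade4", "DRAK", names(fam$proteins))
write_fasta(fam$proteins, file.path(data_dir, "kinase_family.fasta"))
cat(sprintf("family: %d sequences in 4 clades (DRAK clade is the outgroup)\n",
            length(fam$proteins)))
cat("inputs written to", data_dir, "\n")
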