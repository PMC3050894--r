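# Shared sequence-level constants (this file loads before the modules that
# use them at build time).

# 64-codon lookup from the Biostrings standard code ("*" marks stops).
GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

NT_BASES <- c("A", "C", "G", "T")

transition_of <- c(A = "G", G = "A", C = "T", T = "C")

# Stop codons in all three reading frames and no purine pair that could form
# a spurious AG splice acceptor: TAA at offsets 0, 4 and 8.
TRAP_BLOCK <- "TAACTAACTAA"
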