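---
title: "Methods: discovering and characterizing intronic alternative coding exons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and characterizing intronic alternative coding exons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altexon)
```

## The problem

Some genes hide an extra protein-coding exon inside an annotated intron. The
motivating case is the vertebrate DAP-kinase family: the DRP-1 (DAPK2) locus
carries, between its catalytic-domain exons and its CaM-regulatory exons, a
single unannotated exon whose product resembles the extra-catalytic
(dimerization) domain of the paralog ZIPk (DAPK3). Splicing this exon in
place of the CaM/tail exons would produce a ZIPk-like isoform from the DRP-1
locus. Recognizing such an exon computationally needs four kinds of
evidence, and `altexon` implements one stage per kind:

1. **Discovery** — a splice-acceptor-led open reading frame of substantial
   length inside the intron (`find_candidate_exons`).
2. **Homology** — quantified similarity of the candidate peptide to a
   paralog domain (`align_global`, `align_local`, `build_msa`,
   `conservation_profile`).
3. **Motif structure** — a leucine-zipper-like heptad repeat marking a
   dimerization interface (`scan_heptads`, `mutate_d_positions`).
4. **Selection and phylogeny** — protein-coding-like evolution (dN/dS < 1,
   `nei_gojobori`, `sliding_omega`) and a paralog-family tree placing the
   sequences (`neighbor_joining`, `bootstrap_support`,
   `root_with_outgroup`).

Because real loci arrive via accession downloads, the package ships a
seeded simulator (`simulate_locus`, `evolve_cds`, `make_clade_family`) that
builds ground-truthed inputs for every stage, so the whole analysis is
verifiable offline.

## Coordinates and locus model

Internally every interval is 0-based half-open on the coding strand;
GFF3 input/output is 1-based inclusive, converted exactly at the boundary.
Minus-strand loci are reverse-complemented on construction so discovery has
a single code path; the original strand is kept for reporting. Exon `phase`
follows the GFF convention: the number of bases to skip at the exon start
to reach the first complete codon, and is validated (or filled) from the
cumulative coding length of the preceding exons.

## Discovery model

The splice model is deliberately minimal: an acceptor is any AG dinucleotide
immediately 5' of a candidate boundary, a donor any GT immediately 3'. A
polypyrimidine **context score** (pyrimidine count in the 15 nt upstream of
the AG) is reported but not used as a filter; no position weight matrix is
fitted, because a PWM would add parameters that nothing in the downstream
analysis constrains.

For every acceptor boundary in the chosen intron, translation starts at the
boundary *in the frame continuing the upstream exons' phase* — the
candidate is assumed to splice onto the upstream exons in frame, as an
internal ATG is not required for an internal coding exon. The ORF extends
to the first in-frame stop codon or the intron end. Filters: minimum
peptide length `min_aa` (default 100 — a deliberately loose screen given
that known exons of this type encode 165–220 residues), no ambiguous base
inside the ORF, and optionally a required terminal stop. Candidates are
ranked by peptide length (ties: leftmost first). Donor-bounded internal
exons are out of scope: the motivating exon type is 3'-terminal-style,
ending at a conserved stop.

## Pairwise alignment and percentages

`align_global` and `align_local` are Needleman–Wunsch–Gotoh and
Smith–Waterman with affine gaps, implemented in C++ over a precomputed
cell-score matrix. Defaults are the BLAST protein conventions: BLOSUM62,
gap open 11, gap extend 1, with a gap of length L costing
`open + L * extend`. Ties are broken deterministically (aligned pair over
gap-in-`a` over gap-in-`b`). **Percent identity** divides identical aligned
pairs by the number of aligned residue pairs (gap columns excluded), which
is how identity over a stated residue range is conventionally quoted; an
alignment-length denominator is available via `denominator = "columns"`.
**Percent similarity** counts pairs with a strictly positive matrix score
("positives"); restricting the matrix to the 20 standard residues keeps the
diagonal positive, so identity is always a subset of similarity. Full
precision is kept internally; rounding to integers happens only in reports.

## Progressive MSA and conservation

`build_msa` aligns progressively along a UPGMA guide tree built from
pairwise p-distances, merging profiles scored by mean residue frequencies
under the same matrix and gap costs. This replaces CLUSTALW-style
heuristics with a small, documented procedure; exact reproduction of any
particular aligner's output is a non-goal, since the conservation
conclusions are robust to the aligner at the divergences involved.
Sequence weights are Henikoff position-based (gap treated as a symbol
type), so duplicated sequences share weight rather than double-counting.
Column information content is `log2(20)` minus the Shannon entropy of the
gap-excluded, renormalized residue distribution — the quantity a sequence
logo draws — with the gap fraction reported separately and all-gap columns
flagged `NA`.

## Heptad-repeat scan

Coiled-coil zipper interfaces show hydrophobic residues every 7 positions
(the d register of the abcdefg repeat). `scan_heptads` reports every
maximal run p, p+7, p+14, … of at least `min_repeats` positions with at
most `max_mismatch` non-hydrophobic residues, per register. The default
hydrophobic set is {L, I, V, M, F}; alanine is deliberately excluded so
that the canonical loss-of-function construct — every d position mutated to
A, modeled by `mutate_d_positions` — abolishes detection. Only the d
register is scored (no a/d pairing, no Lupas-style propensity matrix): the
scan formalizes exactly the evidence that identifies such zippers in
practice, heptad spacing plus d-position hydrophobicity, without importing
unverifiable parameters.

## Selection screen

`thread_codons` maps a protein MSA back onto its coding sequences (gaps
become `---`; each CDS must re-translate to its row). `nei_gojobori`
implements the 1986 counting method: per-codon synonymous site fractions
from the standard code, observed differences averaged over all minimal
mutational pathways, Jukes–Cantor correction `d = -3/4 ln(1 - 4p/3)`.
Numerical conventions:

* mutations to stop codons are excluded from the per-position site
  denominator, so `N_sites + S_sites = 3` holds exactly per codon;
* pathways through stop codons are excluded; if every ordering is blocked
  the method falls back to all orderings;
* gap-containing codon pairs are dropped pairwise, not listwise;
* `omega` is reported as undefined (`NA` plus a flag) when `dS = 0`, and
  proportions ≥ 3/4 raise a saturation flag rather than a fake number.

`sliding_omega` reports the mean of defined pairwise omegas per window
(default 30 codons, step 10; minimum window 10). A single 30-codon window
is a noisy ratio estimate with upward Jensen bias, so calibration
statements are made about means over windows and replicates, not about
individual windows.

## Phylogeny

Distances are p-distance or Poisson-corrected `-ln(1 - p)` over shared
non-gap columns (at least 20 required per pair; saturation is an error,
never a silent cap). `neighbor_joining` is the canonical Saitou–Nei
agglomeration with the Q criterion, exact on additive matrices to 1e-9;
Q ties break on the lexicographically smallest leaf-label pair and negative
branch lengths are clamped to zero with the deficit recorded.
`bootstrap_support` resamples columns with replacement, rebuilds the tree,
and annotates each internal edge of the full-data tree with the percentage
of replicates containing the same bipartition; replicate r draws from an
RNG stream derived from `(seed, r)`, making supports reproducible and
independent of both evaluation order and taxon input order.
`root_with_outgroup` verifies the outgroup is monophyletic in the unrooted
tree and places the root at the midpoint of the separating edge.

Neighbor joining with bootstrap deliberately replaces maximum-likelihood
inference here: the conclusions carried by this kind of tree (clean
separation of paralog clusters, their branching order) are topological, and
NJ is fully specifiable and testable against exhaustive topology search at
desk scale. An ML mode is an explicit non-goal.

## The simulator: what it emulates, and what it does not

`simulate_locus` builds a plausible discovery substrate: catalytic exons of
random coding sequence separated by GT…AG introns, the implant (the paralog
domain mutated to a target percent identity, back-translated with uniform
codon choice) preceded by an AG acceptor and ended by a stop codon, and
optional CaM/tail exons downstream. The implanted exon is withheld from the
emitted GFF, so discovery is a genuine blind test, and stop-codon blocks
flank the implant so that no spliced ORF from a spurious acceptor can read
through it — the implant is the longest recoverable candidate by
construction. Defaults: 8 catalytic exons (the exon count upstream of the
discovery intron in DRP-1-like loci), 200-residue implant (inside the
observed 165–220 aa range), 70% identity to the paralog, introns 750–1200
nt, GC 0.45.

`evolve_cds` evolves a CDS along a tree by proposal–acceptance: proposals
are Poisson with mean `branch length x nt length` (branch lengths are
expected proposed mutations per nucleotide site), targets drawn with
transition:transversion weight `kappa` (default 2, a realistic vertebrate
value), nonsense proposals rejected, synonymous proposals accepted, and
nonsynonymous ones accepted with the codon's omega. Calibration runs are
performed at `kappa = 1` because the Nei–Gojobori counting method assumes
no transition bias; with `kappa = 2` it is known to underestimate omega,
which is a documented limitation of the estimator rather than of the
simulation. `make_clade_family` realizes a star of clades by point
substitutions and returns the true tree for topology-recovery tests.

What the simulator does **not** emulate — and therefore what passing tests
cannot show about real data: indels in coding evolution (substitutions
only), realistic splice-site motif strength beyond the GT/AG consensus,
codon-usage bias (back-translation is uniform), intron length and GC
heterogeneity of real genomes, and sequencing/annotation error. A candidate
that passes on simulated loci still needs transcript-level evidence in
real data.

## Problem sizes and determinism

The shipped verification runs use: 100 simulated loci for exact-recovery
and identity-calibration checks; 200 random peptide pairs (≤ 30-mers)
against an independent exhaustive alignment DP; 200 random peptides against
a brute-force heptad enumeration plus 100 simulated zipper mutants; 100
additive 5–8-taxon matrices and 100 exhaustive 6-taxon least-squares
topology searches for NJ; 20 two-clade simulations at 100 bootstrap
replicates; and 50 neutral plus 10 purifying (600-codon, two-taxon, total
tree length 1.5 per codon site) dN/dS recoveries. These sizes keep the full
suite to a few minutes on one core while leaving the statistical bands
comfortably wider than run-to-run noise. Every random quantity flows from
an explicit seed through `derive_seed(seed, index)` streams, so all outputs
— simulated FASTA/GFF bundles, bootstrap supports, pipeline JSON reports —
are byte-reproducible.

## Known limitations

* The discovery scan assumes the candidate continues the upstream reading
  frame; exons that begin translation at an internal ATG are not found.
* NG86 dN/dS is a counting method: it underestimates omega under strong
  transition bias and has no site-model likelihood machinery; windows
  shorter than ~30 codons are dominated by sampling noise.
* The progressive MSA has no iterative refinement; at high divergence
  (p-distance ≳ 0.5) guide-tree errors can propagate.
* Bootstrap supports from NJ are not comparable numerically to ML
  bootstrap values from the same data.
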