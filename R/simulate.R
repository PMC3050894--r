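#' Random DNA with a given GC content
#' @param n length in nt
#' @param gc GC fraction in \[0.3, 0.7\]
#' @return DNA string
#' @export
random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Random peptide over the 20 standard residues
#' @param n length in residues
#' @return amino-acid string
#' @export
random_peptide <- function(n) {
  paste(sample(rownames(blosum62()), n, replace = TRUE), collapse = "")
}

#' Mutate a peptide to a target percent identity
#'
#' Substitutes `round(L * (1 - target/100))` positions, chosen without
#' replacement, each to a uniformly drawn different residue; the ungapped
#' identity to the input is therefore the target up to rounding.
#'
#' @param peptide amino-acid string
#' @param target_identity_pct target identity in \[50, 100\]
#' @return mutated peptide
#' @export
mutate_to_identity <- function(peptide, target_identity_pct) {
  stopifnot(target_identity_pct >= 50, target_identity_pct <= 100)
  chars <- strsplit(peptide, "")[[1]]
  k <- round(length(chars) * (1 - target_identity_pct / 100))
  if (k > 0L) {
    pos <- sample.int(length(chars), k)
    aa <- rownames(blosum62())
    for (p in pos) chars[p] <- sample(setdiff(aa, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' @noRd
mutate_fraction <- function(peptide, rate) {
  chars <- strsplit(peptide, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  aa <- rownames(blosum62())
  for (p in hit) chars[p] <- sample(setdiff(aa, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Simulate a multi-exon kinase locus with an implanted intronic exon
#'
#' Emulates the discovery substrate: catalytic-domain coding exons separated
#' by GT...AG introns, followed (optionally) by CaM-regulatory and
#' dimerization-tail exons. A ZIPk-like alternative exon — the paralog
#' domain mutated to `target_identity_pct` and back-translated with uniform
#' codon choice — is implanted in the intron downstream of the last
#' catalytic exon, preceded by an AG acceptor and ended by a stop codon.
#' The implanted exon is withheld from the annotation, making discovery a
#' blind test; its coordinates are returned as ground truth. Stop-codon
#' blocks flanking the implant guarantee that no spliced open reading frame
#' from a spurious acceptor can extend past it, so the implant is the
#' longest recoverable candidate by construction.
#'
#' @param paralog_domain peptide to implant (default: random peptide of
#'   `exon_aa_length`, emulating the ZIPk extra-catalytic domain)
#' @param n_catalytic_exons number of catalytic coding exons (default 8,
#'   the exon count upstream of the discovery intron in DRP-1-like loci)
#' @param exon_aa_length implant length in residues (default 200, inside
#'   the 165-220 aa range such exons occupy); ignored when
#'   `paralog_domain` is supplied
#' @param target_identity_pct identity of the implant to the paralog domain
#' @param intron_length_range min/max intron length in nt
#' @param include_cam_tail also emit CaM and tail exons downstream
#' @param gc_content GC fraction of non-coding sequence
#' @param catalytic_aa total catalytic-domain length in residues
#' @param seed RNG seed (required; output is byte-reproducible)
#' @return list with `locus` (annotated `genomic_locus`, implant withheld),
#'   `paralog` (named peptide), and `truth` (implant interval 0-based
#'   half-open including the stop codon, phase, peptide, acceptor and stop
#'   positions, CDS used)
#' @export
simulate_locus <- function(paralog_domain = NULL, n_catalytic_exons = 8L,
                           exon_aa_length = 200L, target_identity_pct = 70,
                           intron_length_range = c(750L, 1200L),
                           include_cam_tail = TRUE, gc_content = 0.45,
                           catalytic_aa = 270L, seed) {
  if (missing(seed)) stop_altexon("seed is required")
  stopifnot(gc_content >= 0.3, gc_content <= 0.7, n_catalytic_exons >= 2L)
  set.seed(seed)

  if (is.null(paralog_domain)) paralog_domain <- random_peptide(exon_aa_length)
  peptide <- mutate_to_identity(paralog_domain, target_identity_pct)
  exon_cds <- back_translate(peptide)
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)

  # catalytic coding region: full codons plus 0-2 carried-over bases of a
  # codon split across the downstream splice junction
  extra <- sample(0:2, 1L)
  cat_coding <- paste0(back_translate(random_peptide(catalytic_aa)),
                       random_dna(extra, gc_content))
  Lc <- nchar(cat_coding)
  repeat {
    cuts <- sort(sample(seq(40L, Lc - 40L), n_catalytic_exons - 1L))
    if (all(diff(c(0L, cuts, Lc)) >= 30L)) break
  }
  cat_exons <- substring(cat_coding, c(1L, cuts + 1L), c(cuts, Lc))
  q <- (3L - Lc %% 3L) %% 3L  # phase entering the discovery intron

  rand_intron <- function() {
    len <- sample(seq(intron_length_range[1], intron_length_range[2]), 1L)
    paste0("GT", random_dna(len - 4L, gc_content), "AG")
  }

  # discovery intron: GT spacer1 TRAP CC AG [filler][CDS][stop] TRAP spacer2 AG
  filler <- strrep("C", q)
  fixed_len <- 2L + nchar(TRAP_BLOCK) + 2L + 2L + q + nchar(exon_cds) + 3L +
    nchar(TRAP_BLOCK) + 2L
  min_len <- fixed_len + 40L
  if (intron_length_range[2] < min_len) {
    stop_altexon("intron too short for implanted exon: need >= ", min_len,
                 " nt, range allows ", intron_length_range[2])
  }
  target_len <- sample(seq(max(intron_length_range[1], min_len),
                           intron_length_range[2]), 1L)
  s2 <- sample(20:min(220L, target_len - fixed_len - 20L), 1L)
  s1 <- target_len - fixed_len - s2
  spacer1 <- random_dna(s1, gc_content)
  spacer2 <- random_dna(s2, gc_content)

  pre_exon <- paste0("GT", spacer1, TRAP_BLOCK, "CC", "AG")
  post_exon <- paste0(TRAP_BLOCK, spacer2, "AG")
  discovery_intron <- paste0(pre_exon, filler, exon_cds, stop_codon, post_exon)

  # assemble locus left to right, tracking 0-based offsets
  pieces <- character(0)
  cursor <- 0L
  exon_rows <- list()
  add <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    start <- cursor
    cursor <<- cursor + nchar(s)
    start
  }
  add(random_dna(60L, gc_content))  # 5' flank
  for (i in seq_len(n_catalytic_exons)) {
    st <- add(cat_exons[i])
    exon_rows[[length(exon_rows) + 1L]] <-
      data.frame(start = st, end = st + nchar(cat_exons[i]),
                 phase = NA_integer_, role = "catalytic")
    if (i < n_catalytic_exons) add(rand_intron())
  }
  intron_start <- cursor
  add(discovery_intron)
  implant_start <- intron_start + nchar(pre_exon)
  implant_end <- implant_start + q + nchar(exon_cds) + 3L  # stop included
  if (include_cam_tail) {
    st <- add(random_dna(240L, gc_content))  # CaM-domain exon
    exon_rows[[length(exon_rows) + 1L]] <-
      data.frame(start = st, end = st + 240L, phase = NA_integer_, role = "cam")
    add(rand_intron())
    st <- add(random_dna(180L, gc_content))  # dimerization-tail exon
    exon_rows[[length(exon_rows) + 1L]] <-
      data.frame(start = st, end = st + 180L, phase = NA_integer_, role = "tail")
  } else {
    st <- add(random_dna(120L, gc_content))  # 3' terminal non-coding exon
    exon_rows[[length(exon_rows) + 1L]] <-
      data.frame(start = st, end = st + 120L, phase = NA_integer_,
                 role = "other")
  }
  add(random_dna(60L, gc_content))  # 3' flank

  locus <- genomic_locus(id = sprintf("synthetic_locus_seed%d", seed),
                         sequence = paste(pieces, collapse = ""),
                         strand = "+", exons = do.call(rbind, exon_rows))
  truth <- list(
    exon_start = implant_start, exon_end = implant_end, phase = q,
    peptide = peptide, acceptor_pos = implant_start,
    stop_start = implant_end - 3L, cds = exon_cds,
    intron_index = n_catalytic_exons,
    target_identity_pct = target_identity_pct, seed = seed)
  list(locus = locus, paralog = stats::setNames(paralog_domain, "paralog_domain"),
       truth = truth)
}

#' Write a simulated locus bundle to disk
#'
#' Emits `locus.fasta`, `locus.gff` (known exons only), `paralog.fasta` and
#' `truth.json`; byte-identical across runs with the same parameters.
#'
#' @param sim result of [simulate_locus()]
#' @param dir output directory (created if needed)
#' @return named vector of file paths, invisibly
#' @export
write_locus_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    locus_fasta = file.path(dir, "locus.fasta"),
    locus_gff = file.path(dir, "locus.gff"),
    paralog_fasta = file.path(dir, "paralog.fasta"),
    truth_json = file.path(dir, "truth.json"))
  write_fasta(stats::setNames(sim$locus$sequence, sim$locus$id),
              paths[["locus_fasta"]])
  write_gff_exons(sim$locus, paths[["locus_gff"]])
  write_fasta(sim$paralog, paths[["paralog_fasta"]])
  jsonlite::write_json(sim$truth, paths[["truth_json"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Evolve a coding sequence along a tree under a site-specific omega model
#'
#' Proposal-acceptance codon evolution: along each branch the number of
#' proposed point mutations is Poisson with mean `branch length x sequence
#' length in nt` (branch lengths are expected proposals per nucleotide
#' site). Each proposal picks a site uniformly and a target base with
#' transition:transversion weighting `kappa`; it is rejected if it creates
#' a stop codon, accepted if synonymous, and accepted with probability
#' `omega` of that codon otherwise. Each branch uses an RNG stream derived
#' from `(seed, edge index)`.
#'
#' @param ancestor_cds in-frame DNA string, no internal stop
#' @param tree a `phylo` guide tree with branch lengths
#' @param omega_profile per-codon omega values (scalar recycled)
#' @param kappa transition/transversion rate ratio (> 0)
#' @param seed RNG seed (required)
#' @return named character vector of leaf CDS
#' @export
evolve_cds <- function(ancestor_cds, tree, omega_profile = 1, kappa = 2,
                       seed) {
  if (missing(seed)) stop_altexon("seed is required")
  stopifnot(kappa > 0, all(omega_profile >= 0))
  codons <- split_codons(ancestor_cds)
  aa <- codon_aa(codons)
  if (any(aa == "*")) stop_altexon("ancestor CDS contains a stop codon")
  n_cod <- length(codons)
  if (length(omega_profile) == 1L) omega_profile <- rep(omega_profile, n_cod)
  if (length(omega_profile) != n_cod) {
    stop_altexon("omega_profile length ", length(omega_profile),
                 " != codon count ", n_cod)
  }
  if (is.null(tree$edge.length)) stop_altexon("tree must have branch lengths")

  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  states <- vector("list", n_tip + tree$Nnode)
  states[[n_tip + 1L]] <- strsplit(toupper(ancestor_cds), "")[[1]]

  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    set.seed(derive_seed(seed, e))
    states[[child]] <- evolve_branch(states[[parent]], tree$edge.length[e],
                                     omega_profile, kappa)
  }
  stats::setNames(
    vapply(seq_len(n_tip), function(i) paste(states[[i]], collapse = ""),
           character(1)),
    tree$tip.label)
}

#' @noRd
evolve_branch <- function(nts, t, omega, kappa) {
  L <- length(nts)
  n_events <- stats::rpois(1L, t * L)
  p_ts <- kappa / (kappa + 2)
  for (ev in seq_len(n_events)) {
    site <- sample.int(L, 1L)
    cur <- nts[site]
    target <- if (stats::runif(1L) < p_ts) {
      transition_of[[cur]]
    } else {
      sample(setdiff(setdiff(NT_BASES, cur), transition_of[[cur]]), 1L)
    }
    cod_idx <- (site - 1L) %/% 3L + 1L
    cod_pos <- (site - 1L) %% 3L + 1L
    old_codon <- paste(nts[(cod_idx - 1L) * 3L + 1:3], collapse = "")
    new_codon <- old_codon
    substr(new_codon, cod_pos, cod_pos) <- target
    aa_old <- codon_aa(old_codon); aa_new <- codon_aa(new_codon)
    if (aa_new == "*") next                       # nonsense rejected
    accept <- aa_new == aa_old || stats::runif(1L) < omega[cod_idx]
    if (accept) nts[site] <- target
  }
  nts
}

#' Simulate a clade-structured protein family with a known tree
#'
#' A star of clades: a root peptide is diverged into `n_clades` clade
#' ancestors by point substitutions at rate `between_div` per position, and
#' each ancestor into `taxa_per_clade` leaves at rate `within_div`. Mirrors
#' the paralog-cluster structure (DAPk / DRP-1 / ZIPk plus a distant
#' outgroup clade) that the catalytic-domain phylogeny resolves.
#'
#' @param n_clades number of clades (>= 2)
#' @param taxa_per_clade leaves per clade (>= 2)
#' @param within_div per-position substitution probability within a clade
#' @param between_div per-position substitution probability from root to
#'   clade ancestor; must exceed `within_div`
#' @param length peptide length
#' @param seed RNG seed (required)
#' @return list with `proteins` (named peptides, names `cladeI_tJ`) and
#'   `tree` (the true `phylo`, branch lengths = divergence rates)
#' @export
make_clade_family <- function(n_clades = 3L, taxa_per_clade = 4L,
                              within_div = 0.05, between_div = 0.3,
                              length = 300L, seed) {
  if (missing(seed)) stop_altexon("seed is required")
  if (!(between_div > within_div)) {
    stop_altexon("between_div must exceed within_div")
  }
  if (between_div > 0.75 || within_div > 0.75) {
    warning("divergence > 0.75: distances will be near saturation")
  }
  set.seed(seed)
  root <- random_peptide(length)
  proteins <- character(0)
  clade_frags <- character(n_clades)
  for (ci in seq_len(n_clades)) {
    anc <- mutate_fraction(root, between_div)
    leaves <- character(taxa_per_clade)
    nm <- sprintf("clade%d_t%d", ci, seq_len(taxa_per_clade))
    for (ti in seq_len(taxa_per_clade)) {
      leaves[ti] <- mutate_fraction(anc, within_div)
    }
    proteins <- c(proteins, stats::setNames(leaves, nm))
    clade_frags[ci] <- paste0("(", paste0(nm, ":", within_div, collapse = ","),
                              "):", between_div)
  }
  tree <- ape::read.tree(text = paste0("(", paste(clade_frags, collapse = ","),
                                       ");"))
  list(proteins = proteins, tree = tree)
}
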