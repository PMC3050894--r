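#' Run the full discovery-to-phylogeny analysis
#'
#' Orchestrates the stages — intronic exon discovery, homology of the top
#' candidate to the paralog domain, heptad-repeat scan, dN/dS selection
#' screen over an ortholog set, and bootstrap NJ phylogeny of a protein
#' family — into one deterministic report. Stages whose inputs are not
#' configured are marked `"skipped"`; any stage failure aborts with the
#' stage name. Identical config and inputs give an identical report (no
#' timestamps).
#'
#' @param config named list or path to a YAML file with entries:
#'   \describe{
#'     \item{locus_fasta, locus_gff, paralog_fasta}{required input paths}
#'     \item{intron_index}{intron to search (required)}
#'     \item{min_aa, require_stop}{discovery filters (default 100, FALSE)}
#'     \item{ortholog_cds_fasta}{optional in-frame CDS set for the
#'       selection screen}
#'     \item{family_fasta, outgroup}{optional protein family (>= 4) and
#'       outgroup labels for the phylogeny stage}
#'     \item{window_codons, step}{selection windows (default 30, 10)}
#'     \item{bootstrap_replicates, distance_model}{phylogeny settings
#'       (default 100, "poisson")}
#'     \item{seed}{required master seed}
#'   }
#' @return a report list (class `pipeline_report`)
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  required <- c("locus_fasta", "locus_gff", "paralog_fasta", "intron_index",
                "seed")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys)) {
    stop_altexon("config is missing: ", paste(missing_keys, collapse = ", "))
  }
  files <- c("locus_fasta", "locus_gff", "paralog_fasta",
             "ortholog_cds_fasta", "family_fasta")
  for (f in files) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop_altexon("input file not found: ", f, " = ", config[[f]])
    }
  }
  cfg <- utils::modifyList(
    list(min_aa = 100L, require_stop = FALSE, window_codons = 30L,
         step = 10L, bootstrap_replicates = 100L, distance_model = "poisson"),
    config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_altexon("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  # discovery
  discovery <- stage("discovery", {
    locus_seq <- read_fasta(cfg$locus_fasta, type = "dna")
    locus <- genomic_locus(names(locus_seq)[1], locus_seq[[1]])
    locus <- read_gff_exons(cfg$locus_gff, locus)
    cands <- find_candidate_exons(locus, cfg$intron_index,
                                  min_aa = cfg$min_aa,
                                  require_stop = cfg$require_stop)
    list(locus = locus, candidates = cands,
         discarded = attr(cands, "discarded"))
  })
  locus <- discovery$locus
  cands <- discovery$candidates
  top <- if (nrow(cands)) cands[1, ] else NULL
  message(sprintf("discovery: %d candidate(s); discarded min_aa=%d ambiguous=%d no_stop=%d",
                  nrow(cands), discovery$discarded$min_aa,
                  discovery$discarded$ambiguous, discovery$discarded$no_stop))

  # homology of the top candidate to the paralog domain
  homology <- if (is.null(top)) "skipped" else stage("homology", {
    paralog <- read_fasta(cfg$paralog_fasta, type = "protein")
    gl <- align_global(top$peptide, paralog[[1]])
    lo <- align_local(top$peptide, paralog[[1]])
    list(paralog_id = names(paralog)[1],
         global = list(score = gl$score,
                       identity_pct = round(gl$identity_pct),
                       similarity_pct = round(gl$similarity_pct),
                       identity_pct_full = gl$identity_pct,
                       similarity_pct_full = gl$similarity_pct),
         local = list(score = lo$score,
                      a_range = lo$a_range, b_range = lo$b_range,
                      identity_pct = round(lo$identity_pct),
                      similarity_pct = round(lo$similarity_pct)))
  })

  # heptad zipper scan of the top candidate
  heptads <- if (is.null(top)) "skipped" else stage("zipper", {
    hits <- scan_heptads(top$peptide)
    lapply(hits, function(h) h[c("d_positions", "residues_at_d", "n_repeats",
                                 "score")])
  })

  # selection screen over orthologs
  selection <- if (is.null(cfg$ortholog_cds_fasta)) "skipped" else {
    stage("selection", {
      cds <- read_fasta(cfg$ortholog_cds_fasta, type = "dna")
      prots <- vapply(cds, function(s) {
        p <- translate_dna(s)
        sub("\\*$", "", p)
      }, character(1))
      msa <- build_msa(prots)
      codon_aln <- thread_codons(msa, cds)
      win <- sliding_omega(codon_aln, cfg$window_codons, cfg$step)
      pair_omegas <- c()
      nms <- names(codon_aln$codons)
      for (i in seq_len(length(nms) - 1L)) {
        for (j in (i + 1L):length(nms)) {
          r <- nei_gojobori(codon_aln$codons[[i]], codon_aln$codons[[j]])
          if (r$omega_defined) pair_omegas <- c(pair_omegas, r$omega)
        }
      }
      list(n_sequences = length(cds),
           mean_pairwise_omega = if (length(pair_omegas)) mean(pair_omegas)
                                 else NA,
           fraction_windows_omega_lt_1 =
             mean(win$mean_omega[!win$flagged] < 1),
           windows = win)
    })
  }

  # phylogeny of a protein family
  phylogeny <- if (is.null(cfg$family_fasta)) "skipped" else {
    stage("phylogeny", {
      fam <- read_fasta(cfg$family_fasta, type = "protein")
      if (length(fam) < 4L) stop_altexon("family has < 4 sequences")
      msa <- build_msa(fam)
      tree <- bootstrap_support(msa, cfg$bootstrap_replicates, cfg$seed,
                                model = cfg$distance_model)
      rooted <- if (!is.null(cfg$outgroup)) {
        root_with_outgroup(tree, cfg$outgroup)
      } else NULL
      list(newick = ape::write.tree(tree),
           newick_rooted = if (is.null(rooted)) NULL
                           else ape::write.tree(rooted),
           supports = as.list(attr(tree, "support_table")))
    })
  }

  # locus architecture, with the discovered exon annotated as alternative
  architecture <- stage("architecture", {
    ex <- locus$exons
    if (!is.null(top)) {
      ex <- rbind(ex, data.frame(start = top$start, end = top$end,
                                 phase = top$phase, role = "alternative"))
    }
    locus2 <- locus
    locus2$exons <- ex[order(ex$start), ]
    cls <- tryCatch(classify_locus(validate_locus(locus2)),
                    error = function(e) list(label = NA, evidence = list()))
    cls
  })

  cand_report <- if (nrow(cands)) {
    data.frame(start_1based = cands$start + 1L, end_1based = cands$end,
               phase = cands$phase, aa_length = cands$aa_length,
               acceptor_context = cands$acceptor_context,
               stop_at_end = cands$stop_at_end,
               peptide = cands$peptide)
  } else data.frame()

  structure(list(
    locus = list(id = locus$id, length_nt = nchar(locus$sequence),
                 n_exons = nrow(locus$exons), strand = locus$strand),
    candidates = cand_report,
    homology = homology,
    heptads = heptads,
    selection = selection,
    phylogeny = phylogeny,
    architecture = architecture,
    provenance = list(
      package = "altexon",
      version = as.character(utils::packageVersion("altexon")),
      seed = cfg$seed,
      parameters = cfg[setdiff(names(cfg), files)])
  ), class = "pipeline_report")
}

#' Write a pipeline report as JSON
#'
#' @param report a `pipeline_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}
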