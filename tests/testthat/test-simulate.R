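test_that("simulated bundles are byte-reproducible from (params, seed)", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_locus_bundle(simulate_locus(seed = 121), d1)
  write_locus_bundle(simulate_locus(seed = 121), d2)
  for (f in c("locus.fasta", "locus.gff", "paralog.fasta", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  d3 <- withr::local_tempdir()
  write_locus_bundle(simulate_locus(seed = 122), d3)
  expect_false(identical(readLines(file.path(d1, "locus.fasta")),
                         readLines(file.path(d3, "locus.fasta"))))
})

test_that("truth coordinates are self-consistent with the emitted sequence", {
  sim <- simulate_locus(seed = 123)
  tr <- sim$truth
  # re-translating the truth interval (minus its stop codon) in the truth
  # phase reproduces the truth peptide
  dna <- substr(sim$locus$sequence, tr$exon_start + 1, tr$exon_end)
  expect_equal(translate_dna(dna, offset = tr$phase),
               paste0(tr$peptide, "*"))
  # acceptor AG immediately 5' of the exon
  expect_equal(substr(sim$locus$sequence, tr$exon_start - 1, tr$exon_start),
               "AG")
  # stop codon at the recorded position
  stop_cod <- substr(sim$locus$sequence, tr$stop_start + 1, tr$stop_start + 3)
  expect_true(stop_cod %in% c("TAA", "TAG", "TGA"))
})

test_that("implant equals the paralog at 100% target identity", {
  sim <- simulate_locus(target_identity_pct = 100, seed = 124)
  expect_identical(sim$truth$peptide, unname(sim$paralog))
})

test_that("implant identity calibrates to the requested target", {
  measured <- vapply(1:10, function(i) {
    sim <- simulate_locus(target_identity_pct = 70, exon_aa_length = 200,
                          seed = 3000 + i)
    al <- align_global(sim$truth$peptide, unname(sim$paralog))
    percent_identity(al)
  }, numeric(1))
  expect_true(all(abs(measured - 70) <= 2))
})

test_that("the implanted exon annotation is withheld from the GFF", {
  sim <- simulate_locus(seed = 125)
  expect_false("alternative" %in% sim$locus$exons$role)
  intr <- introns(sim$locus)
  row <- intr[intr$index == sim$truth$intron_index, ]
  expect_true(sim$truth$exon_start > row$start &&
                sim$truth$exon_end < row$end)
})

test_that("cam/tail exons are optional and intron bounds are honoured", {
  sim <- simulate_locus(include_cam_tail = FALSE, seed = 126)
  expect_false(any(c("cam", "tail") %in% sim$locus$exons$role))
  expect_error(simulate_locus(intron_length_range = c(100, 200), seed = 1),
               "intron too short")
})

test_that("codon evolution respects branch lengths and omega", {
  set.seed(127)
  anc <- back_translate(random_protein(150))
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  l0 <- evolve_cds(anc, tr0, seed = 1)
  expect_identical(unname(l0[["a"]]), anc)
  expect_identical(unname(l0[["b"]]), anc)

  tr <- ape::read.tree(text = "(a:0.15,b:0.15);")
  l1 <- evolve_cds(anc, tr, omega_profile = 0, kappa = 2, seed = 2)
  # omega 0: only synonymous change is possible
  expect_identical(translate_dna(l1[["a"]]), translate_dna(anc))
  expect_identical(translate_dna(l1[["b"]]), translate_dna(anc))
  expect_false(identical(l1[["a"]], l1[["b"]]))

  expect_error(evolve_cds(anc, tr, omega_profile = c(1, 1), seed = 3),
               "omega_profile length")
  expect_error(evolve_cds("ATGTAAGG", tr, seed = 4), "divisible|stop")
})

test_that("substitution counts match the proposal-rate expectation", {
  set.seed(128)
  anc <- back_translate(random_protein(500))
  tr <- ape::read.tree(text = "(a:0.1,b:0);")
  n_nt <- nchar(anc)
  obs <- vapply(1:30, function(i) {
    leaves <- evolve_cds(anc, tr, omega_profile = 1, kappa = 1,
                         seed = 5000 + i)
    sum(strsplit(leaves[["a"]], "")[[1]] != strsplit(anc, "")[[1]])
  }, numeric(1))
  # proposals ~ Poisson(0.1 * L), nearly all accepted at omega = 1, so each
  # site follows a Jukes-Cantor chain at rate 0.1: expected difference
  # fraction 3/4 (1 - exp(-4t/3)); nonsense rejections (~4% of proposals)
  # only lower the count slightly
  expected <- 0.75 * (1 - exp(-4 * 0.1 / 3)) * n_nt
  expect_lt(abs(mean(obs) - expected),
            3 * sqrt(expected / 30) + 0.04 * expected)
})

test_that("clade families honour their divergence parameters", {
  fam <- make_clade_family(n_clades = 3, taxa_per_clade = 3,
                           within_div = 0, between_div = 0.3,
                           length = 120, seed = 129)
  D <- distance_matrix(fam$proteins, model = "p", min_shared = 20)
  for (ci in 1:3) {
    tips <- grep(sprintf("clade%d_", ci), names(fam$proteins), value = TRUE)
    expect_true(all(D[tips, tips] == 0))
  }
  expect_error(make_clade_family(within_div = 0.3, between_div = 0.2, seed = 1),
               "exceed")
  expect_warning(make_clade_family(within_div = 0.1, between_div = 0.8,
                                   seed = 1),
                 "saturation")
  expect_equal(sort(fam$tree$tip.label), sort(names(fam$proteins)))
})
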