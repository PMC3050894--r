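test_that("codon threading maps residues to codons and gaps to ---", {
  aln <- thread_codons(c(x = "M-A"), c(x = "ATGGCT"))
  expect_equal(aln$codons[["x"]], c("ATG", "---", "GCT"))

  # terminal stop is stripped, internal stop is an error
  aln <- thread_codons(c(x = "MA"), c(x = "ATGGCTTAA"))
  expect_equal(aln$codons[["x"]], c("ATG", "GCT"))
  expect_error(thread_codons(c(x = "MA"), c(x = "ATGTAAGCT")), "internal stop")
  expect_error(thread_codons(c(x = "MV"), c(x = "ATGGCT")), "mismatch at residue 2")
})

test_that("threading simulator orthologs reproduces the true codon alignment", {
  set.seed(101)
  anc <- back_translate(random_protein(80))
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  leaves <- evolve_cds(anc, tr, omega_profile = 0.5, kappa = 2, seed = 3)
  prots <- vapply(leaves, translate_dna, character(1))
  msa <- build_msa(prots)
  aln <- thread_codons(msa, leaves)
  # substitution-only evolution: threading must recover each CDS verbatim
  for (nm in names(leaves)) {
    expect_equal(paste(aln$codons[[nm]][aln$codons[[nm]] != "---"],
                       collapse = ""),
                 unname(leaves[[nm]]))
  }
})

test_that("identical rows give zero distances and stop/gap codons are skipped", {
  r <- nei_gojobori(c("ATG", "GCT"), c("ATG", "GCT"))
  expect_equal(r$pN, 0); expect_equal(r$pS, 0)
  expect_equal(r$dN, 0); expect_equal(r$dS, 0)
  expect_false(r$omega_defined)

  r2 <- nei_gojobori(c("ATG", "---", "GCT"), c("ATG", "AAA", "GCT"))
  expect_equal(r2$n_codons, 2)
})

test_that("a synonymous single difference counts as one synonymous change", {
  r <- nei_gojobori("TTT", "TTC")
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$pN, 0)
  expect_equal(r$N_sites + r$S_sites, 3)
})

test_that("site counts sum to 3 per codon and the measure is symmetric", {
  set.seed(102)
  for (rep in 1:10) {
    a <- vapply(1:30, function(i) random_sense_codon(), character(1))
    b <- vapply(1:30, function(i) random_sense_codon(), character(1))
    r1 <- nei_gojobori(a, b)
    r2 <- nei_gojobori(b, a)
    expect_equal(r1$N_sites + r1$S_sites, 3 * r1$n_codons, tolerance = 1e-9)
    expect_equal(r1[c("N_sites", "S_sites", "Nd", "Sd", "pN", "pS")],
                 r2[c("N_sites", "S_sites", "Nd", "Sd", "pN", "pS")],
                 tolerance = 1e-12)
  }
})

test_that("pathway-averaged difference counts equal exhaustive ordering enumeration", {
  set.seed(103)
  tot <- c(syn = 0, nonsyn = 0)
  for (rep in 1:100) {
    a <- random_sense_codon()
    b <- random_sense_codon()
    r <- nei_gojobori(a, b)
    want <- oracle_codon_counts(a, b)
    expect_equal(c(syn = r$Sd, nonsyn = r$Nd), want, tolerance = 1e-12)
    tot <- tot + want
  }
  expect_gt(sum(tot), 0)  # the sweep actually exercised differences
})

test_that("single-difference codons are classified directly by translation", {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  checked <- 0
  for (a in sense) {
    for (pos in 1:3) {
      for (nt in setdiff(c("A", "C", "G", "T"), substr(a, pos, pos))) {
        b <- a
        substr(b, pos, pos) <- nt
        if (Biostrings::GENETIC_CODE[[b]] == "*") next
        r <- nei_gojobori(a, b)
        syn <- Biostrings::GENETIC_CODE[[a]] == Biostrings::GENETIC_CODE[[b]]
        expect_equal(r$Sd, as.numeric(syn))
        expect_equal(r$Nd, as.numeric(!syn))
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 400)
})

test_that("sliding windows flag undefined omega and find relaxed patches", {
  rows <- thread_codons(c(a = strrep("M", 40), b = strrep("M", 40)),
                        c(a = strrep("ATG", 40), b = strrep("ATG", 40)))
  win <- sliding_omega(rows, window_codons = 20, step = 10)
  expect_true(all(win$flagged))

  expect_error(sliding_omega(rows, window_codons = 5), ">= 10")
  expect_error(sliding_omega(rows, window_codons = 100), "longer than")
})

test_that("a neutral patch inside a purifying background stands out", {
  set.seed(104)
  n_cod <- 120
  omega <- rep(0.1, n_cod)
  omega[51:70] <- 1
  anc <- back_translate(random_protein(n_cod))
  tr <- ape::read.tree(text = "(a:0.25,b:0.25);")
  diffs <- replicate(6, {
    leaves <- evolve_cds(anc, tr, omega_profile = omega, kappa = 1,
                         seed = sample.int(1e6, 1))
    prots <- vapply(leaves, translate_dna, character(1))
    aln <- thread_codons(build_msa(prots), leaves)
    win <- sliding_omega(aln, window_codons = 20, step = 20)
    patch <- win$mean_omega[win$start_codon == 41 | win$start_codon == 61]
    flank <- win$mean_omega[win$start_codon %in% c(1, 21, 81, 101)]
    mean(patch, na.rm = TRUE) - mean(flank, na.rm = TRUE)
  })
  expect_gt(mean(diffs, na.rm = TRUE), 0)
})
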