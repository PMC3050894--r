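test_that("splice scan finds the dinucleotide consensus sites", {
  loc <- genomic_locus("x", "CCCCCC")
  expect_equal(nrow(scan_splice_sites(loc, c(0, 6))), 0L)

  loc <- genomic_locus("x", "TTAGC")
  hits <- scan_splice_sites(loc, c(0, 5))
  expect_equal(hits$kind, "acceptor")
  expect_equal(hits$position, 4L)  # boundary immediately 3' of the AG
  expect_equal(hits$context_score, 2L)  # TT upstream

  expect_equal(nrow(scan_splice_sites(loc, c(2, 2))), 0L)
})

test_that("splice scan equals a brute-force dinucleotide check on random sequence", {
  set.seed(52)
  for (rep in 1:5) {
    seq <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                 collapse = "")
    loc <- genomic_locus("x", seq)
    region <- sort(sample(0:5000, 2))
    if (diff(region) == 0) region <- c(0, 5000)
    hits <- scan_splice_sites(loc, region)
    orac <- oracle_splice_sites(seq, region[1], region[2])
    expect_equal(hits$position[hits$kind == "acceptor"],
                 as.integer(orac$acceptors %||% integer(0)),
                 ignore_attr = TRUE)
    expect_equal(hits$position[hits$kind == "donor"],
                 as.integer(orac$donors %||% integer(0)),
                 ignore_attr = TRUE)
  }
})

test_that("candidate enumeration equals the brute-force oracle on random loci", {
  set.seed(53)
  for (rep in 1:8) {
    L <- sample(2500:5000, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    loc <- genomic_locus("x", seq,
                         exons = data.frame(start = c(0, L - 100),
                                            end = c(sample(50:150, 1), L - 20)))
    min_aa <- sample(c(1, 5, 20), 1)
    require_stop <- rep %% 2 == 0
    got <- find_candidate_exons(loc, 1, min_aa = min_aa,
                                require_stop = require_stop)
    want <- oracle_candidates(loc, 1, min_aa, require_stop)
    expect_equal(got$start, want$start, ignore_attr = TRUE)
    expect_equal(got$end, want$end, ignore_attr = TRUE)
    expect_equal(got$peptide, want$peptide, ignore_attr = TRUE)
    expect_equal(got$stop_at_end, want$stop_at_end, ignore_attr = TRUE)
  }
})

test_that("every reported candidate sits immediately 3' of a genomic AG", {
  sim <- simulate_locus(seed = 54)
  cands <- find_candidate_exons(sim$locus, sim$truth$intron_index, min_aa = 10)
  expect_gt(nrow(cands), 0)
  for (k in seq_len(nrow(cands))) {
    p <- cands$start[k]
    expect_equal(substr(sim$locus$sequence, p - 1, p), "AG")
  }
})

test_that("the implanted exon is recovered exactly at zero divergence", {
  for (seed in c(1, 2, 3)) {
    sim <- simulate_locus(target_identity_pct = 100, seed = seed)
    cands <- find_candidate_exons(sim$locus, sim$truth$intron_index)
    expect_equal(cands$start[1], sim$truth$exon_start)
    expect_equal(cands$end[1], sim$truth$exon_end)
    expect_equal(cands$peptide[1], sim$truth$peptide)
    expect_equal(cands$phase[1], sim$truth$phase)
    expect_true(cands$stop_at_end[1])
  }
})

test_that("recovery persists as implant divergence from the paralog grows", {
  recovered <- vapply(c(100, 80, 60), function(ident) {
    sim <- simulate_locus(target_identity_pct = ident, seed = 60 + ident)
    cands <- find_candidate_exons(sim$locus, sim$truth$intron_index)
    nrow(cands) > 0 && cands$start[1] == sim$truth$exon_start
  }, logical(1))
  # divergence from the paralog changes homology, not splice signals:
  # recovery must not improve as identity drops
  expect_true(all(diff(!recovered) >= 0))
  expect_true(recovered[1])
})

test_that("discovery filters and input validation behave as specified", {
  sim <- simulate_locus(seed = 55)
  expect_equal(nrow(find_candidate_exons(sim$locus, sim$truth$intron_index,
                                         min_aa = 300)), 0L)
  expect_error(find_candidate_exons(sim$locus, 99), "out of range")
  single <- genomic_locus("x", strrep("A", 100),
                          exons = data.frame(start = 0, end = 10))
  expect_error(find_candidate_exons(single, 1), "fewer than 2")
})
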