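test_that("self-alignment gives 100% identity and similarity", {
  al <- align_global("PELICAN", "PELICAN")
  expect_equal(al$identity_pct, 100)
  expect_equal(al$similarity_pct, 100)
  expect_equal(al$aligned_a, "PELICAN")
})

test_that("a single deletion makes one gap column with full identity elsewhere", {
  al <- align_global("AAAA", "AAA")
  expect_equal(nchar(al$aligned_a), 4)
  expect_equal(sum(strsplit(al$aligned_b, "")[[1]] == "-"), 1)
  expect_equal(percent_identity(al), 100)  # over aligned pairs
})

test_that("similar but non-identical residues count as positives only", {
  al <- list(aligned_a = "IL", aligned_b = "LI")
  class(al) <- "pairwise_alignment"
  expect_equal(percent_identity(al), 0)
  expect_equal(percent_similarity(al), 100)  # BLOSUM62 I:L = +2
  expect_equal(percent_identity(structure(list(aligned_a = "AB-",
                                               aligned_b = "AC-"),
                                          class = "pairwise_alignment")), 50)
})

test_that("unrelated sequences give an empty local alignment with score 0", {
  al <- align_local("AAAAAAAA", "WWWWWWWW")
  expect_equal(al$score, 0)
  expect_equal(al$aligned_a, "")
})

test_that("an embedded substring is found exactly by local alignment", {
  set.seed(71)
  core <- random_protein(50)
  host <- paste0(random_protein(80), core, random_protein(70))
  al <- align_local(core, host)
  expect_equal(al$aligned_a, core)
  expect_equal(al$aligned_b, core)
  expect_equal(al$b_range, c(81, 130))
})

test_that("global and local scores equal an independent exhaustive DP", {
  set.seed(72)
  S <- blosum62()
  for (rep in 1:25) {
    a <- random_protein(sample(5:30, 1))
    b <- random_protein(sample(5:30, 1))
    go <- sample(c(5, 11), 1); ge <- 1
    expect_equal(align_global(a, b, gap_open = go, gap_extend = ge)$score,
                 oracle_global_score(a, b, S, go, ge))
    expect_equal(align_local(a, b, gap_open = go, gap_extend = ge)$score,
                 oracle_local_score(a, b, S, go, ge))
  }
})

test_that("alignment scores agree with Biostrings under the same parameters", {
  set.seed(73)
  S <- blosum62()
  for (rep in 1:10) {
    a <- random_protein(40); b <- random_protein(35)
    mine <- align_global(a, b)$score
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
    expect_equal(mine, ref)
  }
})

test_that("alignment scores are symmetric and identity <= similarity <= 100", {
  set.seed(74)
  for (rep in 1:10) {
    a <- random_protein(sample(10:60, 1))
    b <- random_protein(sample(10:60, 1))
    ga <- align_global(a, b); gb <- align_global(b, a)
    expect_equal(ga$score, gb$score)
    la <- align_local(a, b); lb <- align_local(b, a)
    expect_equal(la$score, lb$score)
    expect_lte(ga$identity_pct, ga$similarity_pct)
    expect_lte(ga$similarity_pct, 100)
    expect_gte(ga$identity_pct, 0)
  }
})

test_that("stripping gaps from aligned strings recovers the inputs", {
  set.seed(75)
  a <- random_protein(40); b <- random_protein(45)
  al <- align_global(a, b)
  expect_equal(gsub("-", "", al$aligned_a), a)
  expect_equal(gsub("-", "", al$aligned_b), b)
})

test_that("residues outside the matrix alphabet are rejected by name", {
  expect_error(align_global("MAX", "MAA"), "X")
  expect_error(percent_identity(structure(list(aligned_a = "--",
                                               aligned_b = "A-"),
                                          class = "pairwise_alignment")),
               "no aligned residue pairs")
})
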