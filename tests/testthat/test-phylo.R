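test_that("p and Poisson distances follow their closed forms", {
  rows <- c(a = strrep("L", 100),
            b = paste0(strrep("L", 99), "V"),
            c = strrep("L", 100))
  D <- distance_matrix(rows, model = "p")
  expect_equal(D["a", "c"], 0)
  expect_equal(D["a", "b"], 0.01)
  Dp <- distance_matrix(rows, model = "poisson")
  expect_equal(Dp["a", "b"], -log(0.99))
  # poisson >= p with equality iff p = 0
  expect_true(all(Dp >= D - 1e-12))
  expect_equal(Dp["a", "c"], 0)
})

test_that("p-distance equals a direct column count on simulated alignments", {
  fam <- make_clade_family(n_clades = 2, taxa_per_clade = 2,
                           within_div = 0.1, between_div = 0.3,
                           length = 150, seed = 111)
  D <- distance_matrix(fam$proteins, model = "p")
  m <- do.call(rbind, strsplit(unname(fam$proteins), ""))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(D[i, j], mean(m[i, ] != m[j, ]))
    }
  }
})

test_that("three-taxon NJ solves the three-point formulas exactly", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  cph <- cophenetic(tr)
  expect_equal(cph[rownames(D), colnames(D)], D, tolerance = 1e-9)
  # v_a = (d_ab + d_ac - d_bc)/2 = 1
  expect_equal(sort(tr$edge.length), c(1, 2, 3), tolerance = 1e-9)
})

test_that("NJ reconstructs additive matrices exactly (topology and lengths)", {
  set.seed(112)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    true_tree <- ape::rtree(n)
    D <- cophenetic(true_tree)
    nj <- neighbor_joining(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true_tree), nj)), 0)
    expect_lt(max(abs(cophenetic(nj)[rownames(D), colnames(D)] - D)), 1e-9)
  }
})

test_that("NJ agrees with the ape implementation on random matrices", {
  set.seed(113)
  for (rep in 1:5) {
    n <- 7
    M <- matrix(runif(n * n, 0.1, 1), n, n)
    D <- (M + t(M)) / 2
    diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    mine <- neighbor_joining(D)
    ref <- ape::nj(D)
    expect_equal(as.numeric(ape::dist.topo(mine, ref)), 0)
  }
})

test_that("NJ input validation catches malformed matrices", {
  D <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(D), "symmetric|>= 3")
  D3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(D3), "symmetric")
})

test_that("bootstrap supports are reproducible and bounded", {
  fam <- make_clade_family(n_clades = 2, taxa_per_clade = 3,
                           within_div = 0.05, between_div = 0.35,
                           length = 200, seed = 114)
  msa <- as_msa(fam$proteins)
  t1 <- bootstrap_support(msa, 25, seed = 9)
  t2 <- bootstrap_support(msa, 25, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- attr(t1, "support_table")
  expect_true(all(sup >= 0 & sup <= 100))

  # single replicate: every support is 0 or 100
  t3 <- bootstrap_support(msa, 1, seed = 10)
  expect_true(all(attr(t3, "support_table") %in% c(0, 100)))

  expect_error(bootstrap_support(as_msa(fam$proteins[1:3]), 10, seed = 1),
               ">= 4 taxa")
})

test_that("bootstrap supports do not depend on taxon input order", {
  fam <- make_clade_family(n_clades = 2, taxa_per_clade = 3,
                           within_div = 0.05, between_div = 0.35,
                           length = 150, seed = 115)
  t1 <- bootstrap_support(as_msa(fam$proteins), 20, seed = 4)
  t2 <- bootstrap_support(as_msa(rev(fam$proteins)), 20, seed = 4)
  expect_equal(attr(t1, "support_table")[names(attr(t1, "support_table"))],
               attr(t2, "support_table")[names(attr(t1, "support_table"))])
})

test_that("outgroup rooting places the root mid-edge and checks monophyly", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,c:2):0,d:4);")
  tr <- ape::unroot(tr)
  rooted <- root_with_outgroup(tr, "d")
  expect_true(ape::is.rooted(rooted))
  # midpoint split: both root-child edges equal half the original pendant+stem
  root_edges <- rooted$edge.length[rooted$edge[, 1] == length(rooted$tip.label) + 1]
  expect_equal(root_edges[1], root_edges[2])

  # split outgroup is rejected
  fam <- make_clade_family(n_clades = 3, taxa_per_clade = 2,
                           within_div = 0.05, between_div = 0.3,
                           length = 150, seed = 116)
  nj <- neighbor_joining(distance_matrix(fam$proteins))
  expect_error(root_with_outgroup(nj, c("clade1_t1", "clade2_t1")),
               "not monophyletic")
  expect_error(root_with_outgroup(nj, "nosuch"), "not in tree")
})

test_that("clade structure is recovered monophyletically after outgroup rooting", {
  fam <- make_clade_family(n_clades = 4, taxa_per_clade = 3,
                           within_div = 0.05, between_div = 0.25,
                           length = 250, seed = 117)
  nj <- neighbor_joining(distance_matrix(fam$proteins))
  out <- grep("clade4", names(fam$proteins), value = TRUE)
  rooted <- root_with_outgroup(nj, out)
  for (ci in 1:3) {
    tips <- grep(sprintf("clade%d_", ci), names(fam$proteins), value = TRUE)
    expect_true(ape::is.monophyletic(rooted, tips))
  }
})
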