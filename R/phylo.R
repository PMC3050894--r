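#' Pairwise distance matrix from a protein MSA
#'
#' p-distance is the mismatch fraction over columns where both sequences
#' have a residue; the Poisson correction is -ln(1 - p). Pairs must share at
#' least `min_shared` gap-free columns.
#'
#' @param msa an `msa` object or named aligned character vector
#' @param model "p" or "poisson"
#' @param min_shared minimum shared non-gap columns per pair (default 20)
#' @return symmetric numeric matrix with taxon labels and zero diagonal
#' @export
distance_matrix <- function(msa, model = c("p", "poisson"), min_shared = 20L) {
  model <- match.arg(model)
  aligned <- if (inherits(msa, "msa")) msa$sequences else msa
  m <- do.call(rbind, strsplit(unname(aligned), ""))
  n <- nrow(m)
  labels <- names(aligned)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- m[i, ] != "-" & m[j, ] != "-"
      ns <- sum(shared)
      if (ns < min_shared) {
        stop_altexon("pair ", labels[i], "/", labels[j], " shares only ", ns,
                     " gap-free columns (need >= ", min_shared, ")")
      }
      p <- sum(m[i, shared] != m[j, shared]) / ns
      d <- if (model == "p") p else {
        if (p >= 1) stop_altexon("saturated pair ", labels[i], "/", labels[j],
                                 ": p = 1, Poisson distance undefined")
        -log(1 - p)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' The canonical Saitou-Nei agglomeration with the Q criterion, exact on
#' additive distances. Ties in Q are broken by the lexicographically
#' smallest pair of cluster labels (each cluster is represented by its
#' smallest leaf label), making the output deterministic. Negative branch
#' lengths are clamped to 0 and the total clamped deficit recorded in the
#' `"clamped_deficit"` attribute.
#'
#' @param D symmetric distance matrix with unique row/column labels, >= 3
#'   taxa
#' @return an unrooted `phylo` object
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop_altexon("D must be square")
  if (max(abs(D - t(D))) > 1e-8) stop_altexon("D must be symmetric")
  n0 <- nrow(D)
  if (n0 < 3L) stop_altexon("neighbor joining needs >= 3 taxa")
  labels <- rownames(D)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop_altexon("D must have unique labels")
  }
  if (any(grepl("[(),:;\\s]", labels, perl = TRUE))) {
    stop_altexon("labels must not contain Newick metacharacters or whitespace")
  }

  frag <- labels                # Newick fragment per active cluster
  rep_label <- labels           # smallest leaf label per cluster, for ties
  active <- D
  deficit <- 0
  fmt <- function(x) sprintf("%.12g", x)

  while (nrow(active) > 3L) {
    n <- nrow(active)
    r <- rowSums(active)
    Q <- (n - 2) * active - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      lab <- sort(c(rep_label[ij[1]], rep_label[ij[2]]))
      paste(lab, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]

    vi <- active[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- active[i, j] - vi
    if (vi < 0) { deficit <- deficit - vi; vi <- 0 }
    if (vj < 0) { deficit <- deficit - vj; vj <- 0 }

    du <- (active[i, ] + active[j, ] - active[i, j]) / 2
    new_frag <- paste0("(", frag[i], ":", fmt(vi), ",", frag[j], ":",
                       fmt(vj), ")")
    new_rep <- min(rep_label[i], rep_label[j])

    keep <- setdiff(seq_len(n), c(i, j))
    active <- rbind(cbind(active[keep, keep, drop = FALSE], du[keep]),
                    c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_label <- c(rep_label[keep], new_rep)
  }

  # resolve the final three clusters around one internal node
  d12 <- active[1, 2]; d13 <- active[1, 3]; d23 <- active[2, 3]
  v1 <- (d12 + d13 - d23) / 2
  v2 <- (d12 + d23 - d13) / 2
  v3 <- (d13 + d23 - d12) / 2
  v <- c(v1, v2, v3)
  neg <- v < 0
  deficit <- deficit + sum(-v[neg])
  v[neg] <- 0
  newick <- paste0("(", frag[1], ":", fmt(v[1]), ",", frag[2], ":", fmt(v[2]),
                   ",", frag[3], ":", fmt(v[3]), ");")
  tree <- ape::read.tree(text = newick)
  attr(tree, "clamped_deficit") <- deficit
  tree
}

#' @noRd
bipartitions <- function(tree) {
  # canonical string for each internal edge: the side not containing the
  # alphabetically first taxon, labels sorted
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  n <- length(tree$tip.label)
  out <- character(0)
  nodes <- setdiff(n + seq_len(tree$Nnode), n + 1L)
  for (node in nodes) {
    clade <- ape::extract.clade(tree, node)$tip.label
    side <- if (ref %in% clade) setdiff(tips, clade) else clade
    if (length(side) >= 2L && length(side) <= n - 2L) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  unique(out)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal edge of the full-data tree with
#' the percentage of replicates containing the same bipartition. Replicate
#' r draws its columns from an RNG stream derived from `(seed, r)`, so
#' results are reproducible and independent of evaluation order.
#'
#' @param msa an `msa` object or named aligned character vector with >= 4
#'   taxa
#' @param n_replicates number of bootstrap replicates (>= 1)
#' @param seed master seed (required)
#' @param model distance model passed to [distance_matrix()]
#' @return the full-data NJ `phylo` with `node.label` holding integer
#'   supports in \[0, 100\] (empty for the root) and a `"support_table"`
#'   attribute mapping bipartition strings to supports
#' @export
bootstrap_support <- function(msa, n_replicates, seed,
                              model = c("poisson", "p")) {
  model <- match.arg(model)
  if (missing(seed)) stop_altexon("seed is required")
  if (n_replicates < 1L) stop_altexon("n_replicates must be >= 1")
  aligned <- if (inherits(msa, "msa")) msa$sequences else msa
  if (length(aligned) < 4L) {
    stop_altexon("bootstrap supports need >= 4 taxa")
  }
  m <- do.call(rbind, strsplit(unname(aligned), ""))
  rownames(m) <- names(aligned)
  nc <- ncol(m)

  main <- neighbor_joining(distance_matrix(aligned, model = model))
  main_bi <- bipartitions(main)
  counts <- stats::setNames(numeric(length(main_bi)), main_bi)

  for (r in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, r))
    cols <- sample.int(nc, nc, replace = TRUE)
    rep_aligned <- stats::setNames(
      apply(m[, cols, drop = FALSE], 1, paste, collapse = ""), names(aligned))
    rep_tree <- neighbor_joining(distance_matrix(rep_aligned, model = model))
    rep_bi <- bipartitions(rep_tree)
    hit <- main_bi %in% rep_bi
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / n_replicates)

  # attach supports as internal node labels of the full tree
  n <- length(main$tip.label)
  tips <- sort(main$tip.label)
  ref <- tips[1]
  labs <- character(main$Nnode)
  for (k in seq_len(main$Nnode)) {
    node <- n + k
    if (node == n + 1L) { labs[k] <- ""; next }  # root of the unrooted tree
    clade <- ape::extract.clade(main, node)$tip.label
    side <- if (ref %in% clade) setdiff(tips, clade) else clade
    key <- paste(sort(side), collapse = "|")
    labs[k] <- if (key %in% names(support)) {
      as.character(support[[key]])
    } else ""
  }
  main$node.label <- labs
  attr(main, "support_table") <- support
  main
}

#' Root an unrooted tree with an outgroup
#'
#' Verifies the outgroup is monophyletic in the unrooted tree (there is an
#' edge whose bipartition separates exactly the outgroup), then places the
#' root at the midpoint of that edge.
#'
#' @param tree an unrooted `phylo`
#' @param outgroup_labels tip labels of the outgroup
#' @return a rooted `phylo`
#' @export
root_with_outgroup <- function(tree, outgroup_labels) {
  missing_tips <- setdiff(outgroup_labels, tree$tip.label)
  if (length(missing_tips)) {
    stop_altexon("outgroup labels not in tree: ",
                 paste(missing_tips, collapse = ", "))
  }
  n <- length(tree$tip.label)
  og <- sort(outgroup_labels)
  ingroup <- setdiff(tree$tip.label, og)
  if (length(ingroup) == 0L) stop_altexon("outgroup cannot cover all taxa")
  if (length(og) > 1L) {
    bi <- bipartitions(tree)
    key_og <- paste(og, collapse = "|")
    key_in <- paste(sort(ingroup), collapse = "|")
    if (!(key_og %in% bi || key_in %in% bi)) {
      stop_altexon("outgroup {", paste(og, collapse = ","),
                   "} is not monophyletic: no edge induces the bipartition {",
                   paste(og, collapse = ","), "} | {",
                   paste(sort(ingroup), collapse = ","), "}")
    }
  }
  rooted <- ape::root(tree, outgroup = outgroup_labels, resolve.root = TRUE,
                      edgelabel = TRUE)
  # split the rooted edge evenly across the two root children
  root_node <- n + 1L
  child_edges <- which(rooted$edge[, 1] == root_node)
  if (length(child_edges) == 2L) {
    total <- sum(rooted$edge.length[child_edges])
    rooted$edge.length[child_edges] <- total / 2
  }
  rooted
}
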