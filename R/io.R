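#' Read a FASTA file
#'
#' @param path file path
#' @param type "protein" or "dna"; DNA mode maps U to T and validates the
#'   alphabet A,C,G,T,N
#' @return named character vector of sequences, in file order
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop_altexon("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_altexon("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_altexon("duplicate FASTA id: ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (type == "dna") {
    seqs <- gsub("U", "T", seqs)
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      stop_altexon("non-DNA characters in record '", ids[which(bad)[1]], "'")
    }
  } else {
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", seqs)
    if (any(bad)) {
      stop_altexon("non-protein characters in record '", ids[which(bad)[1]], "'")
    }
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Attach exon annotations from a GFF3 file to a locus
#'
#' Reads exon/CDS features whose seqid matches the locus id and converts the
#' 1-based inclusive GFF coordinates to the internal 0-based half-open
#' convention. Phase is taken from the GFF phase column when present,
#' otherwise computed from the cumulative coding length of preceding exons.
#' An optional `role=` attribute is honoured; other features get role
#' "other".
#'
#' @param path GFF3 file
#' @param locus a `genomic_locus` (its exon table is replaced)
#' @return the locus with exons attached
#' @export
read_gff_exons <- function(path, locus) {
  if (!file.exists(path)) stop_altexon("GFF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("exon", "CDS") & as.character(df$seqnames) == locus$id, ,
           drop = FALSE]
  if (nrow(df) == 0L) {
    stop_altexon("no exon/CDS features for locus '", locus$id, "' in ", path)
  }
  phase <- rep(NA_integer_, nrow(df))
  if ("phase" %in% names(df)) {
    ph <- suppressWarnings(as.integer(as.character(df$phase)))
    phase <- ifelse(is.na(ph), NA_integer_, ph)
  }
  role <- if ("role" %in% names(df)) as.character(df$role) else rep(NA, nrow(df))
  role[is.na(role)] <- "other"
  ex <- data.frame(start = df$start - 1L,  # 1-based inclusive -> 0-based half-open
                   end = df$end,
                   phase = phase,
                   role = role)
  L <- nchar(locus$sequence)
  if (any(ex$start < 0L) || any(ex$end > L)) {
    bad <- which(ex$start < 0L | ex$end > L)[1]
    stop_altexon("feature ", ex$start[bad] + 1L, "-", ex$end[bad],
                 " outside locus bounds (length ", L, ")")
  }
  ex <- ex[order(ex$start), , drop = FALSE]
  if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
    stop_altexon("overlapping exon features in ", path)
  }
  locus$exons <- ex
  validate_locus(locus)
}

#' Write a locus's exon annotations as GFF3
#'
#' Emits 1-based inclusive coordinates, phase in the phase column and the
#' role as a `role=` attribute, so that [read_gff_exons()] round-trips the
#' annotation exactly.
#'
#' @param locus a `genomic_locus`
#' @param path output path
#' @param feature_type GFF type column (default "exon")
#' @return `path`, invisibly
#' @export
write_gff_exons <- function(locus, path, feature_type = "exon") {
  ex <- locus$exons
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", locus$id, nchar(locus$sequence)))
  if (nrow(ex)) {
    lines <- c(lines, sprintf(
      "%s\taltexon\t%s\t%d\t%d\t.\t%s\t%d\tID=%s.exon%d;role=%s",
      locus$id, feature_type, ex$start + 1L, ex$end, locus$strand, ex$phase,
      locus$id, seq_len(nrow(ex)), ex$role))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Newick tree
#'
#' Parses standard Newick with branch lengths; integer internal-node labels
#' are interpreted as bootstrap supports in \[0, 100\]. Unbalanced
#' parentheses are reported with their character position.
#'
#' @param path Newick file
#' @return an [ape::read.tree()] `phylo` object (node labels hold supports)
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_altexon("Newick file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop_altexon("unbalanced ')' at position ", k, " in ", path)
    }
  }
  if (depth != 0L) {
    stop_altexon("unbalanced '(': ", depth, " unclosed at end of ", path)
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop_altexon("failed to parse Newick in ", path)
  tree
}

#' Write a tree to Newick
#'
#' Bootstrap supports stored in `node.label` are emitted as internal-node
#' labels; branch lengths are written with enough digits for a six-decimal
#' round trip.
#'
#' @param tree a `phylo` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}
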