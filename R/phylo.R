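## Distance-based phylogenetics: p-distances from protein alignments,
## neighbor joining with explicit tie-breaking, bootstrap supports on
## bipartitions, concatenated gene sets and outgroup rooting. Trees are ape
## "phylo" objects throughout.

#' Read a protein alignment from aligned FASTA
#'
#' @param path Aligned FASTA path.
#' @return A `protein_alignment`: named character vector of equal-length
#'   gapped rows.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  protein_alignment(setNames(as.character(set),
                             sub("\\s.*$", "", names(set))))
}

#' Construct a protein alignment object
#'
#' @param rows Named character vector of gapped rows (gap `-`), equal
#'   lengths, at least 3 taxa, unique names.
#' @return A `protein_alignment`.
#' @export
protein_alignment <- function(rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named by taxon", call. = FALSE)
  if (anyDuplicated(names(rows)))
    stop("duplicate taxon names", call. = FALSE)
  if (length(unique(nchar(rows))) != 1L)
    stop("ragged alignment", call. = FALSE)
  if (length(rows) < 3L)
    stop("need at least 3 taxa", call. = FALSE)
  structure(toupper(rows), names = names(rows),
            class = "protein_alignment")
}

#' Write a protein alignment as aligned FASTA
#'
#' @param aln A `protein_alignment`.
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  x <- Biostrings::BStringSet(as.character(aln))
  names(x) <- names(aln)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(as.character(aln), "", fixed = TRUE))
}

#' p-distance matrix of a protein alignment
#'
#' `d(i, j)` is the fraction of mismatching residues among columns where
#' both rows are ungapped. A pair with no comparable columns is an error.
#'
#' @param aln A `protein_alignment` (or named character vector).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  ungap <- m != "-"
  d <- matrix(0, n, n, dimnames = list(rownames = names(aln),
                                       colnames = names(aln)))
  dimnames(d) <- list(names(aln), names(aln))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- ungap[i, ] & ungap[j, ]
    nc <- sum(both)
    if (nc == 0L)
      stop("no comparable columns between ", names(aln)[i], " and ",
           names(aln)[j], call. = FALSE)
    d[i, j] <- d[j, i] <- sum(m[i, both] != m[j, both]) / nc
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining: the pair minimizing the Q criterion is
#' joined at each step, ties broken by the lowest taxon-index pair (row
#' first). Negative branch lengths are clamped to zero with the deficit
#' transferred to the sister branch. Returns an unrooted `phylo` tree.
#'
#' @param d Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0) || any(d < 0) ||
      any(!is.finite(d)))
    stop("invalid distance matrix", call. = FALSE)
  lab <- rownames(d)                      # newick fragment per active node
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    c(li, lj)
  }
  while (n > 3L) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    l <- clamp_pair(li, lj)
    newlab <- sprintf("(%s:%.10g,%s:%.10g)", lab[i], l[1], lab[j], l[2])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    lab <- c(lab[keep], newlab)
    rownames(d2) <- colnames(d2) <- paste0("n", seq_len(n - 1L))
    d <- d2
    n <- n - 1L
  }
  ## final three-point resolution
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  la <- max(0, la); lb <- max(0, lb); lc <- max(0, lc)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 lab[1], la, lab[2], lb, lab[3], lc)
  ape::read.tree(text = nwk)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `replicates` times; each
#' replicate yields a p-distance matrix and an NJ tree. The support of an
#' internal edge is the percentage of replicates containing its bipartition.
#' Degenerate alignments (all pairwise distances zero) are flagged and
#' returned as a star tree with undefined supports.
#'
#' @param aln A `protein_alignment`.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the resampling is deterministic given the seed.
#' @return A list of class `bootstrap_nj` with `tree` (node labels carry the
#'   supports in percent), `supports`, `replicates` and `degenerate`.
#' @export
bootstrap_support <- function(aln, replicates = 1000L, seed = 1L) {
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  d <- p_distance_matrix(aln)
  if (max(d) == 0) {
    star <- ape::read.tree(
      text = paste0("(", paste(names(aln), collapse = ","), ");"))
    return(structure(list(tree = star, supports = NULL,
                          replicates = replicates, degenerate = TRUE),
                     class = "bootstrap_nj"))
  }
  main <- nj_tree(d)
  m <- aln_matrix(aln)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  trees <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    sub <- m[, cols, drop = FALSE]
    rows <- setNames(apply(sub, 1L, paste, collapse = ""), names(aln))
    dr <- tryCatch(p_distance_matrix(rows), error = function(e) NULL)
    trees[[r]] <- if (is.null(dr) || max(dr) == 0) NULL else nj_tree(dr)
  }
  ok <- !vapply(trees, is.null, logical(1))
  counts <- ape::prop.clades(main, trees[ok], rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- round(100 * counts / sum(ok), 1)
  tree <- main
  tree$node.label <- supports
  structure(list(tree = tree, supports = supports,
                 replicates = replicates, degenerate = FALSE),
            class = "bootstrap_nj")
}

#' @export
print.bootstrap_nj <- function(x, ...) {
  if (x$degenerate) {
    cat("<bootstrap_nj> degenerate alignment: star tree, supports undefined\n")
  } else {
    cat(sprintf("<bootstrap_nj> %d replicates; internal supports: %s\n",
                x$replicates, paste(x$supports, collapse = ", ")))
  }
  invisible(x)
}

#' Concatenate gene alignments row-wise
#'
#' Every taxon must be present in every alignment; rows are concatenated in
#' the given gene order and partition boundaries are recorded in the
#' `partitions` attribute.
#'
#' @param alns List of `protein_alignment`s (optionally named by gene).
#' @return A `protein_alignment` with attribute `partitions`.
#' @export
concat_alignments <- function(alns) {
  stopifnot(length(alns) >= 1L)
  taxa <- names(alns[[1L]])
  for (a in alns) {
    if (anyDuplicated(names(a))) stop("duplicate taxon", call. = FALSE)
    missing <- setdiff(taxa, names(a))
    extra <- setdiff(names(a), taxa)
    if (length(missing) || length(extra))
      stop("taxon sets differ: missing ",
           paste(c(missing, extra), collapse = ", "), call. = FALSE)
  }
  rows <- vapply(taxa, function(tx)
    paste(vapply(alns, function(a) unname(a[[tx]]), character(1)),
          collapse = ""), character(1))
  widths <- vapply(alns, function(a) nchar(a[[1L]]), integer(1))
  out <- protein_alignment(rows)
  attr(out, "partitions") <- data.frame(
    gene = names(alns) %||% paste0("gene", seq_along(alns)),
    start = cumsum(c(1L, head(widths, -1L))),
    end = cumsum(widths))
  out
}

#' Root a tree on an outgroup taxon
#'
#' The tree is re-rooted at the midpoint of the outgroup's pendant edge.
#'
#' @param tree A `phylo` object.
#' @param outgroup Leaf label.
#' @return A rooted `phylo` object.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("unknown taxon: ", outgroup, call. = FALSE)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (!is.null(rooted$edge.length)) {
    root_node <- ape::Ntip(rooted) + 1L
    kids <- which(rooted$edge[, 1L] == root_node)
    if (length(kids) == 2L) {
      total <- sum(rooted$edge.length[kids])
      rooted$edge.length[kids] <- total / 2
    }
  }
  rooted
}
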