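# Distance-based phylogeny of the SPL domain: p-distances with pairwise gap
# deletion, neighbor-joining, and nonparametric bootstrap supports computed
# by column resampling.

#' p-distance matrix from a protein alignment
#'
#' For each pair of rows, the fraction of differing columns among the
#' columns where neither row carries a gap (pairwise gap deletion).
#'
#' @param alignment Named character vector (or matrix of single characters)
#'   of equal-length aligned rows; `-` marks a gap.
#' @return Symmetric numeric matrix with the taxa as dimnames.
#' @export
p_distance_matrix <- function(alignment) {
  m <- alignment_to_matrix(alignment)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 aligned sequences", call. = FALSE)
  taxa <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        stop(sprintf("no comparable columns between '%s' and '%s'",
                     taxa[i], taxa[j]), call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  d
}

#' @noRd
alignment_to_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    if (is.null(rownames(alignment))) {
      rownames(alignment) <- paste0("t", seq_len(nrow(alignment)))
    }
    return(alignment)
  }
  stopifnot(is.character(alignment))
  if (is.null(names(alignment))) {
    names(alignment) <- paste0("t", seq_along(alignment))
  }
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: all rows must have equal length", call. = FALSE)
  }
  do.call(rbind, lapply(setNames(toupper(alignment), names(alignment)),
                        function(s) strsplit(s, "", fixed = TRUE)[[1]]))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`). For additive input
#' distances the unrooted topology and branch lengths are recovered
#' exactly. Negative branch-length estimates, which NJ can produce on
#' non-additive input, are clamped to zero with a warning.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) or `dist` object.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric", call. = FALSE)
  tree <- ape::nj(stats::as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning("negative branch lengths clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the tree from the full alignment, then resamples alignment
#' columns with replacement `n_reps` times; the support of each internal
#' edge is the percentage of replicate trees containing the same leaf
#' bipartition. Supports are stored as internal node labels, so they
#' round-trip through Newick.
#'
#' @param alignment Named character vector of equal-length aligned rows.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Random seed for the resampling.
#' @return A `phylo` tree whose `node.label` holds supports in `[0, 100]`
#'   (`NA` on the unresolved root node).
#' @export
bootstrap_supports <- function(alignment, n_reps = 1000L, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  m <- alignment_to_matrix(alignment)
  main <- neighbor_joining(p_distance_matrix(m))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[b]] <- suppressWarnings(neighbor_joining(p_distance_matrix(m[, cols, drop = FALSE])))
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  support <- round(100 * counts / n_reps, 1)
  main$node.label <- as.character(support)
  main$node.label[is.na(support)] <- ""
  main
}

#' Annotate tree leaves by miR156 response-element presence
#'
#' Flags each leaf according to whether its associated transcript carries a
#' predicted miR156 response element, the split used to subdivide the SPL
#' class II clade.
#'
#' @param tree A `phylo` tree.
#' @param mre_ids Character vector of leaf (or mapped transcript) ids that
#'   carry an MRE.
#' @param map Optional named character vector mapping leaf labels to
#'   transcript ids; unmapped leaves are matched by their own label.
#' @return The tree with an added `mre_class` logical vector aligned to
#'   `tip.label`.
#' @export
annotate_mre_class <- function(tree, mre_ids, map = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ids <- tree$tip.label
  if (!is.null(map)) {
    mapped <- map[ids]
    ids <- ifelse(is.na(mapped), ids, mapped)
  }
  tree$mre_class <- ids %in% mre_ids
  names(tree$mre_class) <- tree$tip.label
  tree
}

#' Split the tree at its deepest internal edge
#'
#' Reports the two leaf sets flanking the internal edge with the greatest
#' branch length, a simple automatic proxy for the two major subgroups of a
#' family tree.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return List with elements `clade1`, `clade2` (tip label vectors) and
#'   `edge_length`.
#' @export
deepest_split <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > ntip)
  if (length(internal) == 0L) stop("tree has no internal edge", call. = FALSE)
  e <- internal[which.max(tree$edge.length[internal])]
  child <- tree$edge[e, 2]
  desc <- ape::extract.clade(tree, child)$tip.label
  list(clade1 = desc,
       clade2 = setdiff(tree$tip.label, desc),
       edge_length = tree$edge.length[e])
}

#' Read and write Newick trees
#'
#' Thin wrappers over `ape` I/O that preserve topology, branch lengths and
#' bootstrap supports encoded as internal node labels.
#'
#' @param tree A `phylo` tree.
#' @param path File path.
#' @return `write_newick` invisibly returns `path`; `read_newick` returns a
#'   `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop(sprintf("malformed Newick in '%s'", path), call. = FALSE)
  tree
}
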