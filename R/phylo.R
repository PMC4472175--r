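# Distance-based smoke-test phylogenetics: Jukes-Cantor distances on the
# consensus supermatrix, neighbor-joining, and Robinson-Foulds comparison.
# The real analyses these matrices feed (RAxML / MrBayes under
# GTR + GAMMA + I, 500 ML bootstraps, 1,000,000 BI generations with 2000
# burn-in) stay external; these utilities only verify that a matrix carries
# the expected topological signal.

#' Jukes-Cantor distance matrix of a consensus supermatrix
#'
#' Pairwise p is the mismatch fraction over all columns (the matrix contains
#' only called consensus bases, so there is no missing data);
#' d = -(3/4) ln(1 - 4p/3). Saturated pairs (p >= 0.75) are an error.
#'
#' @param matrix \code{cs_matrix}, or a taxa x L character matrix.
#' @return \code{dist} object with taxa labels.
#' @export
jc_distance <- function(matrix) {
  mat <- if (inherits(matrix, "cs_matrix")) matrix$mat else matrix
  n <- nrow(mat)
  if (n < 2L) stop("need at least 2 taxa")
  if (ncol(mat) == 0L) stop("empty matrix")
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    p <- mean(mat[i, ] != mat[j, ])
    if (p >= 0.75)
      stop("saturated pair (p >= 0.75): ", rownames(mat)[i], " vs ",
           rownames(mat)[j])
    d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  stats::as.dist(d)
}

#' Neighbor-joining tree
#'
#' Standard NJ (Saitou-Nei criterion with Studier-Keppler updates, as
#' implemented in \pkg{ape}); negative branch lengths are clamped to zero
#' with a message.
#'
#' @param dist \code{dist} object or symmetric matrix with labels.
#' @return unrooted \code{phylo} tree.
#' @export
neighbor_joining <- function(dist) {
  if (is.matrix(dist)) {
    if (!isSymmetric(unname(dist))) stop("distance matrix must be symmetric")
    dist <- stats::as.dist(dist)
  }
  if (attr(dist, "Size") < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(dist)
  if (any(tr$edge.length < 0)) {
    message(sum(tr$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' Number of bipartitions present in exactly one of the two unrooted trees.
#'
#' @param tree_a,tree_b \code{phylo} objects or Newick strings over the same
#'   leaf set.
#' @return non-negative integer.
#' @export
rf_distance <- function(tree_a, tree_b) {
  ta <- as_phylo(tree_a)
  tb <- as_phylo(tree_b)
  if (!setequal(ta$tip.label, tb$tip.label)) stop("leaf sets differ")
  as.integer(phangorn::RF.dist(ape::unroot(ta), ape::unroot(tb)))
}

#' Write a distance matrix as TSV
#' @param dist \code{dist} object. @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dist_tsv <- function(dist, path) {
  m <- as.matrix(dist)
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
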