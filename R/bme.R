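# The balanced length function, Pauplin pair weights, and the numerical
# tolerance for certified length comparisons.

# Accept a matrix or "dist"; check the DistanceMatrix invariants; return a
# plain double matrix.
as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d)) stop("distances must be a numeric matrix")
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  rel <- abs(d - t(d)) > 1e-9 * pmax(1, abs(d))
  if (any(rel)) stop("distance matrix is not symmetric")
  storage.mode(d) <- "double"
  d
}

# Reorder d so its row i corresponds to leaf i of the tree; errors on a
# taxon-set mismatch.
align_dist <- function(d, tree) {
  d <- as_dist_matrix(d)
  if (nrow(d) != tree$n) stop("matrix size does not match the tree's taxa")
  nm <- rownames(d)
  if (!is.null(nm) && !is.null(tree$taxa)) {
    if (!setequal(nm, tree$taxa)) stop("tree leaf set != matrix taxon set")
    d <- d[tree$taxa, tree$taxa, drop = FALSE]
  }
  d
}

#' Balanced minimum evolution tree length
#'
#' Computes \eqn{L(T) = \sum_{\{i,j\}} d_{ij} 2^{1-\tau_{ij}}} (summed over
#' unordered leaf pairs; equivalently \eqn{\sum_i \sum_{j \ne i} d_{ij}
#' 2^{-\tau_{ij}}} over ordered pairs), where \eqn{\tau_{ij}} is the
#' topological leaf-to-leaf distance. The sum is accumulated in a fixed
#' row-major pair order, so identical inputs give bit-identical lengths.
#'
#' @param d symmetric non-negative distance matrix (or `dist`); if both `d`
#'   and the tree carry taxon names, rows are aligned by name.
#' @param tree a `"phylo_topology"` object on the same taxa.
#' @return the scalar tree length.
#' @examples
#' tr <- decode_tree(c(3, 5), 5)
#' d <- matrix(1, 5, 5); diag(d) <- 0
#' bme_length(d, tr)  # 2.5 for any 5-taxon topology
#' @export
bme_length <- function(d, tree) {
  validate_topology(tree)
  d <- align_dist(d, tree)
  cpp_bme_length(tree$edges, d)
}

#' Pauplin pair weights of a topology
#'
#' The weight of pair (i, j) is \eqn{2^{1-\tau_{ij}}} (0 on the diagonal).
#' For every taxon the weights over all partners sum to exactly 1, so the
#' balanced length is a weighted average-like functional of the distances.
#'
#' @param tree a `"phylo_topology"` object.
#' @return symmetric numeric matrix.
#' @export
pauplin_weights <- function(tree) {
  tau <- path_length_matrix(tree)
  w <- 2^(1 - tau)
  diag(w) <- 0
  w
}

#' Numerical-precision tolerance for tree length comparison
#'
#' For trees with many taxa, pairs at topological distance >= 50 contribute
#' terms below double precision. Their total contribution is bounded by
#' \eqn{\omega = n^2 \, 2^{-49} \max_{ij} d_{ij}}, which can therefore serve
#' as an error tolerance when comparing computed lengths.
#'
#' @param d symmetric non-negative distance matrix (or `dist`).
#' @return the scalar bound.
#' @export
omega_bound <- function(d) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  n^2 * 2^-49 * max(d)
}

#' Certified strict comparison of two tree lengths
#'
#' `TRUE` iff `l1 + omega < l2`, which certifies that the exact length of the
#' first tree is below that of the second even in the presence of the
#' sub-epsilon terms bounded by `omega`. `FALSE` means "not certified", not
#' "greater or equal".
#'
#' @param l1,l2 tree lengths computed from the same distance matrix.
#' @param omega tolerance, typically [omega_bound()] of that matrix.
#' @return logical.
#' @export
certified_less <- function(l1, l2, omega) {
  (l1 + omega) < l2
}
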