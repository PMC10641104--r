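# Path lengths, splits and topology comparison.

#' Leaf-to-leaf topological distance matrix
#'
#' The entry (i, j) counts the edges on the unique path between leaves i and
#' j. Off-diagonal values lie in `2..n-1`; every binary tree has at least two
#' cherries (pairs at distance 2).
#'
#' @param tree a `"phylo_topology"` object.
#' @return symmetric integer matrix with zero diagonal, dimnames set to the
#'   taxon names when the tree carries them.
#' @export
path_length_matrix <- function(tree) {
  validate_topology(tree)
  tau <- cpp_path_lengths(tree$edges, tree$n)
  if (!is.null(tree$taxa)) dimnames(tau) <- list(tree$taxa, tree$taxa)
  tau
}

# Leaves on the side of internal edge `row` away from taxon 1, as a sorted
# integer vector (the canonical representation of a nontrivial split).
split_of_edge <- function(ed, n, row) {
  side <- reachable_nodes(ed[-row, , drop = FALSE], ed[row, 1L])
  leaves <- side[side <= n]
  if (1L %in% leaves) sort(setdiff(seq_len(n), leaves)) else sort(leaves)
}

#' Nontrivial splits (bipartitions) of a topology
#'
#' One split per internal edge, stored canonically as the sorted leaf set on
#' the side *not* containing taxon 1. A binary tree on `n >= 4` taxa has
#' exactly `n-3` of them; internal node labels do not affect the result.
#'
#' @param tree a `"phylo_topology"` object.
#' @return list of sorted integer vectors (empty for `n = 3`).
#' @export
tree_splits <- function(tree) {
  validate_topology(tree)
  n <- tree$n
  if (n == 3L) return(list())
  ed <- tree$edges
  internal <- which(ed[, 1L] > n & ed[, 2L] > n)
  lapply(internal, function(r) split_of_edge(ed, n, r))
}

split_keys <- function(tree) {
  vapply(tree_splits(tree), paste, character(1), collapse = ",")
}

check_same_leaves <- function(t1, t2) {
  if (t1$n != t2$n) stop("trees have different leaf sets")
  if (!is.null(t1$taxa) && !is.null(t2$taxa) && !identical(t1$taxa, t2$taxa))
    stop("trees carry different taxon tables; relabel to a common table first")
  invisible(TRUE)
}

#' Robinson-Foulds distance between two topologies
#'
#' Cardinality of the symmetric difference of the two sets of nontrivial
#' splits: an even number for two binary trees on the same leaves, 0 iff the
#' topologies are identical, at most `2(n-3)`.
#'
#' @param t1,t2 `"phylo_topology"` objects on the same leaf set.
#' @return a non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  k1 <- split_keys(t1)
  k2 <- split_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Are two topologies identical?
#'
#' `TRUE` iff the Robinson-Foulds distance is zero.
#'
#' @inheritParams rf_distance
#' @return logical.
#' @export
same_topology <- function(t1, t2) {
  rf_distance(t1, t2) == 0L
}
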