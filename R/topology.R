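# Unrooted binary leaf-labelled tree topologies.
#
# A topology on n taxa stores its edges as an (2n-3) x 2 integer matrix over
# nodes 1..2n-2: leaves are 1..n, internal nodes n+1..2n-2. Rows are stored
# as (smaller, larger) and sorted ascending by (min endpoint, max endpoint);
# this is the same canonical edge order the step-wise encoding reads, so the
# ordered edge list of a tree is just its stored edge matrix.

canonical_edges <- function(edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  a <- pmin(edges[, 1], edges[, 2])
  b <- pmax(edges[, 1], edges[, 2])
  o <- order(a, b)
  cbind(a[o], b[o], deparse.level = 0)
}

#' Construct an unrooted binary tree topology
#'
#' Builds the package's tree container from an edge list. Leaves must be
#' labelled `1..n` and internal nodes `n+1..2n-2` (in any order); every leaf
#' has degree 1 and every internal node degree 3.
#'
#' @param n taxon count (>= 3).
#' @param edges two-column matrix of node labels, one row per edge
#'   (`2n-3` rows).
#' @param taxa optional character vector of taxon names, position `i` naming
#'   leaf `i`.
#' @param validate check the structural invariants (default `TRUE`).
#' @return an object of class `"phylo_topology"`: a list with elements `n`,
#'   `edges` (canonically ordered) and `taxa`.
#' @examples
#' quartet <- new_topology(4, rbind(c(1, 5), c(2, 5), c(3, 6), c(4, 6), c(5, 6)))
#' quartet
#' @seealso [decode_tree()], [encode_tree()], [random_topology()]
#' @export
new_topology <- function(n, edges, taxa = NULL, validate = TRUE) {
  n <- as.integer(n)
  obj <- structure(list(n = n, edges = canonical_edges(edges), taxa = taxa),
                   class = "phylo_topology")
  if (validate) validate_topology(obj)
  obj
}

#' Validate the structural invariants of a topology
#'
#' Checks leaf degrees (1), internal degrees (3), the edge count `2n-3`,
#' label ranges and connectivity; stops with an informative error on the
#' first violation.
#'
#' @param tree a `"phylo_topology"` object.
#' @return `TRUE`, invisibly.
#' @export
validate_topology <- function(tree) {
  if (!inherits(tree, "phylo_topology")) stop("not a 'phylo_topology' object")
  n <- tree$n
  ed <- tree$edges
  if (is.na(n) || n < 3L) stop("a topology needs at least 3 taxa")
  if (nrow(ed) != 2L * n - 3L)
    stop("expected ", 2L * n - 3L, " edges, found ", nrow(ed))
  if (any(ed < 1L) || any(ed > 2L * n - 2L)) stop("node label out of range")
  deg <- tabulate(ed, nbins = 2L * n - 2L)
  if (any(deg[seq_len(n)] != 1L))
    stop("every leaf must have degree 1")
  if (any(deg[(n + 1L):(2L * n - 2L)] != 3L))
    stop("every internal node must have degree 3")
  if (length(reachable_nodes(ed, 1L)) != 2L * n - 2L)
    stop("tree is not connected")
  if (!is.null(tree$taxa)) {
    if (length(tree$taxa) != n) stop("taxa table must have length n")
    if (anyDuplicated(tree$taxa)) stop("taxon names must be unique")
  }
  invisible(TRUE)
}

# Nodes reachable from `from` along an edge list (frontier expansion; trees
# here are tiny, so quadratic scans are fine).
reachable_nodes <- function(edges, from) {
  seen <- from
  frontier <- from
  repeat {
    inc <- edges[, 1] %in% frontier | edges[, 2] %in% frontier
    nxt <- setdiff(c(edges[inc, ]), seen)
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

taxa_or_default <- function(tree) {
  if (is.null(tree$taxa)) paste0("t", seq_len(tree$n)) else tree$taxa
}

#' @export
print.phylo_topology <- function(x, ...) {
  cat(sprintf("Unrooted binary topology: %d taxa, %d edges\n", x$n,
              nrow(x$edges)))
  cat(" ", write_newick(x), "\n", sep = "")
  invisible(x)
}

#' Convert a topology to an ape "phylo" object
#'
#' @param x a `"phylo_topology"` object.
#' @param ... unused.
#' @return an unrooted `ape::phylo` tree (no branch lengths).
#' @importFrom ape as.phylo
#' @method as.phylo phylo_topology
#' @export
as.phylo.phylo_topology <- function(x, ...) {
  ape::read.tree(text = write_newick(x))
}
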