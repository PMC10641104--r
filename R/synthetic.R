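# Synthetic data: random additive (tree-realizable) distance matrices,
# multiplicative noise, and the two worked-example topologies.

weighted_leaf_paths <- function(tree, weights) {
  n <- tree$n
  ed <- tree$edges
  adj <- adjacency_list(tree)
  wt <- function(a, b) weights[which(ed[, 1L] == min(a, b) &
                                     ed[, 2L] == max(a, b))]
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    acc <- rep(NA_real_, 2L * n - 2L)
    acc[i] <- 0
    frontier <- i
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) for (v in adj[[u]]) if (is.na(acc[v])) {
        acc[v] <- acc[u] + wt(u, v)
        nxt <- c(nxt, v)
      }
      frontier <- nxt
    }
    d[i, ] <- acc[seq_len(n)]
  }
  (d + t(d)) / 2
}

#' Random additive distance matrix from a random tree
#'
#' Samples a uniformly random topology through the step-wise encoding,
#' draws independent exponential branch lengths, and sets each distance to
#' the sum of branch lengths on the leaf-to-leaf path. The result is
#' exactly additive (satisfies the four-point condition), so the balanced
#' minimum evolution optimum is the generating topology — the polynomially
#' solvable regime used as a recovery oracle.
#'
#' @param n taxon count (>= 3).
#' @param mean_bl mean of the exponential branch-length distribution
#'   (default 0.1, a conventional phylogenetic simulation scale).
#' @param seed optional integer seed (`NULL` uses the current RNG state).
#' @return a list with the distance matrix `d` (taxa `t1..tn`), the
#'   generating `tree` and its `branch_lengths` (in the order of the tree's
#'   canonical edge list).
#' @export
random_additive_matrix <- function(n, mean_bl = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (mean_bl <= 0) stop("mean_bl must be positive")
  taxa <- paste0("t", seq_len(n))
  tree <- random_topology(n, taxa = taxa)
  bl <- stats::rexp(nrow(tree$edges), rate = 1 / mean_bl)
  d <- weighted_leaf_paths(tree, bl)
  dimnames(d) <- list(taxa, taxa)
  list(d = d, tree = tree, branch_lengths = bl)
}

#' Perturb a distance matrix with multiplicative noise
#'
#' Each unordered pair gets one Gaussian draw:
#' `d'_ij = d_ij * max(0, 1 + e_ij)` with `e_ij ~ N(0, sigma)`. The clamp
#' keeps the matrix non-negative and the single draw per pair keeps it
#' symmetric; the diagonal stays zero. `sigma = 0` is the identity.
#'
#' @param d symmetric non-negative matrix.
#' @param sigma noise standard deviation (>= 0).
#' @param seed optional integer seed.
#' @return the perturbed matrix.
#' @export
perturb_matrix <- function(d, sigma, seed = NULL) {
  d <- as_dist_matrix(d)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(d)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(d)
  out <- d
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    f <- max(0, 1 + stats::rnorm(1L, 0, sigma))
    out[i, j] <- out[j, i] <- d[i, j] * f
  }
  out
}

#' The two worked-example topologies on five taxa
#'
#' The pair of 5-taxon trees used throughout the documentation to
#' illustrate the step-wise encoding: codes (3,5) — topology
#' ((t1,t2),t5,(t3,t4)) — and (1,3) — topology ((t1,t4),t2,(t3,t5)).
#'
#' @return a named list of two `"phylo_topology"` objects, `T1` and `T2`,
#'   with taxa `t1..t5`.
#' @export
worked_example_trees <- function() {
  taxa <- paste0("t", 1:5)
  list(T1 = decode_tree(c(3L, 5L), 5L, taxa = taxa),
       T2 = decode_tree(c(1L, 3L), 5L, taxa = taxa))
}
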