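# Independent oracles and small generators used across the suite.

# All-pairs leaf distances through igraph's BFS — independent of the
# package's compiled path-length code.
oracle_tau <- function(tree) {
  g <- igraph::graph_from_edgelist(tree$edges, directed = FALSE)
  d <- igraph::distances(g)
  storage.mode(d) <- "integer"
  d[seq_len(tree$n), seq_len(tree$n)]
}

# The ordered-pair form of the balanced length, sum_i sum_{j != i}
# d_ij 2^(-tau_ij), computed from the igraph distances.
oracle_bme <- function(d, tree) {
  tau <- oracle_tau(tree)
  sum(d * 2^-tau * (1 - diag(nrow(d))))
}

# Metric (Euclidean) distance matrix from random points.
random_metric_matrix <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(runif(n * 5), n)
  d <- as.matrix(dist(pts))
  diag(d) <- 0
  dimnames(d) <- NULL
  d
}

# Maximally unbalanced topology: internal nodes n+1..2n-2 form a path.
caterpillar_topology <- function(n) {
  I <- function(j) n + j
  ed <- rbind(c(1, I(1)), c(2, I(1)))
  for (j in 2:(n - 2)) ed <- rbind(ed, c(j + 1, I(j)), c(I(j - 1), I(j)))
  ed <- rbind(ed, c(n, I(n - 2)))
  new_topology(n, ed)
}

# Canonical fingerprint of a topology (splits are label-invariant).
topo_key <- function(tree) {
  paste(sort(vapply(tree_splits(tree), paste, character(1), collapse = ",")),
        collapse = "|")
}

random_tree_seeded <- function(n, seed) {
  set.seed(seed)
  random_topology(n)
}

# Four-point condition: for every quadruple the two largest of the three
# pair sums coincide (within tol).
four_point_holds <- function(d, tol = 1e-10) {
  n <- nrow(d)
  for (q in combn(n, 4, simplify = FALSE)) {
    i <- q[1]; j <- q[2]; k <- q[3]; r <- q[4]
    s <- sort(c(d[i, j] + d[k, r], d[i, k] + d[j, r], d[i, r] + d[j, k]))
    if (s[3] - s[2] > tol) return(FALSE)
  }
  TRUE
}
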