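# NNI and SPR neighbourhoods and the BNNI/BSPR steepest-descent local
# searches under the balanced length.
#
# The descent loops run in compiled code (see src/phyloes.cpp) and evaluate
# every neighbour by direct recomputation of the length function; the pure-R
# enumeration functions below generate the same neighbourhoods move by move
# and exist so that local optimality and descent soundness can be verified
# independently of the compiled path.

adjacency_list <- function(tree) {
  n2 <- 2L * tree$n - 2L
  adj <- vector("list", n2)
  for (r in seq_len(nrow(tree$edges))) {
    u <- tree$edges[r, 1L]
    v <- tree$edges[r, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

swap_subtrees <- function(tree, u, A, v, C) {
  ed <- tree$edges
  key <- function(a, b) which(ed[, 1L] == min(a, b) & ed[, 2L] == max(a, b))
  ed[key(u, A), ] <- c(min(u, C), max(u, C))
  ed[key(v, C), ] <- c(min(v, A), max(v, A))
  new_topology(tree$n, ed, taxa = tree$taxa)
}

#' NNI neighbours of a topology
#'
#' A nearest-neighbour interchange on an internal edge swaps two of the four
#' subtrees hanging off its endpoints. Exactly two of the three pairings
#' give new topologies (the third is symmetric), so each of the `n-3`
#' internal edges contributes 2 neighbours and the full neighbourhood has
#' size `2(n-3)`.
#'
#' @param tree a `"phylo_topology"` object.
#' @param edge optionally, a length-2 vector naming one internal edge; then
#'   only its two neighbours are returned. Must connect two internal nodes.
#' @return a list of `"phylo_topology"` objects.
#' @export
nni_neighbors <- function(tree, edge = NULL) {
  validate_topology(tree)
  n <- tree$n
  adj <- adjacency_list(tree)
  one_edge <- function(u, v) {
    A <- sort(setdiff(adj[[u]], v))
    C <- sort(setdiff(adj[[v]], u))
    list(swap_subtrees(tree, u, A[1L], v, C[1L]),
         swap_subtrees(tree, u, A[1L], v, C[2L]))
  }
  if (!is.null(edge)) {
    u <- min(edge)
    v <- max(edge)
    if (u <= n || v <= n) stop("NNI requires an internal edge")
    hit <- any(tree$edges[, 1L] == u & tree$edges[, 2L] == v)
    if (!hit) stop("no such edge in the tree")
    return(one_edge(u, v))
  }
  internal <- which(tree$edges[, 1L] > n & tree$edges[, 2L] > n)
  out <- list()
  for (r in internal)
    out <- c(out, one_edge(tree$edges[r, 1L], tree$edges[r, 2L]))
  out
}

#' Enumerate all SPR moves of a topology
#'
#' A subtree prune-and-regraft move detaches the subtree rooted at `s`
#' across the edge `(s, p)` (the attachment node `p` must be internal),
#' suppresses `p`, and reattaches the subtree onto another edge `(u, v)` of
#' the remainder. Regraft edges inside the pruned subtree or incident to `p`
#' are excluded, so every listed move changes the topology. The move count
#' is O(n^2).
#'
#' @param tree a `"phylo_topology"` object with `n >= 4`.
#' @return a data.frame with columns `s`, `p`, `u`, `v`, one row per move,
#'   in the deterministic enumeration order of the descent.
#' @export
spr_moves <- function(tree) {
  validate_topology(tree)
  if (tree$n < 4L) stop("SPR needs at least 4 taxa")
  n <- tree$n
  ed <- tree$edges
  adj <- adjacency_list(tree)
  rows <- vector("list", 4L * nrow(ed))
  nr <- 0L
  for (k in seq_len(nrow(ed))) {
    for (dir in 1:2) {
      s <- ed[k, dir]
      p <- ed[k, 3L - dir]
      if (p <= n) next
      inside <- reachable_nodes(ed[-k, , drop = FALSE], s)
      for (j in seq_len(nrow(ed))) {
        u <- ed[j, 1L]
        v <- ed[j, 2L]
        if (u %in% inside || v %in% inside || u == p || v == p) next
        nr <- nr + 1L
        rows[[nr]] <- c(s = s, p = p, u = u, v = v)
      }
    }
  }
  as.data.frame(do.call(rbind, rows[seq_len(nr)]))
}

#' Apply one SPR move
#'
#' @param tree a `"phylo_topology"` object.
#' @param move one row of [spr_moves()] (or any list with elements
#'   `s`, `p`, `u`, `v`).
#' @return the rearranged `"phylo_topology"`.
#' @export
apply_spr <- function(tree, move) {
  s <- move$s
  p <- move$p
  u <- move$u
  v <- move$v
  adj <- adjacency_list(tree)
  xy <- setdiff(adj[[p]], s)
  ed <- tree$edges
  key <- function(a, b) which(ed[, 1L] == min(a, b) & ed[, 2L] == max(a, b))
  ed[key(p, xy[1L]), ] <- c(min(xy[1L], xy[2L]), max(xy[1L], xy[2L]))
  ed[key(p, xy[2L]), ] <- c(min(p, u), max(p, u))
  ed[key(u, v), ] <- c(min(p, v), max(p, v))
  new_topology(tree$n, ed, taxa = tree$taxa)
}

#' All SPR neighbours of a topology
#'
#' @param tree a `"phylo_topology"` object.
#' @return a list of `"phylo_topology"` objects, one per row of
#'   [spr_moves()].
#' @export
spr_neighbors <- function(tree) {
  mv <- spr_moves(tree)
  lapply(seq_len(nrow(mv)), function(i) apply_spr(tree, mv[i, ]))
}

descent_result <- function(tree, d, r) {
  list(tree = new_topology(tree$n, r$edges, taxa = tree$taxa,
                           validate = FALSE),
       length = r$length,
       iterations = r$iterations,
       trace = as.numeric(r$trace))
}

#' Balanced NNI steepest descent
#'
#' Repeatedly evaluates all NNI neighbours (by direct recomputation of the
#' balanced length) and applies the single best strictly improving move —
#' first in the deterministic enumeration order on ties — until the tree is
#' an NNI-local optimum.
#'
#' @param tree starting `"phylo_topology"`.
#' @param d distance matrix on the tree's taxa.
#' @return a list with elements `tree` (the local optimum), `length`,
#'   `iterations` (number of accepted moves) and `trace` (length after each
#'   accepted move).
#' @export
bnni <- function(tree, d) {
  validate_topology(tree)
  d <- align_dist(d, tree)
  descent_result(tree, d, cpp_bnni(tree$edges, d))
}

#' Balanced SPR steepest descent
#'
#' As [bnni()] but over the O(n^2) SPR neighbourhood; the returned tree is
#' an SPR-local optimum.
#'
#' @inheritParams bnni
#' @return as [bnni()].
#' @export
bspr <- function(tree, d) {
  validate_topology(tree)
  d <- align_dist(d, tree)
  descent_result(tree, d, cpp_bspr(tree$edges, d))
}

#' Full local-search refinement: BNNI followed by BSPR
#'
#' The refinement every tree passes through in the evolution strategy:
#' NNI descent first (cheap), then SPR descent from its result.
#'
#' @inheritParams bnni
#' @return a list with `tree`, `length`, `nni_iterations`,
#'   `spr_iterations` and the concatenated descent `trace`.
#' @export
rearrange_tree <- function(tree, d) {
  validate_topology(tree)
  d <- align_dist(d, tree)
  r1 <- cpp_bnni(tree$edges, d)
  r2 <- cpp_bspr(r1$edges, d)
  list(tree = new_topology(tree$n, r2$edges, taxa = tree$taxa,
                           validate = FALSE),
       length = r2$length,
       nni_iterations = r1$iterations,
       spr_iterations = r2$iterations,
       trace = c(as.numeric(r1$trace), as.numeric(r2$trace)))
}
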