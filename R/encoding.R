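# Step-wise tree encoding.
#
# Any unrooted binary topology on taxa 1..n can be grown from the star on
# taxa 1,2,3 (centre n+1) by inserting taxon i+3 on one edge of the partial
# tree at step i; the internal node created at step i is labelled n+1+i.
# Recording, for each step, the index of the chosen edge in the *ordered*
# edge list (ascending by (min endpoint, max endpoint)) gives an integer
# vector (h_1..h_{n-3}) with 1 <= h_i <= 2i+1 that is bijective with the
# (2n-5)!! topologies. The code space is closed under per-component
# mutation, which is what the evolution strategy exploits.

#' Ordered edge list of a topology
#'
#' Returns the edges sorted ascending by (smaller endpoint, larger
#' endpoint) — the deterministic order in which the step-wise encoding
#' indexes insertion edges.
#'
#' @param tree a `"phylo_topology"` object, or a bare two-column edge matrix
#'   (useful for the partial trees that arise mid-construction).
#' @return a two-column integer matrix.
#' @export
ordered_edges <- function(tree) {
  if (inherits(tree, "phylo_topology")) return(tree$edges)
  canonical_edges(tree)
}

check_code <- function(code, n) {
  if (n < 3L) stop("need at least 3 taxa")
  if (length(code) != n - 3L)
    stop("a code for ", n, " taxa must have ", n - 3L, " components")
  if (length(code)) {
    lim <- 2L * seq_along(code) + 1L
    bad <- which(code < 1L | code > lim)
    if (length(bad))
      stop("code component ", bad[1L], " out of range 1..", lim[bad[1L]])
  }
  invisible(TRUE)
}

#' Decode a step-wise tree code into a topology
#'
#' Starts from the star on taxa 1,2,3 with centre `n+1`; at step `i` the
#' `code[i]`-th edge of the ordered edge list is subdivided by a new internal
#' node `n+1+i` to which taxon `i+3` is attached.
#'
#' @param code integer vector of length `n-3` with `1 <= code[i] <= 2i+1`
#'   (empty for `n = 3`).
#' @param n taxon count.
#' @param taxa optional taxon names attached to the result.
#' @return a `"phylo_topology"` object.
#' @examples
#' decode_tree(c(3, 5), 5)  # ((t1,t2),t5,(t3,t4))
#' @export
decode_tree <- function(code, n, taxa = NULL) {
  n <- as.integer(n)
  code <- as.integer(code)
  check_code(code, n)
  edges <- cbind(1:3, rep(n + 1L, 3L))
  for (i in seq_along(code)) {
    ce <- canonical_edges(edges)
    sel <- ce[code[i], ]
    w <- n + 1L + i
    edges <- rbind(ce[-code[i], , drop = FALSE],
                   c(sel[1L], w), c(sel[2L], w), c(i + 3L, w))
  }
  new_topology(n, edges, taxa = taxa, validate = FALSE)
}

#' Encode a topology as its step-wise tree code
#'
#' Inverse of [decode_tree()] up to internal-node relabelling: leaves
#' `t_n` down to `t_4` are stripped (suppressing each attachment node
#' restores one edge), then the construction is replayed forward with
#' canonical labels, reporting each restored edge's index in the ordered
#' edge list. Internal labels of the input may be any permutation of
#' `n+1..2n-2`.
#'
#' @param tree a `"phylo_topology"` object.
#' @return integer vector of length `n-3`.
#' @examples
#' encode_tree(decode_tree(c(3, 5), 5))  # c(3, 5)
#' @export
encode_tree <- function(tree) {
  validate_topology(tree)
  n <- tree$n
  if (n == 3L) return(integer(0))
  ed <- tree$edges
  rec_v <- rec_a <- rec_b <- integer(n)
  for (k in n:4) {
    i <- which(ed[, 1L] == k | ed[, 2L] == k)
    v <- ed[i, 1L] + ed[i, 2L] - k
    j <- setdiff(which(ed[, 1L] == v | ed[, 2L] == v), i)
    a <- ed[j[1L], 1L] + ed[j[1L], 2L] - v
    b <- ed[j[2L], 1L] + ed[j[2L], 2L] - v
    rec_v[k] <- v
    rec_a[k] <- a
    rec_b[k] <- b
    ed <- rbind(ed[-c(i, j), , drop = FALSE], c(a, b))
  }
  centre <- setdiff(unique(c(ed)), 1:3)
  map <- integer(2L * n - 2L)
  map[centre] <- n + 1L
  relab <- function(x) if (x <= n) x else map[x]
  cur <- cbind(1:3, rep(n + 1L, 3L))
  h <- integer(n - 3L)
  for (i in seq_len(n - 3L)) {
    k <- i + 3L
    a <- relab(rec_a[k])
    b <- relab(rec_b[k])
    ce <- canonical_edges(cur)
    idx <- which(ce[, 1L] == min(a, b) & ce[, 2L] == max(a, b))
    if (length(idx) != 1L) stop("encoding failed: restored edge not found")
    h[i] <- idx
    w <- n + 1L + i
    map[rec_v[k]] <- w
    cur <- rbind(ce[-idx, , drop = FALSE],
                 c(min(a, b), w), c(max(a, b), w), c(k, w))
  }
  h
}

#' Draw a uniformly random tree code
#'
#' Each component `h_i` is drawn independently and uniformly from
#' `1..2i+1`, so the induced distribution over the `(2n-5)!!` topologies is
#' uniform. Uses R's current random number generator state.
#'
#' @param n taxon count (>= 3).
#' @return integer vector of length `n-3`.
#' @export
random_code <- function(n) {
  n <- as.integer(n)
  if (n < 3L) stop("need at least 3 taxa")
  if (n == 3L) return(integer(0))
  vapply(seq_len(n - 3L),
         function(i) sample.int(2L * i + 1L, 1L),
         integer(1))
}

#' Draw a uniformly random topology
#'
#' @inheritParams random_code
#' @param taxa optional taxon names.
#' @return a `"phylo_topology"` object.
#' @export
random_topology <- function(n, taxa = NULL) {
  decode_tree(random_code(n), n, taxa = taxa)
}

#' Enumerate all tree codes for n taxa
#'
#' Exhaustive code space: `prod(2i+1) = (2n-5)!!` rows. Intended for the
#' small n used in oracles and exhaustive searches.
#'
#' @param n taxon count (3..8 is practical).
#' @return integer matrix with one code per row (`n = 3` gives a single
#'   zero-column row).
#' @export
all_tree_codes <- function(n) {
  n <- as.integer(n)
  if (n < 3L) stop("need at least 3 taxa")
  if (n == 3L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  grid <- expand.grid(lapply(seq_len(n - 3L), function(i) seq_len(2L * i + 1L)),
                      KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(grid)
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}
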