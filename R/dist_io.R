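# PHYLIP square distance matrices and Newick trees.
#
# Only the square symmetric PHYLIP dialect is supported (the format modern
# distance pipelines emit); names are relaxed tokens, not the classic
# 10-character fields. Newick parsing is delegated to ape; writing uses a
# canonical, bit-stable form so identical topologies always serialize to
# identical strings.

#' Read a square PHYLIP distance matrix
#'
#' The first token is the taxon count n, followed by n rows of
#' `name v1 ... vn`; tokens may wrap across lines. Symmetry (relative
#' tolerance 1e-9), a zero diagonal (1e-12) and non-negativity are enforced.
#'
#' @param file path to the file, or a connection.
#' @param text optionally, the file content as a character string (then
#'   `file` is ignored).
#' @return numeric matrix with taxon names as dimnames, in file order.
#' @export
read_phylip_matrix <- function(file, text = NULL) {
  if (!is.null(text)) {
    tok <- scan(text = text, what = "character", quiet = TRUE)
  } else {
    if (is.character(file) && !file.exists(file))
      stop("no such file: ", file)
    tok <- scan(file, what = "character", quiet = TRUE)
  }
  if (!length(tok)) stop("empty PHYLIP input")
  n <- suppressWarnings(as.integer(tok[1L]))
  if (is.na(n) || n < 3L) stop("first token must be the taxon count (>= 3)")
  tok <- tok[-1L]
  if (length(tok) != n * (n + 1L))
    stop("expected ", n * (n + 1L), " tokens for ", n,
         " taxa, found ", length(tok))
  tok <- matrix(tok, nrow = n, byrow = TRUE)
  taxa <- trimws(tok[, 1L])
  if (any(!nzchar(taxa))) stop("empty taxon name")
  if (anyDuplicated(taxa)) stop("duplicated taxon name: ",
                                taxa[duplicated(taxa)][1L])
  vals <- suppressWarnings(as.numeric(tok[, -1L, drop = FALSE]))
  if (anyNA(vals)) stop("non-numeric distance value")
  d <- matrix(vals, nrow = n)
  if (any(d < 0)) stop("negative distance value")
  if (any(abs(diag(d)) > 1e-12)) stop("nonzero diagonal entry")
  if (any(abs(d - t(d)) > 1e-9 * pmax(1, abs(d))))
    stop("asymmetric distance matrix")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(taxa, taxa)
  d
}

#' Write a square PHYLIP distance matrix
#'
#' Values are printed with 12 significant digits; [read_phylip_matrix()]
#' inverts the writer to that precision.
#'
#' @param d symmetric non-negative numeric matrix; taxon names are taken
#'   from its rownames (default `t1..tn`).
#' @param file path or connection ("" prints to stdout).
#' @return `file`, invisibly.
#' @export
write_phylip_matrix <- function(d, file = "") {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  taxa <- rownames(d)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  rows <- vapply(seq_len(n), function(i)
    paste(c(taxa[i], sprintf("%.12g", d[i, ])), collapse = " "),
    character(1))
  writeLines(c(as.character(n), rows), con = file)
  invisible(file)
}

subtree_newick <- function(node, parent, adj, n, taxa) {
  if (node <= n)
    return(list(label = taxa[node], min_leaf = node))
  kids <- setdiff(adj[[node]], parent)
  parts <- lapply(kids, subtree_newick, parent = node, adj = adj, n = n,
                  taxa = taxa)
  mins <- vapply(parts, `[[`, numeric(1), "min_leaf")
  o <- order(mins)
  list(label = paste0("(", paste(vapply(parts[o], `[[`, character(1),
                                        "label"), collapse = ","), ")"),
       min_leaf = min(mins))
}

#' Write a topology as canonical Newick
#'
#' The tree is displayed as a trifurcation at the internal node adjacent to
#' taxon 1, children ordered by the smallest leaf label in each subtree, no
#' branch lengths. The output is bit-stable for a given topology.
#'
#' @param tree a `"phylo_topology"` object.
#' @param taxa taxon names (defaults to the tree's own table, else
#'   `t1..tn`).
#' @param file optional path or connection; when `NULL` (default) the string
#'   is returned instead.
#' @return the Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, taxa = NULL, file = NULL) {
  validate_topology(tree)
  n <- tree$n
  if (is.null(taxa)) taxa <- taxa_or_default(tree)
  if (length(taxa) != n) stop("need one name per taxon")
  adj <- adjacency_list(tree)
  root <- adj[[1L]]
  parts <- lapply(adj[[root]], subtree_newick, parent = root, adj = adj,
                  n = n, taxa = taxa)
  mins <- vapply(parts, `[[`, numeric(1), "min_leaf")
  o <- order(mins)
  s <- paste0("(", paste(vapply(parts[o], `[[`, character(1), "label"),
                         collapse = ","), ");")
  if (is.null(file)) return(s)
  writeLines(s, con = file)
  invisible(s)
}

#' Read a Newick tree as a topology
#'
#' Branch lengths, if present, are parsed and discarded. A rooted input
#' whose root has degree 2 is unrooted by suppressing the root; any other
#' polytomy is an error (this package handles binary trees only).
#'
#' @param file path to a Newick file.
#' @param text optionally, the Newick string itself (then `file` is
#'   ignored).
#' @param taxa optional taxon table: leaf `i` of the result is the taxon
#'   named `taxa[i]`. When `NULL`, taxa are numbered in order of appearance
#'   in the Newick string.
#' @return a `"phylo_topology"` object carrying the taxon table.
#' @export
read_newick <- function(file, text = NULL, taxa = NULL) {
  if (is.null(text) && is.character(file) && !file.exists(file))
    stop("no such file: ", file)
  ph <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(ph)) stop("could not parse Newick input")
  n <- length(ph$tip.label)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- trimws(ph$tip.label)
  if (is.null(taxa)) {
    idx <- seq_len(n)
    taxa <- labels
  } else {
    idx <- match(labels, taxa)
    if (anyNA(idx))
      stop("unknown taxon name: ", labels[which(is.na(idx))[1L]])
    if (length(taxa) != n) stop("tree and taxon table differ in size")
  }
  edge <- ph$edge
  root <- setdiff(edge[, 1L], edge[, 2L])
  if (sum(edge[, 1L] == root) == 2L) {  # rooted: suppress the root
    kids <- edge[edge[, 1L] == root, 2L]
    edge <- edge[edge[, 1L] != root, , drop = FALSE]
    edge <- rbind(edge, kids)
  }
  nodes <- sort(unique(c(edge)))
  internal <- nodes[nodes > n]
  if (length(internal) != n - 2L)
    stop("polytomy: this reader accepts binary trees only")
  map <- integer(max(nodes))
  map[seq_len(n)] <- idx
  map[internal] <- n + seq_along(internal)
  ed <- cbind(map[edge[, 1L]], map[edge[, 2L]])
  deg <- tabulate(ed, nbins = 2L * n - 2L)
  if (any(deg[(n + 1L):(2L * n - 2L)] != 3L))
    stop("polytomy: this reader accepts binary trees only")
  new_topology(n, ed, taxa = taxa)
}
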