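# The (mu+lambda) evolution strategy over tree codes, the matched-budget
# random-initialization baseline, and exhaustive enumeration for oracles.

#' Evolution strategy configuration
#'
#' Defaults mirror the study conditions: `maxiter = 1000`, `tol = 1e-12`,
#' population size 64 for generations 0-4, 32 for 5-24 and 16 from
#' generation 25 on; mu and lambda both equal the scheduled size.
#'
#' @param maxiter maximum number of generations (>= 1).
#' @param tol stop when the worst-minus-best length in the population falls
#'   to `tol` or below (>= 0).
#' @param pop_schedule data.frame with columns `size` (positive,
#'   non-increasing) and `until` (increasing generation thresholds, last
#'   `Inf`): the population size at generation g is the first `size` with
#'   `g < until`.
#' @param seed integer root seed; it drives the initialization draws and,
#'   through a derived value, the recombination stream.
#' @return a list of class `"es_config"`.
#' @export
es_config <- function(maxiter = 1000L, tol = 1e-12,
                      pop_schedule = data.frame(size = c(64L, 32L, 16L),
                                                until = c(5, 25, Inf)),
                      seed = 1L) {
  maxiter <- as.integer(maxiter)
  if (is.na(maxiter) || maxiter < 1L) stop("maxiter must be >= 1")
  if (!is.numeric(tol) || tol < 0) stop("tol must be >= 0")
  s <- pop_schedule
  if (!is.data.frame(s) || !all(c("size", "until") %in% names(s)) ||
      !nrow(s))
    stop("pop_schedule needs columns 'size' and 'until'")
  if (any(s$size < 1L)) stop("population sizes must be positive")
  if (is.unsorted(rev(s$size))) stop("population sizes must be non-increasing")
  if (is.unsorted(s$until, strictly = TRUE)) stop("'until' must be increasing")
  if (is.finite(s$until[nrow(s)])) stop("last 'until' must be Inf (open-ended)")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(maxiter = maxiter, tol = tol, pop_schedule = s, seed = seed),
            class = "es_config")
}

pop_size_at <- function(g, schedule) {
  as.integer(schedule$size[which(g < schedule$until)[1L]])
}

# Second stream seed: one multiplicative-congruential step of the root seed,
# kept inside the 32-bit integer range.
derive_seed <- function(seed) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 %% 2147483647)
}

#' Recombine a population of tree codes into one offspring code
#'
#' Component j of the child is drawn uniformly from the multiset of the
#' parents' j-th components (duplicates count); components are drawn
#' independently. Because every parent component is in range, the child is
#' always a valid code.
#'
#' @param codes integer matrix, one parent code per row.
#' @return integer vector (one child code).
#' @export
recombine_codes <- function(codes) {
  if (!is.matrix(codes) || !nrow(codes)) stop("need a non-empty code matrix")
  nc <- ncol(codes)
  if (!nc) return(integer(0))
  pick <- sample.int(nrow(codes), nc, replace = TRUE)
  codes[cbind(pick, seq_len(nc))]
}

#' Truncation selection
#'
#' Keeps the `mu` individuals of smallest length from a pool; ties are
#' broken by stable order (the pool is passed parents-first, so parents win
#' ties against offspring).
#'
#' @param pool list of individuals, each a list with a numeric `length`.
#' @param mu number of survivors (0 < mu <= length(pool)).
#' @return the selected sub-list, sorted ascending by length (stable).
#' @export
truncation_select <- function(pool, mu) {
  mu <- as.integer(mu)
  if (is.na(mu) || mu < 1L) stop("mu must be positive")
  if (mu > length(pool)) stop("mu exceeds the pool size")
  lens <- vapply(pool, `[[`, numeric(1), "length")
  ord <- order(lens, method = "radix")
  pool[ord[seq_len(mu)]]
}

#' Anti-stagnation individual replacement
#'
#' If the worst length occurs at least twice in the population and some
#' individual is strictly better, one worst-length individual (the last in
#' stable order) is replaced by a copy of the "second worst" — the
#' individual with the largest length strictly below the worst. Otherwise
#' the population is unchanged.
#'
#' @param pop list of individuals sorted ascending by length.
#' @return the (possibly modified) population, re-sorted stably.
#' @export
individual_replacement <- function(pop) {
  lens <- vapply(pop, `[[`, numeric(1), "length")
  w <- max(lens)
  iw <- which(lens == w)
  if (length(iw) < 2L || !any(lens < w)) return(pop)
  second <- max(lens[lens < w])
  donor <- which(lens == second)[1L]
  pop[[iw[length(iw)]]] <- pop[[donor]]
  lens <- vapply(pop, `[[`, numeric(1), "length")
  pop[order(lens, method = "radix")]
}

new_individual <- function(code, d, n) {
  res <- rearrange_tree(decode_tree(code, n), d)
  list(code = encode_tree(res$tree), tree = res$tree, length = res$length,
       nni = res$nni_iterations, spr = res$spr_iterations)
}

pop_codes <- function(pop) {
  do.call(rbind, lapply(pop, `[[`, "code"))
}

stats_row <- function(g, pop, offspring, trees, nni, spr) {
  lens <- vapply(pop, `[[`, numeric(1), "length")
  data.frame(generation = g, pop_size = length(pop),
             best_length = min(lens), worst_length = max(lens),
             offspring = offspring, trees_total = trees,
             nni_total = nni, spr_total = spr)
}

finish_run <- function(pop, rows, reason, config, taxa) {
  best <- pop[[1L]]
  best$tree$taxa <- taxa
  gens <- do.call(rbind, rows)
  rownames(gens) <- NULL
  stopifnot(!is.unsorted(rev(gens$best_length)))  # monotone best length
  list(tree = best$tree, length = best$length, code = best$code,
       generations = gens, stop_reason = reason,
       trees_generated = gens$trees_total[nrow(gens)],
       nni_iterations = gens$nni_total[nrow(gens)],
       spr_iterations = gens$spr_total[nrow(gens)],
       config = config)
}

# Exhaustive short-circuit used for n <= 4, where the code space has at
# most 3 elements.
run_tiny <- function(d, config, taxa) {
  n <- nrow(d)
  ex <- exhaustive_bme(d)
  pop <- lapply(seq_along(ex$lengths), function(i)
    list(code = ex$codes[i, ], tree = ex$trees[[i]], length = ex$lengths[i],
         nni = 0L, spr = 0L))
  pop <- truncation_select(pop, length(pop))
  k <- length(pop)
  rows <- list(stats_row(0L, pop, 0L, k, 0L, 0L))
  finish_run(pop, rows, "convergence", config, taxa)
}

#' Run the evolution-strategy tree search
#'
#' Implements the hybrid search: lambda random topologies are drawn through
#' the step-wise encoding and refined by BNNI+BSPR; each generation every
#' member spawns one offspring by per-component recombination of the
#' population's codes followed by the same refinement; parents and offspring
#' are pooled and truncation-selected down to the scheduled size; an
#' anti-stagnation replacement then substitutes one duplicated worst
#' individual by the second worst. The loop stops on convergence (all codes
#' identical), on `maxiter`, or when worst - best <= `tol`.
#'
#' @param d symmetric non-negative distance matrix (or `dist`), n >= 3.
#' @param config an [es_config()].
#' @return a list with the best `tree` (a `"phylo_topology"`), its `length`
#'   and `code`, the per-generation `generations` data.frame, `stop_reason`
#'   (`"convergence"`, `"maxiter"` or `"tolerance"`), the totals
#'   `trees_generated`, `nni_iterations`, `spr_iterations`, and `config`.
#' @seealso [phyloes()] for the formula-style front end, [run_ri()] for the
#'   matched-budget baseline.
#' @export
run_phyloes <- function(d, config = es_config()) {
  if (!inherits(config, "es_config")) stop("config must come from es_config()")
  d <- as_dist_matrix(d)
  n <- nrow(d)
  taxa <- rownames(d)
  if (n <= 4L) return(run_tiny(d, config, taxa))

  set.seed(config$seed)
  lambda <- pop_size_at(0L, config$pop_schedule)
  pop <- vector("list", lambda)
  nni <- spr <- 0L
  for (i in seq_len(lambda)) {
    ind <- new_individual(random_code(n), d, n)
    nni <- nni + ind$nni
    spr <- spr + ind$spr
    pop[[i]] <- ind
  }
  pop <- truncation_select(pop, lambda)
  trees <- lambda
  g <- 0L
  rows <- list(stats_row(0L, pop, 0L, trees, nni, spr))

  set.seed(derive_seed(config$seed))
  repeat {
    codes <- pop_codes(pop)
    lens <- vapply(pop, `[[`, numeric(1), "length")
    if (nrow(unique(codes)) == 1L) { reason <- "convergence"; break }
    if (g >= config$maxiter) { reason <- "maxiter"; break }
    if (max(lens) - min(lens) <= config$tol) { reason <- "tolerance"; break }

    k <- length(pop)
    offspring <- vector("list", k)
    for (i in seq_len(k)) {
      ind <- new_individual(recombine_codes(codes), d, n)
      nni <- nni + ind$nni
      spr <- spr + ind$spr
      offspring[[i]] <- ind
    }
    trees <- trees + k
    mu <- pop_size_at(g + 1L, config$pop_schedule)
    pop <- truncation_select(c(pop, offspring), mu)
    pop <- individual_replacement(pop)
    g <- g + 1L
    rows[[length(rows) + 1L]] <- stats_row(g, pop, k, trees, nni, spr)
  }
  finish_run(pop, rows, reason, config, taxa)
}

#' Random-initialization baseline with a fixed tree budget
#'
#' Repeats `budget` times: draw a uniformly random topology, refine it with
#' BNNI+BSPR, keep the best. With `budget` set to the number of trees a
#' [run_phyloes()] run generated, this is the matched-budget exploration
#' baseline the evolution strategy is compared against.
#'
#' @param d symmetric non-negative distance matrix (or `dist`).
#' @param budget number of random restarts (>= 1).
#' @param seed integer seed.
#' @return a list with the best `tree`, `length`, `code`, a per-restart
#'   `progress` data.frame (best length so far), `trees_generated`,
#'   `nni_iterations` and `spr_iterations`.
#' @export
run_ri <- function(d, budget, seed = 1L) {
  d <- as_dist_matrix(d)
  budget <- as.integer(budget)
  if (is.na(budget) || budget < 1L) stop("budget must be >= 1")
  n <- nrow(d)
  taxa <- rownames(d)
  set.seed(as.integer(seed))
  best <- NULL
  nni <- spr <- 0L
  prog <- numeric(budget)
  for (b in seq_len(budget)) {
    ind <- if (n <= 4L) {
      ex <- exhaustive_bme(d)
      i <- which.min(ex$lengths)
      list(code = ex$codes[i, ], tree = ex$trees[[i]],
           length = ex$lengths[i], nni = 0L, spr = 0L)
    } else new_individual(random_code(n), d, n)
    nni <- nni + ind$nni
    spr <- spr + ind$spr
    if (is.null(best) || ind$length < best$length) best <- ind
    prog[b] <- best$length
  }
  best$tree$taxa <- taxa
  list(tree = best$tree, length = best$length, code = best$code,
       progress = data.frame(restart = seq_len(budget), best_length = prog),
       trees_generated = budget, nni_iterations = nni, spr_iterations = spr)
}

#' Exhaustive balanced minimum evolution search
#'
#' Decodes and evaluates every one of the `(2n-5)!!` topologies. Intended
#' as a ground-truth oracle for small n (say n <= 8).
#'
#' @param d symmetric non-negative distance matrix (or `dist`).
#' @return a list with the optimal `tree`, its `length` and `code`, plus
#'   the full `codes` matrix, `trees` list and `lengths` vector.
#' @export
exhaustive_bme <- function(d) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  codes <- all_tree_codes(n)
  trees <- lapply(seq_len(nrow(codes)), function(i)
    decode_tree(codes[i, ], n))
  lengths <- vapply(trees, function(tr) cpp_bme_length(tr$edges, d),
                    numeric(1))
  i <- which.min(lengths)
  best <- trees[[i]]
  best$taxa <- rownames(d)
  list(tree = best, length = lengths[i], code = codes[i, ],
       codes = codes, trees = trees, lengths = lengths)
}
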