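# User-facing model interface: phyloes() returns a classed fit with
# print / summary / plot methods, plus the RI baseline and a paired
# comparison harness.

#' Fit a balanced minimum evolution phylogeny by evolution-strategy search
#'
#' The main entry point: searches the space of unrooted binary leaf-labelled
#' trees for one minimizing the balanced length
#' \eqn{L(T) = \sum_{\{i,j\}} d_{ij} 2^{1-\tau_{ij}}}, combining a
#' (mu+lambda) evolution strategy over the step-wise tree encoding with
#' BNNI/BSPR steepest-descent refinement of every tree.
#'
#' @param d symmetric non-negative distance matrix (or `dist`) over n >= 3
#'   taxa; rownames, when present, become the taxon names.
#' @param maxiter,tol,pop_schedule,seed passed to [es_config()]; the
#'   defaults are the standard study conditions (maxiter 1000, tol 1e-12,
#'   population 64/32/16 with thresholds at generations 5 and 25).
#' @return an object of class `"phyloes"`; components include `tree` (the
#'   best `"phylo_topology"` found), `length`, `stop_reason`,
#'   `generations` (per-generation statistics), `trees_generated`,
#'   `nni_iterations`, `spr_iterations`, `omega` (the certified-comparison
#'   tolerance of `d`) and `call`.
#' @examples
#' sim <- random_additive_matrix(8, seed = 1)
#' fit <- phyloes(sim$d, seed = 1)
#' fit
#' rf_distance(fit$tree, sim$tree)  # 0: the generating tree is recovered
#' @seealso [ri_search()], [compare_with_ri()], [bme_length()]
#' @export
phyloes <- function(d, maxiter = 1000L, tol = 1e-12, pop_schedule = NULL,
                    seed = 1L) {
  cl <- match.call()
  if (is.null(pop_schedule))
    cfg <- es_config(maxiter = maxiter, tol = tol, seed = seed)
  else
    cfg <- es_config(maxiter = maxiter, tol = tol,
                     pop_schedule = pop_schedule, seed = seed)
  d <- as_dist_matrix(d)
  run <- run_phyloes(d, cfg)
  structure(c(run, list(omega = omega_bound(d), n = nrow(d), call = cl)),
            class = "phyloes")
}

#' @export
print.phyloes <- function(x, ...) {
  cat("Balanced minimum evolution fit (evolution strategy)\n")
  cat(sprintf("  taxa: %d\n", x$n))
  cat(sprintf("  best tree length: %.12g\n", x$length))
  cat(sprintf("  stop reason: %s after %d generation(s)\n", x$stop_reason,
              max(x$generations$generation)))
  cat(sprintf("  trees generated: %d (NNI iterations %d, SPR iterations %d)\n",
              x$trees_generated, x$nni_iterations, x$spr_iterations))
  cat(sprintf("  comparison tolerance omega: %.3g\n", x$omega))
  invisible(x)
}

#' @export
summary.phyloes <- function(object, ...) {
  print(object)
  cat("\nPer-generation statistics:\n")
  print(object$generations, row.names = FALSE)
  cat("\nBest tree:\n  ", write_newick(object$tree), "\n", sep = "")
  invisible(object)
}

#' Plot the length trajectory of a fit
#'
#' Best and worst population lengths per generation.
#'
#' @param x a `"phyloes"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.phyloes <- function(x, ...) {
  g <- x$generations
  graphics::plot(g$generation, g$worst_length, type = "s", col = "grey50",
                 xlab = "generation", ylab = "balanced tree length",
                 ylim = range(c(g$best_length, g$worst_length)), ...)
  graphics::lines(g$generation, g$best_length, type = "s", col = "firebrick")
  graphics::legend("topright", legend = c("worst in population", "best"),
                   col = c("grey50", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' @method as.phylo phyloes
#' @export
as.phylo.phyloes <- function(x, ...) as.phylo.phylo_topology(x$tree)

#' Random-initialization baseline search
#'
#' Convenience front end to [run_ri()] returning a classed object.
#'
#' @inheritParams run_ri
#' @return an object of class `"ri_search"`.
#' @export
ri_search <- function(d, budget, seed = 1L) {
  cl <- match.call()
  d <- as_dist_matrix(d)
  run <- run_ri(d, budget, seed = seed)
  structure(c(run, list(omega = omega_bound(d), n = nrow(d), call = cl)),
            class = "ri_search")
}

#' @export
print.ri_search <- function(x, ...) {
  cat("Balanced minimum evolution fit (random initialization baseline)\n")
  cat(sprintf("  taxa: %d\n", x$n))
  cat(sprintf("  best tree length: %.12g\n", x$length))
  cat(sprintf("  restarts: %d (NNI iterations %d, SPR iterations %d)\n",
              x$trees_generated, x$nni_iterations, x$spr_iterations))
  invisible(x)
}

#' Paired comparison of the evolution strategy against the RI baseline
#'
#' For each seed, runs the evolution strategy, counts the trees it
#' generated, and gives the random-initialization baseline exactly that
#' budget — the matched-budget design for judging whether the recombination
#' step earns its keep. Reports lengths, the certified sign of their
#' difference, and the topological (Robinson-Foulds) distance between the
#' two best trees.
#'
#' @param d symmetric non-negative distance matrix (or `dist`).
#' @param seeds integer vector of seeds, one paired run each.
#' @param ... further arguments to [phyloes()] (e.g. `pop_schedule`).
#' @return a data.frame with one row per seed: `es_length`, `ri_length`,
#'   `budget` (trees generated by the ES, and given to the RI),
#'   `length_diff` (ES minus RI), `es_certified_better` (under the omega
#'   tolerance) and `rf` (RF distance between the two best trees).
#' @export
compare_with_ri <- function(d, seeds = 1:3, ...) {
  d <- as_dist_matrix(d)
  omega <- omega_bound(d)
  rows <- lapply(seeds, function(s) {
    es <- phyloes(d, seed = s, ...)
    ri <- run_ri(d, budget = es$trees_generated, seed = s)
    data.frame(seed = s, es_length = es$length, ri_length = ri$length,
               budget = es$trees_generated,
               length_diff = es$length - ri$length,
               es_certified_better = certified_less(es$length, ri$length,
                                                    omega),
               rf = rf_distance(es$tree, ri$tree))
  })
  do.call(rbind, rows)
}

#' Serialize run statistics as JSON
#'
#' Writes the run metadata, the per-generation table and the final block of
#' a fit to a JSON document (the machine-readable companion of the Newick
#' output).
#'
#' @param fit a `"phyloes"` or `"ri_search"` object.
#' @param file path ("" returns the JSON string).
#' @return the JSON string, invisibly.
#' @export
write_run_stats <- function(fit, file = "") {
  final <- list(best_length = as.numeric(sprintf("%.12g", fit$length)),
                best_tree = write_newick(fit$tree),
                trees_generated = fit$trees_generated,
                nni_iterations = fit$nni_iterations,
                spr_iterations = fit$spr_iterations)
  meta <- list(taxa = fit$n, omega = fit$omega)
  doc <- if (inherits(fit, "phyloes")) {
    final$stop_reason <- fit$stop_reason
    meta$maxiter <- fit$config$maxiter
    meta$tol <- fit$config$tol
    meta$seed <- fit$config$seed
    list(meta = meta, generations = fit$generations, final = final)
  } else {
    list(meta = meta, progress = fit$progress, final = final)
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
  if (identical(file, "")) return(invisible(as.character(json)))
  writeLines(as.character(json), con = file)
  invisible(as.character(json))
}
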