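---
title: "Balanced minimum evolution by evolution strategy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced minimum evolution by evolution strategy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloes)
```

## The estimation model

Given `n ≥ 3` taxa and a symmetric non-negative dissimilarity matrix
`D = (d_ij)`, balanced minimum evolution (BME) scores an unrooted binary
leaf-labelled tree `T` by

$$L(T) \;=\; \sum_{\{i,j\}} d_{ij}\, 2^{\,1-\tau_{ij}(T)},$$

where $\tau_{ij}$ is the number of edges on the path between leaves $i$
and $j$. The weights $2^{1-\tau_{ij}}$ are Pauplin's balanced weights:
for every taxon they sum to exactly 1 over its partners (a dyadic sum, so
the identity holds to the last bit in floating point; the suite asserts
`|rowsum − 1| ≤ 1e−12`). The estimate is the minimizer of `L` over the
$(2n-5)!!$ topologies. Two properties anchor the test suite:

* **additive recovery** — if `D` is exactly realizable as path sums on a
  positively-weighted tree (equivalently, satisfies the four-point
  condition), the BME optimum is that tree; the synthetic generator
  produces such matrices, making correctness checkable without any
  external data;
* **dual evaluation forms** — the unordered-pair form above equals the
  ordered-pair form $\sum_i\sum_{j\ne i} d_{ij} 2^{-\tau_{ij}}$; the
  package computes the first, the tests recompute the second through an
  independent BFS oracle and require agreement to 1e−12 relative error.

Lengths are accumulated in a fixed row-major pair order, so a given
(matrix, tree) pair always produces the bit-identical length. No
compensated summation is used at these problem sizes; instead, comparisons
that need to be *certified* can use the tolerance
$\omega = n^2\, 2^{-49} \max_{ij} d_{ij}$, which bounds the total
contribution of leaf pairs at topological distance ≥ 50 (there are fewer
than $n^2$ of them, since every binary tree keeps at least two cherries).
`certified_less(l1, l2, omega)` returns `TRUE` only when `l1 + ω < l2`,
i.e. when the ordering is immune to the sub-epsilon tail; `FALSE` means
"not certified", never "greater".

## The step-wise encoding

Any topology can be grown from the star on taxa 1,2,3 (centre `n+1`) by
inserting taxon `i+3` at step `i` on one edge of the partial tree; the
internal node created at step `i` is `n+1+i`. Edges are indexed in the
*ordered edge list*: ascending by smaller endpoint label, ties by the
larger endpoint (plain lexicographic order on the (min, max) pair — the
worked 5-taxon examples contain no ties, so they fix only the primary
sort; the secondary direction is a package convention that must stay
bit-stable because codes are exchanged between individuals). Recording the
chosen indices gives the code $(h_1,\dots,h_{n-3})$ with
$1 \le h_i \le 2i+1$; the code space size $\prod (2i+1) = (2n-5)!!$
matches the topology count, and the map is a bijection (verified
exhaustively to n = 7 and on random trees to n = 64).

Decoding replays the construction. Encoding strips leaves $t_n$ down to
$t_4$ — suppressing each leaf's attachment node restores one edge — and
then replays forward with canonical labels, reporting each restored edge's
index. Internal labels of the input may be any permutation of
`n+1..2n-2`; the encoder canonicalizes. Both operations are O(n²) here;
asymptotically faster bookkeeping exists but is pointless at the sizes an
R session handles.

Uniform sampling of codes (each $h_i$ uniform on $1..2i+1$) induces the
uniform distribution over topologies — this is both the population
initializer and the null model of the random-initialization baseline.

## Local search

`bnni()` and `bspr()` are steepest-descent searches: evaluate every
neighbour, apply the single best *strictly* improving move, repeat until
none improves. Ties are never accepted (prevents cycling), and among
equally improving moves the first in the deterministic enumeration order
(canonical edge order; for NNI the A↔C swap before A↔D; for SPR prune
directions smaller-endpoint-first and regraft edges in canonical order)
wins, so identical inputs give identical outputs.

* NNI: each of the `n−3` internal edges yields exactly 2 non-symmetric
  subtree swaps; neighbourhood size `2(n−3)`.
* SPR: prune the subtree hanging off a directed edge `(p → s)` (the
  attachment `p` must be internal), suppress `p`, regraft on any edge
  outside the subtree and not incident to `p`; O(n²) moves, a strict
  superset of the NNI neighbourhood for n ≥ 5.

Every neighbour is scored by direct recomputation of `L` (O(n²) per
neighbour). Incremental delta formulas for NNI/SPR under balanced weights
exist and could sit behind the same interface, but direct recomputation
*is* the behavioural contract here: the descent trace returned by the
compiled code is re-checked in the tests against a from-scratch oracle,
and local optimality of returned trees is verified by brute-force
neighbourhood scans (to n = 12) using the independent pure-R move
enumeration. `rearrange_tree()` composes BNNI then BSPR — the refinement
applied to every tree the evolution strategy touches.

## The evolution strategy

`run_phyloes()` implements the loop:

1. draw λ random codes, decode, refine each with BNNI+BSPR, re-encode;
2. while not converged: each member spawns one offspring whose component
   `j` is sampled uniformly from the multiset of the parents' `j`-th
   components; offspring are refined and re-encoded; parents ∪ offspring
   are truncation-selected down to the scheduled μ (stable sort — parents
   win ties, so the incumbent best is never lost); then, if the worst
   length occurs more than once and a strictly better individual exists,
   one duplicated worst (the last in stable order) is replaced by a copy
   of the largest length strictly below it — a gentle anti-stagnation
   nudge that accelerates convergence without touching the best.

Stopping: **convergence** (all codes identical — checked on codes, which
is equivalent to topological identity by the bijection), **maxiter**, or
**tolerance** (worst − best ≤ tol, tested on the population after
replacement). When several conditions hold simultaneously the reason is
reported with that priority. Defaults: maxiter 1000, tol 1e−12,
population 64 for generations 0–4, 32 for 5–24, 16 afterwards (shrinking
keeps the best individuals through the same stable truncation). μ = λ =
the scheduled size throughout.

Randomness: the root seed drives the initialization draws; a derived seed
(one multiplicative-congruential step) re-seeds the generator for the
recombination phase. Since no other code path consumes randomness, runs
are exactly reproducible per (matrix, config, seed), and adding logging
cannot perturb trajectories. For n ≤ 4 the code space has at most 3
elements, so the run short-circuits to exhaustive evaluation and returns
well-formed statistics with stop reason "convergence".

`run_ri()` is the exploration control: the same number of
refine-from-random-tree operations, no recombination, best kept.
`compare_with_ri()` pairs the two per seed with matched tree budgets and
reports lengths, the ω-certified sign of the difference and the RF
distance between the winners — the desk-scale version of the
ES-versus-restarts comparison design, run on synthetic matrices.

## Synthetic data

`random_additive_matrix(n, mean_bl, seed)` samples a uniform topology,
draws i.i.d. exponential branch lengths (default mean 0.1, a conventional
simulation scale for substitution-per-site distances), and returns exact
path-sum distances — additive by construction, so the BME optimum is
known. `perturb_matrix(d, sigma)` applies one clamped multiplicative
Gaussian factor `max(0, 1 + ε)` per unordered pair: symmetry and
non-negativity survive by construction (additive noise would need
rescaling), and σ = 0 is the identity. What the generator does *not*
emulate: estimation noise correlated across pairs sharing tree paths,
rate heterogeneity, alignment gaps — so passing tests demonstrate
correctness of the optimization machinery on well-posed inputs, not
robustness to every pathology of real distance estimates. The moderate-σ
behaviour is therefore *reported* (RF to the generator) rather than
bounded in the tests.

## Numerical and design choices

* Strict floating-point improvement (`<`, no epsilon) accepts descent
  moves; the ω machinery exists for *reporting* certified comparisons,
  while the search itself compares raw doubles — mixing ω into move
  acceptance would make descent termination depend on the data scale.
* Degenerate inputs: n = 3 returns the unique star; all-equal distance
  matrices make every topology tie at `L = n/2` and the search returns a
  valid representative; an all-zero matrix gives ω = 0.
* PHYLIP I/O is square-symmetric only, relaxed names, 12 significant
  digits on write; symmetry (1e−9 relative), zero diagonal (1e−12) and
  non-negativity are enforced on read. Newick output is canonical
  (trifurcation at the internal node adjacent to taxon 1, children by
  smallest descendant leaf), hence bit-stable per topology; reading
  accepts rooted binary inputs (the degree-2 root is suppressed) and
  rejects any other polytomy.
* Problem sizes in the suite — exhaustive enumeration to n = 7 (945
  topologies), brute-force local-optimality scans to n = 12, encoding
  round-trips to n = 64, search recovery at n = 10 and 20 with 10 seeds,
  the ES-vs-RI harness at n = 12 with 3 seeds — were chosen as the
  smallest scales at which each property is non-trivial while keeping the
  whole suite comfortably interactive.

## Known limitations

Sequential reference implementation: one tree refined at a time (the
population loop is a plain R loop over compiled descents); no
batch/device parallelism. Distance estimation from alignments is out of
scope — matrices are consumed, not produced. Branch lengths are never
estimated; the output is a topology. TBR and other richer rearrangements
are not implemented. For n beyond a few hundred taxa the O(n²)-per-
neighbour SPR scans make runs slow; the design target is the desk scale
at which the package's guarantees can actually be verified.
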