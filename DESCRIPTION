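Package: phyloes
Title: Evolution-Strategy Search for Balanced Minimum Evolution Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Distance-based phylogenetic tree estimation under the balanced
    minimum evolution (BME) criterion. Implements a (mu+lambda) evolution
    strategy over a bijective step-wise tree encoding, hybridized with
    steepest-descent local search on the balanced nearest-neighbour
    interchange (BNNI) and balanced subtree prune-and-regraft (BSPR)
    neighbourhoods, together with a matched-budget random-initialization
    baseline, Robinson-Foulds topology comparison, a numerical-precision
    tolerance for certified tree-length comparisons, readers and writers for
    square PHYLIP distance matrices and Newick trees, and generators for
    synthetic additive and noisy distance matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
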