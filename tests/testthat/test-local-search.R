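test_that("each internal edge yields exactly two NNI neighbours", {
  quartet <- decode_tree(3L, 4)
  nb <- nni_neighbors(quartet)
  expect_length(nb, 2)
  keys <- vapply(nb, topo_key, character(1))
  all3 <- vapply(1:3, function(h) topo_key(decode_tree(h, 4)), character(1))
  expect_setequal(keys, setdiff(all3, topo_key(quartet)))

  set.seed(413)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    tr <- random_topology(n)
    nb <- nni_neighbors(tr)
    expect_length(nb, 2 * (n - 3))
    for (x in nb) expect_true(validate_topology(x))
  }

  # external edges are refused
  expect_error(nni_neighbors(quartet, edge = c(1, 5)), "internal")
})

test_that("NNI neighbours of a 5-taxon tree sit at RF distance 2", {
  tr <- decode_tree(c(3, 5), 5)
  internal <- tr$edges[tr$edges[, 1] > 5 & tr$edges[, 2] > 5, , drop = FALSE]
  for (r in seq_len(nrow(internal))) {
    nb <- nni_neighbors(tr, edge = internal[r, ])
    expect_length(nb, 2)
    for (x in nb) expect_identical(rf_distance(tr, x), 2L)
  }
})

test_that("SPR moves are closed, quadratic, and subsume NNI", {
  quartet <- decode_tree(2L, 4)
  spr_keys <- unique(vapply(spr_neighbors(quartet), topo_key, character(1)))
  nni_keys <- unique(vapply(nni_neighbors(quartet), topo_key, character(1)))
  expect_setequal(spr_keys, nni_keys)  # n = 4: both give the other 2 trees

  set.seed(414)
  tr <- random_topology(6)
  spr_nb <- spr_neighbors(tr)
  for (x in spr_nb) {
    expect_true(validate_topology(x))
    expect_false(same_topology(x, tr))  # every listed move changes the tree
  }
  spr_keys <- unique(vapply(spr_nb, topo_key, character(1)))
  nni_keys <- unique(vapply(nni_neighbors(tr), topo_key, character(1)))
  expect_true(all(nni_keys %in% spr_keys))
  expect_gt(length(spr_keys), length(nni_keys))
})

test_that("BNNI descends to the generating quartet", {
  sim <- random_additive_matrix(4, seed = 21)
  gen_code <- encode_tree(sim$tree)
  wrong <- decode_tree(setdiff(1:3, gen_code)[1], 4)
  r <- bnni(wrong, sim$d)
  expect_true(same_topology(r$tree, sim$tree))
  expect_gte(r$iterations, 1L)

  # already optimal: unchanged, zero iterations
  r2 <- bnni(r$tree, sim$d)
  expect_identical(r2$iterations, 0L)
  expect_true(same_topology(r2$tree, r$tree))
})

test_that("descent traces strictly decrease and end at the reported tree", {
  set.seed(415)
  for (rep in 1:8) {
    n <- sample(8:14, 1)
    d <- random_metric_matrix(n, seed = 415000 + rep)
    tr <- random_topology(n)
    L0 <- bme_length(d, tr)
    for (r in list(bnni(tr, d), bspr(tr, d))) {
      expect_lte(r$length, L0)
      if (r$iterations > 0) {
        trace <- c(L0, r$trace)
        expect_true(all(diff(trace) < 0))  # every accepted move improves
        expect_equal(r$length, bme_length(d, r$tree), tolerance = 1e-14)
        expect_equal(r$length, oracle_bme(d, r$tree), tolerance = 1e-12)
      }
    }
  }
})

test_that("a BNNI optimum need not be a BSPR optimum", {
  # frozen instance located by scanning noisy additive matrices at n = 7
  sim <- random_additive_matrix(7, seed = 67)
  d <- perturb_matrix(sim$d, 0.35, seed = 1067)
  set.seed(67)
  tr <- random_topology(7)
  rn <- bnni(tr, d)
  rs <- bspr(rn$tree, d)
  expect_lt(rs$length, rn$length)
})

test_that("returned trees are genuine local optima (brute-force scan)", {
  for (case in list(c(8, 31), c(12, 32))) {
    n <- case[1]
    d <- random_metric_matrix(n, seed = case[2])
    set.seed(case[2])
    start <- random_topology(n)
    rn <- bnni(start, d)
    for (x in nni_neighbors(rn$tree))
      expect_gte(bme_length(d, x), rn$length)
    rs <- bspr(rn$tree, d)
    for (x in spr_neighbors(rs$tree))
      expect_gte(bme_length(d, x), rs$length)
  }
})

test_that("rearrange_tree composes both descents and never worsens", {
  sim <- random_additive_matrix(10, seed = 23)
  d <- perturb_matrix(sim$d, 0.2, seed = 24)
  set.seed(25)
  tr <- random_topology(10)
  r <- rearrange_tree(tr, d)
  expect_lte(r$length, bme_length(d, tr))
  # idempotent on its own output
  r2 <- rearrange_tree(r$tree, d)
  expect_identical(r2$nni_iterations + r2$spr_iterations, 0L)
  expect_true(same_topology(r2$tree, r$tree))
})

test_that("multistart rearrangement reaches the exhaustive optimum", {
  d <- random_metric_matrix(6, seed = 33)
  ex <- exhaustive_bme(d)
  set.seed(33)
  best <- Inf
  for (i in 1:20)
    best <- min(best, rearrange_tree(random_topology(6), d)$length)
  expect_equal(best, ex$length, tolerance = 1e-12)
})
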