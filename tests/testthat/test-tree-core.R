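test_that("path lengths match forced small-tree values", {
  star <- decode_tree(integer(0), 3)
  tau <- path_length_matrix(star)
  expect_identical(tau, matrix(c(0L, 2L, 2L, 2L, 0L, 2L, 2L, 2L, 0L), 3))

  quartet <- decode_tree(3L, 4)  # cherries (1,2) and (3,4)
  tau <- path_length_matrix(quartet)
  expect_identical(tau[1, 2], 2L)
  expect_identical(tau[3, 4], 2L)
  expect_identical(tau[cbind(c(1, 1, 2, 2), c(3, 4, 3, 4))],
                   rep(3L, 4))
})

test_that("path lengths agree with a breadth-first-search oracle", {
  set.seed(401)
  for (rep in 1:100) {
    n <- sample(4:64, 1)
    tr <- random_topology(n)
    expect_identical(unname(path_length_matrix(tr)), oracle_tau(tr))
  }
})

test_that("path-length matrices satisfy their structural bounds", {
  set.seed(402)
  for (rep in 1:20) {
    n <- sample(4:32, 1)
    tau <- path_length_matrix(random_topology(n))
    off <- tau[upper.tri(tau)]
    expect_true(all(diag(tau) == 0))
    expect_true(all(off >= 2) && all(off <= n - 1))
    expect_gte(sum(off == 2), 2)  # at least two cherries
  }
})

test_that("splits are canonical, label-invariant and n-3 in number", {
  quartet <- decode_tree(3L, 4)
  expect_identical(tree_splits(quartet), list(c(3L, 4L)))
  expect_identical(tree_splits(decode_tree(integer(0), 3)), list())

  fig_top <- decode_tree(c(3, 5), 5)  # ((t1,t2),t5,(t3,t4))
  sp <- tree_splits(fig_top)
  expect_length(sp, 2)
  expect_setequal(vapply(sp, paste, character(1), collapse = ","),
                  c("3,4", "3,4,5"))

  # relabel internal nodes 6,7,8 -> 8,6,7: splits unchanged
  perm <- c(1:5, 8L, 6L, 7L)
  relab <- new_topology(5, matrix(perm[fig_top$edges], ncol = 2))
  expect_identical(topo_key(relab), topo_key(fig_top))

  set.seed(403)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    expect_length(tree_splits(random_topology(n)), n - 3)
  }
})

test_that("RF distance takes its forced values on small trees", {
  t12 <- decode_tree(3L, 4)   # ((1,2),(3,4))
  expect_identical(rf_distance(t12, t12), 0L)
  t13 <- decode_tree(1L, 4)   # t4 inserted on (1,5): cherry (1,4)? check below
  # the three quartet topologies are the codes 1,2,3; any two differ by 2
  quartets <- lapply(1:3, function(h) decode_tree(h, 4))
  for (i in 1:2) for (j in (i + 1):3)
    expect_identical(rf_distance(quartets[[i]], quartets[[j]]), 2L)

  # 5-taxon shapes ((1,2),(3,4),5) vs ((1,3),(2,4),5): disjoint split sets
  a <- read_newick(text = "((t1,t2),(t3,t4),t5);", taxa = paste0("t", 1:5))
  b <- read_newick(text = "((t1,t3),(t2,t4),t5);", taxa = paste0("t", 1:5))
  expect_identical(rf_distance(a, b), 4L)
})

test_that("RF distance is a metric and matches phangorn", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(5:24, 1)
    t1 <- random_topology(n)
    t2 <- random_topology(n)
    t3 <- random_topology(n)
    d12 <- rf_distance(t1, t2)
    expect_identical(d12, rf_distance(t2, t1))
    expect_identical(d12 %% 2L, 0L)
    expect_identical(d12 == 0L, same_topology(t1, t2))
    expect_lte(rf_distance(t1, t3), d12 + rf_distance(t2, t3))
    # independent implementation
    taxa <- paste0("t", seq_len(n))
    p1 <- ape::as.phylo(new_topology(n, t1$edges, taxa = taxa))
    p2 <- ape::as.phylo(new_topology(n, t2$edges, taxa = taxa))
    expect_identical(as.integer(phangorn::RF.dist(p1, p2)), d12)
  }
})

test_that("all 15 five-taxon topologies are pairwise distinct", {
  keys <- apply(all_tree_codes(5), 1, function(h)
    topo_key(decode_tree(h, 5)))
  expect_identical(length(unique(keys)), 15L)
})

test_that("trees on different leaf sets are rejected", {
  expect_error(rf_distance(decode_tree(3L, 4), decode_tree(c(3L, 5L), 5)),
               "leaf")
})
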