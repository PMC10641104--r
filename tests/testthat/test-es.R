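fake_ind <- function(len, id) list(code = c(id, id), length = len, id = id)

test_that("recombination samples components from the parental multisets", {
  # identical parents: the child is forced
  codes <- rbind(c(3L, 5L), c(3L, 5L), c(3L, 5L))
  set.seed(416)
  for (i in 1:20) expect_identical(recombine_codes(codes), c(3L, 5L))

  # degenerate first component
  codes <- rbind(c(1L, 3L), c(1L, 5L))
  set.seed(417)
  for (i in 1:50) expect_identical(recombine_codes(codes)[1], 1L)

  # two parents: each of the 4 products near probability 1/4
  codes <- rbind(c(1L, 3L), c(3L, 5L))
  set.seed(418)
  draws <- replicate(40000, paste(recombine_codes(codes), collapse = ","))
  counts <- table(draws)
  expect_setequal(names(counts), c("1,3", "1,5", "3,3", "3,5"))
  p <- 1 / 4
  sigma3 <- 3 * sqrt(40000 * p * (1 - p))
  expect_true(all(abs(counts - 40000 * p) < sigma3))

  expect_error(recombine_codes(matrix(integer(0), 0, 2)), "non-empty")
})

test_that("truncation selection keeps the mu best, stably", {
  pool <- list(fake_ind(3, 1), fake_ind(1, 2), fake_ind(2, 3))
  sel <- truncation_select(pool, 2)
  expect_identical(vapply(sel, `[[`, numeric(1), "length"), c(1, 2))

  expect_length(truncation_select(pool, 3), 3)
  expect_error(truncation_select(pool, 0), "positive")
  expect_error(truncation_select(pool, 4), "pool")

  ties <- list(fake_ind(1, 1), fake_ind(1, 2), fake_ind(1, 3),
               fake_ind(1, 4))
  sel <- truncation_select(ties, 2)
  expect_identical(vapply(sel, `[[`, numeric(1), "id"), c(1, 2))
})

test_that("individual replacement resolves duplicated worst individuals", {
  pop <- list(fake_ind(5, 1), fake_ind(5, 2), fake_ind(4, 3))
  out <- individual_replacement(pop)
  expect_identical(sort(vapply(out, `[[`, numeric(1), "length")),
                   c(4, 4, 5))

  # unique worst: unchanged
  pop <- list(fake_ind(5, 1), fake_ind(4, 2), fake_ind(3, 3))
  expect_identical(individual_replacement(pop), pop)

  # all equal: no strictly better donor exists
  pop <- list(fake_ind(2, 1), fake_ind(2, 2), fake_ind(2, 3))
  expect_identical(individual_replacement(pop), pop)
})

test_that("runs are deterministic given matrix, config and seed", {
  sim <- random_additive_matrix(8, seed = 41)
  d <- perturb_matrix(sim$d, 0.25, seed = 42)
  a <- run_phyloes(d, es_config(seed = 7))
  b <- run_phyloes(d, es_config(seed = 7))
  expect_identical(a$code, b$code)
  expect_identical(a$length, b$length)
  expect_identical(a$generations, b$generations)
  expect_identical(a$stop_reason, b$stop_reason)
})

test_that("run statistics are well-formed and internally consistent", {
  sim <- random_additive_matrix(8, seed = 43)
  d <- perturb_matrix(sim$d, 0.3, seed = 44)
  r <- run_phyloes(d, es_config(seed = 3))
  g <- r$generations
  expect_true(all(diff(g$best_length) <= 0))          # elitist best
  expect_true(all(diff(g$trees_total) > 0) || nrow(g) == 1)
  expect_true(all(g$best_length <= g$worst_length))
  expect_true(r$stop_reason %in% c("convergence", "maxiter", "tolerance"))
  expect_identical(r$trees_generated, g$trees_total[nrow(g)])
  expect_equal(r$length, bme_length(d, r$tree), tolerance = 1e-14)
  expect_identical(encode_tree(r$tree), r$code)
})

test_that("tiny instances short-circuit to the exhaustive optimum", {
  # n = 3: the single topology
  d3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  r3 <- run_phyloes(d3, es_config(seed = 1))
  expect_identical(r3$tree$edges, cbind(1:3, c(4L, 4L, 4L)))
  expect_identical(r3$stop_reason, "convergence")

  # n = 4: global optimum among the 3 topologies
  d4 <- random_metric_matrix(4, seed = 45)
  r4 <- run_phyloes(d4, es_config(seed = 1))
  ex <- exhaustive_bme(d4)
  expect_equal(r4$length, ex$length, tolerance = 1e-15)
  expect_true(same_topology(r4$tree, ex$tree))
})

test_that("six-taxon searches attain the exhaustive optimum", {
  for (s in 1:2) {
    d <- random_metric_matrix(6, seed = 50 + s)
    r <- run_phyloes(d, es_config(seed = s))
    ex <- exhaustive_bme(d)
    expect_equal(r$length, ex$length, tolerance = 1e-12)
  }
})

test_that("the exhaustive optimum is recovered on most 7-taxon seeds", {
  hits <- 0
  for (s in 1:10) {
    d <- random_metric_matrix(7, seed = 600 + s)
    r <- run_phyloes(d, es_config(seed = s))
    ex <- exhaustive_bme(d)
    hits <- hits + (abs(r$length - ex$length) < 1e-10)
  }
  expect_gte(hits, 9)
})

test_that("additive input at n = 12 returns the generating topology", {
  sim <- random_additive_matrix(12, seed = 61)
  r <- run_phyloes(sim$d, es_config(seed = 2))
  expect_identical(rf_distance(r$tree, sim$tree), 0L)
})

test_that("the population schedule shrinks at its thresholds", {
  cfg <- es_config()
  expect_identical(phyloes:::pop_size_at(0, cfg$pop_schedule), 64L)
  expect_identical(phyloes:::pop_size_at(4, cfg$pop_schedule), 64L)
  expect_identical(phyloes:::pop_size_at(5, cfg$pop_schedule), 32L)
  expect_identical(phyloes:::pop_size_at(24, cfg$pop_schedule), 32L)
  expect_identical(phyloes:::pop_size_at(25, cfg$pop_schedule), 16L)
  expect_identical(phyloes:::pop_size_at(1000, cfg$pop_schedule), 16L)

  expect_error(es_config(maxiter = 0), "maxiter")
  expect_error(es_config(tol = -1), "tol")
  expect_error(es_config(pop_schedule = data.frame(size = c(16, 32),
                                                   until = c(5, Inf))),
               "non-increasing")
})

test_that("the RI baseline is reproducible and monotone in its budget", {
  sim <- random_additive_matrix(8, seed = 71)
  d <- perturb_matrix(sim$d, 0.3, seed = 72)
  a <- run_ri(d, budget = 1, seed = 9)
  b <- run_ri(d, budget = 1, seed = 9)
  expect_identical(a$code, b$code)
  expect_identical(a$length, b$length)

  small <- run_ri(d, budget = 5, seed = 9)
  large <- run_ri(d, budget = 10, seed = 9)  # same stream: nested restarts
  expect_lte(large$length, small$length)
  expect_identical(large$progress$best_length[5], small$length)

  d6 <- random_metric_matrix(6, seed = 73)
  ex <- exhaustive_bme(d6)
  r <- run_ri(d6, budget = 50, seed = 1)
  expect_gte(r$length, ex$length - 1e-12)
  expect_equal(r$length, ex$length, tolerance = 1e-10)
})
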