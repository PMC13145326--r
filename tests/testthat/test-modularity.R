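id2 <- function() {
  weighted_matrix(matrix(c(1, 0, 0, 1), 2, 2,
                         dimnames = list(c("r1", "r2"), c("c1", "c2"))))
}

test_that("bipartite Q matches closed forms and the naive summation oracle", {
  m <- id2()
  split2 <- make_partition(m, c(1, 2), c(1, 2))
  expect_equal(bipartite_weighted_q(m, split2), 0.5)
  expect_equal(bipartite_weighted_q(m, make_partition(m, c(1, 1), c(1, 1))), 0)

  set.seed(21)
  for (rep in 1:10) {
    m <- random_count_matrix(4, 4)
    zr <- sample(1:3, 4, replace = TRUE)
    zc <- sample(1:3, 4, replace = TRUE)
    expect_equal(bipartite_weighted_q(m, make_partition(m, zr, zc)),
                 naive_bipartite_q(unclass(m), zr, zc))
  }
})

test_that("directed Q matches its closed form and requires a food web", {
  a <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("p1", "p2"), c("q1", "q2")))
  m <- weighted_matrix(a, kind = "foodweb")
  p <- make_partition(m, c(1, 2), c(1, 2))
  expect_equal(directed_weighted_q(m, p), 0.5)  # 2 * (1/2 - 1/4)
  expect_equal(directed_weighted_q(m, make_partition(m, c(1, 1), c(1, 1))), 0)
  occ <- weighted_matrix(a, kind = "occurrence")
  expect_error(directed_weighted_q(occ, p), "foodweb")
  # the two objectives agree on the shared carrier
  set.seed(3)
  for (rep in 1:5) {
    m <- random_count_matrix(4, 3, kind = "foodweb")
    zr <- sample(1:2, 4, replace = TRUE)
    zc <- sample(1:2, 3, replace = TRUE)
    pp <- make_partition(m, zr, zc)
    expect_equal(directed_weighted_q(m, pp), bipartite_weighted_q(m, pp))
  }
})

test_that("uncovered nodes are an error", {
  m <- id2()
  p <- tibble::tibble(node = c("r1", "c1", "c2"),
                      side = c("rows", "cols", "cols"), module = 1L)
  expect_error(bipartite_weighted_q(m, p), "cover")
})

test_that("optimizer recovers planted blocks and reports consistent q", {
  m <- two_block_matrix()
  fm <- find_modules(m, n_restarts = 20, seed = 1)
  expect_equal(fm$n_modules, 2)
  expect_equal(fm$q, bipartite_weighted_q(m, fm), tolerance = 1e-10)
  # planted 2-block value: each block holds half the weight
  expect_equal(fm$q, exhaustive_best_q(m), tolerance = 1e-12)
  td <- tidy(fm)
  block1 <- td$module[td$node %in% c("s1", "s2", "a", "b")]
  block2 <- td$module[td$node %in% c("s3", "s4", "c", "d")]
  expect_length(unique(block1), 1)
  expect_length(unique(block2), 1)
  expect_true(block1[1] != block2[1])

  flat <- weighted_matrix(matrix(1, 3, 3, dimnames = list(paste0("r", 1:3),
                                                          paste0("c", 1:3))))
  ff <- find_modules(flat, n_restarts = 10, seed = 2)
  expect_lte(ff$q, 1e-12)
  expect_equal(ff$n_modules, 1)
})

test_that("best-of-restarts q is non-decreasing in the restart budget", {
  set.seed(31)
  m <- random_count_matrix(5, 5)
  qs <- vapply(c(1, 3, 10), function(k) {
    find_modules(m, n_restarts = k, seed = 99)$q
  }, numeric(1))
  expect_true(all(diff(qs) >= -1e-12))
})

test_that("optimizer matches exhaustive search on small instances", {
  set.seed(41)
  for (rep in 1:4) {
    nr <- sample(2:3, 1)
    nc <- sample(2:4, 1)
    m <- random_count_matrix(nr, nc, max_w = 3, kind = "foodweb")
    for (obj in c("bipartite", "directed")) {
      fm <- find_modules(m, obj, n_restarts = 60, seed = rep)
      expect_equal(fm$q, exhaustive_best_q(m, obj), tolerance = 1e-10)
      # merging any two modules of the optimum never improves on it
      if (fm$n_modules >= 2) {
        td <- tidy(fm)
        merged <- td
        merged$module[merged$module == 2] <- 1L
        qm <- if (obj == "bipartite") bipartite_weighted_q(m, merged)
          else directed_weighted_q(m, merged)
        expect_lte(qm, fm$q + 1e-12)
      }
    }
  }
})

test_that("module ids are canonical and runs are seed-deterministic", {
  set.seed(51)
  m <- random_count_matrix(6, 5)
  f1 <- find_modules(m, n_restarts = 8, seed = 7)
  f2 <- find_modules(m, n_restarts = 8, seed = 7)
  expect_identical(tidy(f1), tidy(f2))
  # module 1 carries the largest total weight
  tot <- c(rowSums(unclass(m)), colSums(unclass(m)))
  names(tot) <- c(rownames(m), colnames(m))
  td <- tidy(f1)
  mw <- tapply(tot[td$node], td$module, sum)
  expect_true(all(diff(mw) <= 0))
})

test_that("normalized modularity is 1 for block-diagonal and flagged when undefined", {
  m <- two_block_matrix()
  fm <- find_modules(m, n_restarts = 10, seed = 3)
  expect_equal(normalize_q(m, fm), 1)
  flat <- weighted_matrix(matrix(1, 3, 3, dimnames = list(paste0("r", 1:3),
                                                          paste0("c", 1:3))))
  one <- make_partition(flat, rep(1, 3), rep(1, 3))
  expect_warning(nq <- normalize_q(flat, one), "undefined")
  expect_true(is.na(nq))
  # general matrices: normalized value in (0, 1], at least as large as raw q
  set.seed(61)
  g <- generate_modular_network(synthetic_spec(
    n_resources = 20, n_consumers = 8, n_modules = 2, mixing = 0.2,
    total_events = 200, seed = 8))
  nq <- normalize_q(g$matrix, g$partition)
  expect_gt(nq, 0)
  expect_lte(nq, 1)
  expect_gte(nq, g$partition$q - 1e-12)
})

test_that("degenerate single-link matrix yields the trivial partition", {
  m <- weighted_matrix(matrix(5, 1, 1, dimnames = list("r1", "c1")))
  fm <- find_modules(m, n_restarts = 3, seed = 1)
  expect_equal(fm$n_modules, 1)
  expect_equal(fm$q, 0)
})
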