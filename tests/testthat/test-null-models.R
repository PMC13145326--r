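test_that("vaznull preserves W, connectance and coverage", {
  # single-configuration cases
  single <- weighted_matrix(matrix(5, 1, 1, dimnames = list("r1", "c1")))
  expect_equal(bare(vaznull_replicate(single, seed = 1)), bare(single))
  id <- weighted_matrix(matrix(c(1, 0, 0, 1), 2, 2,
                               dimnames = list(c("r1", "r2"), c("c1", "c2"))))
  for (s in 1:10) {
    rep_m <- vaznull_replicate(id, seed = s)
    expect_equal(total_weight(rep_m), 2)
    expect_equal(sum(rep_m > 0), 2L)
    expect_true(all(rowSums(rep_m) > 0) && all(colSums(rep_m) > 0))
  }
  set.seed(111)
  m <- random_count_matrix(10, 6)
  for (s in 1:50) {
    rep_m <- vaznull_replicate(m, seed = s)
    expect_equal(total_weight(rep_m), total_weight(m))
    expect_equal(sum(rep_m > 0), sum(m > 0))
    expect_true(all(rowSums(rep_m) > 0) && all(colSums(rep_m) > 0))
  }
})

test_that("vaznull replicate marginals track observed marginals", {
  set.seed(121)
  m <- random_count_matrix(10, 6, max_w = 8)
  reps <- build_ensemble("vaznull", m, n = 200, base_seed = 7)$replicates
  mean_cols <- Reduce(`+`, lapply(reps, colSums)) / length(reps)
  expect_gt(cor(mean_cols, colSums(m), method = "spearman"), 0.9)
})

test_that("module-constrained nulls keep blocks and inter-module cells fixed", {
  set.seed(131)
  g <- generate_modular_network(synthetic_spec(
    n_resources = 20, n_consumers = 8, n_modules = 2, mixing = 0.2,
    total_events = 300, seed = 19))
  m <- g$matrix
  p <- g$partition
  v <- tidy(p)
  a <- unclass(m)
  for (s in 1:5) {
    rep_m <- module_constrained_replicate(m, p, seed = s)
    b <- unclass(rep_m)
    expect_equal(sum(b), sum(a))
    for (mod in 1:2) {
      ri <- v$node[v$side == "rows" & v$module == mod]
      ci <- v$node[v$side == "cols" & v$module == mod]
      expect_equal(sum(b[ri, ci]), sum(a[ri, ci]))
      expect_equal(sum(b[ri, ci] > 0), sum(a[ri, ci] > 0))
      # off-block cells are copied unchanged
      expect_equal(b[ri, setdiff(colnames(a), ci)],
                   a[ri, setdiff(colnames(a), ci)])
    }
  }
  # block-diagonal matrices stay block-diagonal
  bd <- two_block_matrix()
  pbd <- module_partition(make_partition(bd, rep(1:2, each = 2), rep(1:2, each = 2)), bd)
  rep_bd <- module_constrained_replicate(bd, pbd, seed = 3)
  expect_equal(sum(unclass(rep_bd)[3:4, 1:2]) + sum(unclass(rep_bd)[1:2, 3:4]), 0)
})

test_that("module_resample draws the requested number of events", {
  set.seed(141)
  m <- random_count_matrix(6, 5)
  W <- total_weight(m)
  # the full draw returns the whole network's events
  full <- module_resample(m, W, seed = 1)
  expect_equal(sum(full$weight), W)
  a_back <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(full))) {
    a_back[full$resource[i], full$consumer[i]] <- full$weight[i]
  }
  expect_equal(a_back, bare(m))
  # partial draws conserve the event count
  for (k in c(1, 5, W - 1)) {
    expect_equal(sum(module_resample(m, k, seed = k)$weight), k)
  }
  expect_error(module_resample(m, W + 1, seed = 1), "without replacement")
})

test_that("single-event resamples pick consumers by marginal totals", {
  a <- matrix(c(8, 0, 0, 2), 2, 2, dimnames = list(c("r1", "r2"), c("c1", "c2")))
  m <- weighted_matrix(a)
  set.seed(151)
  picks <- vapply(1:2000, function(i) module_resample(m, 1)$consumer, character(1))
  # c1 carries 80% of events
  expect_equal(mean(picks == "c1"), 0.8, tolerance = 0.05)
})

test_that("ensembles are reproducible from the base seed", {
  set.seed(161)
  m <- random_count_matrix(6, 4)
  e1 <- build_ensemble("vaznull", m, n = 5, base_seed = 42)
  e2 <- build_ensemble("vaznull", m, n = 5, base_seed = 42)
  expect_identical(lapply(e1$replicates, unclass), lapply(e2$replicates, unclass))
  e3 <- build_ensemble("module_resample", m, n = 3, base_seed = 9, n_events = 10)
  e4 <- build_ensemble("module_resample", m, n = 3, base_seed = 9, n_events = 10)
  expect_identical(e3$replicates, e4$replicates)
  expect_equal(e3$n, 3)
})
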