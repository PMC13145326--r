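test_that("z-scores follow the standardization formula and Table-style labels", {
  nulls <- c(10, 12, 14, 16, 18)
  z0 <- zscore(mean(nulls), nulls, "wnoda")
  expect_equal(z0$z, 0)
  expect_equal(z0$interpretation, "non-significant")

  z25 <- zscore(mean(nulls) + 2.5 * sd(nulls), nulls, "wnoda")
  expect_equal(z25$z, 2.5)
  expect_equal(z25$interpretation, "nested")
  expect_equal(z25$z, (z25$x_obs - z25$null_mean) / z25$null_sd)

  expect_equal(zscore(mean(nulls) - 3 * sd(nulls), nulls, "fdis")$interpretation,
               "niche filtering")
  expect_equal(zscore(mean(nulls) + 3 * sd(nulls), nulls, "fdis")$interpretation,
               "limiting similarity")
  expect_equal(zscore(mean(nulls) + 3 * sd(nulls), nulls, "cwm")$interpretation,
               "trait matching")
  expect_equal(zscore(mean(nulls) - 3 * sd(nulls), nulls, "cwm")$interpretation,
               "trait barrier")
  expect_equal(zscore(mean(nulls) + 3 * sd(nulls), nulls, "modularity")$interpretation,
               "modular")
  expect_equal(zscore(mean(nulls) - 3 * sd(nulls), nulls, "wnoda")$interpretation,
               "anti-nested")

  expect_error(zscore(1, rep(5, 10), "wnoda"), "Degenerate")
  expect_error(zscore(1, c(2), "wnoda"), "two")
})

test_that("abundance-degree regression matches lm and handles edge cases", {
  # perfectly collinear points
  ab <- c(10, 100, 1000, 10000)
  d <- data.frame(abundance = ab, degree = 2 * log10(ab) + 1)
  res <- suppressWarnings(abundance_degree_regression(d))  # perfect fit
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 1)

  set.seed(191)
  d2 <- data.frame(abundance = rlnorm(20, 3, 1))
  d2$degree <- round(3 * log10(d2$abundance) + rnorm(20))
  res2 <- abundance_degree_regression(d2)
  ref <- summary(lm(degree ~ log10(abundance), data = d2))
  expect_equal(res2$r_squared, ref$r.squared)
  expect_equal(res2$f_statistic, unname(ref$fstatistic[1]))
  expect_equal(res2$n_points, 20L)

  expect_error(abundance_degree_regression(data.frame(abundance = c(1, 2),
                                                      degree = c(1, 2))),
               "at least 3")
  expect_error(abundance_degree_regression(data.frame(abundance = c(1, 1, 1),
                                                      degree = c(1, 2, 3))),
               "variance")
  expect_error(abundance_degree_regression(data.frame(abundance = c(0, 1, 2),
                                                      degree = c(1, 2, 3))),
               "positive")
})

test_that("nmi scores label recovery and agrees with igraph", {
  expect_equal(nmi(c(1, 1, 2, 2), c(2, 2, 7, 7)), 1)
  set.seed(201)
  a <- sample(1:3, 40, replace = TRUE)
  b <- sample(1:3, 40, replace = TRUE)
  expect_lt(nmi(a, b), 0.3)
  skip_if_not_installed("igraph")
  expect_equal(nmi(a, b), igraph::compare(a, b, method = "nmi"), tolerance = 1e-12)
})

small_config <- function(seed = 5) {
  g_occ <- generate_modular_network(synthetic_spec(
    n_resources = 24, n_consumers = 8, n_modules = 2, mixing = 0.15,
    total_events = 260, seed = 31))
  g_fw <- generate_modular_network(synthetic_spec(
    n_resources = 18, n_consumers = 8, n_modules = 2, mixing = 0.15,
    total_events = 200, seed = 37), kind = "foodweb")
  tr <- generate_traits(g_occ$partition, convergence = 0.7, n_quant = 3,
                        n_cat = 1, seed = 41)
  list(
    networks = list(occurrence = g_occ$matrix, foodweb = g_fw$matrix),
    traits = tr,
    abundance = g_occ$abundance,
    resource_meta = list(occurrence = tibble::tibble(
      node = rownames(g_occ$matrix),
      category = rep(c("IL", "CL", "SC", "MR"), 6))),
    seed = seed,
    n_null_network = 12, n_null_module = 25, n_restarts = 6, restarts_null = 3
  )
}

test_that("run_full_analysis is deterministic and structurally complete", {
  cfg <- small_config()
  r1 <- run_full_analysis(cfg)
  r2 <- run_full_analysis(cfg)
  expect_identical(glance(r1), glance(r2))
  expect_identical(tidy(r1), tidy(r2))

  for (nm in c("occurrence", "foodweb")) {
    r <- r1$networks[[nm]]
    expect_s3_class(r$partition, "module_partition")
    expect_true(is.finite(r$q_z$z))
    expect_true(is.finite(r$wnoda_z$z))
    expect_true(is.finite(r$wnoda_sm_z$z))
    expect_gt(nrow(r$assembly$fdis), 0)
    expect_gt(nrow(r$assembly$cwm), 0)
    expect_true(all(c("r_squared", "f_statistic", "p_value") %in%
                      names(r$regression)))
  }
  # habitat composition tested only where metadata was supplied
  expect_gt(nrow(r1$networks$occurrence$assembly$composition_chisq), 0)
  expect_equal(nrow(r1$networks$foodweb$assembly$composition_chisq), 0)
  # z-scores in the tidy view are recomputable from their components
  td <- tidy(r1)
  has_parts <- !is.na(td$null_mean) & !is.na(td$null_sd)
  expect_equal(td$z[has_parts],
               (td$x_obs[has_parts] - td$null_mean[has_parts]) / td$null_sd[has_parts])
})

test_that("config errors name the failing stage or entry", {
  expect_error(run_full_analysis(list(networks = list())), "missing")
  cfg <- small_config()
  cfg$abundance <- cfg$abundance[1:2]  # drops most consumers
  expect_error(run_full_analysis(cfg), "regression")
})

test_that("plots build without error", {
  cfg <- small_config()
  m <- cfg$networks$occurrence
  p <- find_modules(m, n_restarts = 4, seed = 2)
  expect_s3_class(ggplot2::autoplot(m, partition = p), "ggplot")
  d <- data.frame(abundance = c(3, 30, 300, 80), degree = c(1, 4, 9, 5))
  expect_s3_class(plot_abundance_degree(d), "ggplot")
})
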