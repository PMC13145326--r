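five_consumer_traits <- function() {
  trait_table(tibble::tibble(
    consumer = paste0("c", 1:5),
    size = c(10, 25, 14, 40, 22),
    gape = c(1.2, 2.5, 1.4, 3.3, 2.2),
    tooth = c("conical", "triangular", "conical", "triangular", "villiform"),
    eye = c("dorsal", "lateral", "dorsal", "ventral", "lateral")
  ))
}

test_that("gower distances match definition and the hand-coded oracle", {
  tt <- trait_table(tibble::tibble(
    consumer = c("a", "b"),
    t1 = c("x", "x"), t2 = c("u", "v"), t3 = c("m", "m"), t4 = c("p", "p")
  ))
  sp <- gower_space(tt)
  # differ in exactly 1 of 4 equally weighted categorical traits
  expect_equal(sp$dist["a", "b"], 1 / 4)

  same <- trait_table(tibble::tibble(
    consumer = c("a", "b"), t1 = c(3, 3), t2 = c("x", "x")
  ))
  expect_warning(sp2 <- gower_space(same), "zero range")
  expect_equal(sp2$dist["a", "b"], 0)

  tt5 <- five_consumer_traits()
  sp5 <- gower_space(tt5)
  expect_equal(sp5$dist, oracle_gower(tt5), tolerance = 1e-12)
  # embedding reproduces (corrected) distances
  emb_d <- as.matrix(dist(sp5$coords))
  if (sp5$correction == 0) {
    expect_equal(emb_d, sp5$dist, tolerance = 1e-8)
  } else {
    off <- sp5$dist + sp5$correction
    diag(off) <- 0
    expect_equal(emb_d, off, tolerance = 1e-6)
  }
})

test_that("gower distances agree with cluster::daisy on mixed traits", {
  skip_if_not_installed("cluster")
  tt5 <- five_consumer_traits()
  df <- as.data.frame(tt5[, -1])
  df$tooth <- factor(df$tooth)
  df$eye <- factor(df$eye)
  d_ref <- as.matrix(cluster::daisy(df, metric = "gower"))
  expect_equal(unname(gower_space(tt5)$dist), unname(d_ref), tolerance = 1e-10)
})

test_that("fdis matches closed forms and is invariant to rigid motions", {
  tt5 <- five_consumer_traits()
  sp5 <- gower_space(tt5)
  co <- sp5$coords

  expect_equal(fdis(co[1, , drop = FALSE], 1), 0)
  d12 <- sqrt(sum((co[1, ] - co[2, ])^2))
  expect_equal(fdis(co[1:2, ], c(1, 1)), d12 / 2)

  w <- c(3, 1, 2, 5, 4)
  centroid <- colSums(co * w) / sum(w)
  direct <- sum(w * sqrt(rowSums(sweep(co, 2, centroid)^2))) / sum(w)
  expect_equal(fdis(co, w), direct)

  # translation and rotation leave fdis unchanged; scaling is linear
  shifted <- sweep(co, 2, rnorm(ncol(co)), "+")
  expect_equal(fdis(shifted, w), direct)
  set.seed(9)
  qr_rot <- qr.Q(qr(matrix(rnorm(ncol(co)^2), ncol(co))))
  expect_equal(fdis(co %*% qr_rot, w), direct)
  expect_equal(fdis(co * 3, w), 3 * direct)
})

test_that("module fdis uses all consumers of a module's resources", {
  set.seed(171)
  g <- generate_modular_network(synthetic_spec(
    n_resources = 20, n_consumers = 8, n_modules = 2, mixing = 0.2,
    total_events = 250, seed = 23))
  tr <- generate_traits(g$partition, convergence = 0.5, seed = 5)
  sp <- gower_space(tr)
  out <- module_fdis(g$matrix, g$partition, 1, sp)
  # consumer set = every consumer interacting with module-1 resources
  v <- tidy(g$partition)
  rows <- v$node[v$side == "rows" & v$module == 1]
  users <- colnames(g$matrix)[colSums(unclass(g$matrix)[rows, ]) > 0]
  expect_setequal(out$consumers$consumer, users)
  expect_equal(out$consumers$weight,
               unname(colSums(unclass(g$matrix)[rows, users])))
  expect_gte(out$fdis, 0)

  # trait-identical consumers give fdis 0
  flat <- trait_table(tibble::tibble(
    consumer = colnames(g$matrix), t1 = 1:8 * 0 + 3, t2 = rep("x", 8)))
  expect_warning(sp_flat <- gower_space(flat), "zero range")
  expect_equal(module_fdis(g$matrix, g$partition, 1, sp_flat)$fdis, 0)
})

test_that("cwm matches closed forms and stays within the value range", {
  expect_equal(cwm(c(1, 3), c(1, 1)), 2)
  expect_equal(cwm(c(3, 0), c(2, 1)), 2)
  set.seed(181)
  for (rep in 1:10) {
    v <- rnorm(6)
    w <- runif(6)
    out <- cwm(v, w)
    expect_gte(out, min(v))
    expect_lte(out, max(v))
  }
  expect_error(cwm(c(1, 2), c(0, 0)), "positive")
})

test_that("composition chi-square matches hand evaluation", {
  res <- categorical_composition_test(c(a = 10, b = 0), c(a = 0.5, b = 0.5))
  expect_equal(res$statistic, 10)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(10, 1, lower.tail = FALSE))

  # proportional observed counts give statistic 0
  res0 <- categorical_composition_test(c(a = 30, b = 60, c = 10),
                                       c(a = 0.3, b = 0.6, c = 0.1))
  expect_equal(res0$statistic, 0)

  # cross-check against stats::chisq.test
  o <- c(a = 25, b = 20, c = 15)
  p <- c(a = 0.5, b = 0.3, c = 0.2)
  ref <- suppressWarnings(stats::chisq.test(o, p = p))
  mine <- categorical_composition_test(o, p)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, unname(ref$p.value))

  # 3x overrepresentation of one habitat among 60 occurrences is detected
  obs <- c(IL = 30, CL = 10, SC = 10, MR = 10)
  expect_lt(categorical_composition_test(obs, c(IL = 0.25, CL = 0.25,
                                                SC = 0.25, MR = 0.25))$p_value,
            0.05)
  expect_error(categorical_composition_test(c(a = 1, b = 1), c(a = 1, b = 0)),
               "merge")
})

test_that("individual-level trait values collapse to means but keep raw lists", {
  tt <- trait_table(tibble::tibble(
    consumer = c("a", "b"),
    body = list(c(10, 12, 14), c(30, 34)),
    tooth = c("conical", "triangular")
  ))
  expect_equal(tt$body, c(12, 32))
  raw <- attr(tt, "individual_values")$body
  expect_equal(raw[["b"]], c(30, 34))
})
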