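#' Module partitions
#'
#' A `module_partition` assigns every node of a weighted matrix (both the
#' resource rows and the consumer columns) to exactly one module, and stores
#' the modularity of that assignment. Module ids are contiguous integers
#' starting at 1, canonicalized by descending module total weight.
#'
#' @param assignment Data frame with columns `node`, `side` (`"rows"` /
#'   `"cols"`) and `module` (integer).
#' @param m The [weighted_matrix()] the partition refers to.
#' @param objective `"bipartite"` or `"directed"`; used to recompute `q`.
#' @param restarts_used Number of optimizer restarts behind this partition.
#' @return A `module_partition` object.
#' @export
module_partition <- function(assignment, m, objective = c("bipartite", "directed"),
                             restarts_used = NA_integer_) {
  objective <- match.arg(objective)
  assignment <- tibble::as_tibble(assignment)[, c("node", "side", "module")]
  assignment <- canonicalize_modules(assignment, m)
  p <- structure(
    list(assignment = assignment, q = NA_real_,
         n_modules = length(unique(assignment$module)),
         restarts_used = restarts_used, objective = objective),
    class = "module_partition"
  )
  p$q <- if (objective == "bipartite") bipartite_weighted_q(m, p) else directed_weighted_q(m, p)
  p
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules over %d nodes, Qw = %.4f (%s, %s restarts)\n",
              x$n_modules, nrow(x$assignment), x$q, x$objective,
              ifelse(is.na(x$restarts_used), "?", x$restarts_used)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.module_partition <- function(x, ...) x$assignment

#' @exportS3Method generics::glance
glance.module_partition <- function(x, ...) {
  tibble::tibble(q = x$q, n_modules = x$n_modules,
                 restarts_used = x$restarts_used, objective = x$objective)
}

# assignment tibble -> integer vectors aligned with rows/cols of m
partition_vectors <- function(m, p) {
  a <- if (inherits(p, "module_partition")) p$assignment else tibble::as_tibble(p)
  a_rows <- a[a$side == "rows", ]
  a_cols <- a[a$side == "cols", ]
  zr <- a_rows$module[match(rownames(m), a_rows$node)]
  zc <- a_cols$module[match(colnames(m), a_cols$node)]
  if (anyNA(zr) || anyNA(zc)) {
    miss <- c(rownames(m)[is.na(zr)], colnames(m)[is.na(zc)])
    abort(paste0("Partition does not cover nodes: ", paste(head(miss, 5), collapse = ", ")))
  }
  list(zr = as.integer(zr), zc = as.integer(zc))
}

canonicalize_modules <- function(assignment, m) {
  tot <- c(rowSums(unclass(m)), colSums(unclass(m)))
  names(tot) <- c(rownames(m), colnames(m))
  mod_weight <- tapply(tot[assignment$node], assignment$module, sum)
  ord <- names(sort(mod_weight, decreasing = TRUE))
  relabel <- setNames(seq_along(ord), ord)
  assignment$module <- as.integer(relabel[as.character(assignment$module)])
  assignment
}

#' Weighted modularity of a partition
#'
#' `bipartite_weighted_q()` evaluates the weighted bipartite (Barber-type)
#' modularity
#' \deqn{Q = \frac{1}{W}\sum_{ij: \; \mathrm{same \; module}} \left(A_{ij} - \frac{r_i c_j}{W}\right)}
#' with \eqn{r_i}, \eqn{c_j} the row/column marginal totals and \eqn{W} the
#' total weight. `directed_weighted_q()` evaluates the weighted directed
#' unipartite form used for food webs viewed as prey-to-predator graphs,
#' \deqn{Q = \sum_s \left[\frac{W_{ss}}{W} - \frac{W_s^{out}}{W}\frac{W_s^{in}}{W}\right],}
#' summing over modules \eqn{s}; on the bipartite carrier the two forms agree
#' algebraically, but both are exposed to mirror the occurrence-network /
#' food-web split.
#'
#' @param m A [weighted_matrix()].
#' @param p A [module_partition()] or a data frame with `node`, `side`,
#'   `module` covering all nodes of `m`.
#' @return The modularity, a number in \[-1, 1\].
#' @export
bipartite_weighted_q <- function(m, p) {
  v <- partition_vectors(m, p)
  a <- unclass(m)
  W <- sum(a)
  same <- outer(v$zr, v$zc, "==")
  expected <- outer(rowSums(a), colSums(a)) / W
  sum((a - expected)[same]) / W
}

#' @rdname bipartite_weighted_q
#' @export
directed_weighted_q <- function(m, p) {
  if (!identical(attr(m, "kind"), "foodweb")) {
    abort("The directed unipartite objective applies to `kind = \"foodweb\"` matrices.")
  }
  v <- partition_vectors(m, p)
  a <- unclass(m)
  W <- sum(a)
  mods <- sort(unique(c(v$zr, v$zc)))
  q <- 0
  for (s in mods) {
    w_ss <- sum(a[v$zr == s, v$zc == s, drop = FALSE])
    w_out <- sum(rowSums(a)[v$zr == s])  # prey out-strength in module s
    w_in <- sum(colSums(a)[v$zc == s])   # predator in-strength in module s
    q <- q + w_ss / W - (w_out / W) * (w_in / W)
  }
  q
}

#' Find modules by stochastic optimization
#'
#' Optimizes weighted modularity by simulated annealing restarted
#' `n_restarts` times, retaining the configuration with the highest
#' modularity (ties broken towards the lexicographically smallest canonical
#' assignment, for reproducibility). The annealing schedule is fixed:
#' initial temperature calibrated from the mean absolute modularity change
#' of random single-node moves, geometric cooling (factor `cooling` per
#' sweep), proposals mixing single-node moves (including moves to an empty
#' module) with module merges, stopping after \eqn{n^2} consecutive
#' rejections. Every restart ends with greedy hill-climbing over node moves
#' and module merges.
#'
#' @param m A [weighted_matrix()].
#' @param objective `"bipartite"` (occurrence networks) or `"directed"`
#'   (food webs).
#' @param n_restarts Number of independent optimizer runs (default 100,
#'   the conventional restart budget for annealing-based module detection).
#' @param seed Integer seed making the whole search reproducible.
#' @param method `"simulated_annealing"` (default) or
#'   `"weighted_label_propagation"`, a faster greedy label-update route used
#'   for large null ensembles.
#' @param cooling Geometric cooling factor per sweep.
#' @return A [module_partition()] with `q`, `n_modules` and `restarts_used`.
#' @examples
#' m <- weighted_matrix(rbind(
#'   s1 = c(a = 3, b = 2, c = 0, d = 0),
#'   s2 = c(a = 2, b = 3, c = 0, d = 0),
#'   s3 = c(a = 0, b = 0, c = 3, d = 2),
#'   s4 = c(a = 0, b = 0, c = 2, d = 3)))
#' find_modules(m, n_restarts = 10, seed = 1)
#' @export
find_modules <- function(m, objective = c("bipartite", "directed"),
                         n_restarts = 100, seed = NULL,
                         method = c("simulated_annealing", "weighted_label_propagation"),
                         cooling = 0.995) {
  objective <- match.arg(objective)
  method <- match.arg(method)
  stopifnot(n_restarts >= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- unclass(m)
  n <- nrow(a) + ncol(a)
  if (n == 1 || sum(a > 0) == 0) {
    return(module_partition(trivial_assignment(m), m, objective, restarts_used = n_restarts))
  }
  anneal <- method == "simulated_annealing"
  best <- NULL
  best_q <- -Inf
  best_key <- NULL
  for (k in seq_len(n_restarts)) {
    res <- sa_partition(a, anneal = anneal, cooling = cooling)
    z <- res$assignment
    key <- canonical_key(z)
    if (res$q > best_q + 1e-12 ||
        (abs(res$q - best_q) <= 1e-12 && !is.null(best_key) && key_less(key, best_key))) {
      best <- z
      best_q <- res$q
      best_key <- key
    }
  }
  if (best_q <= 1e-12) {
    # nothing beats the unpartitioned network: report one module, Q = 0
    return(module_partition(trivial_assignment(m), m, objective,
                            restarts_used = n_restarts))
  }
  assignment <- tibble::tibble(
    node = c(rownames(a), colnames(a)),
    side = rep(c("rows", "cols"), c(nrow(a), ncol(a))),
    module = as.integer(best) + 1L
  )
  module_partition(assignment, m, objective, restarts_used = n_restarts)
}

trivial_assignment <- function(m) {
  tibble::tibble(
    node = c(rownames(m), colnames(m)),
    side = rep(c("rows", "cols"), c(nrow(m), ncol(m))),
    module = 1L
  )
}

# relabel an assignment vector by first appearance -> comparable across runs
canonical_key <- function(z) {
  relabel <- integer(0)
  out <- integer(length(z))
  nxt <- 1L
  seen <- new.env()
  for (i in seq_along(z)) {
    k <- as.character(z[i])
    v <- seen[[k]]
    if (is.null(v)) {
      seen[[k]] <- nxt
      out[i] <- nxt
      nxt <- nxt + 1L
    } else out[i] <- v
  }
  out
}

key_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  length(i) > 0 && d[i[1]] < 0
}

#' Normalized modularity
#'
#' Divides the observed modularity by the modularity of an idealized fully
#' modular version of the matrix: every row's inter-module weight is moved
#' inside its module, proportionally to the row's existing within-module
#' cells (or spread evenly over the module's consumers when the row has no
#' within-module interaction), preserving row marginal totals and module
#' sizes. Raw Qw is sensitive to network size and connectance, so normalized
#' values are reported when comparing networks.
#'
#' @inheritParams bipartite_weighted_q
#' @return `q / q_max`, in \[0, 1\] for non-negative `q`; `NA` with a warning
#'   when the idealized modularity is 0 (no normalization possible).
#' @export
normalize_q <- function(m, p) {
  v <- partition_vectors(m, p)
  ideal <- ideal_modular_matrix(unclass(m), v$zr, v$zc)
  q <- bipartite_weighted_q(m, p)
  ideal_wm <- structure(ideal, kind = attr(m, "kind"),
                        class = c("weighted_matrix", "matrix", "array"))
  q_max <- bipartite_weighted_q(ideal_wm, p)
  if (abs(q_max) < 1e-12) {
    warn("Idealized modularity is 0; normalized modularity undefined.")
    return(NA_real_)
  }
  q / q_max
}

ideal_modular_matrix <- function(a, zr, zc) {
  out <- a
  for (i in seq_len(nrow(a))) {
    inb <- which(zc == zr[i])
    if (length(inb) == 0) next  # module has no consumers; row weight cannot move
    w_in <- sum(a[i, inb])
    w_out <- sum(a[i, ]) - w_in
    if (w_out == 0) next
    out[i, -inb] <- 0
    if (w_in > 0) {
      out[i, inb] <- a[i, inb] * (w_in + w_out) / w_in
    } else {
      out[i, inb] <- w_out / length(inb)
    }
  }
  out
}
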