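#' Synthetic network specification
#'
#' Bundles the parameters of the planted-structure generator. Defaults
#' mirror the scale of the empirical system the package is designed around:
#' an occurrence network of 149 community samples by 17 predator
#' species/stages carrying 3010 interaction events (use
#' `n_resources = 113`, `n_modules = 6`, `total_events = 1271` for a
#' food-web-scale matrix). `mixing` is the probability that an interaction
#' event falls outside its consumer's module; `nestedness` in \[0, 1\]
#' controls a rank-decay profile of within-module resource use that makes
#' blocks internally nested; abundances are lognormal.
#'
#' @param n_resources,n_consumers,n_modules Dimensions.
#' @param mixing Probability of an out-of-module event.
#' @param nestedness Within-module nestedness strength in \[0, 1\].
#' @param abundance_meanlog,abundance_sdlog Lognormal abundance parameters.
#' @param total_events Total interaction events W.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_resources = 149, n_consumers = 17, n_modules = 7,
                           mixing = 0.15, nestedness = 0.3,
                           abundance_meanlog = log(50), abundance_sdlog = 1.2,
                           total_events = 3010, seed = 1) {
  if (mixing < 0 || mixing > 1) abort("`mixing` must be in [0, 1].")
  if (nestedness < 0 || nestedness > 1) abort("`nestedness` must be in [0, 1].")
  if (n_resources < n_modules || n_consumers < n_modules) {
    abort("Each side needs at least as many nodes as modules.")
  }
  if (total_events < n_resources + n_consumers) {
    abort("`total_events` too small to cover every node.")
  }
  structure(list(n_resources = n_resources, n_consumers = n_consumers,
                 n_modules = n_modules, mixing = mixing, nestedness = nestedness,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 total_events = total_events, seed = seed),
            class = "synthetic_spec")
}

#' Generate a modular weighted network with planted structure
#'
#' Assigns resources and consumers to modules, draws each interaction
#' event's consumer with probability proportional to its (lognormal)
#' abundance, keeps the event inside the consumer's module with probability
#' `1 - mixing`, and picks the resource within the chosen module following
#' a rank-decay profile whose steepness grows with the `nestedness`
#' strength (uniform at 0). Every node is guaranteed at least one event by
#' moving events from the fullest cells, keeping W exact.
#'
#' @param spec A [synthetic_spec()].
#' @param kind Passed to [weighted_matrix()].
#' @param abundance Optional named consumer abundances, e.g. to build an
#'   occurrence network and a food web over the same predator assemblage;
#'   drawn from the spec's lognormal by default.
#' @return List: `matrix` (a [weighted_matrix()]), `partition` (the planted
#'   [module_partition()]), `abundance` (named consumer abundances).
#' @export
generate_modular_network <- function(spec, kind = "occurrence", abundance = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  k <- spec$n_modules
  res_mod <- sort(rep_len(seq_len(k), spec$n_resources))
  con_mod <- sort(rep_len(seq_len(k), spec$n_consumers))
  if (is.null(abundance)) {
    abundance <- rlnorm(spec$n_consumers, spec$abundance_meanlog, spec$abundance_sdlog)
  } else if (length(abundance) != spec$n_consumers || any(abundance <= 0)) {
    abort("`abundance` must be positive, one value per consumer.")
  }
  res_labels <- sprintf("r%03d", seq_len(spec$n_resources))
  con_labels <- sprintf("c%02d", seq_len(spec$n_consumers))
  names(abundance) <- con_labels

  # module resource lists, and per-consumer accessible-resource counts that
  # shrink with within-module abundance rank: with probability `nestedness`
  # an event is confined to the top resources its consumer can access, so
  # specialists' resource sets nest inside generalists' (structure beyond
  # what marginal totals impose); otherwise the draw is uniform in the block
  res_idx <- lapply(seq_len(k), function(s) which(res_mod == s))
  access <- integer(spec$n_consumers)
  for (s in seq_len(k)) {
    js <- which(con_mod == s)
    rank_in_mod <- rank(-abundance[js], ties.method = "first")
    access[js] <- pmax(1L, ceiling(length(res_idx[[s]]) *
                                     (length(js) - rank_in_mod + 1) / length(js)))
  }

  a <- matrix(0L, spec$n_resources, spec$n_consumers,
              dimnames = list(res_labels, con_labels))
  consumers <- sample.int(spec$n_consumers, spec$total_events, replace = TRUE,
                          prob = abundance)
  outside <- runif(spec$total_events) < spec$mixing
  # out-of-module events land uniformly in a random other module
  for (e in which(outside)) {
    j <- consumers[e]
    others <- setdiff(seq_len(k), con_mod[j])
    s <- if (k > 1) others[sample.int(length(others), 1)] else con_mod[j]
    i <- res_idx[[s]][sample.int(length(res_idx[[s]]), 1)]
    a[i, j] <- a[i, j] + 1L
  }
  # within-module events: each consumer's events spread over its accessible
  # resources along a rank-decay profile; a `nestedness` fraction is placed
  # deterministically (largest-remainder rounding of the expected surface),
  # the rest multinomially, so strength 1 gives a smooth nested block and
  # strength 0 a uniform noisy one
  eta <- spec$nestedness
  intra <- tabulate(consumers[!outside], nbins = spec$n_consumers)
  for (j in seq_len(spec$n_consumers)) {
    w_j <- intra[j]
    if (w_j == 0) next
    idx <- res_idx[[con_mod[j]]]
    n_s <- length(idx)
    p <- rep(1 - eta, n_s)
    top <- seq_len(min(access[j], n_s))
    p[top] <- p[top] + eta * n_s * exp(-3 * (top - 1) / n_s) / length(top)
    p <- p / sum(p)
    n_det <- round(eta * w_j)
    det <- largest_remainder(n_det * p)
    rnd <- if (w_j > n_det) as.vector(stats::rmultinom(1, w_j - n_det, p)) else 0L
    a[idx, j] <- a[idx, j] + as.integer(det + rnd)
  }
  a <- fill_empty_nodes(a, res_mod, con_mod)

  m <- weighted_matrix(a, kind = kind)
  assignment <- tibble::tibble(
    node = c(res_labels, con_labels),
    side = rep(c("rows", "cols"), c(spec$n_resources, spec$n_consumers)),
    module = c(res_mod, con_mod)
  )
  partition <- module_partition(assignment, m,
                                objective = if (kind == "foodweb") "directed" else "bipartite")
  list(matrix = m, partition = partition, abundance = abundance)
}

# integer allocation of `target` (non-negative reals summing to an integer)
largest_remainder <- function(target) {
  fl <- floor(target)
  rem <- round(sum(target)) - sum(fl)
  if (rem > 0) {
    add <- order(target - fl, decreasing = TRUE)[seq_len(rem)]
    fl[add] <- fl[add] + 1
  }
  fl
}

# guarantee every row/column >= 1 event by moving events from the fullest
# cells; total weight is conserved
fill_empty_nodes <- function(a, res_mod, con_mod) {
  for (i in which(rowSums(a) == 0)) {
    donors <- which(a >= 2, arr.ind = TRUE)
    d <- donors[which.max(a[donors]), , drop = FALSE]
    j <- d[1, 2]
    a[d] <- a[d] - 1L
    a[i, j] <- a[i, j] + 1L
  }
  for (j in which(colSums(a) == 0)) {
    donors <- which(a >= 2, arr.ind = TRUE)
    d <- donors[which.max(a[donors]), , drop = FALSE]
    i <- d[1, 1]
    a[d] <- a[d] - 1L
    a[i, j] <- a[i, j] + 1L
  }
  a
}

#' Generate consumer traits with planted module convergence
#'
#' Quantitative traits are drawn around module-specific means, with the
#' within-module standard deviation shrinking as `convergence` approaches 1
#' (`value = convergence * mean_module + N(0, 1 - convergence)`), so
#' `convergence = 0` yields module-independent traits and `convergence = 1`
#' zero within-module variance. Categorical traits are drawn from
#' module-biased category distributions with the bias growing the same way.
#'
#' @param partition A [module_partition()] (or its `tidy()` assignment);
#'   consumer modules are taken from the `cols` side.
#' @param convergence Trait convergence strength in \[0, 1\].
#' @param n_quant,n_cat Numbers of quantitative and categorical traits
#'   (defaults emulate a 12-trait ecomorphological table).
#' @param n_levels Category levels per categorical trait.
#' @param seed Integer seed.
#' @return A [trait_table()].
#' @export
generate_traits <- function(partition, convergence, n_quant = 8, n_cat = 4,
                            n_levels = 3, seed = 1) {
  if (convergence < 0 || convergence > 1) abort("`convergence` must be in [0, 1].")
  set.seed(seed)
  assignment <- if (inherits(partition, "module_partition")) partition$assignment
    else tibble::as_tibble(partition)
  cols <- assignment[assignment$side == "cols", ]
  consumers <- cols$node
  mod <- cols$module
  k <- max(mod)
  df <- tibble::tibble(consumer = consumers)
  for (q in seq_len(n_quant)) {
    mu <- rnorm(k, 0, 1.5)
    df[[sprintf("q%02d", q)]] <- convergence * mu[mod] +
      rnorm(length(mod), 0, 1 - convergence + 1e-12)
  }
  for (cc in seq_len(n_cat)) {
    pref <- ((seq_len(k) + cc - 1) %% n_levels) + 1
    vals <- vapply(mod, function(s) {
      p <- rep((1 - convergence) / n_levels, n_levels)
      p[pref[s]] <- p[pref[s]] + convergence
      sample.int(n_levels, 1, prob = p)
    }, integer(1))
    df[[sprintf("k%02d", cc)]] <- paste0("lv", vals)
  }
  trait_table(df)
}

#' Generate an abundance-driven (neutral) network
#'
#' Every interaction event draws its consumer with probability proportional
#' to abundance and its resource uniformly, so expected consumer degree
#' increases with abundance and no module or trait structure is planted.
#'
#' @param abundances Named positive consumer abundances.
#' @param n_resources Number of resource nodes.
#' @param total_events Total events W.
#' @param seed Integer seed.
#' @param kind Passed to [weighted_matrix()].
#' @param resource_abundances Optional positive weights making resource
#'   draws proportional to resource abundance instead of uniform.
#' @return A [weighted_matrix()].
#' @export
generate_neutral_network <- function(abundances, n_resources, total_events,
                                     seed = 1, kind = "occurrence",
                                     resource_abundances = NULL) {
  if (any(abundances <= 0)) abort("Abundances must be positive.")
  set.seed(seed)
  nc <- length(abundances)
  con_labels <- if (!is.null(names(abundances))) names(abundances)
    else sprintf("c%02d", seq_len(nc))
  res_labels <- sprintf("r%03d", seq_len(n_resources))
  a <- matrix(0L, n_resources, nc, dimnames = list(res_labels, con_labels))
  consumers <- sample.int(nc, total_events, replace = TRUE, prob = abundances)
  resources <- if (is.null(resource_abundances)) {
    sample.int(n_resources, total_events, replace = TRUE)
  } else {
    if (length(resource_abundances) != n_resources || any(resource_abundances <= 0)) {
      abort("`resource_abundances` must be positive, one per resource.")
    }
    sample.int(n_resources, total_events, replace = TRUE, prob = resource_abundances)
  }
  for (e in seq_len(total_events)) {
    a[resources[e], consumers[e]] <- a[resources[e], consumers[e]] + 1L
  }
  a <- fill_empty_nodes(a, NULL, NULL)
  weighted_matrix(a, kind = kind)
}

#' Normalized mutual information between two labelings
#'
#' Scores recovery of planted module labels:
#' \eqn{\mathrm{NMI} = 2 I(A; B) / (H(A) + H(B))}, 1 for identical
#' partitions (up to relabeling), 0 for independent ones.
#'
#' @param a,b Two label vectors over the same nodes.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij)
  pj <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  ha <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  hb <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (ha + hb == 0) return(1)
  2 * mi / (ha + hb)
}
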