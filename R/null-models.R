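#' Connectance-preserving null model (Vazquez-style)
#'
#' Generates one randomized matrix that strictly preserves the number of
#' nonzero cells (connectance) and the total weight W, while maintaining the
#' degree distribution probabilistically: cells are selected with probability
#' proportional to the product of row and column marginal totals. The
#' procedure (1) draws a binary skeleton of exactly C cells without
#' replacement, forcing coverage of every row and column that carries
#' interactions (uncovered rows/columns are filled first, then free draws);
#' (2) distributes the remaining W - C integer interaction events over the
#' skeleton cells with the same probabilities.
#'
#' @param m A [weighted_matrix()] with integer events (non-integer weights
#'   are rescaled with a warning).
#' @param seed Optional integer seed.
#' @return A [weighted_matrix()] with the same labels, W and nonzero-cell
#'   count as `m`.
#' @export
vaznull_replicate <- function(m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ev <- as_integer_events(m)
  a <- ev$m
  out <- vaznull_fill(a)
  structure(out / ev$factor, kind = attr(m, "kind"),
            class = c("weighted_matrix", "matrix", "array"))
}

# core skeleton + event distribution on a plain integer matrix
vaznull_fill <- function(a, max_tries = 100) {
  nr <- nrow(a); nc <- ncol(a)
  r <- rowSums(a); cc <- colSums(a)
  W <- sum(a)
  C <- sum(a > 0)
  if (C < max(sum(r > 0), sum(cc > 0))) {
    abort("Infeasible: fewer nonzero cells than rows/columns needing coverage.")
  }
  p <- outer(r, cc)
  shuf <- function(x) if (length(x) <= 1) x else sample(x)
  for (try in seq_len(max_tries)) {
    sel <- matrix(FALSE, nr, nc)
    # coverage phase: every row with interactions draws one column, then
    # every still-uncovered column draws one row
    for (i in shuf(which(r > 0))) {
      j <- sample.int(nc, 1, prob = cc)
      sel[i, j] <- TRUE
    }
    for (j in shuf(which(cc > 0 & colSums(sel) == 0))) {
      i <- sample.int(nr, 1, prob = r)
      sel[i, j] <- TRUE
    }
    used <- sum(sel)
    if (used > C) next  # coverage spent more cells than available; redraw
    if (C > used) {
      free <- which(!sel & p > 0)
      if (length(free) < C - used) next
      extra <- free[sample.int(length(free), C - used, prob = p[free])]
      sel[extra] <- TRUE
    }
    out <- matrix(0, nr, nc, dimnames = dimnames(a))
    cells <- which(sel)
    out[cells] <- 1
    remaining <- W - C
    if (remaining > 0) {
      alloc <- as.vector(stats::rmultinom(1, remaining, prob = p[cells]))
      out[cells] <- out[cells] + alloc
    }
    return(out)
  }
  abort("Could not draw a feasible skeleton covering every row and column.")
}

#' Module-membership-constrained null model
#'
#' Complements the Vazquez-style null by keeping species membership within
#' each module constant: the randomization is applied independently inside
#' each module's diagonal block (its resources by its consumers), preserving
#' the block's nonzero-cell count and weight, while all inter-module cells
#' are copied unchanged. Coverage inside a block is only enforced for rows
#' and columns that carry interactions within the observed block.
#'
#' @param m A [weighted_matrix()].
#' @param p A [module_partition()] covering `m`.
#' @param seed Optional integer seed.
#' @return A [weighted_matrix()]; the base partition remains valid for it
#'   and per-block totals match the base matrix.
#' @export
module_constrained_replicate <- function(m, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ev <- as_integer_events(m)
  a <- ev$m
  v <- partition_vectors(m, p)
  out <- a
  for (s in sort(unique(c(v$zr, v$zc)))) {
    ri <- which(v$zr == s)
    ci <- which(v$zc == s)
    if (length(ri) == 0 || length(ci) == 0) next
    block <- a[ri, ci, drop = FALSE]
    if (sum(block > 0) <= 1) next
    shuffled <- tryCatch(
      vaznull_fill(block),
      error = function(e) abort(sprintf("Module %d: %s", s, conditionMessage(e)))
    )
    out[ri, ci] <- shuffled
  }
  structure(out / ev$factor, kind = attr(m, "kind"),
            class = c("weighted_matrix", "matrix", "array"))
}

#' Resample interactions into a null module
#'
#' Draws a fixed number of interaction events from the whole network's
#' events (each cell contributes events equal to its weight), without
#' replacement by default, returning the sampled (resource, consumer)
#' multiset as one null module. This preserves the number of interactions
#' per module while randomizing the identity of interacting species, so
#' consumers from other modules can enter the null module.
#'
#' @param m A [weighted_matrix()].
#' @param n_events Number of interaction events the null module holds
#'   (typically the observed module's interaction count).
#' @param seed Optional integer seed.
#' @param replace Sample events with replacement instead (default `FALSE`,
#'   keeping null modules sub-multisets of the observed network).
#' @return A tibble with columns `resource`, `consumer`, `weight` (events
#'   sampled per cell).
#' @export
module_resample <- function(m, n_events, seed = NULL, replace = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  ev <- as_integer_events(m)
  a <- ev$m
  W <- sum(a)
  if (n_events < 1) abort("`n_events` must be at least 1.")
  if (!replace && n_events > W) {
    abort(sprintf("Cannot draw %d events without replacement from W = %d.", n_events, W))
  }
  cells <- which(a > 0)
  counts <- if (replace) {
    as.vector(stats::rmultinom(1, n_events, prob = a[cells]))
  } else {
    # weighted without-replacement draw of events = hypergeometric per cell
    drawn <- sample.int(W, n_events)
    cell_of_event <- rep(seq_along(cells), a[cells])
    tabulate(cell_of_event[drawn], nbins = length(cells))
  }
  keep <- counts > 0
  idx <- arrayInd(cells[keep], dim(a))
  tibble::tibble(
    resource = rownames(a)[idx[, 1]],
    consumer = colnames(a)[idx[, 2]],
    weight = counts[keep] / ev$factor
  )
}

#' Build a null ensemble
#'
#' Generates `n` independent replicates of one of the three randomization
#' schemes, with per-replicate seeds derived deterministically from
#' `base_seed` so ensembles are reproducible end to end.
#'
#' @param generator `"vaznull"`, `"module_constrained"` or
#'   `"module_resample"`.
#' @param m A [weighted_matrix()].
#' @param p A [module_partition()] (required for `"module_constrained"`).
#' @param n Number of replicates (2000 Monte Carlo null modules per
#'   empirical module for the trait-assembly tests; 1000 by default for
#'   network-level metrics).
#' @param base_seed Integer seed for the whole ensemble.
#' @param n_events Events per null module (for `"module_resample"`).
#' @param replace Passed to [module_resample()].
#' @return A `null_ensemble`: list with `replicates`, `generator`, `n`,
#'   `base_seed`.
#' @export
build_ensemble <- function(generator = c("vaznull", "module_constrained", "module_resample"),
                           m, p = NULL, n = 1000, base_seed = 1,
                           n_events = NULL, replace = FALSE) {
  generator <- match.arg(generator)
  stopifnot(n >= 1)
  seeds <- derive_seeds(base_seed, n)
  replicates <- switch(
    generator,
    vaznull = purrr::map(seeds, ~ vaznull_replicate(m, seed = .x)),
    module_constrained = {
      if (is.null(p)) abort("`module_constrained` needs a partition `p`.")
      purrr::map(seeds, ~ module_constrained_replicate(m, p, seed = .x))
    },
    module_resample = {
      if (is.null(n_events)) abort("`module_resample` needs `n_events`.")
      purrr::map(seeds, ~ module_resample(m, n_events, seed = .x, replace = replace))
    }
  )
  structure(list(replicates = replicates, generator = generator, n = n,
                 base_seed = base_seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d %s replicates (base_seed %d)\n",
              x$n, x$generator, x$base_seed))
  invisible(x)
}

# deterministic child seeds, kept inside the 32-bit integer range
derive_seeds <- function(base_seed, n) {
  (as.integer(base_seed) + 7919L * seq_len(n)) %% 2147483647L
}
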