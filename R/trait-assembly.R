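#' Consumer trait tables
#'
#' Validates a per-consumer trait table: one row per consumer, a `consumer`
#' label column, and one column per trait. Numeric columns are treated as
#' quantitative traits, character/factor columns as categorical. A
#' list-column of numeric vectors holds individual-level measurements (e.g.
#' per-individual body sizes); it is collapsed to the per-consumer mean for
#' distance and CWM computations while the raw values are kept in the
#' `"individual_values"` attribute for resampling.
#'
#' @param df Data frame with a `consumer` column and trait columns.
#' @param m Optional [weighted_matrix()]; every consumer column of `m` must
#'   appear in the table.
#' @return A `trait_table` tibble with a `trait_types` attribute.
#' @export
trait_table <- function(df, m = NULL) {
  df <- tibble::as_tibble(df)
  if (!"consumer" %in% names(df)) abort("Trait table needs a `consumer` column.")
  if (anyDuplicated(df$consumer)) abort("Duplicate consumers in trait table.")
  if (!is.null(m)) {
    missing <- setdiff(colnames(m), df$consumer)
    if (length(missing) > 0) {
      abort(paste0("Traits missing for consumers: ", paste(missing, collapse = ", ")))
    }
  }
  raw <- list()
  for (nm in setdiff(names(df), "consumer")) {
    col <- df[[nm]]
    if (is.list(col)) {
      raw[[nm]] <- setNames(col, df$consumer)
      df[[nm]] <- vapply(col, function(v) mean(as.numeric(v)), numeric(1))
    } else if (is.factor(col)) {
      df[[nm]] <- as.character(col)
    }
  }
  types <- vapply(df[setdiff(names(df), "consumer")],
                  function(col) if (is.numeric(col)) "quantitative" else "categorical",
                  character(1))
  quant <- names(types)[types == "quantitative"]
  bad <- quant[vapply(df[quant], function(v) any(!is.finite(v)), logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Non-finite quantitative trait values in: ", paste(bad, collapse = ", ")))
  }
  structure(df, trait_types = types, individual_values = raw,
            class = c("trait_table", class(df)))
}

#' Mixed-trait distance space
#'
#' Builds the multidimensional trait space used by functional dispersion:
#' Gower distances over mixed traits (range-normalized absolute differences
#' for quantitative traits, simple matching for categorical ones, equal
#' trait weights), embedded by principal-coordinates analysis with a
#' Cailliez additive correction when the distance matrix is not Euclidean.
#' All axes with positive corrected eigenvalues are kept, so Euclidean
#' distances in the embedding reproduce the corrected Gower distances.
#' Zero-range quantitative traits carry no information and are excluded
#' with a warning.
#'
#' @param t A [trait_table()] with at least two consumers.
#' @return A `gower_space`: list with `dist` (Gower distance matrix),
#'   `coords` (consumers x axes), `eig`, `correction` (additive constant
#'   used, 0 if none).
#' @export
gower_space <- function(t) {
  stopifnot(inherits(t, "trait_table"))
  if (nrow(t) < 2) abort("Need at least two consumers to build a trait space.")
  types <- attr(t, "trait_types")
  labels <- t$consumer
  n <- length(labels)
  d_sum <- matrix(0, n, n)
  k_used <- 0
  for (nm in names(types)) {
    col <- t[[nm]]
    if (types[[nm]] == "quantitative") {
      rng <- diff(range(col))
      if (rng == 0) {
        warn(sprintf("Quantitative trait '%s' has zero range; excluded.", nm))
        next
      }
      d_sum <- d_sum + abs(outer(col, col, "-")) / rng
    } else {
      d_sum <- d_sum + outer(col, col, "!=")
    }
    k_used <- k_used + 1
  }
  if (k_used == 0) abort("No informative traits left.")
  d <- d_sum / k_used
  dimnames(d) <- list(labels, labels)
  emb <- pcoa_embed(d)
  structure(list(dist = d, coords = emb$coords, eig = emb$eig,
                 correction = emb$correction, traits_used = k_used),
            class = "gower_space")
}

# classical PCoA; add = TRUE applies the Cailliez constant when needed
pcoa_embed <- function(d) {
  n <- nrow(d)
  dd <- stats::as.dist(d)
  fit <- suppressWarnings(cmdscale(dd, k = n - 1, eig = TRUE))
  correction <- 0
  if (any(fit$eig < -1e-8 * max(abs(fit$eig)))) {
    fit <- suppressWarnings(cmdscale(dd, k = n - 1, eig = TRUE, add = TRUE))
    correction <- fit$ac
  }
  keep <- fit$eig > 1e-8 * max(fit$eig)
  keep_idx <- which(keep[seq_len(ncol(fit$points))])
  coords <- fit$points[, keep_idx, drop = FALSE]
  rownames(coords) <- rownames(d)
  list(coords = coords, eig = fit$eig, correction = correction)
}

#' Functional dispersion (FDis)
#'
#' The abundance-weighted mean distance of consumers to their weighted
#' centroid in multidimensional trait space:
#' \deqn{c = \frac{\sum_i w_i x_i}{\sum_i w_i}, \qquad
#'       \mathrm{FDis} = \frac{\sum_i w_i \lVert x_i - c \rVert}{\sum_i w_i}.}
#' Low FDis indicates trait convergence among the weighted consumers, high
#' FDis trait divergence. A single consumer with positive weight has
#' FDis = 0 by convention.
#'
#' @param coords Consumer coordinates (rows) from [gower_space()].
#' @param weights Non-negative per-consumer weights summing to > 0, in row
#'   order of `coords` (or named by consumer).
#' @return FDis, a non-negative number.
#' @export
fdis <- function(coords, weights) {
  coords <- as.matrix(coords)
  if (!is.null(names(weights)) && !is.null(rownames(coords))) {
    weights <- weights[rownames(coords)]
  }
  if (length(weights) != nrow(coords)) abort("One weight per consumer required.")
  if (anyNA(weights) || any(weights < 0)) abort("Weights must be non-negative.")
  sw <- sum(weights)
  if (sw <= 0) abort("Weights must sum to a positive value.")
  active <- weights > 0
  if (sum(active) <= 1) return(0)
  centroid <- colSums(coords * weights) / sw
  dists <- sqrt(rowSums(sweep(coords, 2, centroid)^2))
  sum(weights * dists) / sw
}

#' Module-level functional dispersion
#'
#' Measures the functional diversity of the consumers exploiting a module's
#' resources. The consumer set is all consumers in the network with at
#' least one interaction with the module's resources (not only module
#' members), each weighted by its total interaction weight with those
#' resources. This makes FDis defined for every module, including
#' monospecific ones, and lets consumers from other modules enter when the
#' module's resources impose weak barriers. Alternatively,
#' `weighting = "global_abundance"` weights consumers by a supplied global
#' abundance instead of module-specific exploitation.
#'
#' @param m A [weighted_matrix()].
#' @param p A [module_partition()] covering `m`.
#' @param module_id Integer module id.
#' @param space A [gower_space()] over all consumers of `m`.
#' @param weighting `"module_interactions"` (default) or
#'   `"global_abundance"`.
#' @param abundance Named per-consumer abundances (needed for
#'   `"global_abundance"`).
#' @return A list with `fdis`, `consumers` (tibble `consumer`, `weight`)
#'   and `module`.
#' @export
module_fdis <- function(m, p, module_id, space,
                        weighting = c("module_interactions", "global_abundance"),
                        abundance = NULL) {
  weighting <- match.arg(weighting)
  v <- partition_vectors(m, p)
  rows <- which(v$zr == module_id)
  if (length(rows) == 0) abort(sprintf("Module %d has no resources.", module_id))
  w <- colSums(unclass(m)[rows, , drop = FALSE])
  users <- w > 0
  if (!any(users)) abort(sprintf("No consumer uses the resources of module %d.", module_id))
  weights <- if (weighting == "module_interactions") {
    w[users]
  } else {
    if (is.null(abundance)) abort("`global_abundance` weighting needs `abundance`.")
    abundance[names(w)[users]]
  }
  coords <- space$coords[names(w)[users], , drop = FALSE]
  list(fdis = fdis(coords, weights),
       consumers = tibble::tibble(consumer = names(w)[users], weight = as.numeric(weights)),
       module = module_id)
}

# FDis of one resampled null module (event multiset from module_resample)
resampled_fdis <- function(events, space) {
  w <- tapply(events$weight, events$consumer, sum)
  coords <- space$coords[names(w), , drop = FALSE]
  fdis(coords, as.numeric(w))
}

#' Community-weighted mean (CWM)
#'
#' The abundance-weighted mean of a quantitative trait,
#' \eqn{\sum_i w_i v_i / \sum_i w_i}; always lies within the range of the
#' trait values.
#'
#' @param values Per-consumer quantitative trait values.
#' @param weights Non-negative weights summing to > 0 (module interaction
#'   weights or abundances), aligned with `values` (or both named).
#' @return The weighted mean.
#' @export
cwm <- function(values, weights) {
  if (!is.null(names(weights)) && !is.null(names(values))) {
    weights <- weights[names(values)]
  }
  if (length(values) != length(weights)) abort("`values` and `weights` lengths differ.")
  sw <- sum(weights)
  if (sw <= 0) abort("Weights must sum to a positive value.")
  sum(weights * values) / sw
}

# CWM of one resampled null module for a named trait vector
resampled_cwm <- function(events, trait_values) {
  w <- tapply(events$weight, events$consumer, sum)
  cwm(trait_values[names(w)], as.numeric(w))
}

#' Chi-square test of category representation
#'
#' Compares observed category counts within a module (habitat types of its
#' community samples, prey categories of its prey, or categorical trait
#' levels of its consumers) against expected proportions taken from the
#' whole network, via a Pearson chi-square goodness-of-fit test with
#' `k - 1` degrees of freedom.
#'
#' @param observed_counts Named non-negative counts per category.
#' @param expected_proportions Named proportions summing to 1, covering the
#'   categories of `observed_counts`.
#' @return A tibble with `statistic`, `df`, `p_value`, `n`.
#' @export
categorical_composition_test <- function(observed_counts, expected_proportions) {
  if (!is.null(names(observed_counts)) && !is.null(names(expected_proportions))) {
    expected_proportions <- expected_proportions[names(observed_counts)]
  }
  o <- as.numeric(observed_counts)
  p <- as.numeric(expected_proportions)
  if (anyNA(p)) abort("Expected proportions missing for some observed categories.")
  if (abs(sum(p) - 1) > 1e-8) abort("Expected proportions must sum to 1.")
  if (sum(o) <= 0) abort("Observed counts must sum to > 0.")
  if (any(p == 0 & o > 0)) {
    abort("Category with expected proportion 0 but positive observed count; merge categories first.")
  }
  n <- sum(o)
  e <- p * n
  keep <- e > 0
  stat <- sum((o[keep] - e[keep])^2 / e[keep])
  df <- length(o) - 1
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE), n = n)
}
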