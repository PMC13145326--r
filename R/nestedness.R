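#' Weighted nestedness (WNODA)
#'
#' Weighted Nestedness based on Overlap and Decreasing Abundance, ranging
#' from 0 (perfectly non-nested) to 100 (perfectly nested). For every pair
#' of nodes on the same side, ordered by marginal total (larger first), the
#' pair score is the percentage of the smaller-total node's nonzero cells
#' whose value is strictly lower than the corresponding cell of the
#' larger-total node, that corresponding cell being nonzero. Pairs with
#' equal marginal totals score 0 (the decreasing-abundance requirement), as
#' do cell comparisons with equal values. The index is the mean pair score
#' over all row pairs and column pairs jointly.
#'
#' The index is invariant to row/column permutation and to multiplying all
#' cells by a positive constant (comparisons are ordinal), and equals the
#' value on the transposed matrix.
#'
#' @param m A [weighted_matrix()] (or plain labelled matrix) with at least
#'   two rows or two columns.
#' @return A number in \[0, 100\].
#' @examples
#' stair <- matrix(c(4, 3, 2, 1, 3, 2, 1, 0, 2, 1, 0, 0, 1, 0, 0, 0), 4, 4,
#'   byrow = TRUE, dimnames = list(paste0("r", 1:4), paste0("c", 1:4)))
#' wnoda(stair)  # 100
#' @export
wnoda <- function(m) {
  a <- unclass(m)
  if (nrow(a) < 2 && ncol(a) < 2) {
    abort("WNODA is undefined for a single-row, single-column matrix.")
  }
  rows <- wnoda_pair_scores(a)
  cols <- wnoda_pair_scores(t(a))
  scores <- c(rows, cols)
  if (length(scores) == 0) return(NaN)
  mean(scores)
}

# per-pair nestedness scores across all row pairs of `a`
# vectorized over columns: for each column accumulate, for every ordered
# pair (u dominant, v subordinate), whether a[v,j] in (0, a[u,j])
wnoda_pair_scores <- function(a) {
  n <- nrow(a)
  if (n < 2) return(numeric(0))
  tot <- rowSums(a)
  nz <- rowSums(a > 0)
  hits <- matrix(0, n, n)  # hits[u, v]: count of v's cells nested under u
  for (j in seq_len(ncol(a))) {
    x <- a[, j]
    hits <- hits + (outer(x, x, ">") & outer(rep(TRUE, n), x > 0))
  }
  # score[u, v] applies when u strictly dominates v by marginal total;
  # equal-total pairs contribute 0 through the strict inequality
  frac <- 100 * sweep(hits, 2, pmax(nz, 1), "/")
  p <- frac * outer(tot, tot, ">")
  (p + t(p))[upper.tri(p)]
}

#' WNODA restricted to same-module areas
#'
#' Computes WNODA over matrix areas where both nodes of a pair belong to the
#' same module, restricting cell comparisons to the module's own
#' resource-by-consumer block. A high same-module WNODA together with high
#' modularity indicates a compound topology: a modular network whose modules
#' are internally nested. Modules are aggregated weighted by their number of
#' contributing pairs (primary) and as a simple module mean (secondary).
#'
#' @param m A [weighted_matrix()].
#' @param p A [module_partition()] covering `m`.
#' @return A list with `wnoda_sm` (pair-weighted), `module_mean`,
#'   `per_module` (tibble: `module`, `wnoda`, `n_pairs`) and `n_pairs_used`.
#' @export
wnoda_sm <- function(m, p) {
  v <- partition_vectors(m, p)
  a <- unclass(m)
  mods <- sort(unique(c(v$zr, v$zc)))
  per <- purrr::map_dfr(mods, function(s) {
    sub <- a[v$zr == s, v$zc == s, drop = FALSE]
    if ((nrow(sub) < 2 && ncol(sub) < 2) || sum(sub) == 0) {
      return(tibble::tibble(module = s, wnoda = NA_real_, n_pairs = 0L))
    }
    scores <- c(wnoda_pair_scores(sub), wnoda_pair_scores(t(sub)))
    tibble::tibble(module = s, wnoda = mean(scores), n_pairs = length(scores))
  })
  used <- per[per$n_pairs > 0, ]
  if (nrow(used) == 0) {
    abort("No module has more than one node on either side; same-module WNODA undefined.")
  }
  list(
    wnoda_sm = sum(used$wnoda * used$n_pairs) / sum(used$n_pairs),
    module_mean = mean(used$wnoda),
    per_module = per,
    n_pairs_used = sum(used$n_pairs)
  )
}

#' WNODA of one module's submatrix
#'
#' Extracts the block of a module's resources by its consumers and computes
#' [wnoda()] on it. Modules with one consumer or fewer are skipped with an
#' `NA` marker, matching the convention of comparing nestedness only for
#' modules with more than one predator species.
#'
#' @inheritParams wnoda_sm
#' @param module_id Integer module id.
#' @return WNODA of the submatrix, or `NA` for modules with <= 1 consumer.
#' @export
module_wnoda <- function(m, p, module_id) {
  v <- partition_vectors(m, p)
  sub <- unclass(m)[v$zr == module_id, v$zc == module_id, drop = FALSE]
  if (ncol(sub) <= 1) return(NA_real_)
  if (nrow(sub) < 2 && ncol(sub) < 2) return(NA_real_)
  if (sum(sub) == 0) return(NA_real_)
  wnoda(sub)
}
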