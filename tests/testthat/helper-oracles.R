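# Independent oracles and small fixture builders. These deliberately use
# direct enumeration / naive loops, separate from the package's vectorized
# or compiled code paths.

# all set partitions of n items as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive-search maximum modularity over every partition of the nodes
exhaustive_best_q <- function(m, objective = "bipartite") {
  nodes <- c(rownames(m), colnames(m))
  sides <- rep(c("rows", "cols"), c(nrow(m), ncol(m)))
  best <- -Inf
  for (z in all_partitions(length(nodes))) {
    p <- tibble::tibble(node = nodes, side = sides, module = z)
    q <- if (objective == "bipartite") bipartite_weighted_q(m, p)
      else directed_weighted_q(m, p)
    if (q > best) best <- q
  }
  best
}

# naive cell-by-cell modularity sum (oracle for bipartite_weighted_q)
naive_bipartite_q <- function(a, zr, zc) {
  W <- sum(a)
  r <- rowSums(a)
  cc <- colSums(a)
  q <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (zr[i] == zc[j]) q <- q + a[i, j] - r[i] * cc[j] / W
    }
  }
  unname(q) / W
}

# independent pair-enumeration WNODA oracle: explicit double loop over
# same-side pairs, explicit per-cell comparisons
oracle_wnoda <- function(a) {
  score_pairs <- function(mat) {
    tot <- rowSums(mat)
    out <- c()
    n <- nrow(mat)
    for (u in seq_len(n - 1)) {
      for (v in (u + 1):n) {
        if (tot[u] == tot[v]) {
          out <- c(out, 0)
          next
        }
        dom <- if (tot[u] > tot[v]) u else v
        sub <- u + v - dom
        nz <- which(mat[sub, ] > 0)
        if (length(nz) == 0) {
          out <- c(out, 0)
          next
        }
        hit <- 0
        for (j in nz) {
          if (mat[dom, j] > 0 && mat[sub, j] < mat[dom, j]) hit <- hit + 1
        }
        out <- c(out, 100 * hit / length(nz))
      }
    }
    out
  }
  rowp <- if (nrow(a) >= 2) score_pairs(a) else c()
  colp <- if (ncol(a) >= 2) score_pairs(t(a)) else c()
  mean(c(rowp, colp))
}

# hand-coded Gower distance for mixed trait data frames
oracle_gower <- function(df) {
  traits <- setdiff(names(df), "consumer")
  n <- nrow(df)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (tr in traits) {
        col <- df[[tr]]
        if (is.numeric(col)) {
          acc <- acc + abs(col[i] - col[j]) / diff(range(col))
        } else {
          acc <- acc + as.numeric(col[i] != col[j])
        }
      }
      d[i, j] <- acc / length(traits)
    }
  }
  dimnames(d) <- list(df$consumer, df$consumer)
  d
}

# random valid count matrix with no empty rows or columns
random_count_matrix <- function(nr, nc, max_w = 5, kind = "occurrence") {
  repeat {
    a <- matrix(sample(0:max_w, nr * nc, replace = TRUE), nr, nc,
                dimnames = list(paste0("r", seq_len(nr)), paste0("c", seq_len(nc))))
    if (all(rowSums(a) > 0) && all(colSums(a) > 0)) break
  }
  weighted_matrix(a, kind = kind)
}

staircase_matrix <- function() {
  matrix(c(4, 3, 2, 1,
           3, 2, 1, 0,
           2, 1, 0, 0,
           1, 0, 0, 0), 4, 4, byrow = TRUE,
         dimnames = list(paste0("r", 1:4), paste0("c", 1:4)))
}

two_block_matrix <- function() {
  weighted_matrix(rbind(
    s1 = c(a = 3, b = 2, c = 0, d = 0),
    s2 = c(a = 2, b = 3, c = 0, d = 0),
    s3 = c(a = 0, b = 0, c = 3, d = 2),
    s4 = c(a = 0, b = 0, c = 2, d = 3)), kind = "foodweb")
}

# strip weighted_matrix attributes down to a plain numeric matrix
bare <- function(m) {
  a <- unclass(m)
  matrix(as.numeric(a), nrow(a), ncol(a), dimnames = dimnames(a))
}

# partition helper: assignment tibble from plain module vectors
make_partition <- function(m, zr, zc) {
  tibble::tibble(
    node = c(rownames(m), colnames(m)),
    side = rep(c("rows", "cols"), c(nrow(m), ncol(m))),
    module = c(zr, zc)
  )
}

# random data-independent partition with k modules on both sides
random_partition <- function(m, k) {
  module_partition(make_partition(
    m,
    sample(rep_len(seq_len(k), nrow(m))),
    sample(rep_len(seq_len(k), ncol(m)))), m)
}
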