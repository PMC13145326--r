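#' Weighted interaction matrices
#'
#' `weighted_matrix()` wraps a labelled non-negative matrix as the single data
#' carrier used throughout the package. Rows are resource nodes (community
#' samples in an occurrence network, prey items in a food web), columns are
#' consumer nodes (predator species or stages), and cells hold interaction
#' counts: individuals per community sample, or prey occurrences in stomachs.
#'
#' All-zero rows or columns are rejected by default because they carry no
#' interaction events and make degree-probabilistic null models degenerate;
#' `drop_empty = TRUE` removes them with a warning instead. Non-integer
#' weights are accepted but flagged, since the null models redistribute
#' integer interaction events.
#'
#' @param x A numeric matrix with row and column names, or a data frame in
#'   edge-list form with columns `row_label`, `col_label`, `weight` (absent
#'   pairs become 0).
#' @param kind Either `"occurrence"` (community x predator) or `"foodweb"`
#'   (prey x predator).
#' @param drop_empty Drop all-zero rows/columns with a warning instead of
#'   erroring.
#' @return A `weighted_matrix`: the validated matrix with attributes `kind`
#'   and class.
#' @examples
#' m <- weighted_matrix(matrix(c(2, 1, 0, 3), 2, 2,
#'   dimnames = list(c("p1", "p2"), c("c1", "c2"))), kind = "foodweb")
#' total_weight(m)
#' @export
weighted_matrix <- function(x, kind = c("occurrence", "foodweb"),
                            drop_empty = FALSE) {
  kind <- match.arg(kind)
  if (is.data.frame(x)) {
    x <- pivot_edge_list(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix or an edge-list data frame.")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("`x` must have row and column labels.")
  }
  if (anyDuplicated(rownames(x))) {
    abort(paste0("Duplicate row labels: ",
                 paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(x))) {
    abort(paste0("Duplicate column labels: ",
                 paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", ")))
  }
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Cell [%s, %s] is negative or non-finite (value %s).",
      rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]], format(x[bad[1, , drop = FALSE]])
    ))
  }
  empty_r <- rowSums(x) == 0
  empty_c <- colSums(x) == 0
  if (any(empty_r) || any(empty_c)) {
    if (drop_empty) {
      warn(sprintf("Dropping %d all-zero rows and %d all-zero columns.",
                   sum(empty_r), sum(empty_c)))
      x <- x[!empty_r, !empty_c, drop = FALSE]
    } else {
      abort(paste0(
        "All-zero rows/columns carry no interactions: ",
        paste(c(rownames(x)[empty_r], colnames(x)[empty_c]), collapse = ", "),
        ". Use drop_empty = TRUE to remove them."
      ))
    }
  }
  if (sum(x) <= 0) abort("Matrix must contain at least one positive cell.")
  if (any(x != round(x))) {
    warn("Non-integer cell weights: null models treat cells as integer interaction events.")
  }
  structure(x, kind = kind, class = c("weighted_matrix", "matrix", "array"))
}

pivot_edge_list <- function(df) {
  need <- c("row_label", "col_label", "weight")
  if (!all(need %in% names(df))) {
    abort("Edge list needs columns row_label, col_label, weight.")
  }
  w <- suppressWarnings(as.numeric(df$weight))
  if (anyNA(w)) {
    i <- which(is.na(w))[1]
    abort(sprintf("Non-numeric weight for edge (%s, %s): '%s'.",
                  df$row_label[i], df$col_label[i], as.character(df$weight[i])))
  }
  rows <- unique(as.character(df$row_label))
  cols <- unique(as.character(df$col_label))
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  for (i in seq_len(nrow(df))) {
    m[as.character(df$row_label[i]), as.character(df$col_label[i])] <-
      m[as.character(df$row_label[i]), as.character(df$col_label[i])] + w[i]
  }
  m
}

#' @export
print.weighted_matrix <- function(x, ...) {
  cat(sprintf("<weighted_matrix [%s]> %d resources x %d consumers, W = %s, %d links\n",
              attr(x, "kind"), nrow(x), ncol(x), format(sum(x)), sum(x > 0)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  if (nrow(x) > 6 || ncol(x) > 6) cat("...\n")
  invisible(x)
}

#' Read a weighted matrix from TSV
#'
#' Two plain-text layouts are supported: `matrix_tsv` (first row = consumer
#' labels, first column = resource labels) and `edge_list_tsv` (header
#' `row_label`, `col_label`, `weight`; absent pairs are 0).
#'
#' @param path Path to a UTF-8 TSV file.
#' @param format `"matrix_tsv"` or `"edge_list_tsv"`.
#' @inheritParams weighted_matrix
#' @return A validated [weighted_matrix()].
#' @export
read_weighted_matrix <- function(path, format = c("matrix_tsv", "edge_list_tsv"),
                                 kind = c("occurrence", "foodweb"),
                                 drop_empty = FALSE) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "matrix_tsv") {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    lab <- df[[1]]
    vals <- as.data.frame(df[, -1, drop = FALSE])
    num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
    if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals), dimnames = list(NULL, names(vals)))
    if (anyNA(num)) {
      idx <- which(is.na(num), arr.ind = TRUE)[1, ]
      abort(sprintf("Non-numeric cell at row '%s', column '%s': '%s'.",
                    lab[idx[1]], colnames(num)[idx[2]], vals[idx[1], idx[2]]))
    }
    rownames(num) <- lab
    weighted_matrix(num, kind = kind, drop_empty = drop_empty)
  } else {
    df <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
    weighted_matrix(as.data.frame(df), kind = kind, drop_empty = drop_empty)
  }
}

#' Write a weighted matrix to TSV
#'
#' @param m A [weighted_matrix()].
#' @param path Output path.
#' @param format `"matrix_tsv"` or `"edge_list_tsv"` (nonzero cells only).
#' @return `path`, invisibly.
#' @export
write_weighted_matrix <- function(m, path, format = c("matrix_tsv", "edge_list_tsv")) {
  format <- match.arg(format)
  if (format == "matrix_tsv") {
    df <- tibble::as_tibble(as.data.frame(unclass(m)), rownames = "label")
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    idx <- which(m > 0, arr.ind = TRUE)
    df <- tibble::tibble(
      row_label = rownames(m)[idx[, 1]],
      col_label = colnames(m)[idx[, 2]],
      weight = m[idx]
    )
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Degrees and marginal totals
#'
#' `node_degree()` counts strictly positive cells per node: for a consumer,
#' the number of communities it occupies (occurrence network) or prey items
#' it consumes (food web). `marginal_totals()` sums the interaction weight
#' per node; over either side the totals sum to the total weight W.
#'
#' @param m A [weighted_matrix()].
#' @param side `"rows"` (resources) or `"cols"` (consumers).
#' @return A tibble with columns `node` and `degree` (or `total`).
#' @export
node_degree <- function(m, side = c("rows", "cols")) {
  side <- match.arg(side)
  a <- unclass(m) > 0
  v <- if (side == "rows") rowSums(a) else colSums(a)
  tibble::tibble(node = names(v), degree = as.integer(v))
}

#' @rdname node_degree
#' @export
marginal_totals <- function(m, side = c("rows", "cols")) {
  side <- match.arg(side)
  v <- if (side == "rows") rowSums(unclass(m)) else colSums(unclass(m))
  tibble::tibble(node = names(v), total = as.numeric(v))
}

#' @rdname node_degree
#' @export
total_weight <- function(m) sum(unclass(m))

#' Node metadata table
#'
#' Validates a category label per node (habitat per community sample, prey
#' category per prey item) against the matrix side it annotates.
#'
#' @param df Data frame with columns `node` and `category`.
#' @param m A [weighted_matrix()] the metadata annotates.
#' @param side Which side of `m` the nodes belong to.
#' @return A tibble (`node`, `category`) covering every node on that side.
#' @export
node_metadata <- function(df, m, side = c("rows", "cols")) {
  side <- match.arg(side)
  labels <- if (side == "rows") rownames(m) else colnames(m)
  df <- tibble::as_tibble(df)
  if (!all(c("node", "category") %in% names(df))) {
    abort("Metadata needs columns `node` and `category`.")
  }
  if (anyDuplicated(df$node)) abort("Duplicate node labels in metadata.")
  missing <- setdiff(labels, df$node)
  if (length(missing) > 0) {
    abort(paste0("Metadata missing nodes: ", paste(head(missing, 5), collapse = ", ")))
  }
  df[match(labels, df$node), c("node", "category")]
}

as_integer_events <- function(m, tol = 1e-9) {
  # null models redistribute integer interaction events; rescale if needed
  a <- unclass(m)
  if (all(abs(a - round(a)) < tol)) {
    return(list(m = round(a), factor = 1))
  }
  for (f in 10^(1:6)) {
    if (all(abs(a * f - round(a * f)) < tol * f)) {
      warn(sprintf("Rescaling non-integer weights by %g to integer events.", f))
      return(list(m = round(a * f), factor = f))
    }
  }
  abort("Cell weights cannot be rescaled to integer interaction events.")
}
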