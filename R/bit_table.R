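#' @title Bit-table representation of a binary transaction database
#'
#' @description A bit-table is a 0/1 matrix with transactions as rows and
#' items as columns: entry (t, j) is 1 exactly when item j is present in
#' transaction t. All support counting in this package is integer arithmetic
#' on these tables (inner products and elementwise products), so results are
#' exact and need no floating-point tolerance.
#'
#' @param values matrix coercible to integer, every entry 0 or 1. A matrix
#'   with zero columns (or zero rows) is a legal, empty table.
#' @param row_ids integer vector of original transaction indices (1-based),
#'   strictly increasing, one per row. Defaults to `1:nrow(values)`.
#' @param item_labels character vector of item labels, one per column.
#'   Defaults to column names, or `"1","2",...` when absent.
#' @param level non-negative integer; 0 for an input table, k for a table
#'   whose columns encode k-itemsets.
#'
#' @return An object of class `bit_table`: a list with elements `values`
#'   (integer matrix), `row_ids`, `item_labels`, `level`.
#' @examples
#' B <- bit_table(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)),
#'                item_labels = c("A", "B", "C"))
#' column_support(B$values[, 1])
#' @export
bit_table <- function(values, row_ids = NULL, item_labels = NULL, level = 0L) {
  values <- as.matrix(values)
  if (length(values) > 0L && !all(values %in% c(0, 1))) {
    bad <- arrayInd(which(!(values %in% c(0, 1)))[1L], dim(values))
    stop(sprintf("bit_table: entry at row %d, column %d is not 0/1",
                 bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
  }
  storage.mode(values) <- "integer"
  if (is.null(row_ids)) row_ids <- seq_len(nrow(values))
  row_ids <- as.integer(row_ids)
  if (length(row_ids) != nrow(values)) {
    stop("bit_table: row_ids length must equal the number of rows",
         call. = FALSE)
  }
  if (length(row_ids) > 1L && any(diff(row_ids) <= 0L)) {
    stop("bit_table: row_ids must be strictly increasing", call. = FALSE)
  }
  if (is.null(item_labels)) {
    item_labels <- colnames(values)
    if (is.null(item_labels)) item_labels <- as.character(seq_len(ncol(values)))
  }
  item_labels <- as.character(item_labels)
  if (length(item_labels) != ncol(values)) {
    stop("bit_table: item_labels length must equal the number of columns",
         call. = FALSE)
  }
  dimnames(values) <- NULL
  structure(list(values = values, row_ids = row_ids,
                 item_labels = item_labels, level = as.integer(level)),
            class = "bit_table")
}

#' @export
print.bit_table <- function(x, ...) {
  cat(sprintf("bit_table: %d transactions x %d columns (level %d), %d ones\n",
              nrow(x$values), ncol(x$values), x$level, sum(x$values)))
  invisible(x)
}

#' @export
dim.bit_table <- function(x) dim(x$values)

as_bit_table <- function(x) {
  if (inherits(x, "bit_table")) x else bit_table(x)
}

#' Support of a single item column
#'
#' The support of an item is the number of transactions containing it,
#' computed as the inner product of the item's occurrence column with itself
#' (for a 0/1 vector this inner product equals the count of ones).
#'
#' @param b binary (0/1) vector.
#' @return Non-negative integer support count.
#' @export
column_support <- function(b) {
  b <- as.numeric(b)
  if (!all(b %in% c(0, 1))) {
    stop("column_support: input must contain only 0/1 entries", call. = FALSE)
  }
  as.integer(crossprod(b))
}

#' Pairwise co-occurrence supports of all columns of a bit-table
#'
#' Computes S = t(B) %*% B. Entry (i, j) counts the transactions in which
#' columns i and j are both 1, i.e. the support of the union of the two
#' itemsets the columns encode; the diagonal holds the per-column supports.
#' This single cross-product is how candidate supports are obtained without
#' rescanning the original database.
#'
#' @param B a [bit_table] (or 0/1 matrix).
#' @return Symmetric non-negative integer matrix, one row/column per column
#'   of `B`.
#' @export
pairwise_supports <- function(B) {
  B <- as_bit_table(B)
  S <- crossprod(B$values)
  storage.mode(S) <- "integer"
  S
}

#' Hadamard (elementwise) product of two binary columns
#'
#' On 0/1 columns the elementwise product is the logical AND: the result is
#' 1 exactly in the transactions containing both encoded itemsets. Candidate
#' columns for (k+1)-itemsets are built this way from level-k columns.
#'
#' @param b_i,b_j binary vectors of equal length.
#' @return Integer 0/1 vector.
#' @export
hadamard_column <- function(b_i, b_j) {
  if (length(b_i) != length(b_j)) {
    stop("hadamard_column: columns must have equal length", call. = FALSE)
  }
  if (!all(b_i %in% c(0, 1)) || !all(b_j %in% c(0, 1))) {
    stop("hadamard_column: inputs must contain only 0/1 entries",
         call. = FALSE)
  }
  as.integer(b_i) * as.integer(b_j)
}

#' Mining configuration
#'
#' @param minsupp minimum support: a positive integer (absolute transaction
#'   count) or, for convenience, a fraction in (0,1) which is converted to
#'   `ceiling(minsupp * n_transactions)` by [mine_frequent()].
#' @param min_items minimum itemset size reported by closed-set extraction
#'   (default 1, the most inclusive convention).
#' @param max_level optional cap on itemset size; mining stops after this
#'   level.
#' @param subset_filter discard candidates with an infrequent (k-1)-subset
#'   before support counting (a pure optimization; never changes output).
#' @param delete_zero_rows drop transactions whose row sum becomes zero as
#'   levels progress (a pure optimization; never changes supports).
#' @param max_cells memory guard: a level that would materialize more than
#'   this many dense candidate-column cells aborts with an error instead of
#'   exhausting memory.
#' @return An object of class `mining_config`.
#' @export
mining_config <- function(minsupp, min_items = 1L, max_level = NULL,
                          subset_filter = TRUE, delete_zero_rows = TRUE,
                          max_cells = 5e6) {
  if (!is.numeric(minsupp) || length(minsupp) != 1L || minsupp <= 0) {
    stop("mining_config: minsupp must be a positive number", call. = FALSE)
  }
  if (minsupp >= 1) minsupp <- as.integer(minsupp)
  if (!is.numeric(min_items) || min_items < 1) {
    stop("mining_config: min_items must be >= 1", call. = FALSE)
  }
  if (!is.null(max_level) && max_level < 1) {
    stop("mining_config: max_level must be >= 1 when given", call. = FALSE)
  }
  structure(list(minsupp = minsupp, min_items = as.integer(min_items),
                 max_level = if (is.null(max_level)) NULL else
                   as.integer(max_level),
                 subset_filter = isTRUE(subset_filter),
                 delete_zero_rows = isTRUE(delete_zero_rows),
                 max_cells = max_cells),
            class = "mining_config")
}

# resolve a fractional minsupp against the level-0 transaction count
resolve_minsupp <- function(cfg, n_transactions) {
  if (cfg$minsupp < 1) cfg$minsupp <- as.integer(ceiling(cfg$minsupp *
                                                           n_transactions))
  if (cfg$minsupp < 1L) cfg$minsupp <- 1L
  cfg
}

# lexicographic order of the rows of an index-tuple matrix
order_tuples <- function(mat) {
  if (nrow(mat) <= 1L) return(seq_len(nrow(mat)))
  do.call(order, lapply(seq_len(ncol(mat)), function(j) mat[, j]))
}

tuple_keys <- function(mat) {
  if (nrow(mat) == 0L) return(character(0))
  if (ncol(mat) == 1L) return(as.character(mat[, 1L]))
  apply(mat, 1L, paste, collapse = " ")
}
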