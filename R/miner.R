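#' @name miner
#' @title Level-wise frequent itemset mining on the bit-table
#'
#' @description The miner walks the Apriori levels entirely with matrix
#' algebra. Level 1 keeps the columns of the input table whose column sum
#' reaches `minsupp`. At level k the candidate k-itemsets are formed by
#' joining pairs of frequent (k-1)-itemsets that share their first k-2
#' (lexicographically ordered) item indices; the candidate's occurrence
#' column is the Hadamard product of the two parent columns, and its support
#' is available without a database rescan as an entry of the cross-product
#' matrix S = t(B) %*% B of the previous level's table. Columns below
#' `minsupp` are erased, rows whose sum drops to zero are deleted, and an
#' index table records, for each surviving column, the original item indices
#' of the itemset it encodes.
NULL

new_level_result <- function(level, values, row_ids, index_table, supports) {
  structure(list(level = as.integer(level),
                 bit_table = structure(list(values = values,
                                            row_ids = as.integer(row_ids),
                                            item_labels = NULL,
                                            level = as.integer(level)),
                                       class = "bit_table"),
                 index_table = index_table,
                 supports = as.integer(supports)),
            class = "level_result")
}

#' @export
print.level_result <- function(x, ...) {
  cat(sprintf("level %d: %d itemsets over %d rows\n", x$level,
              ncol(x$bit_table$values), nrow(x$bit_table$values)))
  invisible(x)
}

drop_zero_rows <- function(values, row_ids) {
  if (nrow(values) == 0L || ncol(values) == 0L) {
    return(list(values = values[0L, , drop = FALSE], row_ids = integer(0)))
  }
  keep <- rowSums(values) > 0L
  list(values = values[keep, , drop = FALSE], row_ids = row_ids[keep])
}

#' Frequent single items (level 1)
#'
#' Erases the columns of the level-0 table whose support is below `minsupp`,
#' deletes rows left with all zeros, and records each surviving column's
#' original item index in the level-1 index table.
#'
#' @param B0 a level-0 [bit_table].
#' @param cfg a [mining_config].
#' @return A `level_result` with fields `level`, `bit_table`, `index_table`
#'   (one original item index per row) and `supports`.
#' @export
frequent_singletons <- function(B0, cfg) {
  B0 <- as_bit_table(B0)
  cfg <- resolve_minsupp(cfg, nrow(B0$values))
  supports <- if (ncol(B0$values) == 0L) integer(0) else
    as.integer(colSums(B0$values))
  keep <- which(supports >= cfg$minsupp)
  values <- B0$values[, keep, drop = FALSE]
  row_ids <- B0$row_ids
  if (cfg$delete_zero_rows) {
    z <- drop_zero_rows(values, row_ids)
    values <- z$values
    row_ids <- z$row_ids
  }
  new_level_result(1L, values, row_ids,
                   matrix(keep, ncol = 1L), supports[keep])
}

assert_sorted_index <- function(index_table) {
  n <- nrow(index_table)
  if (n <= 1L) return(invisible(TRUE))
  ord <- order_tuples(index_table)
  if (!identical(ord, seq_len(n))) {
    stop("join_candidates: index table is not lexicographically sorted",
         call. = FALSE)
  }
  invisible(TRUE)
}

# enumerate joinable pairs within prefix blocks; returns parent column
# indices (i, j) and the merged k-tuples
joinable_pairs <- function(index_table) {
  k1 <- ncol(index_table)           # parents are (k-1)-itemsets
  n <- nrow(index_table)
  if (n < 2L) {
    return(list(i = integer(0), j = integer(0),
                tuples = matrix(integer(0), 0L, k1 + 1L)))
  }
  prefix_key <- if (k1 == 1L) rep("", n) else
    tuple_keys(index_table[, -k1, drop = FALSE])
  blocks <- split(seq_len(n), factor(prefix_key, levels = unique(prefix_key)))
  ii <- integer(0); jj <- integer(0)
  for (blk in blocks) {
    nb <- length(blk)
    if (nb < 2L) next
    pi <- rep(seq_len(nb - 1L), times = (nb - 1L):1L)
    pj <- sequence((nb - 1L):1L) + pi
    ii <- c(ii, blk[pi])
    jj <- c(jj, blk[pj])
  }
  tuples <- cbind(index_table[ii, , drop = FALSE],
                  index_table[jj, k1])
  dimnames(tuples) <- NULL
  list(i = ii, j = jj, tuples = tuples)
}

# TRUE for candidates all of whose (k-1)-subsets are frequent. The two
# subsets obtained by dropping either of the last two items are the
# generating parents, so only drops at positions 1..k-2 are checked.
subset_filter_keep <- function(tuples, prev_keys) {
  k <- ncol(tuples)
  n <- nrow(tuples)
  if (n == 0L || k <= 2L) return(rep(TRUE, n))
  keep <- rep(TRUE, n)
  for (d in seq_len(k - 2L)) {
    sub <- tuples[, -d, drop = FALSE]
    keep <- keep & (tuple_keys(sub) %in% prev_keys)
  }
  keep
}

#' Candidate generation by prefix join
#'
#' Joins every pair of frequent (k-1)-itemsets that share their first k-2
#' item indices (pairs are only enumerated inside these prefix blocks, which
#' are contiguous because the index table is kept lexicographically sorted).
#' Each candidate's occurrence column is the Hadamard product of the two
#' parent columns. Candidates with an infrequent (k-1)-subset are discarded
#' before support counting when `subset_filter` is on.
#'
#' @param prev the `level_result` for level k-1.
#' @param subset_filter apply the downward-closure filter (default TRUE).
#' @return A `candidate_set`: list with `level`, `tuples` (candidate index
#'   tuples, one row each), `columns` (their occurrence columns) and
#'   `row_ids`.
#' @export
join_candidates <- function(prev, subset_filter = TRUE) {
  stopifnot(inherits(prev, "level_result"))
  assert_sorted_index(prev$index_table)
  jp <- joinable_pairs(prev$index_table)
  tuples <- jp$tuples
  ii <- jp$i; jj <- jp$j
  if (subset_filter && nrow(tuples) > 0L) {
    keep <- subset_filter_keep(tuples, tuple_keys(prev$index_table))
    tuples <- tuples[keep, , drop = FALSE]
    ii <- ii[keep]; jj <- jj[keep]
  }
  V <- prev$bit_table$values
  columns <- V[, ii, drop = FALSE] * V[, jj, drop = FALSE]
  structure(list(level = prev$level + 1L, tuples = tuples,
                 columns = columns, row_ids = prev$bit_table$row_ids),
            class = "candidate_set")
}

#' Support pruning and row deletion
#'
#' Keeps candidate columns whose column sum reaches `minsupp`, deletes rows
#' whose sum across the kept columns is zero (they can support no larger
#' itemset), and sorts the surviving index tuples lexicographically.
#'
#' @param candidates a `candidate_set` from [join_candidates()].
#' @param cfg a [mining_config].
#' @return A `level_result` for level k (possibly with zero itemsets, which
#'   ends the mining loop).
#' @export
prune <- function(candidates, cfg) {
  stopifnot(inherits(candidates, "candidate_set"))
  supports <- if (ncol(candidates$columns) == 0L) integer(0) else
    as.integer(colSums(candidates$columns))
  keep <- which(supports >= cfg$minsupp)
  values <- candidates$columns[, keep, drop = FALSE]
  tuples <- candidates$tuples[keep, , drop = FALSE]
  supports <- supports[keep]
  ord <- order_tuples(tuples)
  values <- values[, ord, drop = FALSE]
  tuples <- tuples[ord, , drop = FALSE]
  supports <- supports[ord]
  row_ids <- candidates$row_ids
  if (cfg$delete_zero_rows) {
    z <- drop_zero_rows(values, row_ids)
    values <- z$values
    row_ids <- z$row_ids
  }
  new_level_result(candidates$level, values, row_ids, tuples, supports)
}

# Fused join+prune used by mine_frequent: candidate supports are read off
# the cross-product matrix S of the previous level, so occurrence columns
# are materialized only for candidates that are already known frequent.
# Output is identical to prune(join_candidates(prev), cfg); only the memory
# footprint differs.
next_level <- function(prev, cfg) {
  jp <- joinable_pairs(prev$index_table)
  tuples <- jp$tuples
  ii <- jp$i; jj <- jp$j
  if (cfg$subset_filter && nrow(tuples) > 0L) {
    keep <- subset_filter_keep(tuples, tuple_keys(prev$index_table))
    tuples <- tuples[keep, , drop = FALSE]
    ii <- ii[keep]; jj <- jj[keep]
  }
  if (nrow(tuples) == 0L) {
    return(new_level_result(prev$level + 1L,
                            prev$bit_table$values[0L, integer(0), drop = FALSE][
                              , integer(0), drop = FALSE],
                            integer(0),
                            matrix(integer(0), 0L, prev$level + 1L),
                            integer(0)))
  }
  S <- pairwise_supports(prev$bit_table)
  supports <- S[cbind(ii, jj)]
  freq <- which(supports >= cfg$minsupp)
  n_cells <- as.numeric(nrow(prev$bit_table$values)) * length(freq)
  if (n_cells > cfg$max_cells) {
    stop(sprintf(paste0(
      "mine_frequent: level %d would materialize %.3g candidate-column ",
      "cells, above the max_cells guard of %.3g; raise max_cells or ",
      "minsupp"), prev$level + 1L, n_cells, cfg$max_cells), call. = FALSE)
  }
  V <- prev$bit_table$values
  values <- V[, ii[freq], drop = FALSE] * V[, jj[freq], drop = FALSE]
  tuples <- tuples[freq, , drop = FALSE]
  supports <- supports[freq]
  ord <- order_tuples(tuples)
  values <- values[, ord, drop = FALSE]
  tuples <- tuples[ord, , drop = FALSE]
  supports <- as.integer(supports[ord])
  row_ids <- prev$bit_table$row_ids
  if (cfg$delete_zero_rows) {
    z <- drop_zero_rows(values, row_ids)
    values <- z$values
    row_ids <- z$row_ids
  }
  new_level_result(prev$level + 1L, values, row_ids, tuples, supports)
}

#' Mine all frequent itemsets
#'
#' Runs the level-wise loop: frequent singletons, then repeated prefix-join
#' candidate generation and support pruning, until a level is empty or
#' `max_level` is reached. The union of index tuples across the returned
#' levels is exactly the set of frequent itemsets of size >= 1; each carries
#' its exact support and, through its occurrence column and the preserved
#' row ids, its supporting-transaction set.
#'
#' @param B0 a level-0 [bit_table] (or 0/1 matrix).
#' @param cfg a [mining_config].
#' @return An object of class `bb_levels`: a list of `level_result`s with
#'   attributes `item_labels` and `n_transactions` taken from `B0`.
#' @examples
#' B <- bit_table(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)),
#'                item_labels = c("A", "B", "C"))
#' levels <- mine_frequent(B, mining_config(minsupp = 2))
#' frequent_itemsets(levels)
#' @export
mine_frequent <- function(B0, cfg) {
  B0 <- as_bit_table(B0)
  if (!inherits(cfg, "mining_config")) {
    stop("mine_frequent: cfg must be a mining_config", call. = FALSE)
  }
  cfg <- resolve_minsupp(cfg, nrow(B0$values))
  levels <- list()
  lev <- frequent_singletons(B0, cfg)
  while (ncol(lev$bit_table$values) > 0L) {
    levels[[lev$level]] <- lev
    if (!is.null(cfg$max_level) && lev$level >= cfg$max_level) break
    lev <- next_level(lev, cfg)
  }
  structure(levels, class = "bb_levels",
            item_labels = B0$item_labels,
            n_transactions = nrow(B0$values),
            minsupp = cfg$minsupp)
}

#' @export
print.bb_levels <- function(x, ...) {
  n <- vapply(x, function(l) ncol(l$bit_table$values), integer(1))
  cat(sprintf("frequent itemsets over %d levels: %s\n", length(x),
              paste(n, collapse = " + ")))
  invisible(x)
}

#' Flatten mining levels to a table of frequent itemsets
#'
#' @param levels a `bb_levels` object from [mine_frequent()].
#' @return data.frame with columns `size`, `support`, `items`
#'   (space-separated labels) and list-column `item_idx`, sorted by size
#'   then lexicographically.
#' @export
frequent_itemsets <- function(levels) {
  stopifnot(inherits(levels, "bb_levels"))
  labels <- attr(levels, "item_labels")
  rows <- lapply(levels, function(lev) {
    idx <- lapply(seq_len(nrow(lev$index_table)),
                  function(r) lev$index_table[r, ])
    data.frame(
      size = rep(lev$level, length(idx)),
      support = lev$supports,
      items = vapply(idx, function(ii) paste(labels[ii], collapse = " "),
                     character(1)),
      item_idx = I(idx),
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(size = integer(0), support = integer(0),
                      items = character(0), item_idx = I(list())))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
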