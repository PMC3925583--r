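#' @name closed
#' @title Frequent closed itemsets and inclusion-maximal biclusters
#'
#' @description A frequent itemset is closed when no proper superset has the
#' same support. Because support is anti-monotone, it suffices to compare
#' each k-itemset against its immediate (k+1)-supersets: if any proper
#' superset ties the support, some immediate superset does, and that
#' superset — having support >= minsupp — is itself in the frequent set, so
#' the check never needs to look outside the mined levels. Each closed
#' itemset corresponds one-to-one to an inclusion-maximal all-ones submatrix
#' (bicluster) of the input: its columns are the itemset and its rows are
#' all supporting transactions. Row-maximality is automatic (the row set is
#' ALL supporting rows); column-maximality is exactly closedness.
NULL

level_rows <- function(lev, j) {
  lev$bit_table$row_ids[lev$bit_table$values[, j] == 1L]
}

#' Extract the frequent closed itemsets from mined levels
#'
#' @param levels a `bb_levels` object from [mine_frequent()].
#' @param cfg the [mining_config] used for mining (supplies `min_items`).
#' @return data.frame with columns `size`, `support`, `items`
#'   (space-separated labels), and list-columns `item_idx` (original item
#'   indices) and `rows` (original supporting-transaction indices), sorted
#'   by size ascending then lexicographically.
#' @examples
#' B <- bit_table(rbind(c(1, 1, 0), c(1, 1, 0), c(1, 1, 1)),
#'                item_labels = c("A", "B", "C"))
#' cfg <- mining_config(minsupp = 2)
#' extract_closed(mine_frequent(B, cfg), cfg)   # only AB:3 is closed
#' @export
extract_closed <- function(levels, cfg) {
  stopifnot(inherits(levels, "bb_levels"))
  cfg <- resolve_minsupp(cfg, attr(levels, "n_transactions"))
  labels <- attr(levels, "item_labels")
  nlev <- length(levels)
  closed_flags <- lapply(levels, function(lev)
    rep(TRUE, nrow(lev$index_table)))
  for (k in seq_len(max(0L, nlev - 1L))) {
    lk <- levels[[k]]
    lk1 <- levels[[k + 1L]]
    if (nrow(lk1$index_table) == 0L) next
    keys_k <- tuple_keys(lk$index_table)
    # a k-itemset is non-closed iff some immediate frequent superset ties
    # its support; walk each (k+1)-itemset and mark its equal-support
    # k-subsets
    for (d in seq_len(k + 1L)) {
      sub_keys <- tuple_keys(lk1$index_table[, -d, drop = FALSE])
      hit <- match(sub_keys, keys_k)
      ok <- !is.na(hit) & lk$supports[hit] == lk1$supports
      closed_flags[[k]][hit[ok]] <- FALSE
    }
  }
  pieces <- lapply(seq_len(nlev), function(k) {
    lev <- levels[[k]]
    keep <- which(closed_flags[[k]])
    if (k < cfg$min_items) keep <- integer(0)
    idx <- lapply(keep, function(r) lev$index_table[r, ])
    data.frame(
      size = rep(k, length(keep)),
      support = lev$supports[keep],
      items = vapply(idx, function(ii) paste(labels[ii], collapse = " "),
                     character(1)),
      item_idx = I(idx),
      rows = I(lapply(keep, function(j) level_rows(lev, j))),
      stringsAsFactors = FALSE
    )
  })
  if (length(pieces) == 0L) {
    return(data.frame(size = integer(0), support = integer(0),
                      items = character(0), item_idx = I(list()),
                      rows = I(list())))
  }
  do.call(rbind, c(pieces, list(make.row.names = FALSE)))
}

resolve_items <- function(items, B0) {
  if (is.character(items)) {
    idx <- match(items, B0$item_labels)
    if (anyNA(idx)) {
      stop(sprintf("unknown item label(s): %s",
                   paste(items[is.na(idx)], collapse = " ")), call. = FALSE)
    }
    sort(idx)
  } else {
    idx <- sort(unique(as.integer(items)))
    if (length(idx) == 0L || any(idx < 1L) || any(idx > ncol(B0$values))) {
      stop("item indices out of range", call. = FALSE)
    }
    idx
  }
}

supporting_rows <- function(idx, B0) {
  which(rowSums(B0$values[, idx, drop = FALSE]) == length(idx))
}

#' Map a closed itemset to its inclusion-maximal bicluster
#'
#' @param J an itemset: integer item indices or character item labels, or a
#'   one-row slice of the [extract_closed()] output.
#' @param B0 the level-0 [bit_table] the itemset was mined from.
#' @return A `bicluster` (fields `rows`, `cols`, `labels`); `rows` are ALL
#'   transactions containing every item of `J`.
#' @export
itemset_to_bicluster <- function(J, B0) {
  B0 <- as_bit_table(B0)
  if (is.data.frame(J)) J <- J$item_idx[[1L]]
  if (is.list(J) && !is.null(J$items)) J <- J$items
  idx <- resolve_items(J, B0)
  rows <- supporting_rows(idx, B0)
  if (length(rows) == 0L) {
    stop("itemset_to_bicluster: itemset is supported by no transaction",
         call. = FALSE)
  }
  new_bicluster(B0$row_ids[rows], idx, B0$item_labels[idx])
}

#' Map every extracted closed itemset to its bicluster
#'
#' @param closed the data.frame returned by [extract_closed()].
#' @param B0 the level-0 [bit_table].
#' @return List of `bicluster` objects, in the order of `closed`.
#' @export
closed_to_biclusters <- function(closed, B0) {
  B0 <- as_bit_table(B0)
  lapply(closed$item_idx, itemset_to_bicluster, B0 = B0)
}

#' Independently verify that an itemset is closed
#'
#' Recomputes the itemset's support by a direct row scan of the level-0
#' table and tests every single-item extension for equal support. This
#' checker shares no state with the miner and is used to spot-check its
#' output.
#'
#' @param J itemset as integer item indices or character labels.
#' @param B0 the level-0 [bit_table].
#' @return TRUE iff no single-item extension of `J` has the same support.
#' @export
verify_closedness <- function(J, B0) {
  B0 <- as_bit_table(B0)
  idx <- resolve_items(J, B0)
  rows <- supporting_rows(idx, B0)
  others <- setdiff(seq_len(ncol(B0$values)), idx)
  if (length(others) == 0L) return(TRUE)
  ext <- colSums(B0$values[rows, others, drop = FALSE])
  all(ext < length(rows))
}

#' Mine the frequent closed itemsets of a binary matrix in one call
#'
#' Convenience wrapper: [mine_frequent()] then [extract_closed()], with
#' optional bicluster materialization.
#'
#' @param B0 a level-0 [bit_table] or 0/1 matrix.
#' @param minsupp minimum support (absolute count, or fraction in (0,1)
#'   converted by ceiling against the transaction count).
#' @param min_items minimum itemset size to report.
#' @param biclusters also return the bicluster view (default FALSE).
#' @param ... further arguments to [mining_config()].
#' @return list with elements `closed` (data.frame), `levels` (`bb_levels`)
#'   and, when requested, `biclusters`.
#' @examples
#' B <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
#' res <- mine_closed(B, minsupp = 2)
#' res$closed[, c("items", "support")]
#' @export
mine_closed <- function(B0, minsupp, min_items = 1L, biclusters = FALSE,
                        ...) {
  B0 <- as_bit_table(B0)
  cfg <- mining_config(minsupp = minsupp, min_items = min_items, ...)
  levels <- mine_frequent(B0, cfg)
  closed <- extract_closed(levels, cfg)
  out <- list(closed = closed, levels = levels)
  if (biclusters) out$biclusters <- closed_to_biclusters(closed, B0)
  out
}
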