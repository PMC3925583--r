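#' @name oracle
#' @title Brute-force reference enumerators
#'
#' @description Deliberately naive reference implementations that apply the
#' definitions of frequency, closedness and bicluster maximality literally,
#' by exhaustive enumeration over all item subsets. They exist to validate
#' the level-wise miner: on any instance small enough to enumerate, the
#' miner must reproduce their output exactly. The item count is capped at 24
#' so the 2^m subset enumeration stays tractable.
#'
#' Rows are encoded as item bitmasks and a subset's support is counted by a
#' full scan, so these functions share no code path with the bit-table
#' miner.
NULL

ORACLE_MAX_ITEMS <- 24L

row_bitmasks <- function(values) {
  m <- ncol(values)
  if (m == 0L) return(integer(nrow(values)))
  as.integer(values %*% bitwShiftL(1L, seq_len(m) - 1L))
}

mask_to_items <- function(mask, m) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
}

check_item_cap <- function(m) {
  if (m > ORACLE_MAX_ITEMS) {
    stop(sprintf(
      "oracle: %d items exceeds the brute-force cap of %d (2^m enumeration)",
      m, ORACLE_MAX_ITEMS), call. = FALSE)
  }
}

# supports of every non-empty item subset, indexed by bitmask 1..2^m-1
all_subset_supports <- function(values) {
  m <- ncol(values)
  rmask <- row_bitmasks(values)
  masks <- seq_len(2L^m - 1L)
  supports <- integer(length(masks))
  for (r in rmask) {
    supports <- supports + as.integer(bitwAnd(masks, r) == masks)
  }
  supports
}

itemset_frame <- function(masks, supports, m, item_labels) {
  sizes <- vapply(masks, function(x) length(mask_to_items(x, m)), integer(1))
  idx <- lapply(masks, mask_to_items, m = m)
  ord <- order_itemset_list(idx, sizes)
  data.frame(
    size = sizes[ord],
    support = supports[ord],
    items = vapply(idx[ord], function(ii)
      paste(item_labels[ii], collapse = " "), character(1)),
    item_idx = I(idx[ord]),
    stringsAsFactors = FALSE
  )
}

# order itemsets by (size ascending, lexicographic on index tuples)
order_itemset_list <- function(idx, sizes) {
  if (length(idx) == 0L) return(integer(0))
  maxlen <- max(sizes)
  pad <- t(vapply(idx, function(ii) c(ii, rep(0L, maxlen - length(ii))),
                  integer(maxlen)))
  if (maxlen == 1L) pad <- matrix(unlist(idx), ncol = 1L)
  do.call(order, c(list(sizes), lapply(seq_len(maxlen),
                                       function(j) pad[, j])))
}

#' @rdname oracle
#' @param B0 a level-0 [bit_table] (or 0/1 matrix) with at most 24 items.
#' @param cfg a [mining_config].
#' @return `enumerate_frequent_bruteforce` and `enumerate_closed_bruteforce`
#'   return a data.frame with columns `size`, `support`, `items`
#'   (space-separated labels) and list-column `item_idx`, sorted by size then
#'   lexicographically.
#' @export
enumerate_frequent_bruteforce <- function(B0, cfg) {
  B0 <- as_bit_table(B0)
  m <- ncol(B0$values)
  check_item_cap(m)
  cfg <- resolve_minsupp(cfg, nrow(B0$values))
  if (m == 0L) {
    return(itemset_frame(integer(0), integer(0), 0L, character(0)))
  }
  supports <- all_subset_supports(B0$values)
  keep <- which(supports >= cfg$minsupp)
  itemset_frame(keep, supports[keep], m, B0$item_labels)
}

#' @rdname oracle
#' @details `enumerate_closed_bruteforce` tests every proper superset (not
#'   only immediate ones) for equal support, applying the closedness
#'   definition verbatim.
#' @export
enumerate_closed_bruteforce <- function(B0, cfg) {
  B0 <- as_bit_table(B0)
  m <- ncol(B0$values)
  check_item_cap(m)
  cfg <- resolve_minsupp(cfg, nrow(B0$values))
  if (m == 0L) {
    return(itemset_frame(integer(0), integer(0), 0L, character(0)))
  }
  supports <- all_subset_supports(B0$values)
  freq <- which(supports >= cfg$minsupp)
  closed <- logical(length(freq))
  for (i in seq_along(freq)) {
    mk <- freq[i]
    same <- freq[supports[freq] == supports[mk]]
    proper_superset <- same[same != mk & bitwAnd(same, mk) == mk]
    closed[i] <- length(proper_superset) == 0L
  }
  keep <- freq[closed]
  out <- itemset_frame(keep, supports[keep], m, B0$item_labels)
  out[out$size >= cfg$min_items, , drop = FALSE]
}

#' @rdname oracle
#' @param min_rows,min_cols minimum number of rows/columns a bicluster must
#'   span to be reported.
#' @return `enumerate_maximal_biclusters_bruteforce` returns a list of
#'   `bicluster` objects (fields `rows`, `cols`, `labels`), each an
#'   inclusion-maximal all-ones submatrix.
#' @export
enumerate_maximal_biclusters_bruteforce <- function(B0, min_rows = 1L,
                                                    min_cols = 1L) {
  B0 <- as_bit_table(B0)
  m <- ncol(B0$values)
  check_item_cap(m)
  if (m == 0L || nrow(B0$values) == 0L) return(list())
  rmask <- row_bitmasks(B0$values)
  out <- list()
  for (mask in seq_len(2L^m - 1L)) {
    cols <- mask_to_items(mask, m)
    if (length(cols) < min_cols) next
    rows <- which(bitwAnd(rmask, mask) == mask)
    if (length(rows) < min_rows || length(rows) == 0L) next
    # column-maximality: no column outside `cols` is 1 on all of `rows`
    common <- Reduce(bitwAnd, rmask[rows])
    if (common != mask) next
    # row-maximality holds by construction: `rows` is ALL supporting rows
    out[[length(out) + 1L]] <- new_bicluster(B0$row_ids[rows], cols,
                                             B0$item_labels[cols])
  }
  if (length(out) == 0L) return(list())
  sizes <- vapply(out, function(b) length(b$cols), integer(1))
  idx <- lapply(out, `[[`, "cols")
  out[order_itemset_list(idx, sizes)]
}

new_bicluster <- function(rows, cols, labels) {
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 labels = as.character(labels)),
            class = "bicluster")
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("bicluster: %d rows x %d cols [%s]\n",
              length(x$rows), length(x$cols),
              paste(x$labels, collapse = " ")))
  invisible(x)
}
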