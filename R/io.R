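#' @name io
#' @title Readers and writers for transaction and binary-matrix formats
#'
#' @description Supported inputs: FIMI transaction files (one transaction of
#' whitespace-separated integer item labels per line — the community
#' standard for itemset mining), dense 0/1 CSV/TSV, and MatrixMarket sparse
#' coordinate files. Item labels are kept as given at I/O; internally items
#' are densely re-indexed in first-appearance order (the join rule needs a
#' total order) and the label map is retained for output. Transaction ids in
#' result files are 0-based positions in the input, while MatrixMarket
#' coordinates stay 1-based on disk, following each format's own
#' convention.
NULL

#' Read a FIMI transaction file
#'
#' @param path file path; each non-empty line is one transaction of
#'   whitespace-separated integer item labels. Empty lines are kept as empty
#'   transactions (they contribute no support). Duplicate items within a
#'   line are collapsed with a warning.
#' @return A `transaction_db`: list with `transactions` (list of integer
#'   label vectors, input order preserved) and `item_universe` (distinct
#'   labels in first-appearance order).
#' @export
read_transactions_fimi <- function(path) {
  lines <- readLines(path)
  dup_lines <- integer(0)
  transactions <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) {
      transactions[[i]] <- integer(0)
      next
    }
    vals <- suppressWarnings(as.integer(toks))
    if (anyNA(vals)) {
      stop(sprintf("read_transactions_fimi: non-integer token '%s' on line %d",
                   toks[which(is.na(vals))[1L]], i), call. = FALSE)
    }
    if (anyDuplicated(vals)) {
      dup_lines <- c(dup_lines, i)
      vals <- unique(vals)
    }
    transactions[[i]] <- vals
  }
  if (length(dup_lines) > 0L) {
    warning(sprintf(
      "read_transactions_fimi: duplicate items collapsed on line(s) %s",
      paste(dup_lines, collapse = ", ")), call. = FALSE)
  }
  universe <- unique(unlist(transactions))
  if (is.null(universe)) universe <- integer(0)
  structure(list(transactions = transactions, item_universe = universe),
            class = "transaction_db")
}

#' @export
print.transaction_db <- function(x, ...) {
  cat(sprintf("transaction_db: %d transactions over %d items\n",
              length(x$transactions), length(x$item_universe)))
  invisible(x)
}

#' Build the level-0 bit-table of a transaction database
#'
#' @param db a `transaction_db` from [read_transactions_fimi()].
#' @return A level-0 [bit_table]; columns follow `item_universe`
#'   (first-appearance) order and carry the original labels.
#' @export
transactions_to_bit_table <- function(db) {
  stopifnot(inherits(db, "transaction_db"))
  n <- length(db$transactions)
  m <- length(db$item_universe)
  values <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    values[i, match(db$transactions[[i]], db$item_universe)] <- 1L
  }
  bit_table(values, item_labels = as.character(db$item_universe))
}

#' Read a binary matrix as a level-0 bit-table
#'
#' @param path file path.
#' @param format `"csv"`, `"tsv"` (dense 0/1 text) or `"mtx"` (MatrixMarket
#'   sparse coordinate; stored entries must equal 1).
#' @param header for dense formats: first row holds item labels.
#' @param row_names for dense formats: first column holds transaction
#'   labels (stored in attribute `transaction_labels`).
#' @param transpose transpose after reading, so that what the file stores
#'   as columns becomes the transactions (e.g. a samples-as-rows file when
#'   genes should play the transaction role).
#' @return A level-0 [bit_table].
#' @export
read_binary_matrix <- function(path, format = c("csv", "tsv", "mtx"),
                               header = FALSE, row_names = FALSE,
                               transpose = FALSE) {
  format <- match.arg(format)
  if (format == "mtx") {
    M <- as.matrix(Matrix::readMM(path))
    if (length(M) > 0L && !all(M %in% c(0, 1))) {
      bad <- arrayInd(which(!(M %in% c(0, 1)))[1L], dim(M))
      stop(sprintf(
        "read_binary_matrix: entry at row %d, column %d is not 0/1",
        bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
    }
    labels <- NULL
    tlabels <- NULL
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = header, sep = sep,
                            row.names = if (row_names) 1L else NULL,
                            check.names = FALSE,
                            colClasses = if (row_names) NULL else "numeric")
    M <- as.matrix(df)
    labels <- if (header) colnames(df) else NULL
    tlabels <- if (row_names) rownames(df) else NULL
    if (length(M) > 0L && !all(M %in% c(0, 1))) {
      bad <- arrayInd(which(!(M %in% c(0, 1)))[1L], dim(M))
      stop(sprintf(
        "read_binary_matrix: entry at row %d, column %d is not 0/1",
        bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
    }
  }
  if (transpose) {
    M <- t(M)
    tmp <- labels; labels <- tlabels; tlabels <- tmp
  }
  dimnames(M) <- NULL      # unlabeled columns get positional labels
  B <- bit_table(M, item_labels = labels)
  attr(B, "transaction_labels") <- tlabels
  B
}

#' Write a bit-table to disk
#'
#' @param B a [bit_table].
#' @param path output path.
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @param header write the item labels as a header row (dense formats).
#' @return `path`, invisibly.
#' @export
write_binary_matrix <- function(B, path, format = c("csv", "tsv", "mtx"),
                                header = FALSE) {
  B <- as_bit_table(B)
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(B$values * 1, sparse = TRUE), path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    M <- B$values
    if (header) colnames(M) <- B$item_labels
    utils::write.table(M, path, sep = sep, row.names = FALSE,
                       col.names = header, quote = FALSE)
  }
  invisible(path)
}

#' Write closed itemsets (and optionally biclusters) to a results file
#'
#' One tab-separated line per itemset: the space-separated item labels, the
#' support count and — with `emit_rows` — the space-separated 0-based ids of
#' the supporting transactions. A JSON metadata sidecar (`<path>.meta.json`)
#' recording the input hash, thresholds, seed and package version is always
#' written, so two runs on the same input and configuration produce
#' byte-identical outputs.
#'
#' @param closed data.frame from [extract_closed()] (already sorted by its
#'   contract).
#' @param path output path for the tab-separated results.
#' @param emit_rows also emit supporting-transaction ids.
#' @param metadata named list merged into the sidecar (e.g. `input_hash`,
#'   `minsupp`, `min_items`, `seed`).
#' @return `path`, invisibly.
#' @export
write_results <- function(closed, path, emit_rows = FALSE,
                          metadata = list()) {
  lines <- character(nrow(closed))
  for (i in seq_len(nrow(closed))) {
    fields <- c(closed$items[i], closed$support[i])
    if (emit_rows) {
      fields <- c(fields, paste(closed$rows[[i]] - 1L, collapse = " "))
    }
    lines[i] <- paste(fields, collapse = "\t")
  }
  writeLines(lines, path)
  meta <- c(list(n_itemsets = nrow(closed),
                 emit_rows = emit_rows,
                 version = as.character(utils::packageVersion("bitbiclust"))),
            metadata)
  jsonlite::write_json(meta[order(names(meta))],
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Hash a file's contents (for the results metadata sidecar)
#'
#' @param path file path.
#' @return md5 hex digest string.
#' @export
input_hash <- function(path) {
  as.character(tools::md5sum(path))
}
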