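#' @name binarization
#' @title Fold-change binarization of expression matrices
#'
#' @description Biclustering of expression data on a bit-table starts by
#' calling each gene expressed (1) or not (0) against a fold-change cutoff.
#' With `scale = "ratio"` the matrix holds (non-negative) expression ratios
#' and a value is called 1 when it reaches the cutoff (`mode = "up"`), or
#' when it reaches the cutoff in either direction, i.e. `>= cutoff` or
#' `<= 1/cutoff` (`mode = "abs"`). With `scale = "log2"` the matrix holds
#' log2 ratios and the thresholds become `>= log2(cutoff)` and
#' `|x| >= log2(cutoff)` respectively. The default — ratio scale, up-calls,
#' cutoff 2 — is the common twofold-change convention; `mode = "abs"` is
#' offered because "twofold change" plausibly includes down-regulation, and
#' the choice is explicit rather than silent.
NULL

#' Read a genes-by-samples expression matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path file path.
#' @param sep field separator; `","` for CSV (default), `"\t"` for TSV.
#' @return Numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_expression <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  as.matrix(df)
}

#' Binarize an expression matrix into a level-0 bit-table
#'
#' @param X numeric matrix (genes x samples; `NA` entries allowed) or an
#'   object coercible to one.
#' @param cutoff positive fold-change cutoff (default 2, i.e. twofold).
#' @param mode `"up"` calls up-regulation only; `"abs"` calls both
#'   directions.
#' @param scale `"ratio"` for expression ratios (all values must be
#'   non-negative), `"log2"` for log2 ratios.
#' @param transpose treat samples as transactions instead of genes
#'   (transposes before building the table).
#' @return A level-0 [bit_table]; genes are the transactions and samples the
#'   items unless `transpose`. Missing entries become 0 and their count is
#'   reported in a warning.
#' @examples
#' X <- matrix(c(2.5, 1.2, 0.4, 8), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' binarize(X, cutoff = 2, mode = "abs")$values
#' @export
binarize <- function(X, cutoff = 2, mode = c("up", "abs"),
                     scale = c("ratio", "log2"), transpose = FALSE) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("binarize: cutoff must be a positive number", call. = FALSE)
  }
  X <- as.matrix(X)
  if (transpose) X <- t(X)
  if (scale == "ratio" && any(X < 0, na.rm = TRUE)) {
    stop("binarize: ratio-scale input must be non-negative; use scale = \"log2\" for log ratios",
         call. = FALSE)
  }
  n_missing <- sum(is.na(X))
  if (scale == "ratio") {
    bits <- if (mode == "up") X >= cutoff else X >= cutoff | X <= 1 / cutoff
  } else {
    thr <- log2(cutoff)
    bits <- if (mode == "up") X >= thr else abs(X) >= thr
  }
  bits[is.na(bits)] <- FALSE
  if (n_missing > 0L) {
    warning(sprintf("binarize: %d missing entries set to 0", n_missing),
            call. = FALSE)
  }
  values <- matrix(as.integer(bits), nrow(X), ncol(X))
  labels <- colnames(X)
  if (is.null(labels)) labels <- as.character(seq_len(ncol(X)))
  B <- bit_table(values, item_labels = labels)
  attr(B, "transaction_labels") <- rownames(X)
  B
}
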