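#' @name synthio
#' @title Seeded synthetic binary matrices with optional planted biclusters
#'
#' @description Generators for the two synthetic regimes used throughout the
#' tests: uniform-density random bit-tables (every entry independently 1
#' with a given probability), and matrices with implanted all-ones blocks
#' (planted biclusters) optionally degraded by entry-wise dropout noise.
#' Every generator is seed-addressable: the same seed and arguments yield a
#' bitwise-identical matrix on any platform (Mersenne-Twister with inversion
#' sampling, fixed explicitly), so every downstream number in this package
#' is reproducible even though no canonical "random 1000 x 1000 matrix"
#' exists.
NULL

# run `expr` under a fixed, fully specified RNG state, restoring the
# caller's state afterwards; seed = NULL uses the ambient stream
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  old_kind <- RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  set.seed(as.integer(seed))
  on.exit({
    do.call(RNGkind, as.list(old_kind))
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

#' Uniform-density random bit-table
#'
#' @param n_rows,n_cols positive matrix dimensions.
#' @param density probability in \[0, 1\] that an entry is 1.
#' @param seed integer seed; `NULL` draws from the ambient RNG stream.
#' @return A level-0 [bit_table] with attribute `realized_density`, the
#'   achieved ones-fraction.
#' @examples
#' B <- random_binary(50, 50, density = 0.1, seed = 1)
#' attr(B, "realized_density")
#' @export
random_binary <- function(n_rows, n_cols, density, seed = NULL) {
  if (n_rows < 1L || n_cols < 1L) {
    stop("random_binary: dimensions must be positive", call. = FALSE)
  }
  if (!is.numeric(density) || density < 0 || density > 1) {
    stop("random_binary: density must be in [0, 1]", call. = FALSE)
  }
  values <- with_rng(seed, {
    matrix(as.integer(stats::runif(n_rows * n_cols) < density),
           n_rows, n_cols)
  })
  B <- bit_table(values)
  attr(B, "realized_density") <- mean(values)
  B
}

#' Implant all-ones blocks (planted biclusters) into a bit-table
#'
#' Sets each block's submatrix to 1, then flips each block entry back to 0
#' independently with probability `noise`. Blocks may overlap. With
#' `noise = 0` on a zero base, mining at thresholds matching a block's
#' dimensions recovers exactly the implanted column sets.
#'
#' @param base a [bit_table] (or 0/1 matrix) to implant into.
#' @param blocks list of blocks, each a `list(rows =, cols =)` of row and
#'   column index vectors within the matrix bounds.
#' @param noise per-entry dropout probability in \[0, 1\].
#' @param seed integer seed for the dropout draws.
#' @return A [bit_table] with the blocks implanted.
#' @examples
#' base <- bit_table(matrix(0L, 10, 10))
#' B <- implant_blocks(base, list(list(rows = 1:3, cols = 4:6)))
#' sum(B$values)
#' @export
implant_blocks <- function(base, blocks, noise = 0, seed = NULL) {
  base <- as_bit_table(base)
  if (!is.numeric(noise) || noise < 0 || noise > 1) {
    stop("implant_blocks: noise must be in [0, 1]", call. = FALSE)
  }
  values <- base$values
  with_rng(seed, {
    for (blk in blocks) {
      ri <- as.integer(blk$rows)
      ci <- as.integer(blk$cols)
      if (length(ri) == 0L || length(ci) == 0L ||
          any(ri < 1L) || any(ri > nrow(values)) ||
          any(ci < 1L) || any(ci > ncol(values))) {
        stop("implant_blocks: block indices out of matrix bounds",
             call. = FALSE)
      }
      block <- matrix(1L, length(ri), length(ci))
      if (noise > 0) {
        drop <- matrix(stats::runif(length(block)) < noise,
                       length(ri), length(ci))
        block[drop] <- 0L
      }
      values[ri, ci] <- block
    }
  })
  bit_table(values, row_ids = base$row_ids, item_labels = base$item_labels,
            level = base$level)
}
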