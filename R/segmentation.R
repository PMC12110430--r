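#' Cut an index range into contiguous blocks
#'
#' Partitions the time indices `1..n` into `p = floor(n/m)` contiguous,
#' ordered blocks.  Every block except the first has length exactly `m`;
#' the first block absorbs the remainder `n - (p-1)*m`, so its length lies
#' in `[m, 2m)`.  Block boundaries sit at `n - (p - l)*m` counting from the
#' right, which is the bookkeeping the cumulative block design relies on.
#'
#' @param n series length (single positive integer).
#' @param m block length; must satisfy `1 <= m <= n/2` so that at least
#'   two full blocks exist.
#' @return An object of class `"block_plan"`: a list with elements `n`,
#'   `m`, `p` (number of blocks) and integer vectors `start`, `end` giving
#'   the 1-based inclusive range of each block.
#' @examples
#' cut_blocks(600, 25)  # 24 blocks of length 25
#' cut_blocks(10, 3)    # blocks {1..4}, {5..7}, {8..10}
#' @seealso [block_design()] for the design matrix built on a plan.
#' @export
cut_blocks <- function(n, m) {
  n <- as.integer(n)[1L]
  m <- as.integer(m)[1L]
  if (is.na(n) || is.na(m))
    stop("'n' and 'm' must be single finite integers")
  if (m < 1L)
    stop("invalid block length: 'm' must be at least 1")
  if (2L * m > n)
    stop("invalid block length: need at least two blocks, so m <= n/2 ",
         "(got m = ", m, ", n = ", n, ")")
  p <- n %/% m
  end <- n - (p - seq_len(p)) * m
  start <- c(1L, end[-p] + 1L)
  structure(list(n = n, m = m, p = p, start = as.integer(start),
                 end = as.integer(end)),
            class = "block_plan")
}

#' @export
print.block_plan <- function(x, ...) {
  cat("Block plan: n =", x$n, ", m =", x$m, ", p =", x$p, "blocks\n")
  cat("  first block length:", x$end[1L], "\n")
  invisible(x)
}

# block index of each time index i (vectorised)
block_of <- function(plan, i) findInterval(i, plan$start)

#' Cumulative block design matrix
#'
#' Expands an `n x q` regressor matrix into the `n x (p*q)` design on which
#' change-point detection becomes sparse variable selection.  The columns
#' for block `l` equal the original covariates with all rows *before*
#' block `l` set to zero, so a coefficient on block `l`'s columns is the
#' *increment* of the regression coefficient from block `l-1` to block `l`;
#' block 1's columns are the covariates themselves (the baseline
#' coefficient).  Summing the per-block coefficient vectors cumulatively
#' therefore recovers the per-segment regression coefficients.
#'
#' @param x numeric matrix of regressors (`n x q`), rows in time order.
#' @param plan a `"block_plan"` from [cut_blocks()] built for the same `n`.
#' @return An `n x (p*q)` numeric matrix with a `"colmap"` attribute: a
#'   data frame mapping every column to its `(block, covariate)` pair.
#' @examples
#' p <- cut_blocks(4, 2)
#' block_design(matrix(1:4), p)  # columns (1,2,3,4) and (0,0,3,4)
#' @export
block_design <- function(x, plan) {
  x <- as.matrix(x)
  if (!inherits(plan, "block_plan")) stop("'plan' must be a block_plan")
  n <- nrow(x)
  q <- ncol(x)
  if (n != plan$n)
    stop("dimension mismatch: plan built for n = ", plan$n,
         " but x has ", n, " rows")
  p <- plan$p
  Z <- matrix(0, n, p * q)
  for (l in seq_len(p)) {
    rows <- plan$start[l]:n
    Z[rows, ((l - 1L) * q + 1L):(l * q)] <- x[rows, , drop = FALSE]
  }
  colmap <- data.frame(column = seq_len(p * q),
                       block = rep(seq_len(p), each = q),
                       covariate = rep.int(seq_len(q), p))
  colnames(Z) <- paste0("b", colmap$block, ".x", colmap$covariate)
  attr(Z, "colmap") <- colmap
  Z
}

#' Lagged design for autoregressive modelling
#'
#' Builds the response/regressor pair for an AR(`order`) fit of a
#' univariate series: row `t` of the regressor matrix holds
#' `(y[t-1], ..., y[t-order])` and the response starts at `order + 1`, so
#' the effective sample size shrinks by `order`.
#'
#' @param y numeric vector (time order).
#' @param order autoregressive order, a positive integer.
#' @return List with components `y` (length `n - order`) and `x`
#'   (`(n - order) x order` matrix, columns `lag1..lagorder`).
#' @examples
#' ar_design(c(1, 2, 3, 4), 1)
#' @export
ar_design <- function(y, order) {
  y <- as.numeric(y)
  order <- as.integer(order)[1L]
  if (is.na(order) || order < 1L) stop("'order' must be a positive integer")
  n0 <- length(y)
  if (n0 <= order + 2L)
    stop("insufficient data: series of length ", n0,
         " cannot support lag order ", order)
  idx <- (order + 1L):n0
  x <- vapply(seq_len(order), function(k) y[idx - k], numeric(length(idx)))
  colnames(x) <- paste0("lag", seq_len(order))
  list(y = y[idx], x = x)
}
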