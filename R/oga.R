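# Orthogonal greedy selection along the block design, HDIC stopping rule,
# trimming, and the mapping from surviving columns to change-point windows.

# Mean-center the response and every column of the candidate matrix.
# Columns that are constant (zero after centering) are flagged unusable so
# the greedy criterion never divides by a zero norm.
center_cols <- function(y, Z) {
  yc <- y - mean(y)
  Zc <- sweep(Z, 2L, colMeans(Z), `-`)
  css <- colSums(Zc^2)
  usable <- css > 1e-20 * pmax(colSums(Z^2), 1)
  list(y = yc, Z = Zc, usable = usable)
}

# Relative floor for sigma^2 estimates: a perfect (zero-residual) fit is
# clamped here so that log(sigma^2) is constant across perfect fits and the
# model-dimension penalty decides between them deterministically.
sigma2_floor <- function(yc) {
  f <- 1e-12 * mean(yc^2)
  if (f <= 0) f <- .Machine$double.xmin
  f
}

# Exact least-squares residual sum of squares of y on Z[, J] (QR route).
# The empty set uses the convention "projection onto nothing is zero", so
# the RSS is just sum(y^2) (for centered y, n * mean(y^2)).
ls_rss <- function(y, Z, J) {
  if (length(J) == 0L) return(sum(y^2))
  f <- stats::.lm.fit(Z[, J, drop = FALSE], y)
  sum(f$residuals^2)
}

#' Orthogonal greedy selection path
#'
#' Forward stepwise selection on a (centered) candidate matrix: at each
#' step the column maximising `|z_j' r| / (sqrt(n) * ||z_j||)` over the
#' not-yet-selected columns is added (ties broken by lowest column index),
#' the column is orthogonalised against the previously selected ones
#' (modified Gram--Schmidt with one re-orthogonalisation pass), and the
#' residual is updated by projecting the orthonormalised column out.  The
#' recorded residual sums of squares equal, step by step, the exact
#' least-squares RSS on the raw selected columns, because the
#' orthonormalised basis spans the same space.
#'
#' Columns that become numerically collinear with the selected span are
#' dropped from candidacy instead of crashing the scan, so perfectly
#' duplicated relevant columns yield at most one survivor.
#'
#' @param y centered numeric response.
#' @param Z centered candidate matrix (columns are candidates).
#' @param Dn maximum number of greedy steps.
#' @param usable logical mask of admissible columns (e.g. the
#'   constant-column flags from centering); defaults to all columns.
#' @return List with `selected` (ordered distinct column indices), `rss`
#'   (residual sum of squares `||r^(d)||^2` after each step,
#'   non-increasing), `n` and `rn` (number of rows / candidate columns).
#' @export
oga_path <- function(y, Z, Dn, usable = rep(TRUE, ncol(Z))) {
  n <- length(y)
  rn <- ncol(Z)
  if (!any(usable))
    stop("no usable candidate columns (all constant or zero)")
  Dn <- min(as.integer(Dn), sum(usable), n - 1L)
  if (Dn < 1L) stop("'Dn' must allow at least one greedy step")
  znorm2 <- colSums(Z^2)
  r <- y
  Qb <- matrix(0, n, Dn)
  selected <- integer(Dn)
  rss <- numeric(Dn)
  avail <- usable
  d <- 0L
  while (d < Dn && any(avail)) {
    score <- abs(as.vector(crossprod(Z, r))) / sqrt(n * znorm2)
    score[!avail] <- -Inf
    v <- NULL
    repeat {
      j <- which.max(score)           # ties -> lowest index
      if (!is.finite(score[j])) break
      v <- Z[, j]
      if (d > 0L) {
        Qd <- Qb[, seq_len(d), drop = FALSE]
        v <- v - Qd %*% crossprod(Qd, v)
        v <- v - Qd %*% crossprod(Qd, v)   # re-orthogonalise
      }
      nv2 <- sum(v^2)
      if (nv2 > 1e-14 * znorm2[j]) break
      avail[j] <- FALSE                # collinear with selected span
      score[j] <- -Inf
      v <- NULL
    }
    if (is.null(v)) break
    d <- d + 1L
    Qb[, d] <- v / sqrt(nv2)
    r <- r - Qb[, d] * sum(Qb[, d] * r)
    selected[d] <- j
    rss[d] <- sum(r^2)
    avail[j] <- FALSE
  }
  if (d == 0L) stop("greedy selection could not add any column")
  list(selected = selected[seq_len(d)], rss = rss[seq_len(d)],
       n = n, rn = rn)
}

# HDIC(J_d) = log(sigma^2_d) + d * cn * log(rn) / n along the greedy path,
# with sigma^2_d = RSS_d / n clamped at `floor`.  Returns the argmin d.
hdic_argmin <- function(path, cn, floor) {
  n <- path$n
  sig2 <- pmax(path$rss / n, floor)
  hd <- log(sig2) + seq_along(sig2) * cn * log(path$rn) / n
  which.min(hd)
}

# Trim: keep column j_l of the HDIC-selected set iff deleting it strictly
# worsens HDIC.  All HDIC values here are recomputed by QR least squares on
# the raw columns so the leave-one-out comparisons are internally
# consistent.  A single-column selection is kept as is; an empty trim
# result falls back to the first selected column.
trim_selection <- function(y, Z, path, d_hat, cn, floor) {
  J <- path$selected[seq_len(d_hat)]
  if (d_hat == 1L) return(J)
  n <- path$n
  pen <- cn * log(path$rn) / n
  h_full <- log(max(ls_rss(y, Z, J) / n, floor)) + d_hat * pen
  keep <- vapply(seq_len(d_hat), function(l) {
    h_l <- log(max(ls_rss(y, Z, J[-l]) / n, floor)) + (d_hat - 1L) * pen
    h_l > h_full
  }, logical(1L))
  if (!any(keep)) return(J[1L])
  sort(J[keep])
}

# Map surviving columns to candidate change-point windows.
#
# A block enters the active set A if any of its q columns survived the
# trim.  Block 1 carries the baseline coefficient, so only blocks >= 2
# signal changes.  Maximal runs of consecutive active blocks are located;
# for each run the candidate block index is (last block of run) - 1, which
# places the true change point in the interior of the two-block window in
# both the boundary-change and interior-change signatures.  The window for
# candidate block k covers blocks k and k+1: indices
# {n - (p-k+1)m + 1, ..., n - (p-k-1)m}, always exactly 2m long.
select_segments <- function(J, colmap, plan) {
  blocks <- sort(unique(colmap$block[match(J, colmap$column)]))
  interior <- setdiff(blocks, 1L)
  if (length(interior) == 0L)
    return(list(A = blocks, k = integer(0), s = 0L,
                windows = matrix(integer(0), 0L, 2L,
                                 dimnames = list(NULL, c("start", "end")))))
  runs <- split(interior, cumsum(c(1L, diff(interior) != 1L)))
  k <- vapply(runs, max, integer(1L)) - 1L
  k <- sort(unique(pmin(pmax(k, 1L), plan$p - 1L)))
  n <- plan$n; m <- plan$m; p <- plan$p
  windows <- cbind(start = n - (p - k + 1L) * m + 1L,
                   end   = n - (p - k - 1L) * m)
  list(A = blocks, k = as.integer(k), s = length(k), windows = windows)
}
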