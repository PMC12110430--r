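# Sup-Wald refinement within a selected window and the full piecewise fit.

#' Sup-Wald change-point scan over a window
#'
#' For every admissible split `h` (the last pre-change index, scanned
#' strictly between `q` positions from either end of the window), the
#' response is regressed on `[X, Z_h]` where `Z_h` equals `X` with all
#' rows up to `h` zeroed.  The Wald statistic of the post-change increment
#' `delta_h` is `delta_h' (Z_h' M Z_h) delta_h` with
#' `M = I - X (X'X)^{-1} X'`; by partitioned regression this equals the
#' drop in residual sum of squares from adding `Z_h`, so the argmax over
#' `h` is the least-squares change-point location.  Ties are broken by the
#' smallest `h`.
#'
#' Rank deficiency is handled through pivoted QR: the projection onto the
#' window regressors uses their column space whatever its rank, and
#' increment components aliased with the retained columns at a given
#' split are set to zero (they carry no identifiable coefficient change),
#' so the statistic is always the RSS drop on the identified subspace.
#' A window whose regressors are identically zero cannot be scanned.
#'
#' @param yw numeric response over the window (length `2m`).
#' @param xw regressor matrix over the window (`2m x q`).
#' @param q number of regressors (defaults to `ncol(xw)`).
#' @return List with `h_grid` (admissible local split indices), `stat`
#'   (Wald profile) and `h_hat` (local argmax).
#' @examples
#' sup_wald(c(0, 0, 0, 0, 5, 5, 5, 5), matrix(1, 8, 1))$h_hat  # 4
#' @export
sup_wald <- function(yw, xw, q = ncol(xw)) {
  xw <- as.matrix(xw)
  nw <- nrow(xw)
  if (length(yw) != nw) stop("'yw' and 'xw' must have matching length")
  if (nw <= 2L * q + 2L)
    stop("window too short for a sup-Wald scan: need more than 2q + 2 rows")
  qx <- qr(xw)
  if (qx$rank == 0L)
    stop("window regressor matrix is zero; cannot scan")
  Q1 <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  Px <- tcrossprod(Q1)
  h_grid <- (q + 2L):(nw - q - 1L)
  stat <- rep(NA_real_, length(h_grid))
  for (i in seq_along(h_grid)) {
    h <- h_grid[i]
    Zh <- xw
    Zh[seq_len(h), ] <- 0
    fit <- stats::lm.fit(cbind(xw, Zh), yw)
    delta <- fit$coefficients[(q + 1L):(2L * q)]
    delta[is.na(delta)] <- 0               # aliased increment components
    ZMZ <- crossprod(Zh, Zh - Px %*% Zh)
    stat[i] <- drop(crossprod(delta, ZMZ %*% delta))
  }
  if (all(is.na(stat)))
    stop("sup-Wald scan failed at every admissible split")
  best <- which.max(replace(stat, is.na(stat), -Inf))
  list(h_grid = h_grid, stat = stat, h_hat = h_grid[best])
}

#' Piecewise linear regression at given change points
#'
#' Exact least squares of `y` on the stacked design
#' `[X, X * I(i > a_1), ..., X * I(i > a_s)]`: the first `q` coefficients
#' are the baseline regime, each following block of `q` is the coefficient
#' increment after a change point.  Residuals are re-centered to mean zero
#' within every estimated segment `{a_{j-1}+1, ..., a_j}` (with `a_0 = 0`,
#' `a_{s+1} = n`), which is the residual pool the bootstrap resamples.
#'
#' @param y numeric response (length `n`).
#' @param x regressor matrix (`n x q`).
#' @param a_hat strictly increasing integer change points, `0 < a < n`;
#'   may be empty (plain regression, globally centered residuals).
#' @return List with `beta1` (baseline coefficients), `deltas` (list of
#'   increments), `segcoef` (`q x (s+1)` matrix of per-regime
#'   coefficients), `fitted`, `residuals` (raw), `centered` (segment-wise
#'   centered residuals) and `a` (the change points used).
#' @export
fit_piecewise <- function(y, x, a_hat = integer(0)) {
  x <- as.matrix(x)
  n <- length(y)
  q <- ncol(x)
  a_hat <- sort(as.integer(a_hat))
  if (length(a_hat) && (a_hat[1L] <= 0L || a_hat[length(a_hat)] >= n ||
                        anyDuplicated(a_hat)))
    stop("'a_hat' must be strictly increasing with 0 < a < n")
  s <- length(a_hat)
  W <- x
  for (a in a_hat) W <- cbind(W, x * (seq_len(n) > a))
  fit <- stats::lm.fit(W, y)
  cf <- fit$coefficients
  if (anyNA(cf)) {
    # pivoted QR drops aliased columns; their coefficients carry no
    # identifiable effect and are set to zero.  A fully aliased block
    # means a regime with no identifiable coefficients at all.
    blk <- rep(seq_len(s + 1L), each = q)
    dead <- tapply(is.na(cf), blk, all)
    if (any(dead))
      stop("piecewise design is rank deficient (segment ",
           which(dead)[1L], ")")
    cf[is.na(cf)] <- 0
  }
  beta1 <- cf[seq_len(q)]
  deltas <- if (s) lapply(seq_len(s), function(j)
    cf[(j * q + 1L):((j + 1L) * q)]) else list()
  segcoef <- matrix(beta1, q, s + 1L)
  if (s) for (j in seq_len(s)) segcoef[, (j + 1L):(s + 1L)] <-
    segcoef[, (j + 1L):(s + 1L)] + deltas[[j]]
  rownames(segcoef) <- colnames(x)
  colnames(segcoef) <- paste0("regime", seq_len(s + 1L))
  res <- as.vector(fit$residuals)
  bounds <- c(0L, a_hat, n)
  centered <- res
  for (j in seq_len(s + 1L)) {
    idx <- (bounds[j] + 1L):bounds[j + 1L]
    centered[idx] <- res[idx] - mean(res[idx])
  }
  list(beta1 = beta1, deltas = deltas, segcoef = segcoef,
       fitted = y - res, residuals = res, centered = centered, a = a_hat)
}
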