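# The two-stage change-point fit: cutting + greedy segment selection +
# sup-Wald refinement, with block length chosen by BIC over a c0 grid.

# One full pass at a fixed block length m.  Returns everything the caller
# needs to score the fit or to re-run the pipeline on bootstrap responses.
cpreg_once <- function(y, x, m, cn, dn_scale, trace = FALSE) {
  n <- length(y)
  q <- ncol(x)
  plan <- cut_blocks(n, m)
  Z <- block_design(x, plan)
  colmap <- attr(Z, "colmap")
  cc <- center_cols(y, Z)
  rn <- ncol(Z)
  Dn <- max(1L, min(sum(cc$usable),
                    ceiling(sqrt(n / log(rn))) * dn_scale, n - 1L))
  path <- oga_path(cc$y, cc$Z, Dn, cc$usable)
  fl <- sigma2_floor(cc$y)
  d_hat <- hdic_argmin(path, cn, fl)
  J <- trim_selection(cc$y, cc$Z, path, d_hat, cn, fl)
  seg <- select_segments(J, colmap, plan)
  a_hat <- integer(seg$s)
  scans <- if (trace) vector("list", seg$s) else NULL
  if (seg$s > 0L) {
    for (j in seq_len(seg$s)) {
      ws <- seg$windows[j, 1L]
      we <- seg$windows[j, 2L]
      sw <- sup_wald(y[ws:we], x[ws:we, , drop = FALSE], q)
      a_hat[j] <- ws + sw$h_hat - 1L
      if (trace) scans[[j]] <- c(list(window = c(ws, we)), sw)
    }
  }
  pw <- fit_piecewise(y, x, a_hat)
  list(plan = plan, path = path, d_hat = d_hat, J = J, seg = seg,
       a_hat = a_hat, pw = pw, scans = scans)
}

# BIC used to pick the block length.  The "scaled" default is
# n*log(RSS/n) + s*q*log(n); the "literal" variant log(RSS) + s*q*log(n)
# drops the 1/n scaling and is kept for comparison (its penalty dominates
# the data term at any realistic n, so it is not the default).
bic_value <- function(rss, n, s, q, variant) {
  rss <- max(rss, n * .Machine$double.xmin)
  if (variant == "scaled") n * log(rss / n) + s * q * log(n)
  else log(rss) + s * q * log(n)
}

#' Fit a multiple change-point linear regression
#'
#' Two-stage estimation of an unknown number of coefficient change points
#' in `y_i = x_i' beta(i) + eps_i`.  The series is cut into `p = floor(n/m)`
#' blocks and rewritten on a cumulative block design, where each change
#' point shows up as at most two adjacent nonzero coefficient blocks;
#' those blocks are found by orthogonal greedy selection stopped by a
#' high-dimensional information criterion (penalty `cn * log(p*q) / n` per
#' column) and pruned by a trimming step.  Each resulting two-block window
#' (length `2m`) is then scanned by a sup-Wald statistic whose argmax is
#' the refined change-point location, and the full piecewise model is
#' refit by least squares.
#'
#' The block length is `m = ceiling(c0 * sqrt(n))`; unless `m` is given
#' explicitly, every admissible value on `c0_grid` is tried and the fit
#' minimising the BIC `n*log(RSS/n) + s*q*log(n)` is returned (ties go to
#' the smallest `m`).  No intercept is added implicitly: include a column
#' of ones in `x` if one is wanted.
#'
#' @param y numeric response vector, in time order.
#' @param x numeric regressor matrix (`n x q`); omit when `ar_order` is
#'   given.
#' @param m explicit block length (bypasses the `c0` grid search).
#' @param c0_grid grid of block-length multipliers, each within
#'   `[0.1, 1.5]`.
#' @param cn information-criterion penalty multiplier (default 2).
#' @param dn_scale the greedy path is capped at
#'   `ceiling(sqrt(n / log(p*q))) * dn_scale` steps.
#' @param bic `"scaled"` (default) or `"literal"` BIC variant for the
#'   block-length choice.
#' @param ar_order build the regressors as `ar_order` lags of `y`
#'   (autoregressive usage); `x` must then be omitted.
#' @param trace keep the per-window Wald profiles in the returned object.
#' @return An object of class `"cpreg"`: a list with, among others,
#'   `s` (number of change points), `changepoints` (their locations,
#'   last index of each pre-change regime), `blocks` (candidate block
#'   indices), `coefficients` (`q x (s+1)` per-regime matrix), `residuals`
#'   and `resid_centered`, `fitted`, `m`, `c0`, `bic`, and `bic_grid`
#'   (the scored grid).  Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict`, `plot`, `simulate`, `confint`.
#' @examples
#' set.seed(1)
#' n <- 200
#' x <- cbind(1, rnorm(n))
#' y <- x %*% c(1, 1) + c(rep(0, 100), rep(3, 100)) * x[, 1] + rnorm(n, 0, 0.5)
#' fit <- cpreg(y, x)
#' fit$changepoints
#' @export
cpreg <- function(y, x = NULL, m = NULL,
                  c0_grid = seq(0.1, 1.5, by = 0.1),
                  cn = 2, dn_scale = 5, bic = c("scaled", "literal"),
                  ar_order = NULL, trace = FALSE) {
  cl <- match.call()
  bic <- match.arg(bic)
  if (!is.null(ar_order)) {
    if (!is.null(x)) stop("supply either 'x' or 'ar_order', not both")
    d <- ar_design(y, ar_order)
    y <- d$y
    x <- d$x
  }
  if (is.null(x)) stop("regressor matrix 'x' is required (or set 'ar_order')")
  y <- as.numeric(y)
  x <- as.matrix(x)
  n <- length(y)
  q <- ncol(x)
  if (nrow(x) != n) stop("'y' and 'x' must have matching length")
  if (anyNA(y) || anyNA(x)) stop("missing values are not supported")
  if (n < max(4L * q + 4L, 2L * q + 2L))
    stop("series too short: need n >= 4q + 4")

  if (!is.null(m)) {
    ms <- as.integer(m)[1L]
    if (ms < 2L * q + 2L)
      stop("'m' must be at least 2q + 2 = ", 2L * q + 2L)
    c0s <- NA_real_
  } else {
    if (!length(c0_grid)) stop("'c0_grid' must be nonempty")
    if (any(c0_grid < 0.1 - 1e-9 | c0_grid > 1.5 + 1e-9))
      stop("'c0_grid' values must lie in [0.1, 1.5]")
    ms <- as.integer(ceiling(c0_grid * sqrt(n)))
    ord <- order(ms)
    ms <- ms[ord]
    c0s <- c0_grid[ord]
    keep <- !duplicated(ms) & ms >= 2L * q + 3L & 2L * ms < n
    ms <- ms[keep]
    c0s <- c0s[keep]
    if (!length(ms))
      stop("no admissible block length on 'c0_grid' for n = ", n,
           ", q = ", q)
  }

  best <- NULL
  grid <- data.frame(c0 = numeric(0), m = integer(0), s = integer(0),
                     bic = numeric(0))
  err <- NULL
  for (i in seq_along(ms)) {
    res <- tryCatch(cpreg_once(y, x, ms[i], cn, dn_scale, trace),
                    error = function(e) e)
    if (inherits(res, "error")) { err <- res; next }
    b <- bic_value(sum(res$pw$residuals^2), n, res$seg$s, q, bic)
    grid <- rbind(grid, data.frame(c0 = c0s[i], m = ms[i],
                                   s = res$seg$s, bic = b))
    if (is.null(best) || b < best$bic)        # ties: smallest m wins
      best <- list(res = res, bic = b, m = ms[i], c0 = c0s[i])
  }
  if (is.null(best)) {
    if (!is.null(err)) stop("no admissible block length produced a fit: ",
                            conditionMessage(err))
    stop("no admissible block length produced a fit")
  }

  res <- best$res
  structure(list(
    call = cl, y = y, x = x, n = n, q = q,
    s = res$seg$s,
    changepoints = res$a_hat,
    blocks = res$seg$k,
    windows = res$seg$windows,
    coefficients = res$pw$segcoef,
    beta1 = res$pw$beta1,
    deltas = res$pw$deltas,
    residuals = res$pw$residuals,
    resid_centered = res$pw$centered,
    fitted = res$pw$fitted,
    m = best$m, c0 = best$c0, p = res$plan$p,
    bic = best$bic, bic_grid = grid, bic_variant = bic,
    cn = cn, dn_scale = dn_scale,
    oga = list(selected = res$path$selected, d_hat = res$d_hat,
               J = res$J, A = res$seg$A),
    scans = res$scans,
    ar_order = ar_order
  ), class = "cpreg")
}
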