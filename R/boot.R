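# Segment-wise centered residual bootstrap for change-point locations.

# Draw nsim bootstrap response vectors: within each estimated segment the
# centered residuals of that segment are resampled i.i.d. with
# replacement and added to the fitted means (fixed-design bootstrap).
boot_responses <- function(object, nsim = 1L) {
  bounds <- c(0L, object$changepoints, object$n)
  fv <- object$fitted
  ec <- object$resid_centered
  seglen <- diff(bounds)
  if (any(seglen < 2L))
    stop("degenerate segment with fewer than 2 residuals")
  out <- matrix(0, object$n, nsim)
  for (b in seq_len(nsim)) {
    eps <- numeric(object$n)
    for (j in seq_along(seglen)) {
      idx <- (bounds[j] + 1L):bounds[j + 1L]
      eps[idx] <- sample(ec[idx], length(idx), replace = TRUE)
    }
    out[, b] <- fv + eps
  }
  out
}

# For an AR design, optionally regenerate the responses recursively: the
# lagged-response columns are rebuilt from the bootstrap series itself
# instead of being kept at their observed values.  Lags reaching before
# the sample reuse the observed pre-sample values already stored in x.
boot_responses_recursive <- function(object, nsim = 1L) {
  p <- object$ar_order
  bounds <- c(0L, object$changepoints, object$n)
  ec <- object$resid_centered
  regime <- rowSums(outer(seq_len(object$n), object$changepoints, `>`)) + 1L
  coefs <- object$coefficients
  out <- matrix(0, object$n, nsim)
  for (b in seq_len(nsim)) {
    eps <- numeric(object$n)
    for (j in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[j] + 1L):bounds[j + 1L]
      eps[idx] <- sample(ec[idx], length(idx), replace = TRUE)
    }
    ystar <- numeric(object$n)
    for (i in seq_len(object$n)) {
      xr <- vapply(seq_len(p), function(k)
        if (i - k >= 1L) ystar[i - k] else object$x[i, k], numeric(1L))
      ystar[i] <- sum(xr * coefs[, regime[i]]) + eps[i]
    }
    out[, b] <- ystar
  }
  out
}

# Re-run the detection stages on a bootstrap response at the original
# block length and match bootstrap change points to the original ones by
# block-index equality (|k* - k| <= match_tol).  Returns an integer
# vector of matched bootstrap locations, NA where an original change
# point found no counterpart.
boot_replicate <- function(ystar, object, match_tol = 0L) {
  res <- tryCatch(
    cpreg_once(ystar, object$x, object$m, object$cn, object$dn_scale),
    error = function(e) NULL)
  matched <- rep(NA_integer_, object$s)
  if (is.null(res) || res$seg$s == 0L) return(matched)
  for (j in seq_len(object$s)) {
    dk <- abs(res$seg$k - object$blocks[j])
    i <- which(dk <= match_tol)
    if (length(i)) matched[j] <- res$a_hat[i[which.min(dk[i])]]
  }
  matched
}

#' Bootstrap confidence intervals for change-point locations
#'
#' Runs the segment-wise centered residual bootstrap: `B` response vectors
#' are drawn from the fitted piecewise model ([simulate.cpreg()]), the
#' two-stage detector is re-run on each at the original block length (the
#' segmentation is not re-selected), and each bootstrap change point is
#' matched to an original one when its candidate block index agrees.  For
#' each original change point `j`, the matched location differences
#' `a*_j - a_j` over the `B*_j <= B` successful replicates give empirical
#' percentile intervals `[a_j + Q_{alpha/2}, a_j + Q_{1-alpha/2}]`
#' (order-statistic quantiles, endpoints rounded outward and clipped to
#' `[1, n]`).  With `bonferroni = TRUE` each marginal interval is built at
#' level `alpha/s`, giving asymptotically valid joint coverage `1 - alpha`.
#'
#' @param object a `"cpreg"` fit with at least one change point.
#' @param B number of bootstrap replicates.
#' @param level confidence level(s), e.g. `c(0.90, 0.95)`.
#' @param bonferroni build joint (Bonferroni-corrected) intervals.
#' @param seed integer seed; each replicate uses a deterministic
#'   sub-seed derived from it, so results do not depend on evaluation
#'   order.
#' @param match_tol match bootstrap to original change points within this
#'   many blocks (0 = exact block equality, the default).
#' @param recursive for AR designs, regenerate the lagged-response
#'   columns from the bootstrap series instead of keeping them fixed.
#' @return An object of class `"cpreg_boot"`: list with `B`, `B_star`
#'   (effective replicates per change point), `diffs` (list of matched
#'   location differences), `ci` (named list over levels of `s x 2`
#'   integer matrices), `level`, `bonferroni`, `a_hat`, `n`.
#' @seealso [confint.cpreg()] for the one-call interface.
#' @export
cpreg_boot <- function(object, B = 500, level = 0.95, bonferroni = FALSE,
                       seed = NULL, match_tol = 0L, recursive = FALSE) {
  if (!inherits(object, "cpreg")) stop("'object' must be a cpreg fit")
  if (object$s < 1L)
    stop("fitted model has no change points; nothing to bootstrap")
  if (any(level <= 0 | level >= 1)) stop("'level' must be in (0, 1)")
  if (recursive && is.null(object$ar_order))
    stop("'recursive' requires a fit built with 'ar_order'")
  if (!is.null(seed)) set.seed(seed)
  sub <- sample.int(2147483646L, B)
  draws <- matrix(NA_integer_, B, object$s)
  for (b in seq_len(B)) {
    set.seed(sub[b])
    ystar <- if (recursive) boot_responses_recursive(object, 1L)[, 1L]
             else boot_responses(object, 1L)[, 1L]
    draws[b, ] <- boot_replicate(ystar, object, match_tol)
  }
  diffs <- lapply(seq_len(object$s), function(j) {
    d <- draws[, j] - object$changepoints[j]
    d[!is.na(d)]
  })
  B_star <- lengths(diffs)
  alphas <- 1 - level
  ci <- lapply(alphas, function(a) {
    aj <- if (bonferroni) a / object$s else a
    t(vapply(seq_len(object$s), function(j)
      build_ci(object$changepoints[j], diffs[[j]], aj, object$n),
      integer(2L)))
  })
  names(ci) <- format(level)
  for (l in seq_along(ci)) {
    dimnames(ci[[l]]) <- list(paste0("a", seq_len(object$s)),
                              c("lower", "upper"))
  }
  structure(list(B = B, B_star = B_star, diffs = diffs, ci = ci,
                 level = level, bonferroni = bonferroni,
                 a_hat = object$changepoints, n = object$n),
            class = "cpreg_boot")
}

# Percentile interval from matched location differences: empirical
# order-statistic quantiles of the diffs at alpha/2 and 1 - alpha/2,
# endpoints rounded outward to integers and clipped to [1, n].  Empty
# diffs yield an NA interval (reported, not fatal).
build_ci <- function(a, diffs, alpha, n) {
  if (!length(diffs)) return(c(NA_integer_, NA_integer_))
  qs <- stats::quantile(diffs, c(alpha / 2, 1 - alpha / 2),
                        type = 1, names = FALSE)
  c(max(1L, as.integer(floor(a + qs[1L]))),
    min(as.integer(n), as.integer(ceiling(a + qs[2L]))))
}

#' @export
print.cpreg_boot <- function(x, ...) {
  cat("Bootstrap confidence intervals (B =", x$B,
      if (x$bonferroni) ", Bonferroni-joint" else ", pointwise", ")\n")
  for (l in names(x$ci)) {
    cat("\nLevel ", l, ":\n", sep = "")
    m <- cbind(a_hat = x$a_hat, x$ci[[l]], B_star = x$B_star)
    print(m)
  }
  invisible(x)
}

#' Confidence intervals for estimated change points
#'
#' Convenience wrapper around [cpreg_boot()]: returns the bootstrap
#' percentile intervals as a matrix in the usual `confint` layout.
#'
#' @param object a `"cpreg"` fit with at least one change point.
#' @param parm indices of change points to report (default all).
#' @param level single confidence level.
#' @param B,bonferroni,seed,... passed to [cpreg_boot()].
#' @export
confint.cpreg <- function(object, parm = NULL, level = 0.95, B = 500,
                          bonferroni = FALSE, seed = NULL, ...) {
  bt <- cpreg_boot(object, B = B, level = level, bonferroni = bonferroni,
                   seed = seed, ...)
  ci <- bt$ci[[1L]]
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
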