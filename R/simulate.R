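# Synthetic-data generators for piecewise linear regression and the
# Monte-Carlo drivers for the detection-accuracy and bootstrap-coverage
# studies.

#' Simulate a piecewise linear regression series
#'
#' Generates `y_i = x_i' beta(i) + eps_i` where the coefficient vector is
#' `beta1` on the first regime and gains the increment `deltas[[j]]` after
#' change point `a[j]` (a change point is the last index of its regime).
#' Columns flagged in `lag` are lagged-response regressors and are filled
#' in recursively during generation (`y` values before time 1 are taken as
#' 0); the corresponding columns of `x` are overwritten.
#'
#' @param x numeric matrix (`n x q`) of regressors; lag columns may hold
#'   placeholders.
#' @param beta1 first-regime coefficient vector (length `q`).
#' @param deltas list of coefficient increments (each length `q`, none
#'   all-zero), one per change point.
#' @param a strictly increasing integer change points, `1 < a < n`.
#' @param lag integer vector of length `q`: 0 for an exogenous column,
#'   `k > 0` for a column equal to `y_{t-k}`.  `NULL` means no lags.
#' @param sd error standard deviation (i.i.d. normal errors); `sd = 0`
#'   gives a noiseless series.
#' @param seed optional integer seed.
#' @return List with `y`, `x` (lag columns filled in), `a`, `s`, and
#'   `coefficients` (the `q x (s+1)` per-regime coefficient matrix).
#' @examples
#' x <- cbind(1, rnorm(100))
#' d <- sim_cpreg(x, c(1, 0.5), list(c(2, 0)), a = 50, seed = 1)
#' @export
sim_cpreg <- function(x, beta1, deltas = list(), a = integer(0),
                      lag = NULL, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  n <- nrow(x)
  q <- ncol(x)
  a <- as.integer(a)
  s <- length(a)
  if (length(beta1) != q) stop("'beta1' must have length ncol(x)")
  if (length(deltas) != s)
    stop("'deltas' must have one increment per change point")
  if (s && (is.unsorted(a, strictly = TRUE) || a[1L] <= 1L || a[s] >= n))
    stop("'a' must be strictly increasing with 1 < a < n")
  if (any(vapply(deltas, function(d) all(d == 0), logical(1L))))
    stop("each element of 'deltas' must be a nonzero vector")
  coefs <- matrix(beta1, q, s + 1L)
  if (s) for (j in seq_len(s)) coefs[, (j + 1L):(s + 1L)] <-
    coefs[, (j + 1L):(s + 1L)] + deltas[[j]]
  regime <- rowSums(outer(seq_len(n), a, `>`)) + 1L
  eps <- stats::rnorm(n, 0, sd)
  if (is.null(lag) || all(lag == 0L)) {
    y <- rowSums(x * t(coefs)[regime, , drop = FALSE]) + eps
  } else {
    lag <- as.integer(lag)
    if (length(lag) != q) stop("'lag' must have length ncol(x)")
    lc <- which(lag > 0L)
    y <- numeric(n)
    for (i in seq_len(n)) {
      for (c in lc) x[i, c] <- if (i - lag[c] >= 1L) y[i - lag[c]] else 0
      y[i] <- sum(x[i, ] * coefs[, regime[i]]) + eps[i]
    }
  }
  list(y = y, x = x, a = a, s = s, coefficients = coefs)
}

#' The periodic-autoregressive study series
#'
#' The synthetic series used throughout the package's simulation studies:
#' `n = 600` observations with regressors
#' `x_t = (cos(t*pi/30), sin(t*pi/30), y_{t-1})` (period-30 harmonics plus
#' a lag-1 response), first-regime coefficients `(2, 2, 0.1)`, and three
#' coefficient breaks after `t = 150, 300, 450` with increments
#' `(-3, 1, 0.2)`, `(2, 0, -0.3)` and `(2, 2, 0)` — so the per-regime
#' coefficients are `(2, 2, 0.1)`, `(-1, 3, 0.3)`, `(1, 3, 0)` and
#' `(3, 5, 0)`.  Errors are i.i.d. standard normal (scaled by `sd`) and
#' the recursion starts from `y_0 = 0`.
#'
#' @param n series length (change points `a` must lie inside `1..n`).
#' @param a change-point locations.
#' @param sd error standard deviation; `sd = 0` gives the deterministic
#'   (noiseless) series.
#' @param seed optional integer seed.
#' @return As [sim_cpreg()].
#' @export
sim_periodic_ar <- function(n = 600, a = c(150, 300, 450), sd = 1,
                            seed = NULL) {
  t <- seq_len(n)
  x <- cbind(cos = cos(t * pi / 30), sin = sin(t * pi / 30), ylag1 = 0)
  sim_cpreg(x, beta1 = c(2, 2, 0.1),
            deltas = list(c(-3, 1, 0.2), c(2, 0, -0.3), c(2, 2, 0)),
            a = a, lag = c(0L, 0L, 1L), sd = sd, seed = seed)
}

#' Monte-Carlo study of detection accuracy
#'
#' Repeatedly simulates the periodic-autoregressive study series
#' ([sim_periodic_ar()]), runs the two-stage detector on each replicate,
#' and summarises detection accuracy the way such studies are usually
#' tabulated: `call_pct` is the percentage of replicates in which exactly
#' `s` change points were found and every one lies within `tol` of its
#' true location; `c_pct[j]` is the percentage in which the estimate
#' nearest to true point `j` lies within `tol` of it; `mean[j]` and
#' `se[j]` are the mean and standard deviation of those nearest estimates
#' over the replicates where they lie within `cond_tol` of the truth.
#'
#' @param reps number of Monte-Carlo replicates.
#' @param tol closeness tolerance for a correct call (default 5).
#' @param cond_tol conditioning tolerance for the mean/SE summaries
#'   (default 50).
#' @param sd error standard deviation of the simulated series.
#' @param seed integer seed; each replicate uses a deterministic
#'   sub-seed.
#' @param ... further arguments to [cpreg()] (e.g. `cn`, `c0_grid`).
#' @return An object of class `"mc_study"` with fields `reps`,
#'   `call_pct`, `c_pct`, `mean`, `se`, `n_cond`, `s_hat` (the per-
#'   replicate counts) and `a_true`.
#' @export
mc_study <- function(reps = 1000, tol = 5, cond_tol = 50, sd = 1,
                     seed = NULL, ...) {
  if (reps < 1L) stop("'reps' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  sub <- sample.int(2147483646L, reps)
  a_true <- c(150L, 300L, 450L)
  est <- matrix(NA_real_, reps, 3L)
  s_hat <- rep(NA_integer_, reps)
  callv <- logical(reps)
  for (r in seq_len(reps)) {
    dat <- sim_periodic_ar(sd = sd, seed = sub[r])
    fit <- tryCatch(cpreg(dat$y, dat$x, ...), error = function(e) NULL)
    if (is.null(fit)) next
    s_hat[r] <- fit$s
    if (fit$s >= 1L) {
      for (j in 1:3) est[r, j] <-
        fit$changepoints[which.min(abs(fit$changepoints - a_true[j]))]
      callv[r] <- fit$s == 3L &&
        all(abs(fit$changepoints - a_true) <= tol)
    }
  }
  dev <- sweep(est, 2L, a_true)
  hit <- !is.na(dev) & abs(dev) <= tol
  cond <- !is.na(dev) & abs(dev) <= cond_tol
  mean_j <- se_j <- rep(NA_real_, 3L)
  for (j in 1:3) {
    v <- est[cond[, j], j]
    if (length(v)) {
      mean_j[j] <- mean(v)
      se_j[j] <- stats::sd(v)
    }
  }
  structure(list(reps = reps,
                 call_pct = 100 * mean(callv),
                 c_pct = 100 * colMeans(hit),
                 mean = mean_j, se = se_j,
                 n_cond = colSums(cond),
                 s_hat = s_hat, a_true = a_true),
            class = "mc_study")
}

#' @export
print.mc_study <- function(x, ...) {
  cat("Monte-Carlo detection study (", x$reps, " replicates)\n", sep = "")
  cat(sprintf("call%%: %.2f\n", x$call_pct))
  tab <- rbind(`c (%)` = x$c_pct, Mean = x$mean, SE = x$se,
               n_cond = x$n_cond)
  colnames(tab) <- paste0("a", 1:3, " (", x$a_true, ")")
  print(round(tab, 2))
  invisible(x)
}

#' Monte-Carlo study of bootstrap interval coverage
#'
#' For each of `nrep` realizations of the study series, fits the two-stage
#' detector, runs the residual bootstrap with `B` replicates, and checks
#' whether each true change point is covered by the interval of its
#' nearest estimated change point.  Pointwise coverage uses the marginal
#' interval at level `1 - alpha`; joint coverage uses Bonferroni intervals
#' at `alpha / s_hat` each and requires every true point covered.
#'
#' @param nrep number of outer realizations.
#' @param B bootstrap replicates per realization.
#' @param levels confidence levels to evaluate.
#' @param sd error standard deviation of the simulated series.
#' @param seed integer seed (sub-seeds drive each realization and its
#'   bootstrap).
#' @param ... further arguments to [cpreg()].
#' @return An object of class `"coverage_study"`: a matrix of empirical
#'   coverage percentages with one row per level and columns
#'   `joint, a1, a2, a3`, plus attributes `nrep` and `B`.
#' @export
coverage_study <- function(nrep = 500, B = 500, levels = c(0.90, 0.95),
                           sd = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sub <- matrix(sample.int(2147483646L, 2L * nrep), nrep, 2L)
  a_true <- c(150L, 300L, 450L)
  nl <- length(levels)
  cov_pt <- array(FALSE, c(nrep, nl, 3L))
  cov_joint <- matrix(FALSE, nrep, nl)
  for (r in seq_len(nrep)) {
    dat <- sim_periodic_ar(sd = sd, seed = sub[r, 1L])
    fit <- tryCatch(cpreg(dat$y, dat$x, ...), error = function(e) NULL)
    if (is.null(fit) || fit$s < 1L) next
    bt <- tryCatch(cpreg_boot(fit, B = B, level = levels,
                              seed = sub[r, 2L]),
                   error = function(e) NULL)
    if (is.null(bt)) next
    nearest <- vapply(a_true, function(a)
      which.min(abs(fit$changepoints - a)), integer(1L))
    for (l in seq_len(nl)) {
      alpha <- 1 - levels[l]
      marg <- bt$ci[[l]]
      bonf <- t(vapply(seq_len(fit$s), function(j)
        build_ci(fit$changepoints[j], bt$diffs[[j]], alpha / fit$s, fit$n),
        integer(2L)))
      inside <- function(ci, a) !anyNA(ci) && ci[1L] <= a && a <= ci[2L]
      for (j in 1:3) cov_pt[r, l, j] <-
        inside(marg[nearest[j], ], a_true[j])
      cov_joint[r, l] <- all(vapply(1:3, function(j)
        inside(bonf[nearest[j], ], a_true[j]), logical(1L)))
    }
  }
  out <- cbind(joint = 100 * colMeans(cov_joint),
               100 * apply(cov_pt, 2:3, mean))
  colnames(out) <- c("joint", paste0("a", 1:3))
  rownames(out) <- paste0(100 * levels, "%")
  structure(out, nrep = nrep, B = B, class = "coverage_study")
}

#' @export
print.coverage_study <- function(x, ...) {
  cat("Bootstrap coverage study (", attr(x, "nrep"), " realizations, B = ",
      attr(x, "B"), ")\n", sep = "")
  m <- x
  attributes(m) <- attributes(x)[c("dim", "dimnames")]
  print(round(m, 2))
  invisible(x)
}
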