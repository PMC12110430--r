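# S3 methods for "cpreg" objects.

#' @export
print.cpreg <- function(x, ...) {
  cat("Two-stage change-point regression\n")
  cat("n =", x$n, ", q =", x$q, ", block length m =", x$m,
      if (!is.na(x$c0)) paste0("(c0 = ", format(x$c0), ")"), "\n")
  if (x$s == 0L) {
    cat("No change points detected.\n")
  } else {
    cat("Detected", x$s, "change point(s) at:",
        paste(x$changepoints, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.cpreg <- function(object, ...) {
  structure(list(fit = object), class = "summary.cpreg")
}

#' @export
print.summary.cpreg <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-regime coefficients:\n")
  print(round(f$coefficients, 4))
  if (f$s > 0L) {
    cat("\nCandidate blocks:", paste(f$blocks, collapse = ", "),
        "(of", f$p, "blocks)\n")
  }
  rss <- sum(f$residuals^2)
  cat("\nRSS:", format(rss), "  BIC (", f$bic_variant, "):",
      format(f$bic), "\n", sep = "")
  invisible(x)
}

#' Extract coefficients from a change-point fit
#'
#' @param object a `"cpreg"` fit.
#' @param type `"segments"` (default): the `q x (s+1)` matrix of
#'   per-regime coefficients; `"base"`: the first-regime coefficients;
#'   `"deltas"`: the list of coefficient increments at each change point.
#' @param ... unused.
#' @export
coef.cpreg <- function(object, type = c("segments", "base", "deltas"), ...) {
  switch(match.arg(type),
         segments = object$coefficients,
         base = object$beta1,
         deltas = object$deltas)
}

#' @export
fitted.cpreg <- function(object, ...) object$fitted

#' Residuals of a change-point fit
#'
#' @param object a `"cpreg"` fit.
#' @param type `"raw"` least-squares residuals, or `"centered"` residuals
#'   re-centered to mean zero within each estimated segment (the pool the
#'   bootstrap resamples from).
#' @param ... unused.
#' @export
residuals.cpreg <- function(object, type = c("raw", "centered"), ...) {
  switch(match.arg(type),
         raw = object$residuals,
         centered = object$resid_centered)
}

#' Predict from a change-point fit
#'
#' Evaluates the fitted piecewise model.  With no `newdata` this is just
#' the in-sample fit.  Otherwise `newdata` must be a list with components
#' `x` (regressor matrix) and `t` (integer time indices), and each row is
#' scored with the regime its `t` falls in (indices beyond `n` use the
#' last regime).
#'
#' @param object a `"cpreg"` fit.
#' @param newdata optional list with `x` and `t` as described.
#' @param ... unused.
#' @export
predict.cpreg <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  xn <- as.matrix(newdata$x)
  tn <- as.integer(newdata$t)
  if (nrow(xn) != length(tn)) stop("'newdata$x' and 'newdata$t' mismatch")
  regime <- rowSums(outer(tn, object$changepoints, `>`)) + 1L
  rowSums(xn * t(object$coefficients)[regime, , drop = FALSE])
}

#' Plot a change-point fit
#'
#' Plots the response against time with fitted values overlaid, vertical
#' lines at the estimated change points, and (optionally) shaded bootstrap
#' confidence intervals.
#'
#' @param x a `"cpreg"` fit.
#' @param boot optional `"cpreg_boot"` object; its confidence intervals
#'   (first level) are drawn as shaded bands.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cpreg <- function(x, boot = NULL, ...) {
  idx <- seq_len(x$n)
  graphics::plot(idx, x$y, type = "l", col = "grey40",
                 xlab = "time index", ylab = "y", ...)
  graphics::lines(idx, x$fitted, col = "steelblue")
  if (!is.null(boot) && inherits(boot, "cpreg_boot")) {
    ci <- boot$ci[[1L]]
    for (j in seq_len(nrow(ci))) {
      if (anyNA(ci[j, ])) next
      graphics::rect(ci[j, 1L], graphics::par("usr")[3L],
                     ci[j, 2L], graphics::par("usr")[4L],
                     col = grDevices::adjustcolor("tomato", 0.2),
                     border = NA)
    }
  }
  graphics::abline(v = x$changepoints, col = "tomato", lty = 2)
  invisible(x)
}

#' Simulate bootstrap responses from a change-point fit
#'
#' Draws response vectors from the fitted piecewise model by the
#' segment-wise centered residual bootstrap: within each estimated
#' segment, residuals are resampled with replacement from that segment's
#' centered residual pool and added to the fitted means (regressors kept
#' as observed).
#'
#' @param object a `"cpreg"` fit.
#' @param nsim number of response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return An `n x nsim` numeric matrix.
#' @importFrom stats simulate
#' @export
simulate.cpreg <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  boot_responses(object, nsim)
}
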