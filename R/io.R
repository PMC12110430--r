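# CSV input and JSON output helpers.

#' Read a regression series from CSV
#'
#' Expects a header row.  Either columns `t, y, x1..xq` (an ordered
#' response with regressors), or just `t, y` / a single `y` column
#' together with `ar_order`, in which case the regressors are built as
#' lags of `y`.  Rows are sorted by `t`; duplicated or gapped time
#' indices are rejected.
#'
#' @param path CSV file path.
#' @param ar_order optional lag order for univariate input.
#' @return List with `y`, `x`, `t` (the time indices of the returned
#'   rows) and `ar_order`.
#' @export
read_series <- function(path, ar_order = NULL) {
  df <- utils::read.csv(path)
  if (!nrow(df)) stop("empty input: ", path)
  if (!all(vapply(df, is.numeric, logical(1L)))) {
    bad <- which(!vapply(df, is.numeric, logical(1L)))[1L]
    stop("non-numeric values in column '", names(df)[bad], "'")
  }
  if ("t" %in% names(df)) {
    ord <- order(df$t)
    df <- df[ord, , drop = FALSE]
    tt <- as.integer(df$t)
    if (anyDuplicated(tt)) {
      stop("duplicated time index at row ", which(duplicated(tt))[1L])
    }
    if (any(diff(tt) != 1L)) {
      stop("gapped time index after row ", which(diff(tt) != 1L)[1L])
    }
  } else {
    tt <- seq_len(nrow(df))
  }
  if (!("y" %in% names(df))) stop("missing required column 'y'")
  y <- as.numeric(df$y)
  xcols <- setdiff(names(df), c("t", "y"))
  if (!is.null(ar_order)) {
    if (length(xcols))
      stop("'ar_order' requires a univariate series (columns t, y only)")
    d <- ar_design(y, ar_order)
    return(list(y = d$y, x = d$x, t = tt[(ar_order + 1L):length(tt)],
                ar_order = as.integer(ar_order)))
  }
  if (!length(xcols))
    stop("no regressor columns found; supply x1..xq or set 'ar_order'")
  x <- as.matrix(df[xcols])
  list(y = y, x = x, t = tt, ar_order = NULL)
}

#' Write a change-point fit (and optional bootstrap intervals) to JSON
#'
#' Serialises the essentials of a fit to a versioned JSON schema:
#' `{n, q, m_used, s_hat, change_points: [{a_hat, block, ci_90, ci_95}],
#' config, seed, version}`.  Interval fields are `null` when no bootstrap
#' result is supplied (or a level is missing), so the file round-trips
#' losslessly whether or not intervals were computed.
#'
#' @param fit a `"cpreg"` fit.
#' @param path output file path.
#' @param boot optional `"cpreg_boot"` object; levels 0.90 and 0.95 are
#'   looked up for the `ci_90` / `ci_95` fields.
#' @param seed optional integer recorded in the file.
#' @return `path`, invisibly.
#' @export
write_results <- function(fit, path, boot = NULL, seed = NULL) {
  if (!inherits(fit, "cpreg")) stop("'fit' must be a cpreg object")
  ci_at <- function(lv, j) {
    if (is.null(boot)) return(NULL)
    i <- which(abs(as.numeric(names(boot$ci)) - lv) < 1e-9)
    if (!length(i)) return(NULL)
    ci <- boot$ci[[i[1L]]][j, ]
    if (anyNA(ci)) NULL else as.integer(ci)
  }
  cps <- lapply(seq_len(fit$s), function(j) list(
    a_hat = fit$changepoints[j],
    block = fit$blocks[j],
    ci_90 = ci_at(0.90, j),
    ci_95 = ci_at(0.95, j)))
  obj <- list(
    schema_version = "1.0",
    n = fit$n, q = fit$q, m_used = fit$m, s_hat = fit$s,
    change_points = cps,
    config = list(cn = fit$cn, dn_scale = fit$dn_scale,
                  c0 = if (is.na(fit$c0)) NULL else fit$c0,
                  bic = fit$bic_variant,
                  ar_order = fit$ar_order),
    seed = seed,
    version = as.character(utils::packageVersion("cptboot")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
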