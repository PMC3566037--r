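#' Hadi forward-search multivariate outlier detection
#'
#' Identifies multivariate outliers by Hadi's forward-search method: an
#' initial robust ordering of the data, a small "basic subset" of clean
#' records that is grown one record at a time with re-estimated mean and
#' covariance, and a final chi-square distance test against the basic-subset
#' estimates.  The procedure is deterministic: ties in the distance ordering
#' are broken by record index, so repeated runs are bit-identical.
#'
#' The algorithm:
#' \enumerate{
#'   \item Compute squared distances from the coordinate-wise median, scaled
#'     by the scatter matrix of deviations about the median.
#'   \item Order records by these distances and take the cleanest `p + 1` as
#'     the basic subset (grown further if its covariance is singular).
#'   \item Repeatedly re-estimate mean and covariance from the basic subset,
#'     re-rank all records, and grow the subset by one, until it holds
#'     `h = floor((n + p + 1) / 2)` records.
#'   \item Continue the search past `h`, admitting one record per iteration
#'     while the smallest corrected distance among records outside the basic
#'     subset stays below the `chi-square(p)` quantile at `1 - alpha/n`;
#'     distances are corrected by the small-sample covariance inflation
#'     factor `1 + (p+1)/(n-p) + 2/(n-1-3p)`.  Records whose corrected
#'     distance from the final basic-subset estimates exceeds the cutoff are
#'     declared outliers.
#' }
#' On clean data the basic subset grows to (nearly) the full sample, so the
#' distances converge to classical Mahalanobis distances and the expected
#' number of false flags per dataset is about `alpha`.  The third inflation
#' term is dropped when `n <= 3p + 1`, where it is undefined.
#'
#' @param X numeric matrix-like, `n` records by `p` variables; no missing
#'   values (handle missingness before screening).
#' @param alpha significance level governing the per-dataset false-flag
#'   budget; the cutoff uses the Bonferroni-style `1 - alpha/n` quantile.
#' @return An object of class `hadi_report`: list with `flags` (logical per
#'   record), `distances` (final inflation-corrected squared distances),
#'   `cutoff`, `n_flagged`, and `trace` (basic-subset sizes per forward
#'   iteration).
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(100), ncol = 2), c(8, -8))
#' hadi_outliers(X)$flags[51]
#' @export
hadi_outliers <- function(X, alpha = 0.05) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric")
  if (anyNA(X)) stop("X contains missing values; screen complete records only")
  n <- nrow(X)
  p <- ncol(X)
  if (p < 1L) stop("need at least one variable")
  if (n < p + 2L) {
    stop(sprintf("insufficient data for outlier screening: n = %d < p + 2 = %d",
                 n, p + 2L))
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")

  res <- .hadi_forward(X, alpha)
  if (isTRUE(res$singular)) singular_stop(X, res$where)
  structure(
    list(flags = as.logical(res$flags), distances = as.numeric(res$distances),
         cutoff = res$cutoff, n_flagged = sum(res$flags),
         trace = as.integer(res$trace), subset_size = res$subset_size,
         alpha = alpha, n = n, p = p),
    class = "hadi_report")
}

singular_stop <- function(X, where) {
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("V", seq_len(ncol(X)))
  q <- qr(scale(X, scale = FALSE))
  dep <- if (q$rank < ncol(X)) cn[q$pivot[-seq_len(q$rank)]] else cn
  stop(sprintf("degenerate geometry in %s: collinear columns (%s)",
               where, paste(dep, collapse = ", ")))
}

#' @export
print.hadi_report <- function(x, ...) {
  cat(sprintf(
    "Hadi forward-search screen: n = %d, p = %d, alpha = %g\n", x$n, x$p, x$alpha))
  cat(sprintf("  cutoff chi-square(%d, 1 - alpha/n) = %.3f\n", x$p, x$cutoff))
  cat(sprintf("  flagged %d record(s)\n", x$n_flagged))
  invisible(x)
}

#' Screen a cohort table for multivariate outliers and remove them
#'
#' Applies [hadi_outliers()] to the named columns of a cohort table,
#' considering only records complete on those columns, and returns the table
#' with flagged records removed together with the screening report.  The
#' removed record identifiers and step name are kept on the report so that
#' cumulative exclusions across sequential screening steps can be totalled.
#'
#' @param table a data.frame (e.g. a cohort table).
#' @param columns character vector of column names to screen jointly.
#' @param alpha significance level passed to [hadi_outliers()].
#' @param step label for this screening step, recorded with the removals.
#' @param id_col column holding record identifiers (row numbers are used if
#'   absent).
#' @return list with `table` (flagged records removed) and `report`
#'   (the `hadi_report`, with `removed_ids` and `step` fields added).
#' @export
remove_outliers <- function(table, columns, alpha = 0.05,
                            step = "outlier_screen", id_col = "id") {
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols) > 0L) {
    stop("columns absent from table: ", paste(missing_cols, collapse = ", "))
  }
  ids <- if (id_col %in% names(table)) table[[id_col]] else seq_len(nrow(table))
  complete <- stats::complete.cases(table[columns])
  X <- as.matrix(table[complete, columns, drop = FALSE])
  report <- hadi_outliers(X, alpha = alpha)
  removed <- ids[complete][report$flags]
  keep <- !(ids %in% removed)
  report$removed_ids <- removed
  report$step <- step
  list(table = table[keep, , drop = FALSE], report = report)
}
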