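# Two-way random-effects intraclass correlation (absolute agreement).
#
# With subjects as rows and measurements (methods, or repeated scans) as
# columns, the two-way decomposition yields mean squares MSR (rows), MSC
# (columns) and MSE (residual). Shrout-Fleiss absolute-agreement forms:
#
#   ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)
#   ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)
#
# with the conventional F test F = MSR/MSE on (n-1), (n-1)(k-1) df.

#' Construct a complete subjects-by-measurements ratings matrix
#'
#' @param values numeric matrix (or coercible), subjects in rows,
#'   measurements in columns; must be complete.
#' @param subject_ids,column_labels optional dimnames.
#' @return a numeric matrix of class `"ratings_matrix"`.
#' @export
ratings_matrix <- function(values, subject_ids = NULL, column_labels = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("size error: need at least 2 subjects and 2 measurements",
         call. = FALSE)
  }
  if (anyNA(m)) {
    stop("incomplete-matrix error: missing cells are not supported",
         call. = FALSE)
  }
  if (!is.null(subject_ids)) rownames(m) <- subject_ids
  if (!is.null(column_labels)) colnames(m) <- column_labels
  class(m) <- c("ratings_matrix", class(m))
  m
}

#' Extract a two-column eTIV/sbTIV ratings matrix from a scan table
#'
#' Rows with either method missing are dropped.
#'
#' @param table a scan table.
#' @param columns the two (or more) value columns to use.
#' @return a [ratings_matrix()].
#' @export
ratings_from_table <- function(table,
                               columns = c("etiv_mm3", "sbtiv_mm3")) {
  stopifnot(all(columns %in% names(table)))
  v <- as.matrix(as.data.frame(table)[, columns, drop = FALSE])
  v <- v[complete.cases(v), , drop = FALSE]
  ratings_matrix(v, column_labels = columns)
}

#' Two-way ANOVA mean squares of a ratings matrix
#'
#' Decomposes the total sum of squares exactly into row (subject), column
#' (measurement) and residual components.
#'
#' @param m a [ratings_matrix()] (or coercible complete matrix).
#' @return list of class `"variance_components"`: `ms_rows`, `ms_cols`,
#'   `ms_error`, the corresponding sums of squares, and `n`, `k`.
#' @export
anova_mean_squares <- function(m) {
  if (!inherits(m, "ratings_matrix")) m <- ratings_matrix(m)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ss_rows <- k * sum((rm_ - grand)^2)
  ss_cols <- n * sum((cm_ - grand)^2)
  resid <- m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand
  ss_error <- sum(resid^2)
  structure(list(
    ms_rows = ss_rows / (n - 1),
    ms_cols = ss_cols / (k - 1),
    ms_error = ss_error / ((n - 1) * (k - 1)),
    ss_rows = ss_rows, ss_cols = ss_cols, ss_error = ss_error,
    ss_total = sum((m - grand)^2),
    n = n, k = k
  ), class = "variance_components")
}

.icc_result <- function(estimate, form, vc) {
  f <- vc$ms_rows / vc$ms_error
  df1 <- vc$n - 1L
  df2 <- (vc$n - 1L) * (vc$k - 1L)
  structure(list(
    estimate = estimate, form = form,
    f_statistic = f, df1 = df1, df2 = df2,
    p_value = pf(f, df1, df2, lower.tail = FALSE),
    band = classify_icc(estimate),
    components = vc
  ), class = "icc_result")
}

#' ICC(2,1): single-measure absolute agreement
#'
#' Two-way random-effects model, absolute agreement, single measures.
#' Negative estimates are reported as computed, not truncated.
#'
#' @param m a [ratings_matrix()] (or coercible complete matrix).
#' @return an `icc_result`: `estimate`, `form`, `f_statistic`, `df1`, `df2`,
#'   `p_value`, `band`, and the underlying `components`.
#' @export
icc_single <- function(m) {
  vc <- anova_mean_squares(m)
  denom <- vc$ms_rows + (vc$k - 1) * vc$ms_error +
    vc$k * (vc$ms_cols - vc$ms_error) / vc$n
  if (abs(denom) < .Machine$double.eps * max(1, vc$ms_rows)) {
    stop("degenerate-input error: constant matrix has no variance to agree on",
         call. = FALSE)
  }
  .icc_result((vc$ms_rows - vc$ms_error) / denom, "single", vc)
}

#' ICC(2,k): average-measure absolute agreement
#'
#' Two-way random-effects model, absolute agreement, mean of the k
#' measurements.
#'
#' @inheritParams icc_single
#' @return an `icc_result`, as for [icc_single()].
#' @export
icc_average <- function(m) {
  vc <- anova_mean_squares(m)
  denom <- vc$ms_rows + (vc$ms_cols - vc$ms_error) / vc$n
  if (abs(denom) < .Machine$double.eps * max(1, vc$ms_rows)) {
    stop("degenerate-input error: constant matrix has no variance to agree on",
         call. = FALSE)
  }
  .icc_result((vc$ms_rows - vc$ms_error) / denom, "average", vc)
}

#' Qualitative reliability band of an ICC estimate
#'
#' Conventional cut-points: greater than 0.9 excellent, 0.75-0.9 good,
#' 0.5-0.75 moderate, 0.5 or less poor. Values exactly at a cut-point fall
#' in the lower band (the convention reads "greater than"), so 0.9 is
#' "good", 0.75 "moderate" and 0.5 "poor".
#'
#' @param estimate finite ICC estimate (negative values allowed; they band
#'   as "poor").
#' @return one of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
classify_icc <- function(estimate) {
  if (length(estimate) != 1L || !is.finite(estimate)) {
    stop("classify_icc needs a single finite estimate", call. = FALSE)
  }
  if (estimate > 0.9) "excellent"
  else if (estimate > 0.75) "good"
  else if (estimate > 0.5) "moderate"
  else "poor"
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,%s) = %.4f [%s]\n",
              if (x$form == "single") "1" else "k", x$estimate, x$band))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.3g\n",
              x$df1, x$df2, x$f_statistic, x$p_value))
  invisible(x)
}
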