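significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

test_result <- function(statistic, df, p, n, mean_diff, method) {
  out <- data.frame(statistic = statistic, df = df, p = p,
                    n = paste(n, collapse = ","),
                    mean_diff = mean_diff,
                    significance = significance_stars(p),
                    method = method)
  class(out) <- c("test_result", "data.frame")
  out
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: t(%g) = %.4g, p = %.4g %s (mean diff %.4g, n = %s)\n",
              x$method, x$df, x$statistic, x$p, x$significance,
              x$mean_diff, x$n))
  invisible(x)
}

#' Two-sample two-tailed Student's t-test
#'
#' Classical pooled-variance Student's t-test (df `n_a + n_b - 2`) with
#' two-tailed p and the conventional significance coding (`*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001). An unequal-variance (Welch) flag is
#' available. Two identical constant samples give t = 0, p = 1; constant
#' samples with different means have no valid t statistic and raise a
#' degenerate-variance error.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param var_equal pooled-variance Student form (default) or Welch.
#' @return one-row data.frame of class `test_result`: `statistic`, `df`,
#'   `p`, `n`, `mean_diff`, `significance`.
#' @export
#' @examples
#' two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
two_sample_ttest <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least two values")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(test_result(0, length(a) + length(b) - 2L, 1,
                         c(length(a), length(b)), 0, "two-sample t"))
    stop("degenerate variance: constant samples with unequal means")
  }
  tt <- t.test(a, b, var.equal = var_equal)
  test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
              c(length(a), length(b)), mean(a) - mean(b), "two-sample t")
}

#' Paired two-tailed Student's t-test
#'
#' t on the pairwise differences, df `n - 1`, two-tailed p. Identical
#' pairs give t = 0, p = 1; identical nonzero differences raise a
#' degenerate-variance error.
#'
#' @param a,b paired numeric samples of equal length >= 2.
#' @return one-row data.frame of class `test_result`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 2L) stop("need at least two pairs")
  d <- a - b
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(test_result(0, length(a) - 1L, 1, length(a), 0, "paired t"))
    stop("degenerate variance: all pairwise differences identical")
  }
  tt <- t.test(a, b, paired = TRUE)
  test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
              length(a), mean(d), "paired t")
}

#' Compare a metric between two groups of units
#'
#' Convenience wrapper applying [two_sample_ttest()] column-wise to the
#' shared numeric metrics of two [unit_stats()] tables, producing the
#' comparison table with significance stars.
#'
#' @param a,b data.frames of per-unit metrics (rows = units).
#' @param metrics character vector of column names to compare; defaults
#'   to all shared numeric columns.
#' @return data.frame with one row per metric.
#' @export
compare_groups <- function(a, b, metrics = NULL) {
  if (is.null(metrics)) {
    shared <- intersect(names(a), names(b))
    metrics <- shared[vapply(shared, function(m)
      is.numeric(a[[m]]) && is.numeric(b[[m]]), logical(1))]
  }
  rows <- lapply(metrics, function(m) {
    x <- a[[m]][!is.na(a[[m]])]; y <- b[[m]][!is.na(b[[m]])]
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    r <- two_sample_ttest(x, y)
    cbind(metric = m, r)
  })
  do.call(rbind, rows)
}
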