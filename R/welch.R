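#' Welch's two-sample t-test
#'
#' Unequal-variance two-sided t-test with Welch-Satterthwaite degrees of
#' freedom, as used for all pairwise intensity comparisons. Delegates to
#' [stats::t.test()] (`var.equal = FALSE`) after guarding the degenerate
#' zero-variance cases: when both samples have zero variance and equal
#' means, `t = 0` and `p = 1` by convention; with unequal means, `t` is
#' signed infinite and `p = 0`.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return A one-row tibble of class `welch_result`: `t_statistic`, `df`,
#'   `p_value`, `n1`, `n2`, `mean1`, `mean2`, `sd1`, `sd2`. The sign of `t`
#'   matches `mean1 - mean2`.
#' @export
welch_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample must have at least 2 observations", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA", call. = FALSE)
  s1 <- stats::sd(x); s2 <- stats::sd(y)
  m1 <- mean(x); m2 <- mean(y)
  n1 <- length(x); n2 <- length(y)
  if (s1 == 0 && s2 == 0) {
    t_stat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    p <- if (m1 == m2) 1 else 0
    df <- n1 + n2 - 2
  } else {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    t_stat <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  }
  structure(
    tibble::tibble(t_statistic = t_stat, df = df, p_value = p,
                   n1 = n1, n2 = n2, mean1 = m1, mean2 = m2,
                   sd1 = s1, sd2 = s2),
    class = c("welch_result", "tbl_df", "tbl", "data.frame")
  )
}

# Figure-legend style significance stars.
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", "n.s."))
}
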