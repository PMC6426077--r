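#' Yen's maximum-correlation auto-threshold
#'
#' Computes the automatic threshold of Yen, Chang & Chang (1995) by building
#' an intensity histogram (default 256 bins spanning the observed min..max,
#' emulating the 8-bit ImageJ setting) and evaluating the maximum-correlation
#' criterion at every candidate bin boundary:
#' \deqn{TC(t) = \log\frac{\left[P_1(t)\,(1-P_1(t))\right]^2}
#'   {\sum_{i \le t} p_i^2 \; \sum_{i > t} p_i^2}}
#' where \eqn{p_i} are the normalized bin probabilities and
#' \eqn{P_1(t)=\sum_{i\le t} p_i}. The returned threshold is the centre of
#' the maximizing bin (ties broken towards the lowest bin); foreground is
#' defined as pixels strictly above the threshold.
#'
#' @param x Numeric vector, matrix or array of intensities.
#' @param levels Number of histogram bins (default 256).
#' @return The threshold intensity (scalar).
#' @examples
#' img <- c(rep(10, 50), rep(200, 50))
#' yen_threshold(img)      # strictly between 10 and 200
#' @export
yen_threshold <- function(x, levels = 256) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v)) stop("threshold error: no finite pixel values", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    stop("threshold error: degenerate histogram (single non-empty bin)",
         call. = FALSE)
  }
  breaks <- seq(lo, hi, length.out = levels + 1)
  counts <- graphics::hist(v, breaks = breaks, plot = FALSE)$counts
  centers <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  yen_threshold_from_counts(counts, centers)
}

# Criterion evaluation on a pre-binned histogram; shared by yen_threshold()
# and exported for callers that already hold counts.
#' @rdname yen_threshold
#' @param counts Histogram counts per bin.
#' @param centers Bin centre intensities (same length as `counts`).
#' @export
yen_threshold_from_counts <- function(counts, centers) {
  stopifnot(length(counts) == length(centers), length(counts) >= 2)
  if (sum(counts > 0) < 2) {
    stop("threshold error: degenerate histogram (single non-empty bin)",
         call. = FALSE)
  }
  p <- counts / sum(counts)
  n <- length(p)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- rev(cumsum(rev(p^2)))          # P2sq[i] = sum_{j >= i} p_j^2
  t_idx <- seq_len(n - 1)                # candidate thresholds: bins 1..n-1
  num <- (P1[t_idx] * (1 - P1[t_idx]))^2
  den <- P1sq[t_idx] * P2sq[t_idx + 1]
  crit <- ifelse(den > 0 & num > 0, log(num / den), -Inf)
  centers[which.max(crit)]
}
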