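# Independent oracles, implemented without reference to the package internals.

# Analytic category probabilities for a genotype, enumerated by hand from the
# finite outcome space: orientation (co-orient / random attachment / forced
# biorientation) crossed with the deterministic cohesin rules and the
# transient-cohesion Bernoulli.
analytic_outcome_probs <- function(g) {
  p_bi <- if (g$forced_biorientation) 1 else (1 - g$p_monoorient) / 2
  if (!g$cleavage_on) {
    close <- p_bi; far <- 0
  } else if (g$protection_on) {
    close <- p_bi; far <- 0
  } else {
    close <- p_bi * g$p_transient_cohesion
    far <- p_bi * (1 - g$p_transient_cohesion)
  }
  rec8 <- if (!g$cleavage_on) "RETAINED_EVERYWHERE" else
    if (g$protection_on) "PERICENTROMERIC" else "ABSENT"
  list(
    p_biorient = p_bi,
    cen5 = c(SINGLE_FOCUS = 1 - p_bi, SPLIT_CLOSE = close, SPLIT_FAR = far),
    rec8 = rec8,
    divisions = if (g$second_division_on) 2L else 1L
  )
}

# Naive per-bin evaluation of Yen's maximum-correlation criterion, written
# with explicit loops and sums (independent of the vectorized implementation).
yen_oracle <- function(counts, centers) {
  p <- counts / sum(counts)
  n <- length(p)
  best <- -Inf
  best_t <- NA
  for (t in 1:(n - 1)) {
    P1 <- sum(p[1:t])
    s1 <- sum(p[1:t]^2)
    s2 <- sum(p[(t + 1):n]^2)
    num <- (P1 * (1 - P1))^2
    if (s1 > 0 && s2 > 0 && num > 0) {
      crit <- log(num / (s1 * s2))
      if (crit > best) { best <- crit; best_t <- t }
    }
  }
  centers[best_t]
}

# Hand-evaluated Welch statistic and Satterthwaite degrees of freedom.
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p)
}

# Small imaging configuration for fast rendering in tests: fewer z-slices and
# frames than the default acquisition, same noise model.
test_cfg <- function(...) {
  imaging_config(n_z = 5, n_frames = 6, onset_frame = 3, ...)
}
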