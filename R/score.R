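#' Tabulate per-cell phenotype calls into population frequencies
#'
#' Counts and proportions per category per genotype, with exact binomial
#' 95% confidence intervals. `NA` calls are excluded from a variable's
#' denominator; a warning is emitted when a genotype has fewer scorable
#' cells than `n_target`.
#'
#' @param calls Tibble of per-cell calls (as from [analyze_movie()]), with
#'   columns `genotype` plus any of `rec8_pattern`, `cen5_class`,
#'   `biosensor_state`, `divisions`.
#' @param n_target Intended number of scored cells per genotype
#'   (default 50).
#' @return A tibble with columns `genotype`, `variable`, `category`,
#'   `count`, `n`, `proportion`, `ci_low`, `ci_high`.
#' @export
score_population <- function(calls, n_target = 50) {
  if (!is.data.frame(calls) || nrow(calls) == 0) {
    stop("`calls` must be a non-empty data frame", call. = FALSE)
  }
  vars <- list(
    rec8_pattern = REC8_LEVELS,
    cen5_class = CEN5_LEVELS,
    biosensor_state = c("INTACT", "CLEAVED"),
    divisions = c("1", "2")
  )
  vars <- vars[names(vars) %in% names(calls)]
  rows <- list()
  for (gt in unique(calls$genotype)) {
    sub <- calls[calls$genotype == gt, ]
    for (v in names(vars)) {
      obs <- as.character(sub[[v]])
      obs <- obs[!is.na(obs)]
      n <- length(obs)
      if (n == 0) next
      if (n < n_target) {
        warning("genotype ", gt, ": only ", n, " scorable cells for ", v,
                " (target ", n_target, ")", call. = FALSE)
      }
      for (lev in vars[[v]]) {
        k <- sum(obs == lev)
        ci <- stats::binom.test(k, n)$conf.int
        rows[[length(rows) + 1]] <- tibble::tibble(
          genotype = gt, variable = v, category = lev, count = k, n = n,
          proportion = k / n, ci_low = ci[1], ci_high = ci[2])
      }
    }
  }
  dplyr::bind_rows(rows)
}
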