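#' Simulate one cell's meiotic segregation outcome
#'
#' Draws a single cell through meiosis I (and meiosis II where it occurs)
#' under the categorical rules of its genotype. With probability
#' `p_monoorient` the sister kinetochores of the tracked chromosome co-orient
#' to one pole (a single centromere-marker focus in anaphase I); otherwise
#' each sister attaches independently and uniformly at random to one of the
#' two poles, so bi-orientation occurs in half of such cells. Bi-oriented
#' sisters whose pericentromeric cohesin is protected (or cannot be cleaved)
#' split only over short distances; bi-oriented sisters that lose cohesin
#' separate far. The cohesin localization pattern at anaphase I follows
#' cleavage competence and protection: pericentromeric retention when both
#' are intact, retention everywhere when cleavage fails, absence when
#' cleavage proceeds without protection.
#'
#' @param g A [genotype_params()] object.
#' @param seed Integer seed; the outcome is deterministic given `(g, seed)`.
#' @return A `cell_outcome`: list with fields `genotype`, `biorientation_mi`,
#'   `cen5_class_mi` (`SINGLE_FOCUS`/`SPLIT_CLOSE`/`SPLIT_FAR`),
#'   `rec8_pattern_ana1` (`PERICENTROMERIC`/`RETAINED_EVERYWHERE`/`ABSENT`),
#'   `divisions` (1 or 2), `cen5_spore_distribution` (integer vector summing
#'   to 2, one entry per spore/nucleus), `rng_seed`.
#' @export
simulate_cell <- function(g, seed) {
  if (!inherits(g, "genotype_params")) {
    stop("parameter error: `g` must be a genotype_params object", call. = FALSE)
  }
  stopifnot(is.numeric(seed), length(seed) == 1)
  with_seed(seed, {
    # -- meiosis I orientation --------------------------------------------
    if (g$forced_biorientation) {
      coorient <- FALSE
      biorient <- TRUE
    } else if (stats::runif(1) < g$p_monoorient) {
      coorient <- TRUE
      biorient <- FALSE
    } else {
      poles <- sample(c(1L, 2L), 2, replace = TRUE)
      coorient <- FALSE
      biorient <- poles[1] != poles[2]
    }

    # -- anaphase I centromere-marker class -------------------------------
    if (!biorient) {
      cen5_class <- "SINGLE_FOCUS"
      together <- TRUE
    } else if (!g$cleavage_on) {
      cen5_class <- "SPLIT_CLOSE"   # pulled apart but never released
      together <- TRUE
    } else if (g$protection_on) {
      cen5_class <- "SPLIT_CLOSE"
      together <- TRUE
    } else if (g$p_transient_cohesion > 0 &&
               stats::runif(1) < g$p_transient_cohesion) {
      cen5_class <- "SPLIT_CLOSE"
      together <- TRUE
    } else {
      cen5_class <- "SPLIT_FAR"
      together <- FALSE
    }

    # -- cohesin pattern at anaphase I ------------------------------------
    rec8 <- if (!g$cleavage_on) {
      "RETAINED_EVERYWHERE"
    } else if (g$protection_on) {
      "PERICENTROMERIC"
    } else {
      "ABSENT"
    }

    divisions <- if (g$second_division_on) 2L else 1L

    # -- meiosis I nuclei (2 tagged chromatids total) ---------------------
    mi <- if (together) {
      side <- sample(c(1L, 2L), 1)
      if (side == 1L) c(2L, 0L) else c(0L, 2L)
    } else {
      c(1L, 1L)
    }

    # -- meiosis II: each nucleus divides into two spores -----------------
    if (divisions == 2L) {
      spores <- integer(0)
      for (count in mi) {
        pair <- if (count == 2L) {
          if (stats::runif(1) < g$p_missegregate_mii) {
            if (sample(c(1L, 2L), 1) == 1L) c(2L, 0L) else c(0L, 2L)
          } else {
            c(1L, 1L)
          }
        } else if (count == 1L) {
          if (sample(c(1L, 2L), 1) == 1L) c(1L, 0L) else c(0L, 1L)
        } else {
          c(0L, 0L)
        }
        spores <- c(spores, pair)
      }
    } else {
      spores <- mi
    }

    structure(
      list(genotype = g$name,
           biorientation_mi = biorient,
           cen5_class_mi = cen5_class,
           rec8_pattern_ana1 = rec8,
           divisions = divisions,
           cen5_spore_distribution = spores,
           rng_seed = as.integer(seed)),
      class = "cell_outcome"
    )
  })
}

CEN5_LEVELS <- c("SINGLE_FOCUS", "SPLIT_CLOSE", "SPLIT_FAR")
REC8_LEVELS <- c("PERICENTROMERIC", "RETAINED_EVERYWHERE", "ABSENT")

#' Simulate a population of cells and tabulate outcome frequencies
#'
#' Runs [simulate_cell()] on `n` independent substreams derived from `seed`
#' via [substream_seed()] (so the population is reproducible regardless of
#' evaluation order) and tabulates category frequencies with exact binomial
#' 95% confidence intervals.
#'
#' @param g A [genotype_params()] object.
#' @param n Number of cells (`>= 1`).
#' @param seed Integer master seed.
#' @return A `segregation_population`: list with `outcomes` (one row per
#'   cell) and `frequencies` (columns `genotype`, `variable`, `category`,
#'   `count`, `proportion`, `ci_low`, `ci_high`).
#' @export
simulate_population <- function(g, n, seed) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  cells <- lapply(seq_len(n), function(i) simulate_cell(g, substream_seed(seed, i)))
  outcomes <- tibble::tibble(
    cell_id = sprintf("%s_c%04d", g$name, seq_len(n)),
    genotype = g$name,
    biorientation_mi = vapply(cells, `[[`, logical(1), "biorientation_mi"),
    cen5_class_mi = vapply(cells, `[[`, character(1), "cen5_class_mi"),
    rec8_pattern_ana1 = vapply(cells, `[[`, character(1), "rec8_pattern_ana1"),
    divisions = vapply(cells, `[[`, integer(1), "divisions"),
    cen5_spore_distribution = vapply(
      cells, function(x) paste(x$cen5_spore_distribution, collapse = ","),
      character(1)),
    rng_seed = vapply(cells, `[[`, integer(1), "rng_seed")
  )
  frequencies <- tabulate_outcomes(outcomes)
  structure(
    list(genotype = g$name, params = g, n = n, seed = as.integer(seed),
         outcomes = outcomes, frequencies = frequencies),
    class = "segregation_population"
  )
}

#' Tabulate outcome categories with exact binomial confidence intervals
#'
#' @param outcomes A tibble of per-cell outcomes (as in
#'   [simulate_population()]'s `outcomes` element).
#' @return A tibble with one row per genotype x variable x category.
#' @export
tabulate_outcomes <- function(outcomes) {
  vars <- list(
    cen5_class_mi = CEN5_LEVELS,
    rec8_pattern_ana1 = REC8_LEVELS,
    biorientation_mi = c("FALSE", "TRUE"),
    divisions = c("1", "2")
  )
  rows <- list()
  for (gt in unique(outcomes$genotype)) {
    sub <- outcomes[outcomes$genotype == gt, ]
    n <- nrow(sub)
    for (v in names(vars)) {
      obs <- as.character(sub[[v]])
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

#' @export
print.segregation_population <- function(x, ...) {
  cat("<segregation_population> ", x$genotype, ": ", x$n, " cells (seed ",
      x$seed, ")\n", sep = "")
  print(x$frequencies[x$frequencies$count > 0, ], n = 20)
  invisible(x)
}
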