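#' Summarize calls and intensities, with Welch tests against a reference
#'
#' Builds the reporting layer: per-genotype pericentromeric-intensity means
#' with standard errors, pairwise Welch two-sample t-tests of every genotype
#' against a declared reference genotype with figure-legend style
#' annotations (`***` p < 0.001, `**` p < 0.01, `n.s.` otherwise; raw
#' p-values, no multiple-testing correction), and category frequency tables.
#'
#' @param calls Tibble of per-cell calls (as from [analyze_movie()]), with
#'   `genotype` and `pericentromeric_intensity` columns.
#' @param reference Reference genotype name for pairwise tests. `NULL` is
#'   allowed only when a single genotype is present (frequency table only).
#' @param n_target Passed to [score_population()].
#' @return A `phenotype_report`: list with `summary`, `tests` (possibly
#'   empty), `frequencies`.
#' @export
report_run <- function(calls, reference = NULL, n_target = 50) {
  genotypes <- unique(calls$genotype)
  if (is.null(reference)) {
    if (length(genotypes) > 1) {
      stop("config error: `reference` genotype required for multi-genotype input",
           call. = FALSE)
    }
  } else if (!reference %in% genotypes) {
    stop("config error: reference genotype `", reference,
         "` not present in calls", call. = FALSE)
  }

  summary_tbl <- dplyr::bind_rows(lapply(genotypes, function(gt) {
    v <- calls$pericentromeric_intensity[calls$genotype == gt]
    v <- v[!is.na(v)]
    tibble::tibble(
      genotype = gt, n = length(v),
      mean_intensity = if (length(v)) mean(v) else NA_real_,
      sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }))

  tests <- tibble::tibble()
  if (!is.null(reference) && length(genotypes) > 1) {
    ref_v <- calls$pericentromeric_intensity[calls$genotype == reference]
    ref_v <- ref_v[!is.na(ref_v)]
    tests <- dplyr::bind_rows(lapply(setdiff(genotypes, reference), function(gt) {
      v <- calls$pericentromeric_intensity[calls$genotype == gt]
      v <- v[!is.na(v)]
      if (length(v) < 2 || length(ref_v) < 2) {
        return(tibble::tibble(genotype = gt, reference = reference,
                              t_statistic = NA_real_, df = NA_real_,
                              p_value = NA_real_, annotation = NA_character_))
      }
      w <- welch_t_test(v, ref_v)
      tibble::tibble(genotype = gt, reference = reference,
                     t_statistic = w$t_statistic, df = w$df,
                     p_value = w$p_value,
                     annotation = significance_stars(w$p_value))
    }))
  }

  structure(
    list(summary = summary_tbl, tests = tests,
         frequencies = score_population(calls, n_target = n_target)),
    class = "phenotype_report"
  )
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat("<phenotype_report>\n-- intensity summary --\n")
  print(x$summary)
  if (nrow(x$tests)) {
    cat("-- Welch tests vs reference --\n")
    print(x$tests)
  }
  cat("-- frequencies (non-zero) --\n")
  print(x$frequencies[x$frequencies$count > 0, ], n = 30)
  invisible(x)
}

#' Write a phenotype report to CSV files plus a plain-text summary
#'
#' Writes `summary.csv`, `tests.csv`, `frequencies.csv` and `summary.txt`
#' into `dir`.
#'
#' @param report A `phenotype_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "phenotype_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(report$tests, file.path(dir, "tests.csv"), row.names = FALSE)
  utils::write.csv(report$frequencies, file.path(dir, "frequencies.csv"),
                   row.names = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "summary.txt"))
  invisible(dir)
}
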