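#' Render-and-measure a sample of per-cell spot intensities
#'
#' Light-weight single-frame variant of the movie renderer used for
#' statistical calibration experiments: `n` cells, each with one red
#' kinetochore focus and a co-located green focus of the given amplitude,
#' are placed on a grid, corrupted with the Poisson-Gaussian camera model,
#' and then measured exactly as the pipeline measures pericentromeric
#' signal (Yen threshold on the red channel, 8-connected components,
#' mean green intensity over each red footprint, background-median
#' subtraction).
#'
#' @param n Number of cells/spots.
#' @param amplitude Peak green amplitude above background, counts.
#' @param seed Integer seed.
#' @param cfg An [imaging_config()]; only its PSF/noise/background fields
#'   are used.
#' @param box_px Pixels per cell box (default 24).
#' @param min_area Minimum spot area, px.
#' Each cell is rendered and measured in its own crop with its own Yen
#' threshold, exactly as [analyze_movie()] treats cell regions - so
#' measurement variability (photon noise, threshold quantization, footprint
#' size) is independent between cells.
#'
#' @return Numeric vector of background-subtracted per-cell green
#'   intensities, length `n` (`NA`-free; cells with no detected spot,
#'   which essentially never occur at the default amplitudes, are dropped).
#' @export
simulated_intensity_sample <- function(n, amplitude, seed,
                                       cfg = imaging_config(),
                                       box_px = 24, min_area = 2) {
  stopifnot(n >= 1)
  with_seed(seed, {
    vals <- vapply(seq_len(n), function(i) {
      red <- matrix(cfg$background_level, box_px, box_px)
      green <- matrix(cfg$background_level, box_px, box_px)
      c0 <- (box_px + 1) / 2
      red <- add_gaussian_patch(red, c0, c0, cfg$psf_sigma_px,
                                cfg$amplitudes$kinetochore)
      if (amplitude > 0) {
        green <- add_gaussian_patch(green, c0, c0, cfg$psf_sigma_px, amplitude)
      }
      if (isTRUE(cfg$noise)) {
        g <- cfg$poisson_gain
        red[] <- pmax(round(stats::rpois(length(red), red * g) / g +
                              stats::rnorm(length(red), 0, cfg$read_noise_sd)), 0)
        green[] <- pmax(round(stats::rpois(length(green), green * g) / g +
                                stats::rnorm(length(green), 0, cfg$read_noise_sd)), 0)
      }
      spots <- detect_spots(red, min_area = min_area)
      if (nrow(spots) == 0) return(NA_real_)
      spots <- measure_cross_channel(spots[1, ], green)
      spots$cross_channel_mean[1] - stats::median(green)
    }, numeric(1))
    vals[!is.na(vals)]
  })
}

#' Rejection-rate calibration of the Welch test on rendered nulls
#'
#' Repeats, for `n_comparisons` seeded rounds, the comparison of two
#' independently rendered populations with *equal* green amplitudes, and
#' returns the fraction of rounds rejected at level `alpha`. Under the null
#' this should match `alpha` up to binomial error.
#'
#' @param n_comparisons Number of seeded comparisons.
#' @param n_cells Cells per population (default 50).
#' @param amplitude Common green amplitude (default the rec8 amplitude).
#' @param alpha Test level (default 0.05).
#' @param seed Master seed; each round draws two substreams.
#' @param cfg An [imaging_config()].
#' @return List with `rejection_rate`, `n_comparisons`, `alpha`, and the
#'   vector `p_values`.
#' @export
welch_null_calibration <- function(n_comparisons, n_cells = 50,
                                   amplitude = NULL, alpha = 0.05,
                                   seed = 1, cfg = imaging_config()) {
  if (is.null(amplitude)) amplitude <- cfg$amplitudes$rec8
  p_values <- vapply(seq_len(n_comparisons), function(i) {
    x <- simulated_intensity_sample(n_cells, amplitude,
                                    substream_seed(seed, 2L * i - 1L), cfg)
    y <- simulated_intensity_sample(n_cells, amplitude,
                                    substream_seed(seed, 2L * i), cfg)
    welch_t_test(x, y)$p_value
  }, numeric(1))
  list(rejection_rate = mean(p_values < alpha),
       n_comparisons = n_comparisons, alpha = alpha, p_values = p_values)
}

#' Power of the protection-effect comparison at the default effect size
#'
#' Renders, for each seeded run, a protection-on population (full green
#' amplitude at kinetochore footprints) against a protection-off population
#' (no pericentromeric green signal) at `n_cells` cells each, and records
#' the Welch p-value.
#'
#' @inheritParams welch_null_calibration
#' @param n_runs Number of seeded runs.
#' @return List with `fraction_below_001` (fraction of runs with
#'   p < 0.001) and `p_values`.
#' @export
protection_effect_power <- function(n_runs, n_cells = 50, seed = 1,
                                    cfg = imaging_config()) {
  amp <- cfg$amplitudes$rec8
  p_values <- vapply(seq_len(n_runs), function(i) {
    on <- simulated_intensity_sample(n_cells, amp,
                                     substream_seed(seed, 2L * i - 1L), cfg)
    off <- simulated_intensity_sample(n_cells, 0,
                                      substream_seed(seed, 2L * i), cfg)
    welch_t_test(on, off)$p_value
  }, numeric(1))
  list(fraction_below_001 = mean(p_values < 0.001), p_values = p_values)
}
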