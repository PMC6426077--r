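# Crop one cell's box out of a projected frame.
crop_frame <- function(proj, t, role, box) {
  m <- frame_image(proj, t, role = role)
  m[box$y0:box$y1, box$x0:box$x1, drop = FALSE]
}

#' Extract a background-subtracted securin trace for one cell
#'
#' Mean red-securin intensity over a central nuclear disc, minus the median
#' of the crop's border ring (local background), per frame.
#'
#' @param proj A `projected_stack`.
#' @param box List/row with `y0`, `y1`, `x0`, `x1` (1-based, inclusive).
#' @param disc_radius_um Radius of the measurement disc (default 2 um).
#' @param border_px Width of the background border ring (default 2 px).
#' @return Numeric vector, one value per frame.
#' @export
securin_trace <- function(proj, box, disc_radius_um = 2, border_px = 2) {
  n_frames <- dim(proj$data)[1]
  r_px <- disc_radius_um / proj$pixel_size_um
  ny <- box$y1 - box$y0 + 1
  nx <- box$x1 - box$x0 + 1
  cy <- (ny + 1) / 2
  cx <- (nx + 1) / 2
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  disc <- (yy - cy)^2 + (xx - cx)^2 <= r_px^2
  border <- yy <= border_px | yy > ny - border_px |
    xx <= border_px | xx > nx - border_px
  vapply(seq_len(n_frames), function(t) {
    m <- crop_frame(proj, t, "RED_SECURIN", box)
    mean(m[disc]) - stats::median(m[border])
  }, numeric(1))
}

#' Run the full per-cell measurement pipeline on a movie
#'
#' For each cell region: z-projects the stack, extracts the securin trace and
#' detects anaphase onset, then scores the marker-appropriate phenotype in
#' the post-onset window (cohesin pattern, centromere-marker distance class,
#' or biosensor state), counts divisions from the final-frame kinetochore
#' foci, and measures the nuclear-mass area ratio from the histone channel.
#'
#' @param x A `synthetic_movie` (cells and marker taken from its ground
#'   truth) or an `image_stack`.
#' @param cells Tibble of cell regions (`cell_id`, `y0`, `y1`, `x0`, `x1`);
#'   required when `x` is a plain stack.
#' @param marker `"rec8"`, `"cen5"` or `"biosensor"`; required when `x` is a
#'   plain stack.
#' @param projection `"max"` (default) or `"mean"`.
#' @param mode Pericentromeric quantification mode for rec8 calls:
#'   `"line"` (default) or `"dot"`.
#' @param k_sigma,min_area,retained_area_um2,max_focus_area_um2 Detection
#'   and calling parameters (see the call functions).
#' @param drop_fraction,sustain Onset-detection parameters.
#' @return A tibble with one row per cell: `cell_id`, `genotype`, `marker`,
#'   `onset_frame`, `rec8_pattern`, `pericentromeric_intensity`,
#'   `cen5_class`, `max_sep_um`, `biosensor_state`, `divisions`,
#'   `n_foci_final`, `area_ratio`, `flags` (`;`-joined).
#' @export
analyze_movie <- function(x, cells = NULL, marker = NULL,
                          projection = c("max", "mean"),
                          mode = c("line", "dot"),
                          k_sigma = 3, min_area = 4, retained_area_um2 = 3,
                          max_focus_area_um2 = 1.2,
                          drop_fraction = 0.5, sustain = 2) {
  projection <- match.arg(projection)
  mode <- match.arg(mode)
  if (inherits(x, "synthetic_movie")) {
    stack <- x$stack
    if (is.null(cells)) cells <- x$truth$cells
    if (is.null(marker)) marker <- x$marker
  } else if (inherits(x, "image_stack")) {
    stack <- x
    if (is.null(cells) || is.null(marker)) {
      stop("`cells` and `marker` are required for a plain image_stack",
           call. = FALSE)
    }
  } else {
    stop("`x` must be a synthetic_movie or image_stack", call. = FALSE)
  }
  proj <- z_project(stack, projection)
  n_frames <- dim(proj$data)[1]
  ps <- proj$pixel_size_um
  has_histone <- "RED_HISTONE" %in% names(proj$channel_roles)

  rows <- lapply(seq_len(nrow(cells)), function(i) {
    box <- as.list(cells[i, c("y0", "y1", "x0", "x1")])
    flags <- character(0)
    trace <- securin_trace(proj, box)
    onset <- detect_onset(trace, drop_fraction = drop_fraction, sustain = sustain)

    rec8_pattern <- NA_character_; peri_int <- NA_real_
    cen5_class <- NA_character_; max_sep <- NA_real_
    bio_state <- NA_character_

    if (is.na(onset)) {
      flags <- c(flags, "no_onset")
      window <- NULL
    } else {
      w <- scoring_window(onset, proj$frame_interval_min, n_frames)
      if (w$truncated) flags <- c(flags, "window_truncated")
      window <- w$frames
    }

    if (!is.null(window)) {
      green_w <- lapply(window, function(t) crop_frame(proj, t, "GREEN_MARKER", box))
      red_w <- lapply(window, function(t) crop_frame(proj, t, "RED_KINETOCHORE", box))
      if (marker == "rec8") {
        res <- call_rec8_pattern(green_w, red_w, ps, mode = mode,
                                 k_sigma = k_sigma, min_area = min_area,
                                 retained_area_um2 = retained_area_um2)
        rec8_pattern <- res$pattern
        peri_int <- res$intensity
        flags <- c(flags, res$flags)
      } else if (marker == "cen5") {
        spots_w <- lapply(green_w, detect_foci, k_sigma = k_sigma,
                          min_area = min_area)
        res <- call_cen5_class(spots_w, ps)
        cen5_class <- res$class
        max_sep <- res$max_sep_um
        flags <- c(flags, res$flags)
      } else {
        res <- call_biosensor(green_w, ps, k_sigma = k_sigma,
                              min_area = min_area,
                              max_focus_area_um2 = max_focus_area_um2)
        bio_state <- res$state
        flags <- c(flags, res$flags)
      }
    }

    red_final <- crop_frame(proj, n_frames, "RED_KINETOCHORE", box)
    div <- count_divisions(red_final, k_sigma = k_sigma, min_area = min_area)
    flags <- c(flags, div$flags)

    area_ratio <- NA_real_
    if (has_histone) {
      hist_final <- crop_frame(proj, n_frames, "RED_HISTONE", box)
      area_ratio <- tryCatch(
        nuclear_area_ratio(hist_final, expected_masses = 2L * div$divisions),
        error = function(e) {
          flags <<- c(flags, "mass_count_mismatch")
          NA_real_
        })
    }

    tibble::tibble(
      cell_id = cells$cell_id[i],
      genotype = if ("genotype" %in% names(cells)) cells$genotype[i] else NA_character_,
      marker = marker,
      onset_frame = onset,
      rec8_pattern = rec8_pattern,
      pericentromeric_intensity = peri_int,
      cen5_class = cen5_class,
      max_sep_um = max_sep,
      biosensor_state = bio_state,
      divisions = div$divisions,
      n_foci_final = div$n_foci,
      area_ratio = area_ratio,
      flags = paste(unique(flags), collapse = ";"))
  })
  dplyr::bind_rows(rows)
}

#' Simulate, render and analyze one genotype end-to-end
#'
#' Convenience wrapper chaining [simulate_population()], [render_movie()]
#' and [analyze_movie()], joining the per-cell calls to ground truth and
#' marking agreement per call type.
#'
#' @param g A [genotype_params()] object or a preset name.
#' @param n Number of cells.
#' @param seed Integer seed (simulation and rendering use derived
#'   substreams).
#' @param marker Green-channel marker to render and score.
#' @param cfg An [imaging_config()].
#' @param ... Passed to [analyze_movie()].
#' @return A tibble of per-cell calls with ground-truth columns (suffix
#'   `_true`) and logical columns `onset_match`, `divisions_match`, and the
#'   marker-relevant `call_match`.
#' @export
run_genotype_experiment <- function(g, n, seed, marker = "rec8",
                                    cfg = imaging_config(), ...) {
  if (is.character(g)) g <- genotype_presets(g)
  pop <- simulate_population(g, n, substream_seed(seed, 1))
  movie <- render_movie(pop$outcomes, cfg, substream_seed(seed, 2), marker = marker)
  calls <- analyze_movie(movie, ...)
  truth <- movie$truth$cells[, c("cell_id", "onset_frame", "divisions",
                                 "cen5_class", "rec8_pattern",
                                 "biosensor_cleaved", "sep_um")]
  names(truth) <- c("cell_id", "onset_frame_true", "divisions_true",
                    "cen5_class_true", "rec8_pattern_true",
                    "biosensor_cleaved_true", "sep_um_true")
  out <- dplyr::left_join(calls, truth, by = "cell_id")
  out$onset_match <- !is.na(out$onset_frame) &
    out$onset_frame == out$onset_frame_true
  out$divisions_match <- out$divisions == out$divisions_true
  out$call_match <- switch(
    marker,
    rec8 = !is.na(out$rec8_pattern) & out$rec8_pattern == out$rec8_pattern_true,
    cen5 = !is.na(out$cen5_class) & out$cen5_class == out$cen5_class_true,
    biosensor = !is.na(out$biosensor_state) &
      out$biosensor_state == ifelse(out$biosensor_cleaved_true, "CLEAVED", "INTACT"))
  out
}
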