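# Robust background statistics of a 2-D crop: median and MAD (scaled to be
# consistent with a Gaussian sigma). Signal is sparse in these crops, so the
# global median/MAD estimate the camera background.
background_stats <- function(image) {
  list(median = stats::median(image), sigma = stats::mad(image))
}

# Background statistics from the crop's border ring only - robust even when
# diffuse signal (chromatin-wide cohesin, securin) fills the crop interior.
border_stats <- function(image, border_px = 3) {
  ny <- nrow(image); nx <- ncol(image)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ring <- image[yy <= border_px | yy > ny - border_px |
                  xx <= border_px | xx > nx - border_px]
  list(median = stats::median(ring), sigma = stats::mad(ring))
}

# Distance (px) from point (py, px_) to the segment a-b (each c(y, x)).
dist_point_segment <- function(py, px_, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((py - a[1])^2 + (px_ - a[2])^2))
  t <- ((py - a[1]) * ab[1] + (px_ - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((py - (a[1] + t * ab[1]))^2 + (px_ - (a[2] + t * ab[2]))^2)
}

# Detect candidate foci in a crop: Yen threshold, 8-connected components,
# then a contrast filter (component mean must exceed background median by
# k * sigma). Returns the detect_spots() tibble (possibly empty).
detect_foci <- function(image, k_sigma = 3, min_area = 4, levels = 256) {
  bg <- background_stats(image)
  thr <- tryCatch(yen_threshold(image, levels = levels), error = function(e) NULL)
  if (is.null(thr)) return(detect_spots(image, threshold = Inf, min_area = min_area))
  spots <- detect_spots(image, threshold = thr, min_area = min_area)
  spots[spots$mean_intensity - bg$median > k_sigma * max(bg$sigma, 1), ]
}

#' Classify the centromere-marker (GFP dot) configuration of one cell
#'
#' Applies the 2-um rule to green foci detected within the scoring window:
#' one focus is `SINGLE_FOCUS`; two foci whose maximum centroid separation
#' across the window is at most 2 um are `SPLIT_CLOSE`; beyond 2 um,
#' `SPLIT_FAR`. The boundary value of exactly 2.0 um is assigned to
#' `SPLIT_CLOSE` (closed upper bound; a convention that must be fixed, and
#' is).
#'
#' @param spots_by_frame List of [detect_spots()] tibbles, one per window
#'   frame (green channel).
#' @param pixel_size_um Pixel size, um.
#' @return List with `class` (`SINGLE_FOCUS` / `SPLIT_CLOSE` / `SPLIT_FAR`
#'   or `NA`), `max_sep_um`, and `flags` (character vector).
#' @export
call_cen5_class <- function(spots_by_frame, pixel_size_um) {
  counts <- vapply(spots_by_frame, nrow, integer(1))
  if (any(counts > 2)) {
    return(list(class = NA_character_, max_sep_um = NA_real_,
                flags = "more_than_two_foci"))
  }
  if (all(counts == 0)) {
    return(list(class = NA_character_, max_sep_um = NA_real_,
                flags = "no_foci"))
  }
  seps <- vapply(spots_by_frame, function(s) {
    if (nrow(s) == 2) {
      sqrt((s$centroid_y[1] - s$centroid_y[2])^2 +
             (s$centroid_x[1] - s$centroid_x[2])^2) * pixel_size_um
    } else NA_real_
  }, numeric(1))
  if (all(is.na(seps))) {
    return(list(class = "SINGLE_FOCUS", max_sep_um = 0, flags = character(0)))
  }
  max_sep <- max(seps, na.rm = TRUE)
  cls <- if (max_sep <= 2.0) "SPLIT_CLOSE" else "SPLIT_FAR"
  list(class = cls, max_sep_um = max_sep, flags = character(0))
}

#' Call the cohesin (Rec8) localization pattern of one cell at anaphase I
#'
#' For each scoring-window frame: detect kinetochore foci in the red crop,
#' then decide among the three patterns using border-ring background
#' statistics (robust even when signal fills the crop interior).
#' `RETAINED_EVERYWHERE` is called when the supra-background green area is
#' large (chromatin-wide signal, default > `retained_area_um2`);
#' `PERICENTROMERIC` when a compact green focus lies within `corridor_um` of
#' the segment joining the two brightest kinetochore foci (pericentromeric
#' cohesin sits at, or between, the kinetochores); `ABSENT` otherwise. The
#' per-frame pericentromeric intensity is quantified either as the mean of
#' the two brightest green peaks on the line connecting the two kinetochores
#' (`mode = "line"`, the measure used for bi-orienting cells) or as the mean
#' green intensity over the red kinetochore footprints (`mode = "dot"`, the
#' co-localization measure), background-median subtracted; the returned
#' intensity is its window mean, reported for every pattern so that
#' genotype contrasts include signal-free cells.
#'
#' @param green_frames,red_frames Lists of 2-D crops (same order, one per
#'   window frame).
#' @param pixel_size_um Pixel size, um.
#' @param mode `"line"` (default) or `"dot"` - how the intensity value is
#'   measured.
#' @param k_sigma Presence threshold in background SDs (default 3).
#' @param min_area Minimum spot area, px.
#' @param retained_area_um2 Supra-background green area above which the
#'   pattern is chromatin-wide (default 3 um^2).
#' @param corridor_um Maximum distance of a green focus from the
#'   inter-kinetochore segment to count as pericentromeric (default
#'   0.75 um).
#' @return List with `pattern`, `intensity` (background-subtracted
#'   pericentromeric value), and `flags`.
#' @export
call_rec8_pattern <- function(green_frames, red_frames, pixel_size_um,
                              mode = c("line", "dot"), k_sigma = 3,
                              min_area = 4, retained_area_um2 = 3,
                              corridor_um = 0.75) {
  mode <- match.arg(mode)
  stopifnot(length(green_frames) == length(red_frames), length(green_frames) >= 1)
  patterns <- character(0)
  values <- numeric(0)
  flags <- character(0)
  for (j in seq_along(green_frames)) {
    green <- green_frames[[j]]
    red <- red_frames[[j]]
    kin <- detect_foci(red, k_sigma = k_sigma, min_area = min_area)
    if (nrow(kin) == 0) next
    bg <- border_stats(green)
    sig <- max(bg$sigma, 1)

    # chromatin-wide signal?
    green_area_um2 <- sum(green > bg$median + k_sigma * sig) * pixel_size_um^2
    if (green_area_um2 > retained_area_um2) {
      patterns <- c(patterns, "RETAINED_EVERYWHERE")
      values <- c(values, NA_real_)
      next
    }

    # compact green foci near the inter-kinetochore axis?
    a <- c(kin$centroid_y[1], kin$centroid_x[1])
    b <- if (nrow(kin) >= 2) c(kin$centroid_y[2], kin$centroid_x[2]) else a
    foci <- detect_foci(green, k_sigma = k_sigma, min_area = min_area)
    near <- if (nrow(foci)) {
      dist_point_segment(foci$centroid_y, foci$centroid_x, a, b) *
        pixel_size_um <= corridor_um
    } else logical(0)
    patterns <- c(patterns, if (any(near)) "PERICENTROMERIC" else "ABSENT")

    # intensity value
    val <- if (mode == "dot" || nrow(kin) < 2) {
      if (mode == "line") flags <- c(flags, "single_kinetochore_focus")
      kin2 <- measure_cross_channel(kin, green)
      mean(kin2$cross_channel_mean) - bg$median
    } else {
      pr <- tryCatch(line_profile(a, b, list(green = green)),
                     error = function(e) NULL)
      if (is.null(pr)) {
        flags <- c(flags, "degenerate_profile")
        NA_real_
      } else {
        tp <- two_peak_intensity(pr, "green")
        if (tp$fallback) flags <- c(flags, "single_peak_fallback")
        tp$mean - bg$median
      }
    }
    values <- c(values, val)
  }
  if (!length(patterns)) {
    return(list(pattern = NA_character_, intensity = NA_real_,
                flags = c(flags, "no_kinetochore_spots")))
  }
  pattern <- names(sort(table(patterns), decreasing = TRUE))[1]
  list(pattern = pattern,
       intensity = if (all(is.na(values))) NA_real_ else mean(values, na.rm = TRUE),
       flags = unique(flags))
}

#' Call the separase-biosensor state of one cell
#'
#' `INTACT` when a compact green focus (contrast above `k_sigma` background
#' SDs and area at most `max_focus_area_um2`) persists through every scoring
#' window frame; `CLEAVED` when the green signal is diffuse (no such focus)
#' in the window. A blank green channel is called `CLEAVED` and flagged
#' low-signal.
#'
#' @param green_frames List of green crops, one per window frame.
#' @param pixel_size_um Pixel size, um.
#' @param k_sigma Contrast threshold (default 3).
#' @param min_area Minimum focus area, px.
#' @param max_focus_area_um2 Maximum area of a compact focus, um^2.
#' @return List with `state` (`INTACT`/`CLEAVED`) and `flags`.
#' @export
call_biosensor <- function(green_frames, pixel_size_um, k_sigma = 3,
                           min_area = 4, max_focus_area_um2 = 1.2) {
  max_area_px <- max_focus_area_um2 / pixel_size_um^2
  has_focus <- vapply(green_frames, function(green) {
    foci <- detect_foci(green, k_sigma = k_sigma, min_area = min_area)
    any(foci$area_px <= max_area_px)
  }, logical(1))
  low_signal <- vapply(green_frames, function(green) {
    bg <- background_stats(green)
    !any(green > bg$median + k_sigma * max(bg$sigma, 1))
  }, logical(1))
  list(state = if (all(has_focus)) "INTACT" else "CLEAVED",
       flags = if (any(low_signal)) "low_signal" else character(0))
}

#' Count meiotic divisions from the final-frame kinetochore foci
#'
#' Two divisions are called when at least four distinct kinetochore foci are
#' present after meiosis II; otherwise one. Exactly three foci is ambiguous
#' and flagged.
#'
#' @param red_final 2-D red-channel crop of the final frame.
#' @param k_sigma,min_area Focus detection parameters.
#' @return List with `divisions` (1 or 2), `n_foci`, `flags`.
#' @export
count_divisions <- function(red_final, k_sigma = 3, min_area = 4) {
  foci <- detect_foci(red_final, k_sigma = k_sigma, min_area = min_area)
  n <- nrow(foci)
  list(divisions = if (n >= 4) 2L else 1L,
       n_foci = n,
       flags = if (n == 3) "ambiguous_three_foci" else character(0))
}

#' Ratio of the largest to the smallest nuclear mass
#'
#' Thresholds the histone channel with [yen_threshold()], labels the
#' 8-connected bright regions, keeps the `expected_masses` largest, and
#' returns the ratio of the largest to the smallest area. A ratio near 1
#' indicates even chromosome partitioning; large ratios indicate gross
#' missegregation.
#'
#' @param histone_image 2-D histone-channel crop (finite values).
#' @param expected_masses Number of nuclear masses expected (2 after one
#'   division, 4 after two).
#' @return The area ratio (`>= 1`).
#' @export
nuclear_area_ratio <- function(histone_image, expected_masses) {
  stopifnot(expected_masses >= 2)
  thr <- yen_threshold(histone_image)
  lab <- label_components_8(histone_image > thr)
  areas <- tabulate(lab[lab > 0])
  areas <- sort(areas[areas > 0], decreasing = TRUE)
  if (length(areas) < expected_masses) {
    stop("found ", length(areas), " nuclear mass(es) but expected ",
         expected_masses, call. = FALSE)
  }
  kept <- areas[seq_len(expected_masses)]
  max(kept) / min(kept)
}
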