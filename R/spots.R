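# 8-connected component labeling. EBImage::bwlabel is 4-connected, so labels
# that touch only diagonally are merged afterwards with a small union-find
# over the diagonal adjacencies.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  nlab <- max(lab)
  if (nlab == 0L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  if (nr > 1 && nc > 1) {
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
    keep1 <- a1 > 0 & b1 > 0 & a1 != b1
    keep2 <- a2 > 0 & b2 > 0 & a2 != b2
    pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  }
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(pairs) && nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Detect fluorescent spots as supra-threshold connected components
#'
#' Thresholds a 2-D (projected) channel image, labels the 8-connected
#' components of the strictly-supra-threshold mask, discards components
#' smaller than `min_area`, and records for each remaining component its
#' intensity-weighted centroid (sub-pixel, 1-based `(y, x)`), pixel
#' footprint, area and mean intensity. Spots are returned sorted by
#' descending mean intensity.
#'
#' @param image 2-D numeric matrix (finite values).
#' @param threshold Intensity threshold; foreground is `image > threshold`.
#'   Defaults to [yen_threshold()] of the image.
#' @param min_area Minimum component area in pixels (default 2, suppressing
#'   single-pixel noise).
#' @return A tibble with one row per spot: `spot_id`, `centroid_y`,
#'   `centroid_x`, `area_px`, `mean_intensity`, `cross_channel_mean` (`NA`
#'   until filled by [measure_cross_channel()]) and a `footprint` list-column
#'   of linear pixel indices into `image`.
#' @export
detect_spots <- function(image, threshold = yen_threshold(image), min_area = 2) {
  stopifnot(is.matrix(image))
  if (any(!is.finite(image))) stop("image must be finite-valued", call. = FALSE)
  mask <- image > threshold
  empty <- tibble::new_tibble(
    list(spot_id = integer(0), centroid_y = numeric(0),
         centroid_x = numeric(0), area_px = integer(0),
         mean_intensity = numeric(0), cross_channel_mean = numeric(0),
         footprint = list()),
    nrow = 0L)
  if (!any(mask)) return(empty)
  lab <- label_components_8(mask)
  idx <- which(lab > 0)
  labels <- lab[idx]
  areas <- tabulate(labels)
  keep <- which(areas >= min_area)
  if (!length(keep)) return(empty)
  nr <- nrow(image)
  rows_all <- ((idx - 1L) %% nr) + 1L
  cols_all <- ((idx - 1L) %/% nr) + 1L
  vals_all <- image[idx]
  nlab <- max(labels)
  f <- factor(labels, levels = seq_len(nlab))
  sw <- as.vector(rowsum(vals_all, f))
  sy <- as.vector(rowsum(rows_all * vals_all, f))
  sx <- as.vector(rowsum(cols_all * vals_all, f))
  sry <- as.vector(rowsum(rows_all + 0, f))
  srx <- as.vector(rowsum(cols_all + 0, f))
  areas_full <- tabulate(labels, nbins = nlab)
  cy <- ifelse(sw > 0, sy / sw, sry / areas_full)
  cx <- ifelse(sw > 0, sx / sw, srx / areas_full)
  footprints <- split(idx, f)
  mean_int <- sw[keep] / areas_full[keep]
  ord <- order(-mean_int)
  k <- keep[ord]
  tibble::new_tibble(
    list(spot_id = seq_along(k),
         centroid_y = cy[k], centroid_x = cx[k],
         area_px = as.integer(areas_full[k]),
         mean_intensity = mean_int[ord],
         cross_channel_mean = rep(NA_real_, length(k)),
         footprint = unname(footprints[k])),
    nrow = length(k))
}

#' Measure mean intensity of another channel over detected footprints
#'
#' For each spot detected in one channel (typically the red kinetochore
#' channel), computes the arithmetic mean of a second channel (typically the
#' green cohesin channel) over exactly the spot's pixel footprint. Footprints
#' are never re-derived from the second channel.
#'
#' @param spots Tibble from [detect_spots()].
#' @param other_channel 2-D matrix with the same dimensions as the detection
#'   image.
#' @param detection_dim Dimensions of the detection image, used to validate
#'   shape when `spots` is empty of footprints; defaults to
#'   `dim(other_channel)` check against footprint indices.
#' @return `spots` with `cross_channel_mean` filled.
#' @export
measure_cross_channel <- function(spots, other_channel, detection_dim = NULL) {
  stopifnot(is.matrix(other_channel))
  if (!is.null(detection_dim) && !identical(as.integer(detection_dim),
                                            as.integer(dim(other_channel)))) {
    stop("shape mismatch between detection image and `other_channel`",
         call. = FALSE)
  }
  if (nrow(spots) == 0) return(spots)
  max_idx <- length(other_channel)
  spots$cross_channel_mean <- vapply(spots$footprint, function(idx) {
    if (any(idx > max_idx)) {
      stop("shape mismatch between detection image and `other_channel`",
           call. = FALSE)
    }
    mean(other_channel[idx])
  }, numeric(1))
  spots
}
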