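# Bresenham rasterization between two pixel coordinates (1-based, inclusive).
bresenham_line <- function(y0, x0, y1, x1) {
  dy <- abs(y1 - y0); dx <- abs(x1 - x0)
  sy <- if (y0 < y1) 1L else -1L
  sx <- if (x0 < x1) 1L else -1L
  err <- dx - dy
  ys <- integer(0); xs <- integer(0)
  y <- y0; x <- x0
  repeat {
    ys <- c(ys, y); xs <- c(xs, x)
    if (y == y1 && x == x1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx)  { err <- err + dx; y <- y + sy }
  }
  cbind(y = ys, x = xs)
}

#' Sample a line profile between two kinetochore centroids
#'
#' Rasterizes a discrete (Bresenham) line from `a` to `b` (sub-pixel
#' centroids are rounded to pixels; endpoints inclusive) and samples every
#' supplied channel over exactly the same ordered pixel set, so that
#' intensities in different channels are directly comparable position by
#' position.
#'
#' @param a,b Numeric length-2 centroids `(y, x)`, 1-based.
#' @param images Named list of 2-D matrices (one per channel), all with equal
#'   dimensions.
#' @return A `line_profile`: list with `pixels` (tibble of `y`, `x`) and
#'   `values` (named list of numeric vectors, one per channel, equal length).
#' @export
line_profile <- function(a, b, images) {
  stopifnot(length(a) == 2, length(b) == 2, is.list(images), length(images) >= 1)
  dims <- lapply(images, dim)
  if (length(unique(lapply(dims, as.integer))) != 1) {
    stop("shape mismatch: all channel images must have equal dimensions",
         call. = FALSE)
  }
  p0 <- as.integer(round(a)); p1 <- as.integer(round(b))
  if (all(p0 == p1)) {
    stop("profile error: endpoints coincide after rounding to pixels",
         call. = FALSE)
  }
  d <- dim(images[[1]])
  if (any(c(p0, p1) < 1) || p0[1] > d[1] || p1[1] > d[1] ||
      p0[2] > d[2] || p1[2] > d[2]) {
    stop("profile error: endpoints outside the image", call. = FALSE)
  }
  px <- bresenham_line(p0[1], p0[2], p1[1], p1[2])
  values <- lapply(images, function(im) im[cbind(px[, "y"], px[, "x"])])
  structure(
    list(pixels = tibble::tibble(y = px[, "y"], x = px[, "x"]),
         values = values),
    class = "line_profile"
  )
}

#' Mean of the two brightest peaks along a line profile
#'
#' Collapses plateaus (runs of equal values) to single candidates, finds the
#' local maxima of the requested channel's intensity sequence (profile
#' endpoints are admissible maxima), and returns the arithmetic mean of the
#' two brightest. When the profile carries only one local maximum (e.g. a
#' monotonic ramp, or a single focus on the line), the second value falls
#' back to the global second-largest sample and the result is flagged.
#'
#' @param profile A `line_profile`.
#' @param channel Name of the channel in `profile$values` to score.
#' @return List with `mean` (mean of the two peak intensities), `peaks`
#'   (the two values used, descending), and `fallback` (`TRUE` if the
#'   second-largest-sample rule was used).
#' @export
two_peak_intensity <- function(profile, channel) {
  stopifnot(inherits(profile, "line_profile"))
  if (!channel %in% names(profile$values)) {
    stop("unknown channel `", channel, "`", call. = FALSE)
  }
  v <- profile$values[[channel]]
  if (length(v) < 2) stop("profile error: length < 2", call. = FALSE)
  r <- rle(v)
  rv <- r$values
  k <- length(rv)
  is_peak <- logical(k)
  for (i in seq_len(k)) {
    left_ok <- i == 1 || rv[i] > rv[i - 1]
    right_ok <- i == k || rv[i] > rv[i + 1]
    is_peak[i] <- left_ok && right_ok
  }
  peaks <- sort(rv[is_peak], decreasing = TRUE)
  if (length(peaks) >= 2) {
    top2 <- peaks[1:2]
    fallback <- FALSE
  } else {
    top1 <- if (length(peaks) == 1) peaks[1] else max(v)
    second <- sort(v, decreasing = TRUE)[2]
    top2 <- c(top1, second)
    fallback <- TRUE
  }
  list(mean = mean(top2), peaks = top2, fallback = fallback)
}
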