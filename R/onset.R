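#' Detect anaphase onset from a securin intensity trace
#'
#' Anaphase onset is anchored to the abrupt degradation of securin
#' (Pds1). The operational rule: onset is the first frame whose
#' (background-subtracted) intensity falls below `drop_fraction` times the
#' median of all preceding frames, and stays below that level for `sustain`
#' consecutive frames (transient dips are ignored). Frames are 1-based. The
#' rule is invariant to multiplying the whole trace by a positive constant.
#'
#' @param securin_trace Numeric vector, length >= 3.
#' @param drop_fraction Fraction of the preceding-median defining
#'   degradation (default 0.5).
#' @param sustain Number of consecutive frames the trace must stay below the
#'   cutoff (default 2).
#' @return The onset frame index, or `NA_integer_` when no sustained drop is
#'   found (including when a candidate drop is too close to the end of the
#'   trace to confirm sustainment).
#' @examples
#' detect_onset(c(100, 100, 100, 20, 15, 10))  # 4
#' detect_onset(c(100, 100, 30, 100, 100))     # NA (transient dip)
#' @export
detect_onset <- function(securin_trace, drop_fraction = 0.5, sustain = 2) {
  v <- as.numeric(securin_trace)
  if (length(v) < 3) stop("trace length must be >= 3", call. = FALSE)
  stopifnot(drop_fraction > 0, drop_fraction < 1, sustain >= 1)
  n <- length(v)
  for (i in 2:n) {
    cutoff <- drop_fraction * stats::median(v[seq_len(i - 1)])
    last <- i + sustain - 1
    if (last > n) break
    if (all(v[i:last] < cutoff)) return(i)
  }
  NA_integer_
}

#' Frames scored after anaphase onset
#'
#' The scoring window covers the frames within 30 minutes after securin
#' degradation - at the default 15-min frame interval, the two timepoints
#' `{onset, onset + 1}`.
#'
#' @param onset Onset frame (1-based).
#' @param frame_interval_min Minutes between frames.
#' @param n_frames Total frames available; windows that would extend past
#'   the end are truncated and flagged.
#' @return List with `frames` (integer vector) and `truncated` (logical).
#' @export
scoring_window <- function(onset, frame_interval_min = 15, n_frames = Inf) {
  if (is.na(onset)) stop("onset undefined", call. = FALSE)
  stopifnot(frame_interval_min > 0)
  offsets <- 0:floor((30 - 1e-9) / frame_interval_min)
  frames <- onset + offsets
  truncated <- any(frames > n_frames)
  frames <- frames[frames <= n_frames]
  list(frames = as.integer(frames), truncated = truncated)
}
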