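CHANNEL_ROLES <- c("GREEN_MARKER", "RED_KINETOCHORE", "RED_SECURIN",
                   "RED_HISTONE", "RED_SPB")

#' Construct a calibrated multichannel time-lapse z-stack
#'
#' @param data 5-D numeric array with dimension order `T, Z, C, Y, X`
#'   (timepoints, z-slices, channels, rows, columns), non-negative
#'   intensities. Pixel coordinates throughout the package are 1-based
#'   `(y = row, x = column)`.
#' @param pixel_size_um Physical pixel size in micrometres (`> 0`).
#' @param frame_interval_min Minutes between timepoints (`> 0`).
#' @param z_spacing_um Micrometres between z-slices (`> 0`).
#' @param channel_roles Named integer vector mapping biological roles to
#'   channel indices. Valid roles: `GREEN_MARKER`, `RED_KINETOCHORE`,
#'   `RED_SECURIN`, `RED_HISTONE`, `RED_SPB`. Several roles may share one
#'   channel (securin and kinetochore markers are commonly both red).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_um, frame_interval_min = 15,
                        z_spacing_um = 0.85, channel_roles) {
  if (!is.array(data) || length(dim(data)) != 5) {
    stop("format error: `data` must be a 5-D array ordered T,Z,C,Y,X",
         call. = FALSE)
  }
  if (any(dim(data) < 1)) stop("format error: all dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0) {
    stop("config error: `pixel_size_um` must be a positive number", call. = FALSE)
  }
  stopifnot(frame_interval_min > 0, z_spacing_um > 0)
  channel_roles <- validate_channel_roles(channel_roles, dim(data)[3])
  structure(
    list(data = data,
         pixel_size_um = pixel_size_um,
         frame_interval_min = frame_interval_min,
         z_spacing_um = z_spacing_um,
         channel_roles = channel_roles),
    class = "image_stack"
  )
}

validate_channel_roles <- function(channel_roles, n_channels) {
  if (is.list(channel_roles)) channel_roles <- unlist(channel_roles)
  if (is.null(names(channel_roles)) || any(!nzchar(names(channel_roles)))) {
    stop("config error: `channel_roles` must be a named vector", call. = FALSE)
  }
  bad <- setdiff(names(channel_roles), CHANNEL_ROLES)
  if (length(bad)) {
    stop("config error: unknown channel role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx <- as.integer(channel_roles)
  if (any(is.na(idx)) || any(idx < 1) || any(idx > n_channels)) {
    stop("config error: channel role index outside 1..", n_channels, call. = FALSE)
  }
  stats::setNames(idx, names(channel_roles))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("<image_stack> T=", d[1], " Z=", d[2], " C=", d[3], " Y=", d[4],
      " X=", d[5], "\n", sep = "")
  cat("  pixel ", x$pixel_size_um, " um; frame interval ", x$frame_interval_min,
      " min; z spacing ", x$z_spacing_um, " um\n", sep = "")
  cat("  roles: ", paste(names(x$channel_roles), x$channel_roles,
                         sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Resolve a channel role to its channel index
#'
#' @param x An `image_stack` or `projected_stack`.
#' @param role One of the role names in `channel_roles`.
#' @return Integer channel index.
#' @export
channel_index <- function(x, role) {
  if (!role %in% names(x$channel_roles)) {
    stop("config error: role `", role, "` is not mapped to a channel", call. = FALSE)
  }
  unname(x$channel_roles[[role]])
}

#' Write an image stack as a 16-bit multi-page TIFF with a JSON sidecar
#'
#' Pages are written in T-major, then Z, then C order; values are clipped to
#' `[0, 65535]` and rounded (camera counts are integral). A sidecar
#' `<path>.json` records axes, dimensions and calibration so that
#' [read_stack()] can restore the object; the round trip is exact for
#' integer-valued stacks.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  pages <- vector("list", d[1] * d[2] * d[3])
  p <- 0L
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      for (ch in seq_len(d[3])) {
        p <- p + 1L
        m <- stack$data[t, z, ch, , ]
        dim(m) <- d[4:5]
        pages[[p]] <- pmin(pmax(round(m), 0), 65535) / 65535
      }
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(axes = "TZCYX", dim = d,
               pixel_size_um = stack$pixel_size_um,
               frame_interval_min = stack$frame_interval_min,
               z_spacing_um = stack$z_spacing_um,
               channel_roles = as.list(stack$channel_roles))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path.
#' @param config Optional configuration list (fields `axes`, `dim`,
#'   `pixel_size_um`, `frame_interval_min`, `z_spacing_um`,
#'   `channel_roles`); defaults to the `<path>.json` sidecar.
#' @return An `image_stack`.
#' @export
read_stack <- function(path, config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(config)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop("config error: no `config` given and sidecar ", sidecar,
           " not found", call. = FALSE)
    }
    config <- jsonlite::fromJSON(sidecar)
  }
  if (is.null(config$axes) || !identical(toupper(config$axes), "TZCYX")) {
    stop("format error: unsupported axis order `", config$axes,
         "` (expected TZCYX)", call. = FALSE)
  }
  if (is.null(config$pixel_size_um)) {
    stop("config error: `pixel_size_um` missing from config", call. = FALSE)
  }
  d <- as.integer(config$dim)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != d[1] * d[2] * d[3]) {
    stop("format error: TIFF has ", length(pages), " pages but config implies ",
         d[1] * d[2] * d[3], call. = FALSE)
  }
  data <- array(0, dim = d)
  p <- 0L
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      for (ch in seq_len(d[3])) {
        p <- p + 1L
        data[t, z, ch, , ] <- round(pages[[p]] * 65535)
      }
    }
  }
  image_stack(data,
              pixel_size_um = config$pixel_size_um,
              frame_interval_min = config$frame_interval_min %||% 15,
              z_spacing_um = config$z_spacing_um %||% 0.85,
              channel_roles = config$channel_roles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Z-project a stack
#'
#' Reduces the Z axis per pixel (maximum or mean), as done before all 2-D
#' measurements. Maximum projection is the default: it is the common choice
#' for punctate signals and the effective foreground/background contrast is
#' highest there; mean projection is retained as an option.
#'
#' @param stack An `image_stack`.
#' @param method `"max"` or `"mean"`.
#' @return A `projected_stack`: calibrated 4-D array `T, C, Y, X` with the
#'   projection method recorded.
#' @export
z_project <- function(stack, method = c("max", "mean")) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  d <- dim(stack$data)
  proj <- array(0, dim = d[c(1, 3, 4, 5)])
  if (method == "max") {
    acc <- stack$data[, 1, , , , drop = FALSE]
    for (z in seq_len(d[2])[-1]) {
      acc <- pmax(acc, stack$data[, z, , , , drop = FALSE])
    }
  } else {
    acc <- stack$data[, 1, , , , drop = FALSE]
    for (z in seq_len(d[2])[-1]) {
      acc <- acc + stack$data[, z, , , , drop = FALSE]
    }
    acc <- acc / d[2]
  }
  proj[] <- acc
  structure(
    list(data = proj,
         pixel_size_um = stack$pixel_size_um,
         frame_interval_min = stack$frame_interval_min,
         channel_roles = stack$channel_roles,
         method = method),
    class = "projected_stack"
  )
}

#' @export
print.projected_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("<projected_stack> (", x$method, ") T=", d[1], " C=", d[2], " Y=", d[3],
      " X=", d[4], "\n", sep = "")
  invisible(x)
}

#' Extract one 2-D frame image from a projected stack
#'
#' @param proj A `projected_stack`.
#' @param t Timepoint index (1-based).
#' @param role Channel role name (preferred) or `NULL` if `channel` given.
#' @param channel Channel index, used when `role` is `NULL`.
#' @return A Y x X numeric matrix.
#' @export
frame_image <- function(proj, t, role = NULL, channel = NULL) {
  stopifnot(inherits(proj, "projected_stack"))
  ch <- if (!is.null(role)) channel_index(proj, role) else channel
  if (is.null(ch)) stop("give `role` or `channel`", call. = FALSE)
  m <- proj$data[t, ch, , ]
  dim(m) <- dim(proj$data)[3:4]
  m
}
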