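#' Imaging configuration for synthetic movie rendering
#'
#' Defaults reproduce the acquisition regime the pipeline targets: 7 z-slices
#' at 0.85 um spacing, one frame every 15 min, diffraction-limited foci on a
#' uniform camera background with Poisson-Gaussian noise. The default pixel
#' size (0.107 um) is a typical 100x/EMCCD scale.
#'
#' @param pixel_size_um Physical pixel size, um (> 0).
#' @param frame_interval_min Minutes between frames (> 0; default 15).
#' @param n_z Number of z-slices (default 7).
#' @param z_spacing_um Spacing between z-slices, um (default 0.85).
#' @param psf_sigma_px In-plane Gaussian PSF sigma, pixels.
#' @param psf_sigma_z_um Axial attenuation sigma for point-like foci, um.
#' @param background_level Camera background, counts.
#' @param poisson_gain Photon gain for the Poisson component; noisy pixel =
#'   `Poisson(signal * gain) / gain + Gaussian(0, read_noise_sd)`, rounded to
#'   integer counts.
#' @param read_noise_sd Gaussian read-noise standard deviation, counts.
#' @param frame_size Optional `(Y, X)` frame size in pixels; when `NULL` the
#'   renderer sizes the frame to the cell grid. Too-small frames are a layout
#'   error.
#' @param n_frames Number of timepoints in a rendered movie (default 6).
#' @param onset_frame Earliest anaphase-onset frame (default 3); each cell's
#'   true onset is jittered by 0 or 1 frames.
#' @param cell_box_um Side of the square region allotted to one cell, um.
#' @param noise Render Poisson-Gaussian noise? (`FALSE` gives the exact
#'   noiseless signal.)
#' @param amplitudes Named list of peak signal amplitudes above background,
#'   counts: `cen5`, `kinetochore`, `securin`, `rec8`, `chromatin`,
#'   `histone`, `biosensor`.
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size_um = 0.107,
                           frame_interval_min = 15,
                           n_z = 7,
                           z_spacing_um = 0.85,
                           psf_sigma_px = 1.3,
                           psf_sigma_z_um = 0.8,
                           background_level = 100,
                           poisson_gain = 1,
                           read_noise_sd = 2,
                           frame_size = NULL,
                           n_frames = 6,
                           onset_frame = 3,
                           cell_box_um = 5.5,
                           noise = TRUE,
                           amplitudes = list()) {
  amp_defaults <- list(cen5 = 300, kinetochore = 500, securin = 150,
                       rec8 = 300, chromatin = 150, histone = 250,
                       biosensor = 300)
  amplitudes <- utils::modifyList(amp_defaults, as.list(amplitudes))
  pos <- c(pixel_size_um = pixel_size_um, frame_interval_min = frame_interval_min,
           n_z = n_z, z_spacing_um = z_spacing_um, psf_sigma_px = psf_sigma_px,
           psf_sigma_z_um = psf_sigma_z_um, poisson_gain = poisson_gain,
           cell_box_um = cell_box_um, n_frames = n_frames,
           onset_frame = onset_frame)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("config error: all physical quantities must be > 0", call. = FALSE)
  }
  if (background_level < 0 || read_noise_sd < 0) {
    stop("config error: background and read noise must be >= 0", call. = FALSE)
  }
  if (onset_frame < 3 || onset_frame + 2 > n_frames) {
    stop("config error: need onset_frame >= 3 and n_frames >= onset_frame + 2",
         call. = FALSE)
  }
  structure(
    list(pixel_size_um = pixel_size_um, frame_interval_min = frame_interval_min,
         n_z = as.integer(n_z), z_spacing_um = z_spacing_um,
         psf_sigma_px = psf_sigma_px, psf_sigma_z_um = psf_sigma_z_um,
         background_level = background_level, poisson_gain = poisson_gain,
         read_noise_sd = read_noise_sd, frame_size = frame_size,
         n_frames = as.integer(n_frames), onset_frame = as.integer(onset_frame),
         cell_box_um = cell_box_um, noise = noise, amplitudes = amplitudes),
    class = "imaging_config"
  )
}

#' Read / write an imaging configuration as JSON
#'
#' @param path JSON path.
#' @return For `read_imaging_config_json`, an `imaging_config`.
#' @export
read_imaging_config_json <- function(path) {
  spec <- jsonlite::fromJSON(path)
  args <- spec[intersect(names(spec), names(formals(imaging_config)))]
  do.call(imaging_config, args)
}

#' @rdname read_imaging_config_json
#' @param cfg An `imaging_config`.
#' @export
write_imaging_config_json <- function(cfg, path) {
  stopifnot(inherits(cfg, "imaging_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
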