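# Scene geometry constants (um). Spindle axis is horizontal (x); anaphase I
# pulls kinetochore clusters to poles at +/- POLE_OFFSET_UM from the cell
# centre; meiosis II products sit on a 2x2 grid.
POLE_OFFSET_UM <- 2.0
PREONSET_KIN_SEP_UM <- 0.7
MII_ROW_OFFSET_UM <- 1.2
FAR_SEP_UM <- 4.0
CLOSE_SEP_RANGE_UM <- c(0.9, 1.4)
PERICEN_INSET_UM <- 0.55
SECURIN_SIGMA_UM <- 1.6
CHROMATIN_SIGMA_UM <- 1.2
HISTONE_SIGMA_UM <- 0.45
HISTONE_PRE_SIGMA_UM <- 0.9
DIFFUSE_AXIAL_SIGMA_UM <- 2.0
SECURIN_RESIDUAL_FRAC <- 0.05

# Add a 2-D Gaussian of peak `amp` at sub-pixel centre (cy, cx) into `slice`,
# evaluated on a +/- 4 sigma window.
add_gaussian_patch <- function(slice, cy, cx, sigma, amp) {
  r <- ceiling(4 * sigma)
  ys <- max(1L, floor(cy - r)):min(nrow(slice), ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(ncol(slice), ceiling(cx + r))
  if (!length(ys) || !length(xs) || ys[1] > ys[length(ys)] || xs[1] > xs[length(xs)]) {
    return(slice)
  }
  gy <- exp(-((ys - cy)^2) / (2 * sigma^2))
  gx <- exp(-((xs - cx)^2) / (2 * sigma^2))
  slice[ys, xs] <- slice[ys, xs] + amp * (gy %o% gx)
  slice
}

#' Render a synthetic multichannel time-lapse z-stack from simulated outcomes
#'
#' Turns a set of simulated per-cell segregation outcomes into a synthetic
#' microscopy movie plus pixel-exact ground truth, so the measurement modules
#' can be validated end to end. Cells are laid out on a non-overlapping grid.
#' Channel 1 (green) carries the chosen `marker`; channel 2 (red) carries the
#' kinetochore foci and the diffuse nuclear securin signal, which drops to
#' 5% of its baseline at each cell's anaphase-onset frame; channel 3 (red)
#' carries histone-labelled nuclear masses. Foci are rendered as Gaussians
#' sampled into z-slices (per-slice axial attenuation with a mildly widened
#' in-plane sigma; the analysis operates on z-projections, so full 3-D PSF
#' fidelity is not attempted). Noise is `Poisson(signal * gain) / gain +
#' Gaussian(0, read_noise_sd)`, rounded to integer counts.
#'
#' Marker semantics at anaphase I: `"cen5"` renders the centromere-marker
#' foci at their class-determined separation (`SINGLE_FOCUS`: one focus at a
#' pole; `SPLIT_CLOSE`: two foci < 2 um apart at the spindle midzone;
#' `SPLIT_FAR`: two foci at the poles, 4 um apart). `"rec8"` renders the
#' cohesin pattern (`PERICENTROMERIC`: foci at the kinetochores of
#' mono-oriented cells, or just inside the two kinetochores of bi-oriented
#' protected cells; `RETAINED_EVERYWHERE`: a broad chromatin mass plus
#' kinetochore-proximal foci; `ABSENT`: background only). `"biosensor"`
#' renders a chromatin-tethered focus that persists when separase is dead
#' and disperses into a faint diffuse signal at onset when cleavage occurs.
#'
#' @param outcomes Tibble of per-cell outcomes (the `outcomes` element of a
#'   [simulate_population()] result, or a compatible data frame with columns
#'   `cell_id`, `genotype`, `cen5_class_mi`, `rec8_pattern_ana1`,
#'   `divisions`).
#' @param cfg An [imaging_config()].
#' @param seed Integer seed; the rendered stack is bitwise reproducible given
#'   `(outcomes, cfg, seed)`.
#' @param marker `"rec8"`, `"cen5"` or `"biosensor"` - what the green channel
#'   shows.
#' @return A `synthetic_movie`: list with `stack` (an [image_stack()]),
#'   `truth` (list of tibbles `cells`, `spots`, `securin`, `masses`), `cfg`,
#'   `marker`, `seed`.
#' @export
render_movie <- function(outcomes, cfg, seed, marker = c("rec8", "cen5", "biosensor")) {
  marker <- match.arg(marker)
  stopifnot(inherits(cfg, "imaging_config"))
  if (inherits(outcomes, "segregation_population")) outcomes <- outcomes$outcomes
  outcomes <- as.data.frame(outcomes)
  n <- nrow(outcomes)
  if (n < 1) stop("`outcomes` must be non-empty", call. = FALSE)

  ps <- cfg$pixel_size_um
  box <- floor(cfg$cell_box_um / ps)
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  Y <- nrow_grid * box
  X <- ncol_grid * box
  if (!is.null(cfg$frame_size)) {
    fs <- as.integer(cfg$frame_size)
    if (fs[1] < Y || fs[2] < X) {
      stop("layout error: frame_size (", fs[1], "x", fs[2],
           ") too small for ", n, " cells (needs ", Y, "x", X, ")", call. = FALSE)
    }
    Y <- fs[1]; X <- fs[2]
  }
  um2px <- function(u) u / ps

  with_seed(seed, {
    cells <- vector("list", n)
    prim <- vector("list", n)    # render primitives per cell
    securin_rows <- vector("list", n)
    mass_rows <- vector("list", n)

    for (i in seq_len(n)) {
      oc <- outcomes[i, ]
      gy <- (i - 1) %/% ncol_grid
      gx <- (i - 1) %% ncol_grid
      cy <- gy * box + (box + 1) / 2
      cx <- gx * box + (box + 1) / 2
      onset <- cfg$onset_frame + sample(0:1, 1)
      side <- sample(c(-1, 1), 1)
      sep_close <- stats::runif(1, CLOSE_SEP_RANGE_UM[1], CLOSE_SEP_RANGE_UM[2])
      sep_um <- switch(oc$cen5_class_mi,
                       SINGLE_FOCUS = 0,
                       SPLIT_CLOSE = sep_close,
                       SPLIT_FAR = FAR_SEP_UM)
      divisions <- as.integer(oc$divisions)
      gross <- oc$rec8_pattern_ana1 == "ABSENT" && divisions == 2L
      n_spores <- 2L * divisions
      size_f <- exp(stats::rnorm(n_spores, 0, if (gross) 0.35 else 0.05))
      size_f <- pmin(pmax(size_f, 0.55), 1.8)
      cleaved <- oc$rec8_pattern_ana1 != "RETAINED_EVERYWHERE"

      pr <- list()
      add_prim <- function(frame, channel, role, dy_um, dx_um, sigma_px, amp,
                           axial_um, kind) {
        pr[[length(pr) + 1]] <<- data.frame(
          cell_id = oc$cell_id, frame = frame, channel = channel, role = role,
          y_px = cy + um2px(dy_um), x_px = cx + um2px(dx_um),
          sigma_px = sigma_px, amplitude = amp, axial_um = axial_um,
          kind = kind, stringsAsFactors = FALSE)
      }
      sig <- cfg$psf_sigma_px
      A <- cfg$amplitudes

      for (t in seq_len(cfg$n_frames)) {
        pre <- t < onset
        late <- t > onset + 1
        # --- kinetochores (channel 2) ---
        kin <- if (pre) {
          cbind(0, c(-1, 1) * PREONSET_KIN_SEP_UM / 2)
        } else if (late && divisions == 2L) {
          cbind(rep(c(-1, 1), each = 2) * MII_ROW_OFFSET_UM,
                rep(c(-1, 1), 2) * POLE_OFFSET_UM)
        } else {
          cbind(0, c(-1, 1) * POLE_OFFSET_UM)
        }
        for (k in seq_len(nrow(kin))) {
          add_prim(t, 2L, "RED_KINETOCHORE", kin[k, 1], kin[k, 2], sig,
                   A$kinetochore, cfg$psf_sigma_z_um, "focus")
        }
        # --- securin (channel 2, diffuse) ---
        sec_amp <- if (pre) A$securin else A$securin * SECURIN_RESIDUAL_FRAC
        add_prim(t, 2L, "RED_SECURIN", 0, 0, um2px(SECURIN_SIGMA_UM), sec_amp,
                 DIFFUSE_AXIAL_SIGMA_UM, "diffuse")
        securin_rows[[i]] <- rbind(securin_rows[[i]], data.frame(
          cell_id = oc$cell_id, frame = t, amplitude = sec_amp))
        # --- histone masses (channel 3) ---
        if (pre) {
          add_prim(t, 3L, "RED_HISTONE", 0, 0, um2px(HISTONE_PRE_SIGMA_UM),
                   A$histone, DIFFUSE_AXIAL_SIGMA_UM, "mass")
        } else if (!late || divisions == 1L) {
          for (sx in c(-1, 1)) {
            add_prim(t, 3L, "RED_HISTONE", 0, sx * POLE_OFFSET_UM,
                     um2px(HISTONE_SIGMA_UM) *
                       sqrt(if (late) size_f[(sx + 3) / 2] else 1),
                     A$histone, DIFFUSE_AXIAL_SIGMA_UM, "mass")
          }
        } else {
          pos <- cbind(rep(c(-1, 1), each = 2) * MII_ROW_OFFSET_UM,
                       rep(c(-1, 1), 2) * POLE_OFFSET_UM)
          for (k in 1:4) {
            add_prim(t, 3L, "RED_HISTONE", pos[k, 1], pos[k, 2],
                     um2px(HISTONE_SIGMA_UM) * sqrt(size_f[k]),
                     A$histone, DIFFUSE_AXIAL_SIGMA_UM, "mass")
          }
        }
        # --- green marker (channel 1) ---
        if (marker == "cen5") {
          if (pre) {
            add_prim(t, 1L, "GREEN_MARKER", 0, 0, sig, A$cen5,
                     cfg$psf_sigma_z_um, "focus")
          } else if (oc$cen5_class_mi == "SINGLE_FOCUS") {
            add_prim(t, 1L, "GREEN_MARKER", 0, side * POLE_OFFSET_UM, sig,
                     A$cen5, cfg$psf_sigma_z_um, "focus")
          } else {
            for (sx in c(-1, 1)) {
              add_prim(t, 1L, "GREEN_MARKER", 0, sx * sep_um / 2, sig,
                       A$cen5, cfg$psf_sigma_z_um, "focus")
            }
          }
        } else if (marker == "rec8") {
          if (pre) {
            add_prim(t, 1L, "GREEN_MARKER", 0, 0, um2px(CHROMATIN_SIGMA_UM),
                     A$chromatin, DIFFUSE_AXIAL_SIGMA_UM, "diffuse")
            for (sx in c(-1, 1)) {
              add_prim(t, 1L, "GREEN_MARKER", 0, sx * PREONSET_KIN_SEP_UM / 2,
                       sig, A$rec8, cfg$psf_sigma_z_um, "focus")
            }
          } else if (oc$rec8_pattern_ana1 == "PERICENTROMERIC") {
            off <- if (oc$cen5_class_mi == "SINGLE_FOCUS") POLE_OFFSET_UM else
              POLE_OFFSET_UM - PERICEN_INSET_UM
            for (sx in c(-1, 1)) {
              add_prim(t, 1L, "GREEN_MARKER", 0, sx * off, sig, A$rec8,
                       cfg$psf_sigma_z_um, "focus")
            }
          } else if (oc$rec8_pattern_ana1 == "RETAINED_EVERYWHERE") {
            add_prim(t, 1L, "GREEN_MARKER", 0, 0, um2px(CHROMATIN_SIGMA_UM),
                     A$chromatin, DIFFUSE_AXIAL_SIGMA_UM, "diffuse")
            for (sx in c(-1, 1)) {
              add_prim(t, 1L, "GREEN_MARKER", 0, sx * POLE_OFFSET_UM, sig,
                       A$rec8, cfg$psf_sigma_z_um, "focus")
            }
          }
          # ABSENT: background only
        } else { # biosensor
          if (pre || !cleaved) {
            add_prim(t, 1L, "GREEN_MARKER", 0.4, 0.3, sig, A$biosensor,
                     cfg$psf_sigma_z_um, "focus")
          } else {
            # cleaved: the focus' photons disperse over the nuclear volume,
            # so the diffuse peak amplitude conserves integrated intensity
            disp_sigma <- um2px(1.5)
            disp_amp <- A$biosensor * sig^2 / disp_sigma^2
            add_prim(t, 1L, "GREEN_MARKER", 0, 0, disp_sigma,
                     disp_amp, DIFFUSE_AXIAL_SIGMA_UM, "diffuse")
          }
        }
      }
      prim[[i]] <- dplyr::bind_rows(pr)

      cells[[i]] <- tibble::tibble(
        cell_id = oc$cell_id, genotype = oc$genotype, marker = marker,
        onset_frame = onset, divisions = divisions,
        cen5_class = oc$cen5_class_mi, rec8_pattern = oc$rec8_pattern_ana1,
        biosensor_cleaved = cleaved, sep_um = sep_um,
        center_y = cy, center_x = cx,
        y0 = gy * box + 1L, y1 = (gy + 1L) * box,
        x0 = gx * box + 1L, x1 = (gx + 1L) * box)
      mass_rows[[i]] <- tibble::tibble(
        cell_id = oc$cell_id, spore = seq_len(n_spores), size_factor = size_f)
    }

    prims <- dplyr::bind_rows(prim)
    truth <- list(
      cells = dplyr::bind_rows(cells),
      spots = tibble::as_tibble(prims[prims$kind == "focus",
                                      c("cell_id", "frame", "channel", "role",
                                        "y_px", "x_px", "amplitude")]),
      securin = tibble::as_tibble(dplyr::bind_rows(securin_rows)),
      masses = dplyr::bind_rows(mass_rows))

    # --- rasterize ---
    z_mid <- (cfg$n_z + 1) / 2
    data <- array(cfg$background_level, dim = c(cfg$n_frames, cfg$n_z, 3L, Y, X))
    for (t in seq_len(cfg$n_frames)) {
      pt <- prims[prims$frame == t, ]
      for (ch in 1:3) {
        pc <- pt[pt$channel == ch, ]
        if (!nrow(pc)) next
        for (z in seq_len(cfg$n_z)) {
          dz <- (z - z_mid) * cfg$z_spacing_um
          slice <- matrix(0, Y, X)
          touched <- FALSE
          for (r in seq_len(nrow(pc))) {
            attn <- exp(-dz^2 / (2 * pc$axial_um[r]^2))
            amp <- pc$amplitude[r] * attn
            if (amp < 0.25) next
            sig_eff <- pc$sigma_px[r] * sqrt(1 + 0.5 * (dz / pc$axial_um[r])^2)
            slice <- add_gaussian_patch(slice, pc$y_px[r], pc$x_px[r],
                                        sig_eff, amp)
            touched <- TRUE
          }
          if (touched) {
            data[t, z, ch, , ] <- data[t, z, ch, , ] + slice
          }
        }
      }
    }

    if (isTRUE(cfg$noise)) {
      g <- cfg$poisson_gain
      noisy <- stats::rpois(length(data), as.vector(data) * g) / g +
        stats::rnorm(length(data), 0, cfg$read_noise_sd)
      data[] <- pmax(round(noisy), 0)
    }

    stack <- image_stack(
      data, pixel_size_um = ps, frame_interval_min = cfg$frame_interval_min,
      z_spacing_um = cfg$z_spacing_um,
      channel_roles = c(GREEN_MARKER = 1L, RED_KINETOCHORE = 2L,
                        RED_SECURIN = 2L, RED_HISTONE = 3L))
    structure(list(stack = stack, truth = truth, cfg = cfg, marker = marker,
                   seed = as.integer(seed)),
              class = "synthetic_movie")
  })
}

#' @export
print.synthetic_movie <- function(x, ...) {
  cat("<synthetic_movie> marker=", x$marker, ", ",
      nrow(x$truth$cells), " cells, seed ", x$seed, "\n", sep = "")
  print(x$stack)
  invisible(x)
}

#' Write a synthetic movie to disk
#'
#' Writes the stack as TIFF (+ JSON sidecar via [write_stack()]), the
#' ground-truth cell and spot tables as CSV, and the imaging configuration
#' as JSON, under a common path prefix.
#'
#' @param movie A `synthetic_movie`.
#' @param prefix Path prefix (e.g. `"out/run1"`).
#' @return Named character vector of the files written, invisibly.
#' @export
write_movie <- function(movie, prefix) {
  stopifnot(inherits(movie, "synthetic_movie"))
  paths <- c(stack = paste0(prefix, ".tif"),
             cells = paste0(prefix, "_truth_cells.csv"),
             spots = paste0(prefix, "_truth_spots.csv"),
             config = paste0(prefix, "_config.json"))
  write_stack(movie$stack, paths[["stack"]])
  utils::write.csv(movie$truth$cells, paths[["cells"]], row.names = FALSE)
  utils::write.csv(movie$truth$spots, paths[["spots"]], row.names = FALSE)
  write_imaging_config_json(movie$cfg, paths[["config"]])
  invisible(paths)
}
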