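make_stack <- function(dims = c(2, 3, 2, 8, 9), seed = 1) {
  set.seed(seed)
  data <- array(as.double(sample(0:4095, prod(dims), replace = TRUE)), dim = dims)
  image_stack(data, pixel_size_um = 0.1, frame_interval_min = 15,
              z_spacing_um = 0.85,
              channel_roles = c(GREEN_MARKER = 1L, RED_KINETOCHORE = 2L))
}

test_that("stack construction validates dimensions, calibration and roles", {
  expect_error(image_stack(array(0, c(2, 2, 2, 2)), 0.1,
                           channel_roles = c(GREEN_MARKER = 1L)),
               "5-D")
  expect_error(image_stack(array(0, c(1, 1, 1, 4, 4)), -1,
                           channel_roles = c(GREEN_MARKER = 1L)),
               "pixel_size_um")
  # 2 channels but a role pointing at channel 3
  expect_error(image_stack(array(0, c(1, 1, 2, 4, 4)), 0.1,
                           channel_roles = c(GREEN_MARKER = 1L,
                                             RED_KINETOCHORE = 2L,
                                             RED_HISTONE = 3L)),
               "channel role index")
  expect_error(image_stack(array(0, c(1, 1, 1, 4, 4)), 0.1,
                           channel_roles = c(BLUE_THING = 1L)),
               "unknown channel role")
})

test_that("write/read round-trips integer stacks bitwise with metadata", {
  st <- make_stack()
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_stack(st, path)
  st2 <- read_stack(path)
  expect_identical(st2$data, st$data)
  expect_equal(st2$pixel_size_um, st$pixel_size_um)
  expect_equal(st2$frame_interval_min, st$frame_interval_min)
  expect_equal(st2$z_spacing_um, st$z_spacing_um)
  expect_equal(st2$channel_roles, st$channel_roles)
})

test_that("reading rejects unknown axis orders and missing calibration", {
  st <- make_stack()
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_stack(st, path)
  cfg <- jsonlite::fromJSON(paste0(path, ".json"))
  bad <- cfg; bad$axes <- "XYCZT"
  expect_error(read_stack(path, bad), "axis order")
  bad2 <- cfg; bad2$pixel_size_um <- NULL
  expect_error(read_stack(path, bad2), "pixel_size_um")
})

test_that("z-projection reduces correctly and preserves calibration", {
  data <- array(0, c(1, 3, 1, 2, 2))
  data[1, , 1, 1, 1] <- c(2, 5, 3)
  data[1, , 1, 2, 2] <- c(1, 1, 7)
  st <- image_stack(data, 0.1, channel_roles = c(GREEN_MARKER = 1L))
  pmax_ <- z_project(st, "max")
  pmean <- z_project(st, "mean")
  expect_equal(pmax_$data[1, 1, 1, 1], 5)
  expect_equal(pmean$data[1, 1, 1, 1], 10 / 3)
  expect_equal(pmax_$data[1, 1, 2, 2], 7)
  expect_equal(length(dim(pmax_$data)), 4)
  expect_equal(pmax_$pixel_size_um, 0.1)
  # Z = 1: projection equals the single slice
  st1 <- image_stack(array(3, c(1, 1, 1, 2, 2)), 0.1,
                     channel_roles = c(GREEN_MARKER = 1L))
  expect_equal(as.vector(z_project(st1, "max")$data), rep(3, 4))
})

test_that("max projection is idempotent and permutation-invariant over Z", {
  set.seed(5)
  data <- array(runif(2 * 4 * 1 * 6 * 6, 0, 100), c(2, 4, 1, 6, 6))
  st <- image_stack(data, 0.1, channel_roles = c(GREEN_MARKER = 1L))
  p1 <- z_project(st, "max")
  perm <- data[, c(3, 1, 4, 2), , , , drop = FALSE]
  st_perm <- image_stack(perm, 0.1, channel_roles = c(GREEN_MARKER = 1L))
  expect_equal(z_project(st_perm, "max")$data, p1$data)
  # idempotence: projecting an already-projected (Z=1) stack changes nothing
  rep1 <- array(p1$data[1, , , ], c(1, 1, 1, 6, 6))
  st_rep <- image_stack(rep1, 0.1, channel_roles = c(GREEN_MARKER = 1L))
  expect_equal(as.vector(z_project(st_rep, "max")$data), as.vector(rep1))
})

test_that("projection of a noiseless rendered spot preserves its centroid", {
  pop <- simulate_population(genotype_presets("wild_type"), 1, 3)
  cfg <- test_cfg(noise = FALSE)
  movie <- render_movie(pop$outcomes, cfg, 4, marker = "cen5")
  proj <- z_project(movie$stack, "max")
  truth <- movie$truth$spots
  tr <- truth[truth$frame == 1 & truth$role == "GREEN_MARKER", ]
  green <- frame_image(proj, 1, "GREEN_MARKER")
  spots <- detect_spots(green, min_area = 2)
  expect_equal(nrow(spots), 1)
  expect_lt(abs(spots$centroid_y[1] - tr$y_px), 0.5)
  expect_lt(abs(spots$centroid_x[1] - tr$x_px), 0.5)
})
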