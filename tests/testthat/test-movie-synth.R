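test_that("imaging config validates physical quantities and fills amplitude defaults", {
  cfg <- imaging_config()
  expect_equal(cfg$n_z, 7L)
  expect_equal(cfg$z_spacing_um, 0.85)
  expect_equal(cfg$frame_interval_min, 15)
  expect_error(imaging_config(pixel_size_um = 0), "> 0")
  expect_error(imaging_config(n_z = -1), "> 0")
  cfg2 <- imaging_config(amplitudes = list(rec8 = 123))
  expect_equal(cfg2$amplitudes$rec8, 123)
  expect_equal(cfg2$amplitudes$kinetochore, cfg$amplitudes$kinetochore)
})

test_that("imaging config survives a JSON round trip", {
  cfg <- imaging_config(pixel_size_um = 0.09, n_frames = 8, onset_frame = 4)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_imaging_config_json(cfg, path)
  cfg2 <- read_imaging_config_json(path)
  expect_equal(cfg2$pixel_size_um, 0.09)
  expect_equal(cfg2$n_frames, 8L)
  expect_equal(cfg2$amplitudes, cfg$amplitudes)
})

test_that("rendering is bitwise reproducible given the same seed", {
  pop <- simulate_population(genotype_presets("spo13d"), 4, 2)
  cfg <- test_cfg()
  m1 <- render_movie(pop$outcomes, cfg, 9)
  m2 <- render_movie(pop$outcomes, cfg, 9)
  expect_identical(m1$stack$data, m2$stack$data)
  expect_identical(m1$truth$cells, m2$truth$cells)
  m3 <- render_movie(pop$outcomes, cfg, 10)
  expect_false(identical(m1$stack$data, m3$stack$data))
})

test_that("rendered stacks have the configured acquisition geometry", {
  pop <- simulate_population(genotype_presets("wild_type"), 3, 2)
  movie <- render_movie(pop$outcomes, imaging_config(n_frames = 6), 1)
  d <- dim(movie$stack$data)
  expect_equal(d[1], 6)       # T
  expect_equal(d[2], 7)       # seven z-slices
  expect_equal(d[3], 3)       # green + red(kin/securin) + red(histone)
  expect_equal(movie$stack$z_spacing_um, 0.85)
  expect_error(render_movie(pop$outcomes, test_cfg(frame_size = c(20, 20)), 1),
               "layout error")
})

test_that("ground truth respects class separations and securin drop", {
  gts <- c("wild_type", "spo13d", "mam1d")
  for (gt in gts) {
    pop <- simulate_population(genotype_presets(gt), 6, 5)
    movie <- render_movie(pop$outcomes, test_cfg(), 6, marker = "cen5")
    cells <- movie$truth$cells
    expect_true(all(cells$sep_um[cells$cen5_class == "SPLIT_CLOSE"] < 2))
    expect_true(all(cells$sep_um[cells$cen5_class == "SPLIT_FAR"] > 2))
    sec <- movie$truth$securin
    for (i in seq_len(nrow(cells))) {
      tr <- sec[sec$cell_id == cells$cell_id[i], ]
      base <- tr$amplitude[1]
      post <- tr$amplitude[tr$frame >= cells$onset_frame[i]]
      expect_true(all(post < 0.1 * base))
    }
  }
})

test_that("noiseless rendering is photometrically linear in spot amplitude", {
  pop <- simulate_population(genotype_presets("wild_type"), 1, 3)
  cfg1 <- test_cfg(noise = FALSE, amplitudes = list(cen5 = 200))
  cfg2 <- test_cfg(noise = FALSE, amplitudes = list(cen5 = 400))
  m1 <- render_movie(pop$outcomes, cfg1, 4, marker = "cen5")
  m2 <- render_movie(pop$outcomes, cfg2, 4, marker = "cen5")
  g1 <- frame_image(z_project(m1$stack, "max"), 1, "GREEN_MARKER") -
    cfg1$background_level
  g2 <- frame_image(z_project(m2$stack, "max"), 1, "GREEN_MARKER") -
    cfg2$background_level
  expect_equal(sum(g2), 2 * sum(g1), tolerance = 1e-12)
  expect_equal(max(g1), 200, tolerance = 1e-9)
})

test_that("rendered far-split separation is recovered by detection within half a pixel", {
  g <- genotype_params("biori", p_monoorient = 0, protection_on = FALSE,
                       second_division_on = FALSE,
                       forced_biorientation = TRUE)
  pop <- simulate_population(g, 1, 8)
  expect_equal(pop$outcomes$cen5_class_mi, "SPLIT_FAR")
  cfg <- test_cfg(noise = FALSE)
  movie <- render_movie(pop$outcomes, cfg, 2, marker = "cen5")
  onset <- movie$truth$cells$onset_frame[1]
  green <- frame_image(z_project(movie$stack, "max"), onset, "GREEN_MARKER")
  spots <- detect_spots(green, min_area = 2)
  expect_equal(nrow(spots), 2)
  sep_px <- sqrt(diff(spots$centroid_y)^2 + diff(spots$centroid_x)^2)
  true_px <- 4.0 / cfg$pixel_size_um
  expect_lt(abs(sep_px - true_px), 0.5)
})

test_that("movie files round-trip through write_movie", {
  pop <- simulate_population(genotype_presets("wild_type"), 2, 2)
  movie <- render_movie(pop$outcomes, test_cfg(), 3)
  prefix <- tempfile()
  paths <- write_movie(movie, prefix)
  on.exit(unlink(c(paths, paste0(paths[["stack"]], ".json"))))
  expect_true(all(file.exists(paths)))
  st <- read_stack(paths[["stack"]])
  expect_identical(st$data, movie$stack$data)  # noisy stacks are integral
  cells <- read.csv(paths[["cells"]])
  expect_equal(nrow(cells), 2)
})
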