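test_that("Yen threshold separates a two-level image and rejects constants", {
  img <- c(rep(10, 128), rep(200, 128))
  thr <- yen_threshold(img)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  expect_equal(sum(img > thr), 128)
  expect_error(yen_threshold(rep(5, 100)), "degenerate")
})

test_that("Yen threshold equals exhaustive criterion scan on seeded mixture histograms", {
  set.seed(42)
  for (i in 1:100) {
    n1 <- sample(200:2000, 1)
    n2 <- sample(200:2000, 1)
    v <- c(rnorm(n1, runif(1, 40, 90), runif(1, 5, 15)),
           rnorm(n2, runif(1, 140, 220), runif(1, 5, 25)))
    v <- pmin(pmax(round(v), 0), 255)
    counts <- tabulate(v + 1, nbins = 256)
    centers <- 0:255
    if (sum(counts > 0) < 2) next
    expect_identical(yen_threshold_from_counts(counts, centers),
                     yen_oracle(counts, centers))
  }
})

test_that("Yen threshold is shift-equivariant under identical re-binning", {
  set.seed(7)
  v <- c(rnorm(500, 50, 8), rnorm(500, 150, 12))
  thr <- yen_threshold(v, levels = 128)
  thr_shift <- yen_threshold(v + 100, levels = 128)
  expect_equal(thr_shift, thr + 100, tolerance = 1e-9)
})

test_that("spot detection reproduces hand-computed centroids, areas and means", {
  img <- matrix(0, 20, 20)
  img[3:5, 3:5] <- 100    # 3x3 block centred at (4, 4)
  img[12:14, 15:17] <- 100
  spots <- detect_spots(img, threshold = 50, min_area = 1)
  expect_equal(nrow(spots), 2)
  expect_setequal(round(spots$centroid_y, 6), c(4, 13))
  expect_setequal(round(spots$centroid_x, 6), c(4, 16))
  expect_true(all(spots$area_px == 9))
  expect_true(all(spots$mean_intensity == 100))
  expect_equal(nrow(detect_spots(matrix(0, 10, 10), threshold = 1)), 0)
})

test_that("spot detection uses 8-connectivity and respects min_area", {
  img <- matrix(0, 10, 10)
  img[2, 2] <- 100
  img[3, 3] <- 100        # touches only diagonally
  spots <- detect_spots(img, threshold = 50, min_area = 1)
  expect_equal(nrow(spots), 1)
  expect_equal(spots$area_px, 2L)
  expect_equal(nrow(detect_spots(img, threshold = 50, min_area = 3)), 0)
})

test_that("detection on images with disjoint masks equals union of separate detections", {
  set.seed(3)
  a <- matrix(0, 30, 30); a[5:7, 5:7] <- 90
  b <- matrix(0, 30, 30); b[20:22, 24:26] <- 120
  both <- detect_spots(a + b, threshold = 50, min_area = 1)
  sep <- rbind(detect_spots(a, threshold = 50, min_area = 1),
               detect_spots(b, threshold = 50, min_area = 1))
  expect_equal(nrow(both), 2)
  expect_setequal(both$mean_intensity, sep$mean_intensity)
  expect_setequal(both$area_px, sep$area_px)
})

test_that("cross-channel measurement averages the other channel over red footprints", {
  img <- matrix(0, 10, 10)
  img[2:3, 2:3] <- 100    # 4-pixel footprint
  spots <- detect_spots(img, threshold = 50, min_area = 1)
  green <- matrix(7, 10, 10)
  expect_equal(measure_cross_channel(spots, green)$cross_channel_mean, 7)
  # identity: green == red
  expect_equal(measure_cross_channel(spots, img)$cross_channel_mean,
               spots$mean_intensity)
  green2 <- matrix(0, 10, 10)
  green2[2:3, 2:3] <- c(10, 20, 30, 40)
  expect_equal(measure_cross_channel(spots, green2)$cross_channel_mean, 25)
  expect_error(measure_cross_channel(spots, matrix(0, 3, 3),
                                     detection_dim = c(10, 10)),
               "shape mismatch")
})

test_that("cross-channel measurement is linear in the green channel", {
  set.seed(9)
  img <- matrix(0, 15, 15); img[4:6, 4:6] <- 80
  spots <- detect_spots(img, threshold = 40, min_area = 1)
  g1 <- matrix(runif(225, 0, 50), 15, 15)
  g2 <- matrix(runif(225, 0, 50), 15, 15)
  expect_equal(measure_cross_channel(spots, g1 + g2)$cross_channel_mean,
               measure_cross_channel(spots, g1)$cross_channel_mean +
                 measure_cross_channel(spots, g2)$cross_channel_mean)
})

test_that("line profiles rasterize Bresenham lines over identical pixels in all channels", {
  imgs <- list(red = matrix(seq_len(25), 5, 5), green = matrix(0, 5, 5))
  pr <- line_profile(c(1, 1), c(5, 5), imgs)
  expect_equal(pr$pixels$y, 1:5)
  expect_equal(pr$pixels$x, 1:5)
  expect_equal(length(pr$values$red), length(pr$values$green))
  # horizontal line: row 2, columns 1..5
  imgs2 <- list(g = matrix(3, 6, 6))
  pr2 <- line_profile(c(2, 1), c(2, 5), imgs2)
  expect_equal(pr2$pixels$y, rep(2, 5))
  expect_equal(pr2$pixels$x, 1:5)
  expect_true(all(pr2$values$g == 3))
  expect_error(line_profile(c(2.2, 3.1), c(1.8, 2.9), imgs2), "coincide")
})

test_that("two-peak intensity follows the hand-enumerated local-maxima rules", {
  mk <- function(v) structure(list(pixels = NULL, values = list(g = v)),
                              class = "line_profile")
  r <- two_peak_intensity(mk(c(1, 5, 2, 9, 3)), "g")
  expect_equal(r$mean, 7)
  expect_false(r$fallback)
  # constant profile: plateau collapses, mean of equal values
  r2 <- two_peak_intensity(mk(rep(4, 6)), "g")
  expect_equal(r2$mean, 4)
  # monotonic ramp: single maximum, flagged second-largest fallback
  r3 <- two_peak_intensity(mk(c(1, 2, 3, 4)), "g")
  expect_equal(r3$mean, 3.5)
  expect_true(r3$fallback)
  # interior plateau flanked by lower values is one peak
  r4 <- two_peak_intensity(mk(c(1, 6, 6, 6, 2, 8, 1)), "g")
  expect_equal(r4$mean, 7)
  expect_error(two_peak_intensity(mk(c(1)), "g"), "length")
})
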