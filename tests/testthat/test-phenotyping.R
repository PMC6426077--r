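test_that("onset detection applies the sustained-drop rule", {
  expect_equal(detect_onset(c(100, 100, 100, 20, 15, 10)), 4L)
  expect_true(is.na(detect_onset(rep(100, 8))))
  # transient dip does not trigger
  expect_true(is.na(detect_onset(c(100, 100, 30, 100, 100))))
  # drop at the very end cannot be confirmed for `sustain` frames
  expect_true(is.na(detect_onset(c(100, 100, 100, 100, 20))))
  expect_equal(detect_onset(c(100, 100, 100, 100, 20, 10), sustain = 2), 5L)
  expect_error(detect_onset(c(1, 2)), "length")
})

test_that("onset detection is invariant to positive rescaling", {
  set.seed(31)
  for (i in 1:20) {
    tr <- c(runif(4, 80, 120), runif(4, 0, 30))
    expect_identical(detect_onset(tr), detect_onset(tr * runif(1, 0.1, 50)))
  }
})

test_that("scoring window covers the frames within 30 minutes of onset", {
  w <- scoring_window(4, 15)
  expect_equal(w$frames, c(4L, 5L))
  expect_false(w$truncated)
  expect_equal(scoring_window(4, 10)$frames, c(4L, 5L, 6L))
  wt <- scoring_window(6, 15, n_frames = 6)
  expect_equal(wt$frames, 6L)
  expect_true(wt$truncated)
  expect_error(scoring_window(NA), "undefined")
})

test_that("distance classification applies the closed 2-um boundary", {
  mk <- function(sep_px) {
    tibble::tibble(spot_id = 1:2, centroid_y = c(10, 10),
                   centroid_x = c(10, 10 + sep_px), area_px = 9L,
                   mean_intensity = 100, cross_channel_mean = NA_real_,
                   footprint = list(1L, 2L))
  }
  one <- mk(0)[1, ]
  expect_equal(call_cen5_class(list(one, one), 0.1)$class, "SINGLE_FOCUS")
  expect_equal(call_cen5_class(list(mk(10)), 0.1)$class, "SPLIT_CLOSE")  # 1.0 um
  expect_equal(call_cen5_class(list(mk(20)), 0.1)$class, "SPLIT_CLOSE")  # exactly 2.0
  expect_equal(call_cen5_class(list(mk(25)), 0.1)$class, "SPLIT_FAR")    # 2.5 um
  res <- call_cen5_class(list(rbind(mk(10), mk(5)[1, ])), 0.1)
  expect_true(is.na(res$class))
  expect_equal(res$flags, "more_than_two_foci")
})

test_that("division counting needs four foci for a second division", {
  mk_img <- function(n_foci) {
    img <- matrix(100, 60, 60)
    pos <- list(c(15, 15), c(15, 45), c(45, 15), c(45, 45))
    for (k in seq_len(n_foci)) {
      img[pos[[k]][1] + (-1:1), pos[[k]][2] + (-1:1)] <- 600
    }
    img
  }
  expect_equal(count_divisions(mk_img(4))$divisions, 2L)
  expect_equal(count_divisions(mk_img(2))$divisions, 1L)
  amb <- count_divisions(mk_img(3))
  expect_equal(amb$divisions, 1L)
  expect_equal(amb$flags, "ambiguous_three_foci")
})

test_that("nuclear area ratio matches hand-computed component areas", {
  img <- matrix(0, 64, 64)
  img[2:11, 2:11] <- 200      # 100 px
  img[2:11, 30:34] <- 200     # 50 px
  img[30:39, 2:9] <- 200      # 80 px
  img[30:34, 30:34] <- 200    # 25 px
  expect_equal(nuclear_area_ratio(img, 4), 4.0)
  # four equal masses give exactly 1
  img2 <- matrix(0, 64, 64)
  for (off in list(c(2, 2), c(2, 40), c(40, 2), c(40, 40))) {
    img2[off[1]:(off[1] + 9), off[2]:(off[2] + 9)] <- 200
  }
  expect_equal(nuclear_area_ratio(img2, 4), 1.0)
  expect_error(nuclear_area_ratio(img[1:25, ], 4), "expected 4")
})

test_that("area ratio is invariant under integer upsampling", {
  img <- matrix(0, 40, 40)
  img[5:14, 5:10] <- 150   # 60 px
  img[25:34, 25:34] <- 150 # 100 px
  r1 <- nuclear_area_ratio(img, 2)
  up <- img[rep(1:40, each = 2), rep(1:40, each = 2)]
  expect_equal(nuclear_area_ratio(up, 2), r1)
  expect_equal(r1, 100 / 60)
})

test_that("population scoring returns exact binomial intervals and warns on small n", {
  calls <- tibble::tibble(
    genotype = "g1",
    cen5_class = c(rep("SPLIT_FAR", 30), rep("SINGLE_FOCUS", 15),
                   rep("SPLIT_CLOSE", 5)))
  tbl <- score_population(calls, n_target = 50)
  far <- tbl[tbl$category == "SPLIT_FAR", ]
  expect_equal(far$proportion, 0.6)
  expect_equal(far$count, 30L)
  ci <- binom.test(30, 50)$conf.int
  expect_equal(far$ci_low, ci[1])
  expect_equal(far$ci_high, ci[2])
  expect_warning(score_population(calls[1:10, ], n_target = 50), "scorable")
  expect_error(score_population(calls[0, ]), "non-empty")
})

test_that("per-cell pipeline recovers ground truth on small noiseless movies", {
  for (spec in list(list(gt = "wild_type", marker = "rec8",
                         expect = "PERICENTROMERIC"),
                    list(gt = "esp1_2", marker = "rec8",
                         expect = "RETAINED_EVERYWHERE"),
                    list(gt = "spo13d", marker = "rec8", expect = NULL))) {
    pop <- simulate_population(genotype_presets(spec$gt), 3, 21)
    movie <- render_movie(pop$outcomes, test_cfg(noise = FALSE), 22,
                          marker = spec$marker)
    calls <- analyze_movie(movie)
    expect_equal(calls$onset_frame, movie$truth$cells$onset_frame)
    expect_equal(calls$rec8_pattern, movie$truth$cells$rec8_pattern)
    expect_equal(calls$divisions, movie$truth$cells$divisions)
    if (!is.null(spec$expect)) {
      expect_true(all(calls$rec8_pattern == spec$expect))
    }
  }
})

test_that("biosensor state tracks separase activity on synthetic movies", {
  for (gt in c("esp1_2", "spo13d")) {
    pop <- simulate_population(genotype_presets(gt), 3, 31)
    movie <- render_movie(pop$outcomes, test_cfg(), 32, marker = "biosensor")
    calls <- analyze_movie(movie)
    want <- ifelse(movie$truth$cells$biosensor_cleaved, "CLEAVED", "INTACT")
    expect_equal(calls$biosensor_state, want)
  }
})
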