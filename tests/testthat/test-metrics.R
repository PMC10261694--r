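test_that("ROI statistics follow the CV definition with sample SD", {
  v <- array(0, dim = c(6, 6, 2))
  v[1, 1, 1] <- 1; v[1, 2, 1] <- 3
  vol <- pet_volume(v, 0.78, 3, "LC")
  st <- roi_stats(vol, roi_rect(1, c(1, 1), 1, 2))
  expect_equal(st$suv_mean, 2)
  expect_equal(st$sd, sqrt(2))
  expect_equal(st$cv, sqrt(2) / 2 * 100)

  cvol <- pet_volume(array(1.5, dim = c(6, 6, 1)), 0.78, 3, "LC")
  st <- roi_stats(cvol, roi_rect(1, c(2, 2), 3, 3))
  expect_equal(unlist(st[c("suv_mean", "sd", "cv")]), c(suv_mean = 1.5,
                                                        sd = 0, cv = 0))

  # CV is scale invariant
  set.seed(3)
  a <- array(abs(rnorm(72)) + 1, dim = c(6, 6, 2))
  roi <- roi_rect(2, c(2, 3), 4, 3)
  cv1 <- roi_stats(pet_volume(a, 1, 1, ""), roi)$cv
  cv2 <- roi_stats(pet_volume(a * 7.3, 1, 1, ""), roi)$cv
  expect_equal(cv1, cv2)

  # zero-mean ROI reports CV as missing
  zvol <- pet_volume(array(0, dim = c(4, 4, 1)), 1, 1, "")
  expect_true(is.na(roi_stats(zvol, roi_rect(1, c(1, 1), 2, 2))$cv))
})

test_that("circle membership is pixel-centre-within-radius", {
  roi <- roi_circle(1, c(20, 20), diameter_mm = 8, voxel_mm = 0.78)
  expected <- oracle_circle_pixels(c(20, 20), 8, 0.78)
  got <- roi$pixels[order(roi$pixels[, 1], roi$pixels[, 2]), ]
  expected <- expected[order(expected[, 1], expected[, 2]), ]
  expect_equal(unname(got), unname(expected))
})

test_that("lesion SUVmax/SUVpeak follow the VOI and 10 mm peak-ROI rules", {
  # uniform VOI: max = peak = value
  v <- array(1.5, dim = c(30, 30, 9))
  vol <- pet_volume(v, 0.78, 3, "LC")
  voi <- as.matrix(expand.grid(12:18, 12:18, 4:6))
  lm <- measure_lesion(vol, voi)
  expect_equal(lm$suv_max, 1.5)
  expect_equal(lm$suv_peak, 1.5)

  # single hot voxel in zero background: peak = h / N with N the pixel
  # count of the 10 mm circle at 0.78 mm pixels (independent enumeration)
  v <- array(0, dim = c(30, 30, 9))
  v[15, 15, 5] <- 4
  vol <- pet_volume(v, 0.78, 3, "LC")
  lm <- measure_lesion(vol, voi)
  n_px <- nrow(oracle_circle_pixels(c(15, 15), 10, 0.78))
  expect_equal(lm$suv_peak, 4 / n_px)
  expect_equal(lm$max_location, c(15L, 15L, 5L))

  # ties broken by lowest (slice, row, col)
  v <- array(0, dim = c(30, 30, 9))
  v[20, 10, 6] <- 2; v[10, 20, 6] <- 2; v[15, 15, 4] <- 2
  vol <- pet_volume(v, 0.78, 3, "LC")
  lm <- measure_lesion(vol, as.matrix(expand.grid(8:22, 8:22, 4:6)))
  expect_equal(lm$max_location, c(15L, 15L, 4L))

  # peak <= max on random volumes
  set.seed(9)
  for (i in 1:20) {
    v <- array(abs(rnorm(30 * 30 * 9)), dim = c(30, 30, 9))
    vol <- pet_volume(v, 0.78, 3, "LC")
    lm <- measure_lesion(vol, as.matrix(expand.grid(10:20, 10:20, 3:7)))
    expect_lte(lm$suv_peak, lm$suv_max)
  }

  # a peak ROI that would leave the grid is an error
  v <- array(0, dim = c(30, 30, 9)); v[2, 2, 5] <- 1
  vol <- pet_volume(v, 0.78, 3, "LC")
  expect_error(measure_lesion(vol, as.matrix(expand.grid(1:4, 1:4, 5))),
               "outside the image grid")
})

test_that("relative differences and Bland-Altman summaries are exact", {
  expect_equal(relative_difference(1.7, 1.7), 0)
  expect_equal(relative_difference(1.1, 1.0), 10)
  expect_equal(relative_difference(2.48, 1.70), 45.88235, tolerance = 1e-5)
  expect_error(relative_difference(1, 0), "> 0")

  expect_equal(bland_altman(c(0, 0, 0)), list(bias = 0, limits = 0))
  ba <- bland_altman(c(-1, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$limits, 1.96 * sqrt(2))
  expect_error(bland_altman(5), "at least two")

  # translation equivariance of the bias, invariance of the limits
  set.seed(4)
  d <- rnorm(15)
  b0 <- bland_altman(d); b1 <- bland_altman(d + 3.2)
  expect_equal(b1$bias, b0$bias + 3.2)
  expect_equal(b1$limits, b0$limits)
})

test_that("paired comparisons apply the Bonferroni correction and flag
           degenerate input", {
  set.seed(11)
  a <- rnorm(10); b <- a + rnorm(10, 0.5)
  pc <- paired_compare(a, b, "t", n_comparisons = 4)
  expect_equal(pc$p_raw, t.test(a, b, paired = TRUE)$p.value)
  expect_equal(pc$p_adj, min(1, 4 * pc$p_raw))

  pw <- paired_compare(a, b, "wilcoxon", n_comparisons = 4)
  expect_equal(pw$p_raw,
               suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                            exact = FALSE)$p.value))

  # the cap at 1
  c1 <- rnorm(20); c2 <- c1 + rnorm(20, 0, 2)
  pc2 <- paired_compare(c1, c2, "t", n_comparisons = 50)
  expect_lte(pc2$p_adj, 1)

  dg <- paired_compare(a, a, "t", n_comparisons = 4)
  expect_true(dg$degenerate)
  expect_false(dg$significant)
  expect_error(paired_compare(1:3, 1:4), "equal length")
})

test_that("MIP is the pixelwise max along the view axis", {
  v <- array(0, dim = c(8, 9, 10))
  v[3, 4, 5] <- 2.7
  vol <- pet_volume(v, 0.78, 3, "LC")
  cc <- mip(vol, "craniocaudal")
  expect_equal(dim(cc), c(9, 10))
  expect_equal(sum(cc > 0), 1L)
  expect_equal(max(cc), 2.7)

  set.seed(5)
  v <- array(abs(rnorm(8 * 9 * 10)), dim = c(8, 9, 10))
  vol <- pet_volume(v, 0.78, 3, "LC")
  ml <- mip(vol, "mediolateral")
  for (j in seq_len(9)) expect_true(all(ml >= v[, j, ]))

  cvol <- pet_volume(array(1.3, dim = c(4, 4, 4)), 1, 1, "")
  expect_true(all(mip(cvol, "craniocaudal") == 1.3))

  # inverse grayscale window
  img <- matrix(c(-1, 0, 2, 4, 5, 1), 2)
  g <- render_mip(img, window = c(0, 4))
  expect_equal(g, matrix(c(1, 1, 0.5, 0, 0, 0.75), 2))
})

test_that("background ROI placement honours the mask, gap and seed", {
  spec <- small_spec()
  act <- generate_activity_map(spec, seed = 2)
  vol <- pet_volume(act$values, spec$voxel_mm, 3, "LC")
  rois <- place_background_rois(vol, act$masks$gland, n = 5, seed = 31)
  expect_length(rois, 5L)
  slices <- vapply(rois, `[[`, 1L, "slice")
  expect_true(all(dist(slices) >= 5))
  for (r in rois) {
    inside <- act$masks$gland[cbind(r$pixels, r$slice)]
    expect_true(all(inside))
  }
  rois2 <- place_background_rois(vol, act$masks$gland, n = 5, seed = 31)
  expect_identical(rois, rois2)

  # infeasible: only one eligible slice
  gm <- act$masks$gland
  gm[, , -12] <- FALSE
  expect_error(place_background_rois(vol, gm, n = 5, seed = 1),
               "cannot place")
})

test_that("edge ROI placement puts tissue-confined rectangles 5 px from the
           chest-wall FOV edge on edge slices", {
  spec <- small_spec()
  act <- generate_activity_map(spec, seed = 2)
  vol <- pet_volume(act$values, spec$voxel_mm, 3, "LC")
  rois <- place_edge_rois(vol, act$masks$breast, n = 5, rect_px = c(10, 20),
                          seed = 13)
  expect_length(rois, 5L)
  for (r in rois) {
    expect_equal(nrow(r$pixels), 200L)
    expect_equal(min(r$pixels[, 1]), 6L)  # exactly 5 px from row-1 edge
    expect_true(all(act$masks$breast[cbind(r$pixels, r$slice)]))
    expect_true(r$slice <= 12 || r$slice > spec$n_slices - 12)
  }
  slices <- vapply(rois, `[[`, 1L, "slice")
  expect_true(all(dist(slices) >= 5))
  expect_identical(rois, place_edge_rois(vol, act$masks$breast, n = 5,
                                         rect_px = c(10, 20), seed = 13))
})
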