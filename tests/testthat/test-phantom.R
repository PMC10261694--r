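test_that("activity map carries tissue SUV levels and is deterministic", {
  spec <- small_spec()
  act <- generate_activity_map(spec, seed = 7)
  m <- act$masks
  expect_true(all(act$values[m$gland] == 1.18))
  expect_true(all(act$values[m$breast & !m$gland & !m$lesion] == 0.30))
  expect_true(all(act$values[!m$breast] == 0))
  act2 <- generate_activity_map(spec, seed = 7)
  expect_identical(act$values, act2$values)
  act3 <- generate_activity_map(spec, seed = 8)
  expect_false(identical(act$values, act3$values))
})

test_that("lesions are inserted as plateaus and validated against the mask", {
  spec <- small_spec()
  ctr <- c(10, 24, 12)  # inside the half-ellipsoid
  spec$lesions <- list(lesion("focus", ctr, diameter_mm = 6, suv = 2.84))
  act <- generate_activity_map(spec, seed = 1)
  expect_equal(max(act$values), 2.84)
  expect_equal(act$values[ctr[1], ctr[2], ctr[3]], 2.84)

  bad <- small_spec()
  bad$lesions <- list(lesion("focus", c(47, 47, 1), diameter_mm = 8,
                             suv = 3))
  expect_error(generate_activity_map(bad, seed = 1), "outside the breast")
})

test_that("an empty breast mask yields an all-zero volume", {
  spec <- small_spec(breast_semiaxes_rel = c(0, 0, 0))
  act <- generate_activity_map(spec, seed = 1)
  expect_true(all(act$values == 0))
})

test_that("axial sensitivity is 1 at the centre, edge_min at the ends, and
           unimodal", {
  model <- sensitivity_model(edge_min = 0.3)
  n <- 41L
  expect_equal(axial_sensitivity((n + 1) / 2, n, model), 1.0)
  expect_equal(axial_sensitivity(1, n, model), 0.3)
  expect_equal(axial_sensitivity(n, n, model), 0.3)
  prof <- axial_sensitivity(seq_len(n), n, model)
  # direct evaluation of the half-sine profile
  expect_equal(prof, 0.3 + 0.7 * sin(pi * (0:(n - 1)) / (n - 1)))
  half <- seq_len((n + 1) / 2)
  expect_true(all(diff(prof[half]) >= 0))
  expect_true(all(diff(prof[-half]) <= 0))
  expect_equal(prof, rev(prof))
  expect_error(axial_sensitivity(0, n, model), "out of range")
  expect_error(axial_sensitivity(n + 1, n, model), "out of range")
  lin <- axial_sensitivity(seq_len(5), 5, sensitivity_model(0.5, "linear"))
  expect_equal(lin, c(0.5, 0.75, 1, 0.75, 0.5))
})

test_that("simulated scans are unbiased with Poisson count statistics", {
  spec <- small_spec()
  act <- activity_volume(array(1.18, dim = c(50, 50, 11)), spacing = 0.78)

  # zero activity stays exactly zero
  zero <- activity_volume(array(0, dim = c(10, 10, 5)), spacing = 0.78)
  sim0 <- simulate_scan(zero, 3, spec, seed = 1)
  expect_true(all(sim0$values == 0))

  # large-count limit: values ~ activity, CV near zero
  spec_big <- small_spec(counts_per_suv_min = 1e6)
  simb <- simulate_scan(act, 3, spec_big, seed = 2)
  centre <- simb$values[, , 6]
  expect_lt(sd(centre) / mean(centre), 1e-3)
  expect_equal(mean(centre), 1.18, tolerance = 1e-3)

  # unbiasedness: mean within 3 standard errors of the truth
  sim <- simulate_scan(act, 3, spec, seed = 3)
  v <- sim$values[, , 6]
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 1.18), 3 * se)

  # determinism and error handling
  expect_identical(sim$values,
                   simulate_scan(act, 3, spec, seed = 3)$values)
  expect_error(simulate_scan(act, 0, spec, seed = 1), "positive")
})

test_that("voxel noise scales as 1/sqrt(duration) and rises at the axial
           edge", {
  spec <- phantom_spec(n_slices = 40, slice_shape = c(40, 40),
                       sensitivity = sensitivity_model(edge_min = 0.5))
  act <- activity_volume(array(1.18, dim = c(40, 40, 40)), spacing = 0.78)
  lc <- simulate_scan(act, 3, spec, seed = 11)
  fc <- simulate_scan(act, 7, spec, seed = 12)
  centre <- 16:25
  cv <- function(x) sd(x) / mean(x)
  ratio <- cv(lc$values[, , centre]) / cv(fc$values[, , centre])
  expect_equal(ratio, sqrt(7 / 3), tolerance = 0.05)
  edge <- c(1:5, 36:40)
  expect_gt(cv(lc$values[, , edge]), cv(lc$values[, , centre]))
})

test_that("paired datasets are reproducible and share the activity map", {
  spec <- small_spec()
  ds <- make_paired_dataset(spec, 1, seed = 5)
  expect_length(ds, 1L)
  expect_equal(ds[[1]]$lc$duration_min, 3)
  expect_equal(ds[[1]]$fc$duration_min, 7)
  ds2 <- make_paired_dataset(spec, 1, seed = 5)
  expect_identical(ds[[1]]$lc$values, ds2[[1]]$lc$values)
  expect_identical(ds[[1]]$fc$values, ds2[[1]]$fc$values)

  # both acquisitions unbiased for the same activity: gland-mean difference
  # is zero within Monte-Carlo error
  g <- ds[[1]]$activity$masks$gland
  dvals <- ds[[1]]$lc$values[g] - ds[[1]]$fc$values[g]
  se <- sd(dvals) / sqrt(length(dvals))
  expect_lt(abs(mean(dvals)), 3 * se)
})

test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(suv_fat = 1.5, suv_gland = 1.18), "suv_fat")
  expect_error(phantom_spec(duration_lc_min = 7, duration_fc_min = 3),
               "duration")
  expect_error(phantom_spec(counts_per_suv_min = 0), "counts_per_suv_min")
  expect_error(lesion("focus", c(1, 1, 1), diameter_mm = 12, suv = 3),
               "10 mm")
  expect_error(sensitivity_model(edge_min = 0), "edge_min")
})
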