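test_that("the pixel weight matrix follows its closed form", {
  img <- matrix(c(0.5, 0.6, 0.5, 0.9), 2)
  seeds <- holoproj:::seed_set(cbind(c(1, 2), c(1, 1)), "brain")
  w <- pixel_weight_matrix(img, seeds, kappa = 0.1)
  mu <- attr(w, "seed_reference_intensity")
  expect_equal(mu, 0.55)   # mean of 0.5 and 0.6
  expect_equal(w[1, 2], 1 / (1 + (0.05 / 0.1)^2))
  # weight 1 iff intensity equals the seed statistic
  img2 <- matrix(0.55, 2, 2)
  expect_equal(pixel_weight_matrix(img2, seeds, 0.1), matrix(1, 2, 2),
               ignore_attr = TRUE)
  # |diff| = kappa gives exactly 1/2
  img3 <- matrix(c(0.55, 0.65), 1, 2)
  s3 <- holoproj:::seed_set(cbind(1, 1), "brain")
  expect_equal(unclass(pixel_weight_matrix(img3, s3, 0.1))[1, 2], 0.5)
  # strictly decreasing in |diff|
  diffs <- seq(0, 1, by = 0.05)
  wts <- 1 / (1 + (diffs / 0.1)^2)
  expect_true(all(diff(wts) < 0))
  expect_error(pixel_weight_matrix(img, seeds, 0), "positive")
})

test_that("tumor seeding picks the brightest skull-stripped pixel with lexicographic ties", {
  img <- matrix(0.2, 8, 8)
  img[3, 7] <- 0.9
  img[5, 2] <- 0.9
  mask <- matrix(TRUE, 8, 8)
  s <- tumor_seed_point(img, mask)
  expect_equal(unname(s$points[1, ]), c(3L, 7L))
  # restricting the mask changes the answer
  mask2 <- matrix(FALSE, 8, 8)
  mask2[5, 2] <- TRUE
  expect_equal(unname(tumor_seed_point(img, mask2)$points[1, ]), c(5L, 2L))
  expect_error(tumor_seed_point(img, matrix(FALSE, 8, 8)), "empty")
})

test_that("brain seeds fall inside the brain and off the skull ring", {
  seeds <- brain_seed_points(fx_phantom$image)
  expect_gt(nrow(seeds$points), 50)
  expect_true(all(fx_phantom$brain_mask[seeds$points]))
  expect_error(brain_seed_points(matrix(0.5, 64, 64)), "no brain seeds")
})

test_that("a single skull-grade contour leaves no seeds after subtraction", {
  # both Canny passes detect the same strong contour, the difference is
  # empty, and the stage reports unusable contrast
  img <- matrix(0, 64, 64)
  img[20:44, 20:44] <- 0.9
  expect_error(brain_seed_points(img), "no brain seeds")
})

test_that("segmented masks grow monotonically with the arrival threshold", {
  set.seed(5)
  img <- matrix(0.5 + 0.05 * runif(64 * 64), 64, 64)
  seeds <- holoproj:::seed_set(cbind(32, 32), "brain")
  m1 <- segment_region(img, seeds,
                       segmentation_config(arrival_threshold = 0.1))$mask
  m2 <- segment_region(img, seeds,
                       segmentation_config(arrival_threshold = 0.2))$mask
  expect_true(all(m2[m1]))           # inclusion
  expect_gt(sum(m2), sum(m1))
  # threshold 1 covers every reached pixel
  mall <- segment_region(img, seeds,
                         segmentation_config(arrival_threshold = 1))$mask
  expect_true(all(mall))
})

test_that("gray mask is zero outside the binary mask", {
  sl <- fx_seg$slices[[1]]
  expect_true(all(sl$brain$gray_mask[!sl$brain$mask] == 0))
  expect_true(all(sl$tumor$gray_mask[!sl$tumor$mask] == 0))
})

test_that("end-to-end phantom segmentation recovers both regions (Dice >= 0.9)", {
  sl <- fx_seg$slices[[1]]
  expect_true(sl$tumor_present)
  expect_gte(dice(sl$brain$mask, fx_phantom$brain_mask), 0.9)
  expect_gte(dice(sl$tumor$mask, fx_phantom$tumor_mask), 0.9)
  # tumor contained in brain by construction
  expect_true(all(sl$tumor$mask <= sl$brain$mask))
  # the tumor seed itself lies inside the true tumor
  expect_true(fx_phantom$tumor_mask[sl$tumor_seed$points])
})

test_that("series segmentation flags tumor-free slices instead of failing", {
  ser <- make_series(phantom_config(), 4, c(2, 3))
  sg <- segment_brain_and_tumor(normalize_series(as_mr_series(ser)))
  present <- vapply(sg$slices, `[[`, TRUE, "tumor_present")
  expect_identical(present, c(FALSE, TRUE, TRUE, FALSE))
  expect_null(sg$slices[[1]]$tumor)
  d <- vapply(c(2, 3), function(i)
    dice(sg$slices[[i]]$tumor$mask, ser$tumor_masks[[i]]), 0)
  expect_true(mean(d) >= 0.9)
})

test_that("stage errors carry the slice index", {
  bad <- mr_series(list(matrix(0.5, 64, 64)), c(1, 1))
  expect_error(segment_brain_and_tumor(bad), "slice 1")
})
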