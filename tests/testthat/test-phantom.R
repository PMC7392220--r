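test_that("phantom generation is deterministic and respects its invariants", {
  cfg <- phantom_config(seed = 11L)
  a <- make_brain_slice(cfg)
  b <- make_brain_slice(cfg)
  expect_identical(a, b)

  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_true(all(a$tumor_mask <= a$brain_mask))  # tumor contained in brain
  expect_identical(dim(a$image), dim(a$brain_mask))

  c2 <- make_brain_slice(phantom_config(seed = 12L))
  expect_false(identical(a$image, c2$image))
})

test_that("an unperturbed noiseless tumor is an exact rasterized disk", {
  cfg <- phantom_config(irregularity = 0, noise_sigma = 0, tumor_radius = 12)
  p <- make_brain_slice(cfg)
  rr <- matrix(seq_len(nrow(p$image)), nrow(p$image), ncol(p$image))
  cc <- matrix(seq_len(ncol(p$image)), nrow(p$image), ncol(p$image),
               byrow = TRUE)
  disk <- sqrt((rr - cfg$tumor_center[1])^2 +
               (cc - cfg$tumor_center[2])^2) <= 12
  expect_identical(unname(p$tumor_mask), unname(disk))
})

test_that("the brightest in-brain pixel lies inside the tumor", {
  # exhaustive scan of a noiseless phantom; this property is what makes the
  # highest-intensity tumor-seeding rule well posed
  p <- make_brain_slice(phantom_config(noise_sigma = 0,
                                       tissue_intensity = 0.4,
                                       tumor_intensity = 0.8))
  vals <- p$image
  vals[!p$brain_mask] <- -1
  peak <- which(vals == max(vals), arr.ind = TRUE)
  expect_true(all(p$tumor_mask[peak]))
})

test_that("tumor placement escaping the brain is rejected", {
  cfg <- phantom_config(tumor_center = c(20, 20), tumor_radius = 18)
  expect_error(make_brain_slice(cfg), "outside brain")
  expect_error(make_followup_pair(phantom_config(tumor_radius = 40), 3),
               "outside brain")
})

test_that("series slices carry tumor exactly where requested, with taper", {
  ser <- make_series(phantom_config(), 6, c(3, 4))
  n_nonempty <- sum(vapply(ser$tumor_masks, function(m) any(m), TRUE))
  expect_identical(n_nonempty, 2L)
  expect_false(any(ser$tumor_masks[[1]]))
  expect_true(any(ser$tumor_masks[[3]]))

  all4 <- make_series(phantom_config(), 4, 1:4)
  areas <- vapply(all4$tumor_masks, sum, 0L)
  expect_true(all(areas > 0))
  expect_true(areas[1] <= areas[2])  # taper toward the range ends
  expect_true(areas[4] <= areas[3])

  expect_error(make_series(phantom_config(), 0), "n_slices")
  expect_error(make_series(phantom_config(), 3, 4), "tumor_slices")
})

test_that("follow-up pairs share geometry and scale the tumor by the growth factor", {
  same <- make_followup_pair(phantom_config(), 1)
  expect_identical(same$baseline$tumor_mask, same$progression$tumor_mask)
  expect_identical(same$baseline$brain_mask, same$progression$brain_mask)

  cfg0 <- phantom_config(irregularity = 0, noise_sigma = 0)
  grown <- make_followup_pair(cfg0, 2)
  ratio <- sum(grown$progression$tumor_mask) / sum(grown$baseline$tumor_mask)
  expect_lt(abs(ratio - 4), 0.2)  # area of a doubled-radius disk, +-5%

  shrunk <- make_followup_pair(phantom_config(), 0.5)
  dil <- EBImage::dilate(matrix(as.numeric(shrunk$baseline$tumor_mask),
                                nrow(shrunk$baseline$tumor_mask)),
                         EBImage::makeBrush(3L, "box")) > 0
  expect_true(all(dil[shrunk$progression$tumor_mask]))
  expect_error(make_followup_pair(phantom_config(), -1), "growth_factor")
})

test_that("written phantoms round-trip through the package readers", {
  dir <- withr::local_tempdir()
  p <- make_brain_slice(phantom_config())
  files <- write_phantom(p, dir, "t")
  img <- read_raster(file.path(dir, "t.pgm"))
  expect_equal(img, unname(p$image), tolerance = 1 / 65535)
  expect_identical(read_mask_png(file.path(dir, "t_tumor_mask.png")),
                   unname(p$tumor_mask))
  meta <- yaml::read_yaml(file.path(dir, "t.yml"))
  expect_equal(meta$pixel_spacing, 0.6875)
  expect_equal(meta$slice_separation, 6.5)
})
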