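test_that("rmse closed forms", {
  a <- matrix(0, 2, 2)
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(a, a + 1), 1)
  expect_equal(rmse(matrix(c(0, 0), 1), matrix(c(0, 1), 1)), 1 / sqrt(2))
  expect_error(rmse(matrix(0, 2, 2), matrix(0, 2, 3)), "share one shape")
})

test_that("scaled SNR removes the global intensity scale", {
  I <- matrix(c(1, 0), 1)
  Id <- matrix(c(0, 1), 1)
  out <- scaled_snr(I, Id)
  expect_equal(out$beta, 1)
  expect_equal(out$snr, 1 / 2)
  # proportional reconstructions are perfect (exact zero residual gives
  # Inf; floating-point residuals leave an astronomically large ratio)
  set.seed(4)
  J <- matrix(runif(16), 4)
  expect_equal(scaled_snr(J, 2 * J)$snr, Inf)
  expect_gt(scaled_snr(J, 3.7 * J)$snr, 1e9)
  # invariance under positive rescaling of the reconstruction
  K <- matrix(runif(16), 4)
  expect_equal(scaled_snr(J, K)$snr, scaled_snr(J, 250 * K)$snr,
               tolerance = 1e-9)
  expect_error(scaled_snr(J, J * 0), "all zero")
})

test_that("speckle contrast uses the population sd over the masked region", {
  expect_equal(speckle_contrast(matrix(5, 3, 3)), 0)
  v <- matrix(c(1, 3, 1, 3), 2)
  expect_equal(speckle_contrast(v), 0.5)      # sd 1, mean 2
  # scale invariance
  expect_equal(speckle_contrast(7 * v), 0.5)
  # fully developed speckle (unit-mean exponential intensity) has C ~ 1
  set.seed(8)
  s <- matrix(stats::rexp(200 * 200), 200)
  expect_lt(abs(speckle_contrast(s) - 1), 0.02)
  expect_error(speckle_contrast(matrix(0, 2, 2)), "zero mean")
})

test_that("dice handles overlap, disjointness and the empty convention", {
  m <- matrix(FALSE, 4, 4)
  a <- m; a[1:2, 1:2] <- TRUE
  b <- m; b[1:2, 2:3] <- TRUE
  disj <- m; disj[3:4, 3:4] <- TRUE
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, disj), 0)
  expect_equal(dice(a, m), 0)                 # one empty, one not
  expect_equal(dice(a, b), 0.5)               # 2*2 / (4+4)
  expect_equal(dice(m, m), 1)                 # both empty counts as correct
  expect_equal(dice(a, b), dice(b, a))        # symmetry
})

test_that("BF score matches boundaries within the pixel tolerance", {
  a <- matrix(FALSE, 20, 20)
  a[5:12, 5:12] <- TRUE
  expect_equal(bf_score(a, a), 1)
  shifted <- matrix(FALSE, 20, 20)
  shifted[6:13, 5:12] <- TRUE
  expect_equal(bf_score(a, shifted, tolerance = 2), 1)
  expect_equal(bf_score(a, shifted, tolerance = 2),
               bf_score(shifted, a, tolerance = 2))
  far <- matrix(FALSE, 20, 20)
  far[16:19, 16:19] <- TRUE
  expect_equal(bf_score(a, far, tolerance = 2), 0)
  empty <- matrix(FALSE, 20, 20)
  expect_equal(bf_score(empty, empty), 1)
  expect_equal(bf_score(a, empty), 0)
})

test_that("region properties follow the pixel-square hull convention", {
  rect <- matrix(FALSE, 12, 12)
  rect[3:7, 4:9] <- TRUE
  rp <- region_properties(rect, 1)
  expect_equal(rp$solidity, 1)                # convex region
  expect_equal(rp$area_cm2, 30 / 100)
  # 5-pixel plus sign: hull of the pixel squares is a 3x3 square minus the
  # four corner triangles, area 7
  plus <- matrix(FALSE, 7, 7)
  plus[4, 3:5] <- TRUE
  plus[3:5, 4] <- TRUE
  expect_equal(region_properties(plus, 1)$solidity, 5 / 7)
  # 10x10 at 0.5 mm -> 100 * 0.25 mm^2 = 0.25 cm^2
  sq <- matrix(TRUE, 10, 10)
  expect_equal(region_properties(sq, 0.5)$area_cm2, 0.25)
  emp <- region_properties(matrix(FALSE, 3, 3), 1)
  expect_equal(emp$area_cm2, 0)
  expect_true(is.na(emp$solidity))
})

test_that("tumor volume is area times slice spacing", {
  m <- matrix(FALSE, 20, 20)
  m[1:10, 1:10] <- TRUE                       # 100 px
  expect_equal(tumor_volume(list(m), 1, 6.5), 100 * 0.01 * 0.65)
  expect_equal(tumor_volume(list(m, m), 1, 6.5),
               2 * tumor_volume(list(m), 1, 6.5))
  expect_equal(tumor_volume(list(m), 1, 13),
               2 * tumor_volume(list(m), 1, 6.5))  # linear in separation
  expect_equal(tumor_volume(list(m * FALSE), 1, 6.5), 0)
  expect_equal(tumor_volume(list(m), 1, 6.5, slice_thickness = 5,
                            mode = "thickness"),
               100 * 0.01 * 0.5)
  # dimensional scaling in the pixel spacing
  expect_equal(tumor_volume(list(m), 2, 6.5), 4 * tumor_volume(list(m), 1, 6.5))
})
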