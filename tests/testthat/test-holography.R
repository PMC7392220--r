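test_that("zero padding centers the image and preserves its sum", {
  img <- matrix(runif(12), 3, 4)
  out <- zero_pad_center(img, c(9, 10))
  expect_identical(dim(out), c(9L, 10L))
  expect_equal(sum(out), sum(img))
  expect_equal(out[4:6, 4:7], img)
  # factor-1 padding of an already padded image is the identity
  expect_identical(zero_pad_center(out, c(9, 10)), out)
  expect_error(zero_pad_center(matrix(0, 5, 5), c(4, 4)), "larger")
})

test_that("IFTA converges immediately for an impulse and always emits pure phase", {
  imp <- matrix(0, 32, 32)
  imp[17, 17] <- 1  # the zero-frequency position of the centered transform
  fit <- ifta(imp, max_iter = 50, optics = fx_optics)
  expect_identical(fit$trace$iterations, 1L)
  expect_true(fit$trace$converged)
  expect_equal(fit$trace$rmse[1], 0, tolerance = 1e-12)
  expect_equal(fit$hologram$phase, matrix(0, 32, 32), tolerance = 1e-9)
  expect_equal(Mod(exp(1i * fit$hologram$phase)), matrix(1, 32, 32))

  expect_error(ifta(matrix(0, 4, 4)), "all zero")
  expect_error(ifta(matrix(-1, 4, 4)), "nonnegative")
})

test_that("IFTA reduces the reconstruction error on a binary target", {
  pad <- zero_pad_center(text_target(), c(256, 256))
  fit <- ifta(pad, max_iter = 60, epsilon = 0.05,
              optics = optics_config(slm_shape = c(64, 64)))
  tr <- fit$trace
  expect_lte(tr$rmse[tr$iterations], tr$rmse[1])
  expect_lt(tr$rmse[tr$iterations], 0.05)
  expect_true(tr$converged || tr$iterations == 60L)
  if (tr$converged)
    expect_lt(tr$phase_change[tr$iterations], 0.05)
})

test_that("chirp and ramp modulators satisfy their group properties", {
  sh <- c(24, 32)
  chi <- chirp_phase(sh, 6.5e-3, fx_optics)
  expect_equal(Mod(chi), matrix(1, sh[1], sh[2]))
  expect_equal(chi * chirp_phase(sh, -6.5e-3, fx_optics),
               matrix(1 + 0i, sh[1], sh[2]))
  expect_equal(chirp_phase(sh, 0, fx_optics), matrix(1 + 0i, sh[1], sh[2]))
  # scalar oracle at one frequency sample
  o <- fx_optics
  v <- c(3, -5) * o$slm_pixel_pitch / (o$wavelength * o$focal_length)
  expected <- exp(1i * o$k * o$wavelength^2 / 2 * 6.5e-3 * sum(v^2))
  expect_equal(chi[holoproj:::center_index(sh[1]) + 3,
                   holoproj:::center_index(sh[2]) - 5], expected)

  r1 <- ramp_phase(sh, c(2, 3), 1e-2, fx_optics)
  r2 <- ramp_phase(sh, c(-1, 4), 1e-2, fx_optics)
  r12 <- ramp_phase(sh, c(1, 7), 1e-2, fx_optics)
  expect_equal(r1 * r2, r12)
  expect_equal(ramp_phase(sh, c(0, 0), 1e-2, fx_optics),
               matrix(1 + 0i, sh[1], sh[2]))
  expect_error(ramp_phase(sh, c(1, 0), 0, fx_optics), "nonzero")
})

test_that("bin-aligned ramps shift the reconstruction exactly", {
  fit <- ifta(zero_pad_center(text_target(64), fx_shape), 10,
              optics = fx_optics)
  h <- fit$hologram
  shift <- c(7, -11)
  ramped <- phase_hologram(
    Arg(exp(1i * h$phase) * ramp_phase(fx_shape, shift, 1e-2, fx_optics)),
    fx_optics)
  i0 <- fourier_reconstruct(h)$intensity
  i1 <- fourier_reconstruct(ramped)$intensity
  expect_lt(max(abs(i1 - holoproj:::circshift2(i0, shift))), 1e-9)
})

test_that("layer modulation preserves modulus and moves the reconstruction peak", {
  imp <- matrix(0, fx_shape[1], fx_shape[2])
  imp[fx_shape[1] / 2 + 1, fx_shape[2] / 2 + 1] <- 1
  h <- ifta(imp, 5, optics = fx_optics)$hologram
  # near-zero z: the chirp is essentially flat, so the ramp alone moves the
  # peak; the matching-z focus test below covers the defocusing chirp
  lay <- layer_spec(z = 1e-6, shift = c(40, -60))
  u <- modulate_layer(h, lay, fx_optics)
  expect_equal(Mod(u), matrix(1, fx_shape[1], fx_shape[2]))
  # a zero layer is the identity
  u0 <- modulate_layer(h, layer_spec(0, c(0, 0)), fx_optics)
  expect_equal(u0, exp(1i * h$phase))
  rec <- Mod(holoproj:::ifft2c(u))^2
  peak <- which(rec == max(rec), arr.ind = TRUE)[1, ]
  expect_equal(unname(peak),
               c(fx_shape[1] / 2 + 1 + 40, fx_shape[2] / 2 + 1 - 60))
  expect_error(superpose_layers(list(u, matrix(1 + 0i, 4, 4)), fx_optics),
               "share one shape")
})

test_that("superposition takes the argument of the complex sum", {
  f <- exp(1i * matrix(runif(12, 0, 2 * pi), 3, 4))
  h <- superpose_layers(list(f), fx_optics)
  expect_equal(h$phase, holoproj:::wrap_phase(Arg(f)))
  # an exactly cancelled pixel gets phase 0 by convention
  g <- matrix(1 + 0i, 2, 2)
  g2 <- -g
  expect_equal(superpose_layers(list(g, g2), fx_optics)$phase,
               matrix(0, 2, 2))
  expect_error(superpose_layers(list(), fx_optics), "at least one")
})

test_that("a four-layer stack reconstructs four peaks at the configured shifts", {
  imp <- matrix(0, fx_shape[1], fx_shape[2])
  imp[fx_shape[1] / 2 + 1, fx_shape[2] / 2 + 1] <- 1
  shifts <- list(c(-60, -80), c(-60, 80), c(60, -80), c(60, 80))
  layers <- lapply(1:4, function(s) layer_spec(1e-3, shifts[[s]], s))
  built <- build_tumor_stack_hologram(rep(list(imp), 4), layers, fx_optics,
                                      max_iter = 3)
  rec <- fourier_reconstruct(built$hologram)$intensity
  top4 <- arrayInd(order(rec, decreasing = TRUE)[1:4], dim(rec))
  got <- top4 - matrix(rep(fx_shape / 2 + 1, each = 4), 4)
  expect_setequal(apply(got, 1, paste, collapse = ","),
                  vapply(shifts, paste, "", collapse = ","))
  expect_warning(
    build_tumor_stack_hologram(rep(list(imp), 2),
                               lapply(1:2, function(s)
                                 layer_spec(1e-3, c(10, 10), s)),
                               fx_optics, max_iter = 2),
    "overlap")
})

test_that("a degenerate single-layer stack equals the plain IFTA phase", {
  targ <- zero_pad_center(text_target(48), fx_shape)
  built <- build_tumor_stack_hologram(list(targ), list(layer_spec(0, c(0, 0))),
                                      fx_optics, max_iter = 8)
  plain <- ifta(targ, max_iter = 8, optics = fx_optics)
  expect_equal(built$hologram$phase, plain$hologram$phase, tolerance = 1e-12)
})

test_that("a chirped layer comes back into focus under its matching inverse chirp", {
  sl <- fx_seg$slices[[1]]
  supp <- pad_mask(sl$tumor$mask)
  fit <- ifta(zero_pad_center(sl$tumor$gray_mask, fx_shape), 30,
              optics = fx_optics)
  z0 <- 0.05
  u <- modulate_layer(fit$hologram, layer_spec(z = z0), fx_optics)
  conc <- vapply(c(0, z0 / 2, z0, 1.5 * z0), function(z) {
    rec <- Mod(holoproj:::ifft2c(u * chirp_phase(fx_shape, -z, fx_optics)))^2
    sum(rec[supp]) / sum(rec)
  }, 0)
  expect_identical(which.max(conc), 3L)
})

test_that("tiling partitions the extended hologram in row-major order", {
  fit <- ifta(zero_pad_center(text_target(48), fx_shape), 3,
              optics = fx_optics)
  tiles <- tile_hologram(fit$hologram)
  expect_length(tiles, 16L)
  for (t in tiles) expect_identical(dim(t$phase), fx_optics$slm_shape)
  # reassemble
  rebuilt <- matrix(0, fx_shape[1], fx_shape[2])
  idx <- 0L
  for (tr in 1:4) for (tc in 1:4) {
    idx <- idx + 1L
    rebuilt[(tr - 1) * 96 + 1:96, (tc - 1) * 128 + 1:128] <-
      tiles[[idx]]$phase
  }
  expect_identical(rebuilt, fit$hologram$phase)
  # factor-1 "tiling" is the hologram itself
  h1 <- phase_hologram(fit$hologram$phase[1:96, 1:128], fx_optics)
  t1 <- tile_hologram(h1)
  expect_length(t1, 1L)
  expect_identical(t1[[1]]$phase, h1$phase)
  bad <- phase_hologram(matrix(0, 100, 130), fx_optics)
  expect_error(tile_hologram(bad), "integer multiple")
})

test_that("comparative holograms highlight the tumor and separate the exams", {
  sl <- fx_seg$slices[[1]]
  shift <- c(0, round(fx_shape[2] / 4))
  tumor_fp <- pad_mask(sl$tumor$mask)
  means <- vapply(c(1, 2), function(g) {
    built <- build_comparative_hologram(
      sl$brain$gray_mask, sl$tumor$gray_mask,
      sl$brain$gray_mask, sl$tumor$gray_mask,
      gamma = g, shift = shift, optics = fx_optics, max_iter = 20)
    rec <- fourier_reconstruct(built$hologram)$intensity
    mean(rec[tumor_fp])
  }, 0)
  expect_gt(means[2], means[1])  # gamma = 2 highlights

  # zero tumor fields degenerate to the brain-only superposition
  zero <- matrix(0, 320, 260)
  built0 <- build_comparative_hologram(
    sl$brain$gray_mask, zero, sl$brain$gray_mask, zero,
    gamma = 2, shift = shift, optics = fx_optics, max_iter = 10)
  expect_true(all(is.finite(built0$hologram$phase)))
  rec0 <- fourier_reconstruct(built0$hologram)$intensity
  brain_fp <- pad_mask(sl$brain$mask)
  both <- brain_fp | holoproj:::circshift2(brain_fp, shift)
  expect_gt(mean(rec0[both]), mean(rec0[!both]))
})
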