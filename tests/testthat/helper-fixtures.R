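# shared fixtures, built once per test run

# the default phantom and its segmentation are used by several files
fx_phantom <- make_brain_slice(phantom_config())
fx_seg <- segment_brain_and_tumor(normalize_series(as_mr_series(fx_phantom)))

# small optics keep hologram tests fast; the extended frame is 384 x 512
fx_optics <- optics_config(slm_shape = c(96L, 128L))
fx_shape <- fx_optics$slm_shape * 4L

pad_mask <- function(mask, shape = fx_shape)
  zero_pad_center(matrix(as.numeric(mask), nrow(mask)), shape) > 0

# a star-like binary test target for phase retrieval
text_target <- function(n = 128L, seed = 7L) {
  set.seed(seed)
  m <- matrix(0, n, n)
  for (i in 1:12) {
    r <- sample(10:(n - 12), 1)
    c <- sample(10:(n - 12), 1)
    m[r:(r + 6), c:(c + sample(3:10, 1))] <- 1
  }
  m
}
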