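# internal numeric helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("'%s' must be a numeric matrix", name)
  invisible(x)
}

same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stopf("%s must share one shape (got %s vs %s)", what,
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

as_mask <- function(x) {
  if (is.logical(x)) {
    m <- x
  } else {
    m <- x != 0
  }
  dim(m) <- dim(x)
  m
}

# reflect (mirror) out-of-range indices into 1..n
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  ifelse(j < n, j + 1L, p - j + 1L)
}

# separable Gaussian blur with mirrored boundaries; radius 3*sigma
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m, along) {
    n <- if (along == 1L) nrow(m) else ncol(m)
    out <- matrix(0, nrow(m), ncol(m))
    for (o in -r:r) {
      idx <- reflect_index(seq_len(n) + o, n)
      out <- out + k[o + r + 1L] *
        (if (along == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
    }
    out
  }
  conv1(conv1(x, 1L), 2L)
}

# centred unitary 2D transforms: the zero frequency sits at
# (floor(nr/2)+1, floor(nc/2)+1), matching the modulation grids.
shift_gather <- function(n, o) ((seq_len(n) - 1L + o) %% n) + 1L

fftshift2 <- function(x)
  x[shift_gather(nrow(x), ceiling(nrow(x) / 2)),
    shift_gather(ncol(x), ceiling(ncol(x) / 2)), drop = FALSE]

ifftshift2 <- function(x)
  x[shift_gather(nrow(x), floor(nrow(x) / 2)),
    shift_gather(ncol(x), floor(ncol(x) / 2)), drop = FALSE]

fft2c <- function(x)
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))

ifft2c <- function(x)
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))

center_index <- function(n) floor(n / 2) + 1L

# wrap phase into [0, 2*pi)
wrap_phase <- function(x) x %% (2 * pi)

# wrap a phase difference into (-pi, pi]
wrap_diff <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

label8 <- function(mask) label8_c(as_mask(mask))

fill_holes <- function(mask) {
  f <- EBImage::fillHull(matrix(as.integer(mask), nrow(mask)))
  matrix(as.logical(f > 0), nrow(mask))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
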