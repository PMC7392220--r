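# Independent oracle for the Eikonal solve: Gauss-Seidel value iteration of
# the same first-order upwind update, swept in alternating directions until
# a fixed point.  Kept deliberately separate from the package's heap-based
# fast-marching implementation.
eik_value_iteration <- function(W, seeds, tol = 1e-12) {
  n <- nrow(W)
  m <- ncol(W)
  T <- matrix(Inf, n, m)
  for (s in seq_len(nrow(seeds))) T[seeds[s, 1], seeds[s, 2]] <- 0
  repeat {
    Told <- T
    for (pass in 1:4) {
      ri <- if (pass %% 2) 1:n else n:1
      ci <- if (pass < 3) 1:m else m:1
      for (i in ri) for (j in ci) {
        if (T[i, j] == 0) next
        a <- min(if (i > 1) T[i - 1, j] else Inf,
                 if (i < n) T[i + 1, j] else Inf)
        b <- min(if (j > 1) T[i, j - 1] else Inf,
                 if (j < m) T[i, j + 1] else Inf)
        if (is.infinite(a) && is.infinite(b)) next
        f <- 1 / W[i, j]
        t <- if (max(a, b) - min(a, b) >= f) min(a, b) + f
             else (a + b + sqrt(2 * f^2 - (a - b)^2)) / 2
        if (t < T[i, j]) T[i, j] <- t
      }
    }
    newly_finite <- sum(is.finite(T) & !is.finite(Told))
    both <- is.finite(T) & is.finite(Told)
    if (newly_finite == 0 && max(abs(T - Told)[both], 0) < tol) break
  }
  T
}

# brute-force Euclidean distance from every pixel to a mask's pixel set
brute_min_dist <- function(mask, points) {
  idx <- which(mask, arr.ind = TRUE)
  apply(points, 1L, function(p)
    min(sqrt((idx[, 1] - p[1])^2 + (idx[, 2] - p[2])^2)))
}
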