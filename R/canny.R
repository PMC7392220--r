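#' Canny edge detection
#'
#' Gaussian smoothing, central-difference gradients, non-maximum suppression
#' along the quantized gradient direction, and double-threshold hysteresis
#' keeping weak ridge pixels that are 8-connected to strong ones.  The
#' gradient magnitude is normalized by its maximum, so `low`/`high` are
#' relative thresholds in `[0, 1]` (the convention under which the printed
#' 0.1/0.2 pair separates faint tissue contours from high-contrast skull and
#' tumor contours).
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param low lower hysteresis threshold (ridge pixels at or below it are
#'   discarded).
#' @param high upper threshold defining strong edge points.
#' @param sigma Gaussian smoothing sigma in pixels.
#' @return Logical edge mask, one pixel wide along ridges.
#' @export
canny_edges <- function(image, low = 0, high, sigma = 1.4) {
  check_matrix(image)
  if (high <= low) stopf("'high' must exceed 'low' (got %g <= %g)", high, low)
  if (low < 0 || high > 1) stopf("thresholds must lie in [0, 1]")
  nr <- nrow(image)
  nc <- ncol(image)
  g <- gaussian_blur(image, sigma)

  shift <- function(m, dr, dc, fill = 0) {
    out <- matrix(fill, nr, nc)
    rs <- seq_len(nr) + dr
    cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr
    ok_c <- cs >= 1L & cs <= nc
    out[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c], drop = FALSE]
    out
  }
  # central differences with replicated borders (no spurious border edges)
  clamp_shift <- function(m, dr, dc)
    m[pmin(pmax(seq_len(nr) + dr, 1L), nr),
      pmin(pmax(seq_len(nc) + dc, 1L), nc), drop = FALSE]
  gy <- (clamp_shift(g, 1L, 0L) - clamp_shift(g, -1L, 0L)) / 2   # d/drow
  gx <- (clamp_shift(g, 0L, 1L) - clamp_shift(g, 0L, -1L)) / 2   # d/dcol
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, nr, nc))
  mag <- mag / mmax

  # quantize the gradient direction into 4 sectors and suppress non-maxima;
  # exact plateau ties break toward the leading neighbour so ridges stay one
  # pixel wide even for a step located between two pixel columns
  ang <- atan2(gy, gx) %% pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4
  nb <- function(dr, dc) shift(mag, dr, dc, fill = -Inf)
  keep <- matrix(FALSE, nr, nc)
  pairs <- list(`0` = c(0L, 1L), `1` = c(1L, 1L),
                `2` = c(1L, 0L), `3` = c(1L, -1L))
  for (s in 0:3) {
    d <- pairs[[as.character(s)]]
    sel <- sector == s
    keep[sel] <- mag[sel] > nb(d[1], d[2])[sel] &
                 mag[sel] >= nb(-d[1], -d[2])[sel]
  }
  keep <- keep & mag > 0

  weak <- keep & mag > low
  strong <- keep & mag >= high
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  lab <- label8(weak)
  good <- unique(lab[strong])
  weak & matrix(lab %in% good, nr, nc)
}
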