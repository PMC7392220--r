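#' Root mean square error between two images
#'
#' @param reference,test equal-shape numeric matrices, both expected on a
#'   common `[0, 1]` scale.
#' @return Scalar RMSE.
#' @export
rmse <- function(reference, test) {
  same_shape(reference, test, "rmse() inputs")
  sqrt(mean((reference - test)^2))
}

#' Scaled signal-to-noise ratio
#'
#' `SNR = ||I||^2 / ||I - beta I_d||^2` with the scale factor
#' `beta = ||I|| / ||I_d||`, so the result is invariant to any positive
#' rescaling of the reconstructed intensity.  A perfect (proportional)
#' reconstruction gives `Inf`.
#'
#' @param I reference intensity (not all zero).
#' @param I_d reconstructed intensity (not all zero).
#' @return List with `snr` and `beta`.
#' @export
scaled_snr <- function(I, I_d) {
  same_shape(I, I_d, "scaled_snr() inputs")
  nI2 <- sum(I^2)
  nD2 <- sum(I_d^2)
  if (nI2 == 0) stopf("reference intensity is all zero")
  if (nD2 == 0) stopf("reconstructed intensity is all zero (beta undefined)")
  beta <- sqrt(nI2 / nD2)
  denom <- sum((I - beta * I_d)^2)
  list(snr = if (denom == 0) Inf else nI2 / denom, beta = beta)
}

#' Speckle contrast
#'
#' `C = sigma / mu` over the masked region, with the population standard
#' deviation; invariant to positive rescaling of the intensity.  Fully
#' developed speckle has `C = 1`; incoherent averaging lowers it.
#'
#' @param intensity nonnegative intensity raster.
#' @param region_mask logical mask of the evaluation region (default: all).
#' @return Scalar contrast.
#' @export
speckle_contrast <- function(intensity, region_mask = NULL) {
  if (is.null(region_mask))
    region_mask <- matrix(TRUE, nrow(intensity), ncol(intensity))
  region_mask <- as_mask(region_mask)
  same_shape(intensity, region_mask, "intensity and region_mask")
  if (!any(region_mask)) stopf("empty evaluation region")
  v <- intensity[region_mask]
  mu <- mean(v)
  if (mu == 0) stopf("zero mean intensity in the evaluation region")
  sqrt(mean((v - mu)^2)) / mu
}

#' Dice similarity coefficient
#'
#' `2 |A and B| / (|A| + |B|)`; two empty masks score 1 (a correctly empty
#' prediction is correct).
#'
#' @param mask_a,mask_b equal-shape logical masks.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  a <- as_mask(mask_a)
  b <- as_mask(mask_b)
  same_shape(a, b, "dice() masks")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

boundary_pixels <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  inner <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr
    cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr
    ok_c <- cs >= 1L & cs <= nc
    sh[which(ok_r), which(ok_c)] <- mask[rs[ok_r], cs[ok_c], drop = FALSE]
    inner <- inner & sh
  }
  mask & !inner
}

#' Boundary F1 (BF) score
#'
#' Harmonic mean of boundary precision and recall: the fraction of one
#' mask's boundary pixels lying within `tolerance` (Euclidean pixels) of
#' the other's, and vice versa.  Two empty masks score 1.
#'
#' @param mask_a,mask_b equal-shape logical masks.
#' @param tolerance match distance in pixels; default 0.75% of the image
#'   diagonal (the customary convention for this metric).
#' @return Scalar in `[0, 1]`.
#' @export
bf_score <- function(mask_a, mask_b, tolerance = NULL) {
  a <- as_mask(mask_a)
  b <- as_mask(mask_b)
  same_shape(a, b, "bf_score() masks")
  if (is.null(tolerance))
    tolerance <- 0.0075 * sqrt(sum(dim(a)^2))
  ba <- boundary_pixels(a)
  bb <- boundary_pixels(b)
  if (!any(ba) && !any(bb)) return(1)
  if (!any(ba) || !any(bb)) return(0)
  dist_to <- function(bnd) {
    # distance of every pixel to the nearest boundary pixel
    EBImage::distmap(matrix(as.numeric(!bnd), nrow(bnd)), "euclidean")
  }
  da <- dist_to(ba)
  db <- dist_to(bb)
  precision <- mean(db[ba] <= tolerance)
  recall <- mean(da[bb] <= tolerance)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Region area and solidity
#'
#' Area is the pixel count scaled to cm^2 by the pixel spacing.  Solidity
#' is the region's pixel area divided by the area of the convex hull of the
#' union of its pixel squares (each pixel treated as a unit square), so a
#' filled convex region scores exactly 1.
#'
#' @param mask logical mask.
#' @param pixel_spacing mm per pixel, (row, col) (a scalar is recycled).
#' @return List with `area_cm2` and `solidity` (`NA` for an empty mask).
#' @export
region_properties <- function(mask, pixel_spacing) {
  m <- as_mask(mask)
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  if (any(pixel_spacing <= 0)) stopf("pixel_spacing must be positive")
  n <- sum(m)
  if (n == 0) return(list(area_cm2 = 0, solidity = NA_real_))
  area_cm2 <- n * pixel_spacing[1] * pixel_spacing[2] / 100
  px <- which(m, arr.ind = TRUE)
  corners <- rbind(cbind(px[, 1] - 0.5, px[, 2] - 0.5),
                   cbind(px[, 1] - 0.5, px[, 2] + 0.5),
                   cbind(px[, 1] + 0.5, px[, 2] - 0.5),
                   cbind(px[, 1] + 0.5, px[, 2] + 0.5))
  corners <- unique(corners)
  h <- grDevices::chull(corners)
  hp <- corners[h, , drop = FALSE]
  # shoelace
  x <- hp[, 1]
  y <- hp[, 2]
  hull_area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  list(area_cm2 = area_cm2, solidity = n / hull_area)
}

#' Tumor volume from per-slice masks
#'
#' Sum over slices of the slice's area times the slice spacing, in cm^3.
#' The spacing defaults to the center-to-center slice separation; the
#' alternative convention (slice thickness) is selectable.
#'
#' @param masks list of logical masks (one per slice).
#' @param pixel_spacing mm per pixel.
#' @param slice_separation mm between slice centers.
#' @param slice_thickness mm; used when `mode = "thickness"`.
#' @param mode which axial extent multiplies each slice area.
#' @return Volume in cm^3.
#' @export
tumor_volume <- function(masks, pixel_spacing, slice_separation,
                         slice_thickness = NULL,
                         mode = c("separation", "thickness")) {
  mode <- match.arg(mode)
  if (!length(masks)) stopf("need at least one mask")
  step_mm <- if (mode == "separation") slice_separation else slice_thickness
  if (is.null(step_mm) || step_mm <= 0) stopf("axial spacing must be positive")
  areas <- vapply(masks, function(m)
    region_properties(m, pixel_spacing)$area_cm2, 0)
  sum(areas) * step_mm / 10
}

#' Full metrics report for a reconstruction + segmentation
#'
#' Convenience wrapper bundling every quantitative figure used to assess a
#' run into one list.
#'
#' @param reference,reconstructed intensity rasters for RMSE/SNR (optional).
#' @param speckle_region mask for the speckle contrast (optional).
#' @param pred_mask,truth_mask segmentation masks for Dice/BF (optional).
#' @param pixel_spacing mm per pixel for region properties.
#' @return A named list of metrics (entries `NULL` when inputs are absent).
#' @export
metrics_report <- function(reference = NULL, reconstructed = NULL,
                           speckle_region = NULL, pred_mask = NULL,
                           truth_mask = NULL, pixel_spacing = NULL) {
  out <- list()
  if (!is.null(reference) && !is.null(reconstructed)) {
    out$rmse <- rmse(normalize_intensity(reference),
                     normalize_intensity(reconstructed))
    sn <- scaled_snr(reference, reconstructed)
    out$snr <- sn$snr
    out$beta_snr <- sn$beta
    out$speckle_contrast <- speckle_contrast(reconstructed, speckle_region)
  }
  if (!is.null(pred_mask) && !is.null(truth_mask)) {
    out$dice <- dice(pred_mask, truth_mask)
    out$bf_score <- bf_score(pred_mask, truth_mask)
  }
  if (!is.null(pred_mask) && !is.null(pixel_spacing)) {
    rp <- region_properties(pred_mask, pixel_spacing)
    out$area_cm2 <- rp$area_cm2
    out$solidity <- rp$solidity
  }
  out
}
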