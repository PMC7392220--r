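#' Segmentation configuration
#'
#' Holds the tunable parameters of the automated brain/tumor extraction:
#' the two Canny high thresholds (0.1 and 0.2) whose edge-map difference
#' yields the brain seed points, the arrival-time threshold applied to the
#' normalized fast-marching map (0.009), and the softness `kappa` of the
#' intensity-difference weight function.
#'
#' @param canny_high_1,canny_high_2 relative Canny high thresholds,
#'   `canny_high_1 < canny_high_2`.
#' @param canny_low lower hysteresis threshold (0 keeps every weak ridge
#'   pixel connected to a strong one).
#' @param canny_sigma Gaussian sigma for the edge detector.
#' @param opening_size minimum pixel count of a seed component; smaller
#'   8-connected components of the edge-map difference are removed (area
#'   opening).
#' @param arrival_threshold threshold in `(0, 1)` on normalized arrival
#'   times.
#' @param kappa positive softness of the weight function
#'   `W = 1 / (1 + (diff / kappa)^2)`.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(canny_high_1 = 0.1, canny_high_2 = 0.2,
                                canny_low = 0, canny_sigma = 1.4,
                                opening_size = 8L,
                                arrival_threshold = 0.009, kappa = 0.1) {
  if (canny_high_1 >= canny_high_2)
    stopf("canny_high_1 must be < canny_high_2")
  if (arrival_threshold <= 0 || arrival_threshold > 1)
    stopf("arrival_threshold must lie in (0, 1]")
  if (kappa <= 0) stopf("kappa must be positive")
  structure(list(canny_high_1 = canny_high_1, canny_high_2 = canny_high_2,
                 canny_low = canny_low, canny_sigma = canny_sigma,
                 opening_size = as.integer(opening_size),
                 arrival_threshold = arrival_threshold, kappa = kappa),
            class = "segmentation_config")
}

seed_set <- function(points, kind = c("brain", "tumor")) {
  kind <- match.arg(kind)
  points <- matrix(as.integer(points), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  if (!nrow(points)) stopf("seed set must be nonempty")
  structure(list(points = points, kind = kind), class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("<seed_set> ", nrow(x$points), " ", x$kind, " seed point(s)\n",
      sep = "")
  invisible(x)
}

#' Automated brain-tissue seed points
#'
#' Runs the Canny detector twice with the two high thresholds, subtracts the
#' second edge map from the first (removing high-contrast skull and tumor
#' contours detected by both), and area-opens the difference to drop small
#' noise components.  The surviving ON pixels are the initialized target
#' points inside the brain tissue.
#'
#' @param image normalized slice in `[0, 1]`.
#' @param config a [segmentation_config()].
#' @return A `seed_set` of kind `"brain"`.
#' @export
brain_seed_points <- function(image, config = segmentation_config()) {
  e1 <- canny_edges(image, config$canny_low, config$canny_high_1,
                    config$canny_sigma)
  e2 <- canny_edges(image, config$canny_low, config$canny_high_2,
                    config$canny_sigma)
  diffm <- e1 & !e2
  if (any(diffm) && config$opening_size > 1L) {
    lab <- label8(diffm)
    sizes <- tabulate(lab)
    keep <- which(sizes >= config$opening_size)
    diffm <- diffm & matrix(lab %in% keep, nrow(image))
  }
  if (!any(diffm))
    stopf("no brain seeds found (unusable contrast between the two Canny passes)")
  seed_set(which(diffm, arr.ind = TRUE), "brain")
}

#' Tumor seed point
#'
#' The brightest pixel of the skull-stripped image (the gray-level brain
#' mask); ties break to the smallest (row, col) in lexicographic order.
#'
#' @param image normalized slice in `[0, 1]`.
#' @param brain_mask logical brain support.
#' @return A `seed_set` of kind `"tumor"` with a single point.
#' @export
tumor_seed_point <- function(image, brain_mask) {
  brain_mask <- as_mask(brain_mask)
  same_shape(image, brain_mask, "image and brain_mask")
  if (!any(brain_mask)) stopf("empty brain mask")
  m <- max(image[brain_mask])
  cand <- which(brain_mask & image == m, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  seed_set(cand[1, , drop = FALSE], "tumor")
}

#' Pixel weight matrix (fast-marching speed function)
#'
#' `W(x, y) = 1 / (1 + (|I(x, y) - mu| / kappa)^2)` where `mu` is the mean
#' intensity over the seed points.  Weights lie in `(0, 1]`, equal 1 where
#' the intensity matches the seed statistic, and decrease strictly with the
#' gray-level difference.
#'
#' @param image normalized slice.
#' @param seeds a `seed_set`.
#' @param kappa positive softness scale.
#' @return A `weight_matrix` object (numeric matrix with the seed reference
#'   intensity attached).
#' @export
pixel_weight_matrix <- function(image, seeds, kappa = 0.1) {
  stopifnot(inherits(seeds, "seed_set"))
  if (kappa <= 0) stopf("kappa must be positive")
  idx <- cbind(seeds$points[, 1], seeds$points[, 2])
  mu <- mean(image[idx])
  w <- 1 / (1 + ((image - mu) / kappa)^2)
  structure(w, class = c("weight_matrix", class(w)),
            seed_reference_intensity = mu)
}

#' Fast-marching arrival times
#'
#' First-order upwind fast marching on the 4-neighbour grid: `T = 0` at the
#' seeds, each pixel accepted exactly once in min-heap order with
#' deterministic (time, row, col) tie-breaking, solving the upwind
#' discretization of `|grad T| = 1 / F` with the weight matrix as speed `F`.
#' Raw times are min-max normalized over reached pixels; unreached pixels
#' (outside `domain`) are reported as 1.
#'
#' @param weights a [pixel_weight_matrix()] (or any strictly positive
#'   matrix).
#' @param seeds a `seed_set`.
#' @param domain optional logical mask restricting propagation; seeds must
#'   lie inside it.
#' @return An `arrival_map`: list with `values` (normalized, `[0, 1]`),
#'   `raw` (unnormalized times, `Inf` where unreached) and `reached`.
#' @export
fmm_arrival_times <- function(weights, seeds, domain = NULL) {
  stopifnot(inherits(seeds, "seed_set"))
  w <- unclass(weights)
  if (is.null(domain)) domain <- matrix(TRUE, nrow(w), ncol(w))
  domain <- as_mask(domain)
  same_shape(w, domain, "weights and domain")
  if (any(w[domain] <= 0)) stopf("weights must be strictly positive")
  pts <- seeds$points
  if (any(pts[, 1] < 1L) || any(pts[, 1] > nrow(w)) ||
      any(pts[, 2] < 1L) || any(pts[, 2] > ncol(w)))
    stopf("seed outside image bounds")
  if (any(!domain[pts])) stopf("seed outside the propagation domain")
  raw <- fmm_arrival_c(w, pts - 1L, domain)
  reached <- is.finite(raw)
  tmax <- max(raw[reached])
  values <- matrix(1, nrow(w), ncol(w))
  values[reached] <- if (tmax > 0) raw[reached] / tmax else 0
  structure(list(values = values, raw = raw, reached = reached),
            class = "arrival_map")
}

#' Segment one region from seeds
#'
#' Thresholds the normalized arrival-time map, keeps the 8-connected
#' component(s) containing the seeds, and fills interior holes (hyperintense
#' tumor cores propagate slowly under a tissue-seeded weight matrix and
#' would otherwise punch holes in the brain mask).
#'
#' @param image normalized slice.
#' @param seeds a `seed_set`.
#' @param config a [segmentation_config()].
#' @param domain optional logical propagation support.
#' @return A `segmentation_result`: `mask` (logical), `gray_mask`
#'   (image masked), `arrival` (the `arrival_map`), `threshold`, `seeds`.
#' @export
segment_region <- function(image, seeds, config = segmentation_config(),
                           domain = NULL) {
  w <- pixel_weight_matrix(image, seeds, config$kappa)
  arr <- fmm_arrival_times(w, seeds, domain)
  thr <- config$arrival_threshold
  mask <- arr$reached & arr$values <= thr
  if (!any(mask))
    stopf("empty mask at arrival threshold %g", thr)
  lab <- label8(mask)
  good <- unique(lab[seeds$points])
  good <- good[good > 0]
  mask <- mask & matrix(lab %in% good, nrow(image))
  if (!any(mask))
    stopf("no thresholded component contains a seed (threshold %g)", thr)
  mask <- fill_holes(mask)
  structure(list(mask = mask, gray_mask = image * mask, arrival = arr,
                 threshold = thr, seeds = seeds),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result> ", sum(x$mask), " px (", x$seeds$kind,
      " seeds), arrival threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

# tumor presence rule: the candidate seed must be hyperintense relative to
# the skull-stripped tissue distribution.  The test runs on a lightly
# smoothed image so a single bright noise pixel cannot fake a lesion.
tumor_present <- function(image, brain_mask, seed, n_sigma = 2, sigma = 1) {
  sm <- gaussian_blur(image * brain_mask, sigma)
  vals <- sm[brain_mask]
  thr <- mean(vals) + n_sigma * stats::sd(vals)
  sm[seed$points[1, 1], seed$points[1, 2]] >= thr
}

#' Segment brain tissue and tumor area for every slice of a series
#'
#' Per slice: brain seed points from the two-threshold Canny difference, the
#' brain segmented by fast marching from those seeds, the tumor seeded at
#' the brightest pixel of the skull-stripped slice and segmented by a second
#' fast-marching run restricted to the brain support.  Slices whose
#' candidate tumor seed is not hyperintense (below mean + 2 sd of the
#' smoothed skull-stripped intensities) are reported as tumor-free rather
#' than failing.
#'
#' @param series a normalized [mr_series()] (see [normalize_series()]).
#' @param config a [segmentation_config()].
#' @return A `brain_tumor_segmentation`: per-slice list with elements
#'   `brain` (a `segmentation_result`), `tumor` (a `segmentation_result` or
#'   `NULL`), and `tumor_present` (logical), plus the series metadata.
#' @export
segment_brain_and_tumor <- function(series, config = segmentation_config()) {
  stopifnot(inherits(series, "mr_series"))
  slices <- lapply(seq_along(series$slices), function(i) {
    img <- series$slices[[i]]
    res <- tryCatch({
      bseeds <- brain_seed_points(img, config)
      brain <- segment_region(img, bseeds, config)
      tseed <- tumor_seed_point(img, brain$mask)
      present <- tumor_present(img, brain$mask, tseed)
      tumor <- NULL
      if (present) {
        tumor <- segment_region(img, tseed, config, domain = brain$mask)
        tumor$mask <- tumor$mask & brain$mask
        tumor$gray_mask <- img * tumor$mask
      }
      list(brain = brain, tumor = tumor, tumor_present = present,
           tumor_seed = tseed)
    }, error = function(e)
      stopf("slice %d (%s): %s", i, series$ids[i], conditionMessage(e)))
    res
  })
  structure(list(slices = slices, pixel_spacing = series$pixel_spacing,
                 slice_separation = series$slice_separation,
                 slice_thickness = series$slice_thickness,
                 config = config),
            class = "brain_tumor_segmentation")
}

#' @export
print.brain_tumor_segmentation <- function(x, ...) {
  n <- length(x$slices)
  nt <- sum(vapply(x$slices, `[[`, TRUE, "tumor_present"))
  cat("<brain_tumor_segmentation> ", n, " slice(s), tumor detected in ", nt,
      "\n", sep = "")
  invisible(x)
}
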