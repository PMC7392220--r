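#' Configuration for the synthetic brain phantom
#'
#' Describes a synthetic axial brain-MR-like slice: an elliptical brain of
#' mid-intensity textured tissue surrounded by a thin bright skull ring, with
#' a hyperintense star-convex tumor blob, on a dark background.  Geometry
#' defaults follow a typical axial T1-weighted post-contrast acquisition
#' (0.6875 mm pixel spacing, 5 mm slice thickness, 6.5 mm slice separation).
#'
#' @param image_shape integer (rows, cols) of the slice in pixels.
#' @param pixel_spacing mm per pixel (applied to both axes).
#' @param slice_separation mm between slice centers in a stack.
#' @param slice_thickness mm thickness of one slice.
#' @param skull_intensity,tissue_intensity,tumor_intensity intensities in
#'   `[0, 1]`.  The tumor must be hyperintense relative to tissue, and the
#'   skull at least as bright as the tumor.
#' @param tumor_center (row, col) of the tumor center in pixels, or `NULL`
#'   for a default parietal-like off-center placement.
#' @param tumor_radius mean tumor radius in pixels.
#' @param irregularity amplitude in `[0, 1]` of the smooth periodic radial
#'   perturbation of the tumor boundary (0 gives an exact disk).
#' @param texture_amplitude peak amplitude of the bounded smooth intensity
#'   texture inside the brain tissue.  The texture is what gives the Canny
#'   seed-detection stage its weak in-brain contours.
#' @param texture_scale correlation length (pixels) of the tissue texture.
#' @param edge_softness Gaussian sigma (pixels) applied to the noiseless
#'   slice so that structure boundaries have a realistic finite ramp.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param seed integer RNG seed; fixed seed gives bit-identical phantoms.
#'
#' @return An object of class `phantom_config`.
#' @seealso [make_brain_slice()], [make_series()], [make_followup_pair()]
#' @export
phantom_config <- function(image_shape = c(320L, 260L),
                           pixel_spacing = 0.6875,
                           slice_separation = 6.5,
                           slice_thickness = 5,
                           skull_intensity = 0.95,
                           tissue_intensity = 0.40,
                           tumor_intensity = 0.80,
                           tumor_center = NULL,
                           tumor_radius = 18,
                           irregularity = 0.3,
                           texture_amplitude = 0.07,
                           texture_scale = 3,
                           edge_softness = 1,
                           noise_sigma = 0.01,
                           seed = 1L) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 32L))
    stopf("image_shape must be (rows, cols), each at least 32")
  ints <- c(skull = skull_intensity, tissue = tissue_intensity,
            tumor = tumor_intensity)
  if (any(ints < 0) || any(ints > 1))
    stopf("all intensities must lie in [0, 1]")
  if (tumor_intensity <= tissue_intensity)
    stopf("tumor must be hyperintense: tumor_intensity > tissue_intensity")
  if (skull_intensity < tumor_intensity)
    stopf("skull_intensity must be >= tumor_intensity")
  if (irregularity < 0 || irregularity > 1)
    stopf("irregularity must lie in [0, 1]")
  if (pixel_spacing <= 0 || slice_separation <= 0 || slice_thickness <= 0)
    stopf("physical spacings must be positive")
  if (tumor_radius <= 0) stopf("tumor_radius must be positive")
  if (is.null(tumor_center))
    tumor_center <- round(image_shape * c(0.38, 0.64))
  cfg <- list(
    image_shape = image_shape,
    pixel_spacing = pixel_spacing,
    slice_separation = slice_separation,
    slice_thickness = slice_thickness,
    skull_intensity = skull_intensity,
    tissue_intensity = tissue_intensity,
    tumor_intensity = tumor_intensity,
    tumor_center = as.numeric(tumor_center),
    tumor_radius = tumor_radius,
    irregularity = irregularity,
    texture_amplitude = texture_amplitude,
    texture_scale = texture_scale,
    edge_softness = edge_softness,
    noise_sigma = noise_sigma,
    seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  cfg
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config> ", paste(x$image_shape, collapse = "x"),
      " px, ", x$pixel_spacing, " mm/px\n",
      "  tissue/tumor/skull intensities: ",
      x$tissue_intensity, "/", x$tumor_intensity, "/", x$skull_intensity, "\n",
      "  tumor r=", x$tumor_radius, " px at (",
      paste(x$tumor_center, collapse = ", "), "), irregularity ",
      x$irregularity, ", noise sd ", x$noise_sigma, ", seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# brain ellipse semi-axes and skull ring thickness, derived from the shape
brain_geometry <- function(shape) {
  list(center = (shape + 1) / 2,
       semi = c(0.36, 0.38) * shape,
       skull = 3)
}

# low-order Fourier radial perturbation, normalized to max |P| = 1
radial_perturbation <- function(coefs) {
  ks <- 2:(1 + nrow(coefs))
  f <- function(theta) {
    p <- 0
    for (i in seq_along(ks))
      p <- p + coefs[i, 1] * cos(ks[i] * theta) +
           coefs[i, 2] * sin(ks[i] * theta)
    p
  }
  grid <- seq(0, 2 * pi, length.out = 721L)
  m <- max(abs(f(grid)))
  if (m == 0) function(theta) theta * 0 else function(theta) f(theta) / m
}

# rasterize the star-convex tumor: pixel centers with distance <= r(theta)
tumor_mask_from <- function(shape, center, radius, irregularity, perturb) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dr <- rr - center[1]
  dc <- cc - center[2]
  d <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)
  d <= radius * (1 + irregularity * perturb(theta))
}

# shared renderer: same config seed -> same brain texture and tumor shape,
# the noise stream is drawn under its own seed so follow-up exams and stack
# slices share geometry but not noise.
render_slice <- function(config, tumor_radius, noise_seed) {
  shape <- config$image_shape
  geo <- brain_geometry(shape)
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  e <- ((rr - geo$center[1]) / geo$semi[1])^2 +
       ((cc - geo$center[2]) / geo$semi[2])^2
  brain <- e <= 1
  eo <- ((rr - geo$center[1]) / (geo$semi[1] + geo$skull))^2 +
        ((cc - geo$center[2]) / (geo$semi[2] + geo$skull))^2
  skull <- eo <= 1 & !brain

  drawn <- with_seed(config$seed, {
    g <- gaussian_blur(matrix(rnorm(prod(shape)), shape[1], shape[2]),
                       config$texture_scale)
    g <- g / stats::sd(g)
    coefs <- matrix(rnorm(8L), 4L, 2L)
    list(texture = tanh(g), coefs = coefs)
  })
  perturb <- radial_perturbation(drawn$coefs)

  tumor <- matrix(FALSE, shape[1], shape[2])
  if (!is.null(tumor_radius) && tumor_radius > 0) {
    # validate placement: the outermost possible boundary point must stay
    # strictly inside the brain ellipse
    grid <- seq(0, 2 * pi, length.out = 361L)
    rad <- tumor_radius * (1 + config$irregularity * perturb(grid))
    pr <- config$tumor_center[1] + rad * cos(grid)
    pc <- config$tumor_center[2] + rad * sin(grid)
    inside <- ((pr - geo$center[1]) / geo$semi[1])^2 +
              ((pc - geo$center[2]) / geo$semi[2])^2
    if (any(inside >= 1))
      stopf("tumor placement outside brain (radius %.1f px escapes the brain ellipse)",
            tumor_radius)
    tumor <- tumor_mask_from(shape, config$tumor_center, tumor_radius,
                             config$irregularity, perturb)
  }

  img <- matrix(0, shape[1], shape[2])
  img[brain] <- config$tissue_intensity +
    config$texture_amplitude * drawn$texture[brain]
  img[skull] <- config$skull_intensity
  img[tumor] <- config$tumor_intensity
  if (config$edge_softness > 0) img <- gaussian_blur(img, config$edge_softness)
  if (config$noise_sigma > 0) {
    img <- img + with_seed(noise_seed,
      matrix(rnorm(prod(shape), sd = config$noise_sigma),
             shape[1], shape[2]))
  }
  img <- pmin(pmax(img, 0), 1)

  structure(list(image = img, brain_mask = brain, tumor_mask = tumor,
                 config = config),
            class = "phantom_truth")
}

#' Generate one synthetic brain slice with ground truth
#'
#' @param config a [phantom_config()].
#' @return A `phantom_truth` object: `image` (grayscale in `[0, 1]`),
#'   `brain_mask` and `tumor_mask` (logical, tumor contained in brain), and
#'   the config used.
#' @examples
#' p <- make_brain_slice(phantom_config(image_shape = c(96, 96),
#'                                      tumor_center = c(40, 60),
#'                                      tumor_radius = 8))
#' stopifnot(all(p$tumor_mask <= p$brain_mask))
#' @export
make_brain_slice <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  render_slice(config, config$tumor_radius, config$seed)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> ", paste(dim(x$image), collapse = "x"),
      " px; brain ", sum(x$brain_mask), " px; tumor ", sum(x$tumor_mask),
      " px\n", sep = "")
  invisible(x)
}

#' Generate a multi-slice phantom series
#'
#' Slices inside `tumor_slices` carry a tumor whose radius tapers toward the
#' ends of the range (an ellipsoid-like lesion); all other slices have an
#' empty tumor mask.  Brain geometry and tissue texture are identical across
#' slices, the pixel noise differs per slice.
#'
#' @param config a [phantom_config()]; its `tumor_radius` is the mid-lesion
#'   radius.
#' @param n_slices number of slices (>= 1).
#' @param tumor_slices integer vector of 1-based slice indices carrying tumor.
#' @return A `phantom_series` object with `images`, `brain_masks`,
#'   `tumor_masks` (lists), the slice indices and the config.
#' @export
make_series <- function(config = phantom_config(), n_slices,
                        tumor_slices = integer(0)) {
  stopifnot(inherits(config, "phantom_config"))
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stopf("n_slices must be >= 1")
  tumor_slices <- sort(unique(as.integer(tumor_slices)))
  if (length(tumor_slices) &&
      (min(tumor_slices) < 1L || max(tumor_slices) > n_slices))
    stopf("tumor_slices must lie within 1..n_slices")

  radii <- rep(0, n_slices)
  if (length(tumor_slices)) {
    mid <- mean(range(tumor_slices))
    halfw <- diff(range(tumor_slices)) / 2 + 0.5
    f <- sqrt(pmax(0, 1 - ((tumor_slices - mid) / halfw)^2))
    radii[tumor_slices] <- config$tumor_radius * f
  }
  out <- lapply(seq_len(n_slices), function(i) {
    render_slice(config, if (radii[i] > 0) radii[i] else NULL,
                 config$seed + i)
  })
  structure(list(images = lapply(out, `[[`, "image"),
                 brain_masks = lapply(out, `[[`, "brain_mask"),
                 tumor_masks = lapply(out, `[[`, "tumor_mask"),
                 n_slices = n_slices, tumor_slices = tumor_slices,
                 config = config),
            class = "phantom_series")
}

#' @export
print.phantom_series <- function(x, ...) {
  cat("<phantom_series> ", x$n_slices, " slices, tumor in {",
      paste(x$tumor_slices, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Generate a registered follow-up pair
#'
#' Two exams with identical brain geometry and tissue texture (registered by
#' construction) whose tumor radius differs by `growth_factor`; the noise
#' field differs between exams.
#'
#' @param config a [phantom_config()]; `tumor_radius` is the baseline radius.
#' @param growth_factor positive scalar; the follow-up radius is
#'   `growth_factor * tumor_radius`.
#' @return A `phantom_pair`: list with elements `baseline` and `progression`
#'   (each a `phantom_truth`).
#' @export
make_followup_pair <- function(config = phantom_config(), growth_factor) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.numeric(growth_factor) || growth_factor <= 0)
    stopf("growth_factor must be a positive scalar")
  baseline <- render_slice(config, config$tumor_radius, config$seed)
  progression <- render_slice(config, config$tumor_radius * growth_factor,
                              config$seed + 1000003L)
  structure(list(baseline = baseline, progression = progression,
                 growth_factor = growth_factor),
            class = "phantom_pair")
}

#' Convert a phantom series to an [mr_series()]
#'
#' @param x a `phantom_series` or single `phantom_truth`.
#' @return An `mr_series` carrying the phantom's physical spacing metadata.
#' @export
as_mr_series <- function(x) {
  if (inherits(x, "phantom_truth"))
    x <- structure(list(images = list(x$image), config = x$config,
                        n_slices = 1L),
                   class = "phantom_series")
  stopifnot(inherits(x, "phantom_series"))
  cfg <- x$config
  mr_series(x$images,
            pixel_spacing = rep(cfg$pixel_spacing, 2L),
            slice_thickness = cfg$slice_thickness,
            slice_separation = cfg$slice_separation,
            ids = sprintf("phantom-%03d", seq_len(x$n_slices)))
}

#' Write a phantom to disk
#'
#' The image goes out as 16-bit PGM, masks as 8-bit binary PNG (0/255), and
#' physical spacing metadata as a YAML sidecar; everything round-trips
#' through [read_raster()].
#'
#' @param truth a `phantom_truth`.
#' @param dir output directory (created if needed).
#' @param stem file name stem.
#' @return Invisibly, the vector of files written.
#' @export
write_phantom <- function(truth, dir, stem = "phantom") {
  stopifnot(inherits(truth, "phantom_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- file.path(dir, paste0(stem, ".pgm"))
  bm <- file.path(dir, paste0(stem, "_brain_mask.png"))
  tm <- file.path(dir, paste0(stem, "_tumor_mask.png"))
  meta <- file.path(dir, paste0(stem, ".yml"))
  write_pgm16(truth$image, img)
  write_mask_png(truth$brain_mask, bm)
  write_mask_png(truth$tumor_mask, tm)
  cfg <- truth$config
  yaml::write_yaml(list(pixel_spacing = cfg$pixel_spacing,
                        slice_separation = cfg$slice_separation,
                        slice_thickness = cfg$slice_thickness,
                        seed = cfg$seed),
                   meta)
  invisible(c(img, bm, tm, meta))
}
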