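#' Optics configuration
#'
#' Physical parameters of the (simulated) holographic projection bench: a
#' reflective phase-only SLM illuminated by a collimated beam and placed at
#' the front focal plane of a Fourier lens.
#'
#' @param wavelength laser wavelength in meters.
#' @param slm_pixel_pitch SLM sampling interval in meters.
#' @param slm_shape SLM resolution as (rows, cols).
#' @param focal_length Fourier-lens focal length in meters.
#' @return An `optics_config` with the derived wave number `k = 2 pi /
#'   wavelength`.
#' @export
optics_config <- function(wavelength = 670e-9, slm_pixel_pitch = 8e-6,
                          slm_shape = c(1080L, 1920L),
                          focal_length = 0.125) {
  if (wavelength <= 0 || slm_pixel_pitch <= 0 || focal_length <= 0)
    stopf("optics parameters must be positive")
  slm_shape <- as.integer(slm_shape)
  if (length(slm_shape) != 2L || any(slm_shape < 1L))
    stopf("slm_shape must be positive (rows, cols)")
  structure(list(wavelength = wavelength,
                 slm_pixel_pitch = slm_pixel_pitch,
                 slm_shape = slm_shape, focal_length = focal_length,
                 k = 2 * pi / wavelength),
            class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat("<optics_config> lambda ", x$wavelength * 1e9, " nm, pitch ",
      x$slm_pixel_pitch * 1e6, " um, SLM ",
      paste(x$slm_shape, collapse = "x"), ", f ", x$focal_length * 1e3,
      " mm\n", sep = "")
  invisible(x)
}

#' A phase-only hologram
#'
#' @param phase numeric matrix of phases in radians; stored wrapped to
#'   `[0, 2 pi)`.
#' @param optics the [optics_config()] the phase was computed for.
#' @return A `phase_hologram`.
#' @export
phase_hologram <- function(phase, optics) {
  check_matrix(phase)
  stopifnot(inherits(optics, "optics_config"))
  structure(list(phase = wrap_phase(phase), optics = optics),
            class = "phase_hologram")
}

#' @export
print.phase_hologram <- function(x, ...) {
  cat("<phase_hologram> ", paste(dim(x$phase), collapse = "x"),
      " px, phase in [0, 2pi)\n", sep = "")
  invisible(x)
}

hologram_field <- function(h) exp(1i * h$phase)

#' Zero-pad an image into the center of an extended frame
#'
#' The default frame is `pad_factor` times the SLM shape per axis (factor 4
#' turns a 1080 x 1920 SLM window into a 4320 x 7680 extended frame).  An
#' off-center remainder is split evenly with the extra pixel on the
#' trailing side.
#'
#' @param image numeric matrix.
#' @param shape explicit (rows, cols) of the output, or `NULL` to use
#'   `optics$slm_shape * pad_factor`.
#' @param optics an [optics_config()] (needed when `shape` is `NULL`).
#' @param pad_factor integer expansion per axis.
#' @return The padded matrix.
#' @export
zero_pad_center <- function(image, shape = NULL, optics = NULL,
                            pad_factor = 4L) {
  check_matrix(image)
  if (is.null(shape)) {
    stopifnot(inherits(optics, "optics_config"))
    shape <- optics$slm_shape * as.integer(pad_factor)
  }
  shape <- as.integer(shape)
  if (any(dim(image) > shape))
    stopf("image (%s) larger than the target frame (%s)",
          paste(dim(image), collapse = "x"), paste(shape, collapse = "x"))
  out <- matrix(0, shape[1], shape[2])
  r0 <- floor((shape[1] - nrow(image)) / 2)
  c0 <- floor((shape[2] - ncol(image)) / 2)
  out[r0 + seq_len(nrow(image)), c0 + seq_len(ncol(image))] <- image
  out
}

#' Iterative Fourier transform algorithm (phase retrieval)
#'
#' Alternating projections between the object plane and the SLM plane under
#' centered unitary Fourier transforms: start from the target amplitude
#' `sqrt(I)` with zero phase, keep the phase and force unit amplitude at the
#' SLM plane, keep the phase and restore the target amplitude at the object
#' plane.  Iteration stops when the RMS of the wrapped hologram-phase change
#' drops below `epsilon` radians, or at `max_iter`.
#'
#' @param target nonnegative intensity matrix (not all zero).
#' @param max_iter maximum number of iterations.
#' @param epsilon stopping tolerance on the phase change, radians.
#' @param optics an [optics_config()] attached to the returned hologram.
#' @return List with `hologram` (a [phase_hologram()]) and `trace` (per
#'   iteration: `rmse` of the normalized phase-only reconstruction against
#'   the normalized target, `phase_change`; plus `iterations` and
#'   `converged`).
#' @export
ifta <- function(target, max_iter = 200L, epsilon = 0.05,
                 optics = optics_config()) {
  check_matrix(target)
  if (any(target < 0)) stopf("target intensity must be nonnegative")
  if (!any(target > 0)) stopf("target intensity is all zero")
  if (max_iter < 1L) stopf("max_iter must be >= 1")
  amp <- sqrt(target)
  tnorm <- target / max(target)
  phi0 <- matrix(0, nrow(target), ncol(target))
  phih_prev <- matrix(0, nrow(target), ncol(target))
  rmse_tr <- numeric(0)
  change_tr <- numeric(0)
  converged <- FALSE
  for (n in seq_len(max_iter)) {
    uh <- fft2c(amp * exp(1i * phi0))
    phih <- Arg(uh)
    change <- sqrt(mean(wrap_diff(phih - phih_prev)^2))
    phih_prev <- phih
    u0 <- ifft2c(exp(1i * phih))
    recon <- Mod(u0)^2
    rmse_tr <- c(rmse_tr, rmse(recon / max(recon), tnorm))
    change_tr <- c(change_tr, change)
    phi0 <- Arg(u0)
    if (change < epsilon) {
      converged <- TRUE
      break
    }
  }
  list(hologram = phase_hologram(phih_prev, optics),
       trace = list(rmse = rmse_tr, phase_change = change_tr,
                    iterations = length(rmse_tr), converged = converged,
                    epsilon = epsilon))
}

# frequency grid of the SLM plane seen from the reconstruction plane:
# an SLM pixel at physical position x maps to spatial frequency x/(lambda f)
freq_grid <- function(shape, optics) {
  sc <- optics$slm_pixel_pitch / (optics$wavelength * optics$focal_length)
  vi <- (seq_len(shape[1]) - center_index(shape[1])) * sc
  vj <- (seq_len(shape[2]) - center_index(shape[2])) * sc
  list(vi = matrix(vi, shape[1], shape[2]),
       vj = matrix(vj, shape[1], shape[2], byrow = TRUE))
}

#' Quadratic chirp (paraxial propagation transfer function)
#'
#' `chi_z(v) = exp(i k (lambda^2 / 2) z |v|^2)`, a pure phase factor that
#' axially displaces a layer by the propagation distance `z` (negative `z`
#' propagates the other way).  `chirp_phase(shape, -z) ` is the exact
#' inverse of `chirp_phase(shape, z)`.
#'
#' @param shape (rows, cols) of the field.
#' @param z propagation distance in meters.
#' @param optics an [optics_config()].
#' @return A unit-modulus complex matrix.
#' @export
chirp_phase <- function(shape, z, optics = optics_config()) {
  g <- freq_grid(shape, optics)
  exp(1i * optics$k * optics$wavelength^2 / 2 * z * (g$vi^2 + g$vj^2))
}

#' Linear phase ramp (lateral shift of the reconstruction)
#'
#' Shifts are given in reconstruction-plane pixels and realized as exact
#' DFT-bin linear phases, so an integer shift circularly translates the
#' reconstruction by exactly that many pixels (positive = down/right) with
#' no interpolation error.  One reconstruction pixel
#' corresponds to `lambda f / (N pitch)` meters; the equivalent tilt angles
#' satisfy `sin(alpha) = du / z` for the physical shift `du` and layer
#' distance `z`.
#'
#' @param shape (rows, cols) of the field.
#' @param shift (rows, cols) shift in reconstruction-plane pixels.
#' @param z layer propagation distance in meters (part of the physical
#'   bookkeeping: the equivalent SLM tilt satisfies `sin(alpha) = du / z`;
#'   must be nonzero when a shift is requested).
#' @param optics an [optics_config()].
#' @return A unit-modulus complex matrix.
#' @seealso [ramp_physical_shift()] for the shift in meters.
#' @export
ramp_phase <- function(shape, shift, z = NULL, optics = optics_config()) {
  shift <- rep_len(as.numeric(shift), 2L)
  if (!is.null(z) && z == 0 && any(shift != 0))
    stopf("a lateral shift needs a nonzero layer distance z")
  nr <- shape[1]
  nc <- shape[2]
  ii <- matrix(seq_len(nr) - center_index(nr), nr, nc)
  jj <- matrix(seq_len(nc) - center_index(nc), nr, nc, byrow = TRUE)
  exp(-2i * pi * (shift[1] * ii / nr + shift[2] * jj / nc))
}

#' Physical displacement of a pixel shift in the reconstruction plane
#'
#' One reconstruction pixel spans `lambda f / (N pitch)` meters, so a ramp
#' of `shift` pixels displaces the image by `du = shift * lambda f /
#' (N pitch)`; the equivalent SLM tilt angles satisfy `sin(alpha) = du / z`.
#'
#' @param shape (rows, cols) of the extended hologram.
#' @param shift shift in reconstruction-plane pixels.
#' @param optics an [optics_config()].
#' @return Displacement in meters, per axis.
#' @export
ramp_physical_shift <- function(shape, shift, optics = optics_config()) {
  rep_len(as.numeric(shift), 2L) * optics$wavelength *
    optics$focal_length / (shape * optics$slm_pixel_pitch)
}

#' Layer placement for the 3D tumor map
#'
#' @param z propagation distance of the layer in meters.
#' @param shift lateral (rows, cols) shift in reconstruction-plane pixels.
#' @param s optional layer index.
#' @return A `layer_spec`.
#' @export
layer_spec <- function(z, shift = c(0, 0), s = NULL) {
  structure(list(z = z, shift = rep_len(as.numeric(shift), 2L), s = s),
            class = "layer_spec")
}

#' Modulate a hologram field with a layer's chirp and ramp
#'
#' Pointwise product of the complex hologram field with the layer's
#' quadratic chirp and linear ramp; both factors are pure phases so the
#' modulus is preserved.
#'
#' @param field complex hologram field (or a [phase_hologram()]).
#' @param layer a [layer_spec()].
#' @param optics an [optics_config()].
#' @return The modulated complex field.
#' @export
modulate_layer <- function(field, layer, optics = optics_config()) {
  stopifnot(inherits(layer, "layer_spec"))
  if (inherits(field, "phase_hologram")) field <- hologram_field(field)
  shape <- dim(field)
  chi <- chirp_phase(shape, layer$z, optics)
  same_shape(field, chi, "field and modulator")
  field * chi * ramp_phase(shape, layer$shift, layer$z, optics)
}

#' Superpose modulated holograms into one phase distribution
#'
#' Complex addition of all fields followed by the argument, wrapped to
#' `[0, 2 pi)`; the phase of an exactly zero sum is defined as 0.
#'
#' @param fields list of equal-shape complex fields.
#' @param optics an [optics_config()].
#' @return A [phase_hologram()].
#' @export
superpose_layers <- function(fields, optics = optics_config()) {
  if (!length(fields)) stopf("need at least one field to superpose")
  total <- fields[[1]]
  for (f in fields[-1]) {
    same_shape(total, f, "superposed fields")
    total <- total + f
  }
  phi <- Arg(total)
  phi[total == 0] <- 0
  phase_hologram(phi, optics)
}

#' Layered 3D tumor-map hologram (scheme 1)
#'
#' One extended IFTA hologram per tumor slice, each modulated by its layer's
#' chirp (axial placement, default spacing 6.5 mm) and ramp (lateral
#' separation), then superposed into a single phase distribution.
#'
#' @param targets list of intensity rasters (e.g. tumor gray masks), padded
#'   internally to `pad_factor` times the SLM shape.
#' @param layers list of [layer_spec()]s, one per target, or `NULL` for a
#'   default arrangement: axial spacing `layer_spacing` centered on the
#'   stack, lateral shifts placing the layers in distinct quadrants.
#' @param optics an [optics_config()].
#' @param pad_factor frame expansion per axis.
#' @param layer_spacing axial separation between subsequent layers, meters.
#' @param max_iter,epsilon IFTA controls.
#' @return List with `hologram` (the superposed [phase_hologram()]),
#'   `layers`, and per-layer IFTA `traces`.
#' @export
build_tumor_stack_hologram <- function(targets, layers = NULL,
                                       optics = optics_config(),
                                       pad_factor = 4L,
                                       layer_spacing = 6.5e-3,
                                       max_iter = 200L, epsilon = 0.05) {
  if (!length(targets)) stopf("need at least one target slice")
  n <- length(targets)
  shape <- optics$slm_shape * as.integer(pad_factor)
  if (is.null(layers)) {
    qr <- round(shape[1] / 8)
    qc <- round(shape[2] / 8)
    corners <- list(c(-qr, -qc), c(-qr, qc), c(qr, -qc), c(qr, qc))
    layers <- lapply(seq_len(n), function(s)
      layer_spec(z = (s - (n + 1) / 2) * layer_spacing,
                 shift = corners[[(s - 1L) %% 4L + 1L]], s = s))
  }
  if (length(layers) != n) stopf("need one layer_spec per target")
  key <- vapply(layers, function(l) paste(l$shift, collapse = ","), "")
  if (anyDuplicated(key))
    warning("duplicate lateral shifts: layers will overlap in the reconstruction")
  traces <- vector("list", n)
  fields <- vector("list", n)
  for (s in seq_len(n)) {
    padded <- zero_pad_center(targets[[s]], shape)
    fit <- ifta(padded, max_iter = max_iter, epsilon = epsilon,
                optics = optics)
    traces[[s]] <- fit$trace
    fields[[s]] <- modulate_layer(fit$hologram, layers[[s]], optics)
  }
  list(hologram = superpose_layers(fields, optics), layers = layers,
       traces = traces)
}

#' Comparative follow-up hologram (scheme 2)
#'
#' Builds the side-by-side comparison of two co-registered exams: per exam
#' the brain-tissue and tumor holograms are combined with the tumor
#' contribution weighted by `gamma`, the progression exam is ramped to a
#' distinct lateral position, and the two exams' phase distributions are
#' superposed by complex addition into one final hologram.
#'
#' With the default `gamma_mode = "amplitude"` the tumor hologram *field*
#' is weighted, `phi = arg(U_I + gamma U_T)`, which demonstrably raises the
#' reconstructed intensity over the tumor footprint (gamma = 2 roughly
#' doubles it relative to gamma = 1).  `gamma_mode = "phase"` instead
#' scales the tumor *phase*, `phi = arg(U_I) + gamma arg(U_T)`; this
#' variant is kept for reference but empirically scatters energy (the
#' phase sum multiplies the fields, convolving the reconstructions) and
#' does not highlight.
#'
#' @param brain_c,tumor_c intensity rasters of the first exam (after CRT):
#'   brain-tissue and tumor gray masks.  A tumor raster that is all zero
#'   contributes nothing.
#' @param brain_p,tumor_p the progression exam.
#' @param gamma tumor highlighting weight.
#' @param gamma_mode how `gamma` enters, see Details.
#' @param shift lateral separation of the progression exam,
#'   reconstruction-plane pixels (rows, cols).
#' @param z layer distance used for the ramp's angle bookkeeping, meters.
#' @param optics an [optics_config()].
#' @param pad_factor,max_iter,epsilon IFTA controls.
#' @return List with `hologram` (final [phase_hologram()]), the per-exam
#'   phases `phi_c` and `phi_p`, and the IFTA traces.
#' @export
build_comparative_hologram <- function(brain_c, tumor_c, brain_p, tumor_p,
                                       gamma = 2,
                                       gamma_mode = c("amplitude", "phase"),
                                       shift = NULL, z = 6.5e-3,
                                       optics = optics_config(),
                                       pad_factor = 4L, max_iter = 200L,
                                       epsilon = 0.05) {
  gamma_mode <- match.arg(gamma_mode)
  if (gamma <= 0) stopf("gamma must be positive")
  shape <- optics$slm_shape * as.integer(pad_factor)
  if (is.null(shift)) shift <- c(0, round(shape[2] / 4))
  phase_of <- function(x) {
    padded <- zero_pad_center(x, shape)
    if (!any(padded > 0)) return(list(phase = NULL, trace = NULL))
    fit <- ifta(padded, max_iter = max_iter, epsilon = epsilon,
                optics = optics)
    list(phase = fit$hologram$phase, trace = fit$trace)
  }
  ui <- phase_of(brain_c)
  ut <- phase_of(tumor_c)
  uip <- phase_of(brain_p)
  utp <- phase_of(tumor_p)
  if (is.null(ui$phase) || is.null(uip$phase))
    stopf("brain targets must not be all zero")
  r <- ramp_phase(shape, shift, z, optics)
  arg0 <- function(u) {
    phi <- Arg(u)
    phi[u == 0] <- 0
    phi
  }
  if (gamma_mode == "amplitude") {
    uc <- exp(1i * ui$phase)
    if (!is.null(ut$phase)) uc <- uc + gamma * exp(1i * ut$phase)
    up <- exp(1i * uip$phase)
    if (!is.null(utp$phase)) up <- up + gamma * exp(1i * utp$phase)
    phi_c <- wrap_phase(arg0(uc))
    phi_p <- wrap_phase(arg0(up * r))
  } else {
    phi_c <- wrap_phase(ui$phase +
                          if (is.null(ut$phase)) 0 else gamma * ut$phase)
    phi_p <- wrap_phase(Arg(exp(1i * uip$phase) * r) +
                          if (is.null(utp$phase)) 0
                          else gamma * Arg(exp(1i * utp$phase) * r))
  }
  final <- superpose_layers(list(exp(1i * phi_c), exp(1i * phi_p)), optics)
  list(hologram = final, phi_c = phi_c, phi_p = phi_p, shift = shift,
       gamma = gamma, gamma_mode = gamma_mode,
       traces = list(brain_c = ui$trace, tumor_c = ut$trace,
                     brain_p = uip$trace, tumor_p = utp$trace))
}

#' Cut an extended hologram into SLM-sized tiles
#'
#' Non-overlapping tiles in row-major order (tile rows vary slowest); a
#' factor-4 extended frame yields 16 tiles.  Concatenating the tiles in
#' order reproduces the extended phase exactly.
#'
#' @param hologram an extended [phase_hologram()] whose shape is an integer
#'   multiple of the SLM shape per axis.
#' @return List of SLM-sized `phase_hologram`s.
#' @export
tile_hologram <- function(hologram) {
  stopifnot(inherits(hologram, "phase_hologram"))
  slm <- hologram$optics$slm_shape
  shp <- dim(hologram$phase)
  if (any(shp %% slm != 0))
    stopf("extended shape (%s) is not an integer multiple of the SLM shape (%s)",
          paste(shp, collapse = "x"), paste(slm, collapse = "x"))
  nt <- shp %/% slm
  tiles <- vector("list", prod(nt))
  idx <- 0L
  for (tr in seq_len(nt[1])) {
    for (tc in seq_len(nt[2])) {
      idx <- idx + 1L
      tiles[[idx]] <- phase_hologram(
        hologram$phase[(tr - 1L) * slm[1] + seq_len(slm[1]),
                       (tc - 1L) * slm[2] + seq_len(slm[2])],
        hologram$optics)
    }
  }
  tiles
}
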