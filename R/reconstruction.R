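#' Numerical Fourier-lens reconstruction
#'
#' Plane-wave illumination of the phase hologram and a centered unitary
#' Fourier transform stand in for the optical bench: the reconstructed
#' intensity is `|F{exp(i phi)}|^2` and one reconstruction pixel spans
#' `lambda f / (N pitch)` meters per axis.  The transform direction is the
#' one that returns to the synthesis object plane, so reconstructions are
#' oriented like the targets (a Fourier lens determines the image only up
#' to a 180-degree rotation; fixing the direction removes that ambiguity).
#' The transform is unitary, so total intensity equals the pixel count of
#' a unit-amplitude hologram.
#'
#' @param hologram a [phase_hologram()].
#' @return A `recon_plane`: `intensity` (nonnegative matrix), `scale`
#'   (meters per pixel, per axis) and the optics used.
#' @export
fourier_reconstruct <- function(hologram) {
  stopifnot(inherits(hologram, "phase_hologram"))
  o <- hologram$optics
  u <- ifft2c(hologram_field(hologram))
  structure(list(intensity = Mod(u)^2,
                 scale = o$wavelength * o$focal_length /
                   (dim(hologram$phase) * o$slm_pixel_pitch),
                 optics = o),
            class = "recon_plane")
}

#' @export
print.recon_plane <- function(x, ...) {
  cat("<recon_plane> ", paste(dim(x$intensity), collapse = "x"),
      " px, ", signif(x$scale[1] * 1e6, 4), " x ",
      signif(x$scale[2] * 1e6, 4), " um/px\n", sep = "")
  invisible(x)
}

#' Temporally multiplexed reconstruction of hologram tiles
#'
#' Emulates sequential display of the tiles on the SLM: the individual
#' reconstructed intensities add incoherently and are normalized by the
#' tile count, so single- and multi-tile intensities are directly
#' comparable.  Each tile carries an independent speckle realization, so
#' the average has a lower speckle contrast than any single tile.
#'
#' @param tiles list of equal-shape [phase_hologram()]s (see
#'   [tile_hologram()]).
#' @return A `recon_plane` with the mean intensity.
#' @export
multiplexed_reconstruct <- function(tiles) {
  if (!length(tiles)) stopf("need at least one tile")
  planes <- lapply(tiles, fourier_reconstruct)
  total <- planes[[1]]$intensity
  for (p in planes[-1]) {
    same_shape(total, p$intensity, "tile reconstructions")
    total <- total + p$intensity
  }
  out <- planes[[1]]
  out$intensity <- total / length(planes)
  out
}
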