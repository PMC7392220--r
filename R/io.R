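#' An ordered stack of grayscale MR slices with physical metadata
#'
#' @param slices list of numeric matrices sharing one shape, ordered along
#'   the scan axis; coordinates are (row, col) with origin top-left.
#' @param pixel_spacing mm per pixel as (row, col).
#' @param slice_thickness mm.
#' @param slice_separation mm between slice centers.
#' @param ids per-slice identifiers.
#' @return An object of class `mr_series`.
#' @export
mr_series <- function(slices, pixel_spacing, slice_thickness = NA_real_,
                      slice_separation = NA_real_, ids = NULL) {
  if (!is.list(slices) || !length(slices))
    stopf("'slices' must be a non-empty list of matrices")
  shp <- dim(slices[[1]])
  for (i in seq_along(slices)) {
    check_matrix(slices[[i]], sprintf("slices[[%d]]", i))
    if (!identical(dim(slices[[i]]), shp))
      stopf("all slices must share one shape; slice %d is %s, expected %s",
            i, paste(dim(slices[[i]]), collapse = "x"),
            paste(shp, collapse = "x"))
  }
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  if (any(pixel_spacing <= 0)) stopf("pixel_spacing must be positive")
  if (is.null(ids)) ids <- as.character(seq_along(slices))
  structure(list(slices = slices, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness,
                 slice_separation = slice_separation,
                 ids = as.character(ids)),
            class = "mr_series")
}

#' @export
print.mr_series <- function(x, ...) {
  cat("<mr_series> ", length(x$slices), " slice(s) of ",
      paste(dim(x$slices[[1]]), collapse = "x"), " px; spacing ",
      paste(signif(x$pixel_spacing, 4), collapse = " x "),
      " mm/px; separation ", x$slice_separation, " mm\n", sep = "")
  invisible(x)
}

#' @export
length.mr_series <- function(x) length(x$slices)

#' Min-max normalize intensities to `[0, 1]`
#'
#' `(x - min) / (max - min)`; a constant input maps to all zeros (explicit
#' degenerate rule).  Idempotent on its own output when the range was
#' nondegenerate.
#'
#' @param x numeric matrix (or vector) of finite values.
#' @return The normalized object, same shape.
#' @export
normalize_intensity <- function(x) {
  if (!all(is.finite(x))) stopf("non-finite values in input")
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) return(x * 0)
  (x - lo) / (hi - lo)
}

#' Normalize an MR series to `[0, 1]` over the whole stack
#'
#' One min-max transform is shared by all slices so that "brightest pixel"
#' rules are comparable across slices.
#'
#' @param series an [mr_series()].
#' @return The series with normalized slices.
#' @export
normalize_series <- function(series) {
  stopifnot(inherits(series, "mr_series"))
  v <- unlist(series$slices, use.names = FALSE)
  if (!all(is.finite(v))) stopf("non-finite values in series")
  lo <- min(v)
  hi <- max(v)
  series$slices <- lapply(series$slices, function(s)
    if (hi == lo) s * 0 else (s - lo) / (hi - lo))
  series
}

#' Read a grayscale raster into `[0, 1]`
#'
#' Supports 8/16-bit grayscale PNG, TIFF and PGM (P2/P5); values are divided
#' by the format's max code value.  Color input is an error, never silently
#' converted.
#'
#' @param path file path; format chosen by extension.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path)
  } else if (ext %in% c("pgm", "ppm", "pnm")) {
    return(read_pgm(path))
  } else {
    stopf("unsupported raster format '%s'", ext)
  }
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] == 2L) x <- x[, , 1L]  # gray + alpha: keep gray
    else stopf("color input not supported: %s", path)
  }
  x
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch)) stopf("truncated PGM header: %s", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
      } else if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || grepl("[ \t\r\n]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (magic %in% c("P3", "P6")) stopf("color input not supported: %s", path)
  if (!magic %in% c("P2", "P5")) stopf("not a PGM file: %s", path)
  w <- as.integer(tok())
  h <- as.integer(tok())
  maxv <- as.integer(tok())
  n <- w * h
  if (magic == "P5") {
    sz <- if (maxv > 255L) 2L else 1L
    v <- readBin(con, "integer", n = n, size = sz, signed = FALSE,
                 endian = "big")
  } else {
    v <- as.integer(scan(con, what = integer(), n = n, quiet = TRUE))
  }
  matrix(v / maxv, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a `[0, 1]` image as 16-bit binary PGM
#' @param image numeric matrix in `[0, 1]`.
#' @param path output path.
#' @export
write_pgm16 <- function(image, path) {
  check_matrix(image)
  v <- as.integer(round(pmin(pmax(image, 0), 1) * 65535))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n65535\n", ncol(image), nrow(image)), con,
            eos = NULL)
  writeBin(as.vector(t(matrix(v, nrow(image)))), con, size = 2L,
           endian = "big")
  invisible(path)
}

#' Write a binary mask as 8-bit PNG with values {0, 255}
#' @param mask logical (or 0/1) matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask(mask)
  png::writePNG(matrix(as.numeric(m), nrow(m)), path)
  invisible(path)
}

#' Read a binary mask written by [write_mask_png()]
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) read_raster(path) >= 0.5
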