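# Minimal single-frame grayscale DICOM support.  No DICOM reader exists in
# the installed R stack, so this implements exactly the subset the package
# needs: part-10 files, explicit or implicit VR little endian, single-frame
# monochrome pixel data, and the geometry/rescale tags used downstream.
# Sequences with undefined length and compressed transfer syntaxes are
# rejected rather than guessed at.

TS_IMPLICIT <- "1.2.840.10008.1.2"
TS_EXPLICIT <- "1.2.840.10008.1.2.1"
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_u16 <- function(buf, off)
  as.integer(buf[off + 1L]) + 256L * as.integer(buf[off + 2L])

dcm_u32 <- function(buf, off) {
  v <- as.numeric(as.integer(buf[off + 1:4]))
  v[1] + 256 * v[2] + 65536 * v[3] + 16777216 * v[4]
}

dcm_str <- function(bytes) {
  s <- rawToChar(bytes[bytes != as.raw(0)])
  trimws(s)
}

dcm_nums <- function(bytes)
  as.numeric(strsplit(dcm_str(bytes), "\\\\")[[1]])

dcm_us <- function(bytes)
  readBin(bytes, "integer", n = 1L, size = 2L, signed = FALSE,
          endian = "little")

# parse one file into a tag -> list(vr, bytes) map
parse_dicom <- function(path) {
  n <- file.size(path)
  buf <- readBin(path, "raw", n = n)
  if (n < 132L || rawToChar(buf[129:132]) != "DICM")
    stopf("not a part-10 DICOM file: %s", path)
  pos <- 132L
  elems <- list()
  explicit <- TRUE
  while (pos + 8L <= n) {
    group <- dcm_u16(buf, pos)
    elem <- dcm_u16(buf, pos + 2L)
    exp_here <- explicit || group == 2L  # file meta is always explicit
    if (exp_here) {
      vr <- rawToChar(buf[pos + 5:6])
      if (vr %in% LONG_VRS) {
        len <- dcm_u32(buf, pos + 8L)
        hdr <- 12L
      } else {
        len <- dcm_u16(buf, pos + 6L)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- dcm_u32(buf, pos + 4L)
      hdr <- 8L
    }
    if (len >= 4294967295)
      stopf("undefined-length element not supported: %s", path)
    if (pos + hdr + len > n)
      stopf("truncated DICOM element in %s", path)
    key <- sprintf("%04X,%04X", group, elem)
    bytes <- if (len > 0) buf[(pos + hdr + 1L):(pos + hdr + len)] else raw(0)
    elems[[key]] <- list(vr = vr, bytes = bytes)
    if (key == "0002,0010") {
      ts <- dcm_str(bytes)
      if (!ts %in% c(TS_IMPLICIT, TS_EXPLICIT))
        stopf("unsupported transfer syntax '%s' in %s", ts, path)
      explicit <- ts == TS_EXPLICIT
    }
    pos <- pos + hdr + as.integer(len)
    if (key == "7FE0,0010") break
  }
  elems
}

read_dicom_file <- function(path) {
  el <- parse_dicom(path)
  need <- function(key, what) {
    if (is.null(el[[key]]))
      stopf("missing tag (%s) %s in %s", key, what, path)
    el[[key]]$bytes
  }
  rows <- dcm_us(need("0028,0010", "Rows"))
  cols <- dcm_us(need("0028,0011", "Columns"))
  spp <- if (!is.null(el[["0028,0002"]])) dcm_us(el[["0028,0002"]]$bytes) else 1L
  if (spp != 1L) stopf("color DICOM (SamplesPerPixel=%d) not supported: %s",
                       spp, path)
  bits <- dcm_us(need("0028,0100", "BitsAllocated"))
  if (!bits %in% c(8L, 16L)) stopf("unsupported BitsAllocated %d in %s",
                                   bits, path)
  signed <- !is.null(el[["0028,0103"]]) && dcm_us(el[["0028,0103"]]$bytes) == 1L
  spacing <- if (!is.null(el[["0028,0030"]])) dcm_nums(el[["0028,0030"]]$bytes)
             else stopf("missing spacing tag (0028,0030) PixelSpacing in %s",
                        path)
  slope <- if (!is.null(el[["0028,1053"]])) dcm_nums(el[["0028,1053"]]$bytes) else 1
  inter <- if (!is.null(el[["0028,1052"]])) dcm_nums(el[["0028,1052"]]$bytes) else 0
  thick <- if (!is.null(el[["0018,0050"]])) dcm_nums(el[["0018,0050"]]$bytes) else NA_real_
  between <- if (!is.null(el[["0018,0088"]])) dcm_nums(el[["0018,0088"]]$bytes) else NA_real_
  pos_z <- if (!is.null(el[["0020,0032"]])) dcm_nums(el[["0020,0032"]]$bytes)[3]
           else if (!is.null(el[["0020,1041"]])) dcm_nums(el[["0020,1041"]]$bytes)
           else NA_real_
  instance <- if (!is.null(el[["0020,0013"]])) dcm_nums(el[["0020,0013"]]$bytes)
              else NA_real_
  px <- need("7FE0,0010", "PixelData")
  v <- readBin(px, "integer", n = rows * cols, size = bits / 8L,
               signed = if (bits == 8L) signed else signed, endian = "little")
  pixels <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  list(pixels = slope * pixels + inter, rows = rows, cols = cols,
       pixel_spacing = rep_len(spacing, 2L), slice_thickness = thick,
       slice_separation = between, pos_z = pos_z, instance = instance,
       path = path)
}

#' Read a directory of single-frame DICOM files as an MR series
#'
#' Slices are sorted by slice position along the scan axis (falling back to
#' instance number when no position is stored), intensities are rescaled by
#' slope/intercept and then min-max normalized to `[0, 1]` over the whole
#' series.  Only single-frame grayscale little-endian files are supported.
#'
#' @param directory path containing `.dcm` files (any extension is
#'   accepted; non-DICOM files cause an error).
#' @return An [mr_series()].
#' @export
read_dicom_series <- function(directory) {
  files <- sort(list.files(directory, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (!length(files)) stopf("no files in %s", directory)
  parsed <- lapply(files, read_dicom_file)
  shapes <- vapply(parsed, function(p) paste(p$rows, p$cols, sep = "x"), "")
  if (length(unique(shapes)) > 1L) {
    ref <- shapes[1]
    bad <- basename(files[shapes != ref])
    stopf("mixed slice shapes: %s differ from %s (%s)",
          paste(bad, collapse = ", "), basename(files[1]), ref)
  }
  zs <- vapply(parsed, `[[`, 0, "pos_z")
  ord <- if (all(is.finite(zs))) order(zs)
         else order(vapply(parsed, `[[`, 0, "instance"))
  parsed <- parsed[ord]
  sep <- vapply(parsed, `[[`, 0, "slice_separation")
  sep <- if (any(is.finite(sep))) sep[is.finite(sep)][1]
         else if (length(parsed) > 1L && all(is.finite(zs)))
           stats::median(diff(sort(zs)))
         else parsed[[1]]$slice_thickness
  series <- mr_series(lapply(parsed, `[[`, "pixels"),
                      pixel_spacing = parsed[[1]]$pixel_spacing,
                      slice_thickness = parsed[[1]]$slice_thickness,
                      slice_separation = sep,
                      ids = basename(vapply(parsed, `[[`, "", "path")))
  normalize_series(series)
}

# --- writer (used to build synthetic fixtures and export phantoms) -------

dcm_el <- function(con, group, elem, vr, bytes) {
  writeBin(c(group, elem), con, size = 2L, endian = "little")
  if (vr %in% LONG_VRS) {
    writeChar(vr, con, eos = NULL)
    writeBin(raw(2L), con)
    writeBin(length(bytes), con, size = 4L, endian = "little")
  } else {
    writeChar(vr, con, eos = NULL)
    writeBin(length(bytes), con, size = 2L, endian = "little")
  }
  if (length(bytes)) writeBin(bytes, con)
}

pad_even <- function(s, pad = charToRaw(" ")) {
  b <- charToRaw(s)
  if (length(b) %% 2L) b <- c(b, pad)
  b
}

u16_bytes <- function(v)
  writeBin(as.integer(v), raw(), size = 2L, endian = "little")

#' Write a minimal single-frame grayscale DICOM file
#'
#' Explicit VR little endian, 16-bit unsigned monochrome.  Intended for
#' constructing synthetic test series; this is not a general DICOM exporter.
#'
#' @param pixels integer matrix (values in 0..65535).
#' @param path output path.
#' @param pixel_spacing mm per pixel (row, col).
#' @param slice_thickness,slice_separation mm.
#' @param position (x, y, z) image position; `z` orders the series.
#' @param instance instance number.
#' @param rescale_slope,rescale_intercept stored-to-output intensity map.
#' @return Invisibly, `path`.
#' @export
write_dicom <- function(pixels, path, pixel_spacing = c(0.6875, 0.6875),
                        slice_thickness = 5, slice_separation = 6.5,
                        position = c(0, 0, 0), instance = 1L,
                        rescale_slope = 1, rescale_intercept = 0) {
  pixels <- round(pixels)
  if (any(pixels < 0) || any(pixels > 65535))
    stopf("pixel values must lie in 0..65535")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeChar("DICM", con, eos = NULL)

  ts <- pad_even(TS_EXPLICIT, raw(1L))
  meta_len <- 8L + length(ts)  # the (0002,0010) element itself
  dcm_el(con, 0x0002L, 0x0000L, "UL",
         writeBin(meta_len, raw(), size = 4L, endian = "little"))
  dcm_el(con, 0x0002L, 0x0010L, "UI", ts)

  ds <- function(v) pad_even(paste(format(v, trim = TRUE), collapse = "\\"))
  dcm_el(con, 0x0018L, 0x0050L, "DS", ds(slice_thickness))
  dcm_el(con, 0x0018L, 0x0088L, "DS", ds(slice_separation))
  dcm_el(con, 0x0020L, 0x0013L, "IS", ds(instance))
  dcm_el(con, 0x0020L, 0x0032L, "DS", ds(position))
  dcm_el(con, 0x0028L, 0x0002L, "US", u16_bytes(1L))
  dcm_el(con, 0x0028L, 0x0004L, "CS", pad_even("MONOCHROME2"))
  dcm_el(con, 0x0028L, 0x0010L, "US", u16_bytes(nrow(pixels)))
  dcm_el(con, 0x0028L, 0x0011L, "US", u16_bytes(ncol(pixels)))
  dcm_el(con, 0x0028L, 0x0030L, "DS", ds(pixel_spacing))
  dcm_el(con, 0x0028L, 0x0100L, "US", u16_bytes(16L))
  dcm_el(con, 0x0028L, 0x0101L, "US", u16_bytes(16L))
  dcm_el(con, 0x0028L, 0x0102L, "US", u16_bytes(15L))
  dcm_el(con, 0x0028L, 0x0103L, "US", u16_bytes(0L))
  dcm_el(con, 0x0028L, 0x1052L, "DS", ds(rescale_intercept))
  dcm_el(con, 0x0028L, 0x1053L, "DS", ds(rescale_slope))
  px <- writeBin(as.integer(t(pixels)), raw(), size = 2L, endian = "little")
  dcm_el(con, 0x7FE0L, 0x0010L, "OW", px)
  invisible(path)
}
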