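# end-to-end pipeline: phantom -> segmentation -> hologram -> reconstruction
# -> metrics, with a manifest of every artifact written

circshift2 <- function(m, s) {
  nr <- nrow(m)
  nc <- ncol(m)
  m[((seq_len(nr) - 1L - round(s[1])) %% nr) + 1L,
    ((seq_len(nc) - 1L - round(s[2])) %% nc) + 1L, drop = FALSE]
}

# block max-pooling of a logical mask by an integer factor per axis
downsample_mask <- function(mask, factor) {
  nr <- nrow(mask) %/% factor
  nc <- ncol(mask) %/% factor
  out <- matrix(FALSE, nr, nc)
  for (dr in seq_len(factor)) {
    for (dc in seq_len(factor)) {
      out <- out | mask[seq(dr, by = factor, length.out = nr),
                        seq(dc, by = factor, length.out = nc)]
    }
  }
  out
}

# object support of a tile-level reconstruction: union of the padded,
# ramp-shifted target masks, pooled down to the SLM grid and dilated a bit
tile_support <- function(masks, layers, shape, factor) {
  u <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_along(masks)) {
    padded <- zero_pad_center(matrix(as.numeric(masks[[i]]),
                                     nrow(masks[[i]])), shape) > 0
    u <- u | circshift2(padded, layers[[i]]$shift)
  }
  d <- downsample_mask(u, factor)
  as_mask(EBImage::dilate(matrix(as.numeric(d), nrow(d)),
                          EBImage::makeBrush(5L, "box")))
}

write_phase_png <- function(phase, path) {
  png::writePNG(wrap_phase(phase) / (2 * pi), path)
  invisible(path)
}

manifest_entry <- function(files) {
  files <- files[file.exists(files)]
  data.frame(file = basename(files),
             md5 = unname(tools::md5sum(files)),
             stringsAsFactors = FALSE)
}

#' Write a phantom dataset to disk
#'
#' @param config a [phantom_config()].
#' @param out_dir output directory.
#' @param n_slices number of slices.
#' @param tumor_slices 1-based indices of tumor-bearing slices.
#' @return Invisibly, the vector of files written.
#' @export
run_phantom <- function(config = phantom_config(), out_dir,
                        n_slices = 1L, tumor_slices = seq_len(n_slices)) {
  series <- make_series(config, n_slices, tumor_slices)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_len(n_slices)) {
    truth <- structure(list(image = series$images[[i]],
                            brain_mask = series$brain_masks[[i]],
                            tumor_mask = series$tumor_masks[[i]],
                            config = config),
                       class = "phantom_truth")
    files <- c(files, write_phantom(truth, out_dir,
                                    sprintf("slice_%03d", i)))
  }
  invisible(files)
}

#' Run an end-to-end holographic projection scheme
#'
#' `scheme = "stack"`: generate (or accept) a tumor-bearing phantom series,
#' segment every slice, compute the layered 3D tumor-map hologram, tile it,
#' reconstruct with and without temporal multiplexing, and report speckle
#' contrast, per-slice Dice and the tumor volume.  `scheme = "compare"`:
#' generate a registered follow-up pair, segment both exams, compute the
#' comparative side-by-side hologram with tumor highlighting, reconstruct
#' it, and report per-exam tumor area/solidity and their change.
#'
#' @param scheme `"stack"` or `"compare"`.
#' @param out_dir directory for all artifacts (created if needed).
#' @param phantom a [phantom_config()] describing the synthetic study.
#' @param seg a [segmentation_config()].
#' @param optics an [optics_config()]; reduce `slm_shape` for quick runs.
#' @param gamma tumor highlighting weight (compare scheme).
#' @param growth_factor follow-up tumor growth (compare scheme).
#' @param n_slices,tumor_slices series layout (stack scheme).
#' @param layer_spacing axial layer separation in meters (stack scheme).
#' @param pad_factor,max_iter,epsilon hologram synthesis controls.
#' @param seed overrides the phantom config's seed when not `NULL`.
#' @return Invisibly, the manifest (data frame of files and checksums);
#'   also written to `manifest.json` together with the metrics report.
#' @export
run_pipeline <- function(scheme = c("compare", "stack"), out_dir,
                         phantom = phantom_config(),
                         seg = segmentation_config(),
                         optics = optics_config(), gamma = 2,
                         growth_factor = 1.6, n_slices = 6L,
                         tumor_slices = 2:5, layer_spacing = 6.5e-3,
                         pad_factor = 4L, max_iter = 200L, epsilon = 0.05,
                         seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) phantom$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  metrics <- list(scheme = scheme)

  put <- function(name, writer, obj) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    files <<- c(files, path)
    path
  }

  if (scheme == "compare") {
    pair <- make_followup_pair(phantom, growth_factor)
    exams <- list(baseline = pair$baseline, progression = pair$progression)
    segs <- list()
    for (nm in names(exams)) {
      series <- normalize_series(as_mr_series(exams[[nm]]))
      sg <- segment_brain_and_tumor(series, seg)
      segs[[nm]] <- sg$slices[[1]]
      put(paste0(nm, ".pgm"), function(o, p) write_pgm16(o, p),
          exams[[nm]]$image)
      put(paste0(nm, "_brain_mask.png"), write_mask_png, segs[[nm]]$brain$mask)
      tm <- if (is.null(segs[[nm]]$tumor))
        matrix(FALSE, nrow(exams[[nm]]$image), ncol(exams[[nm]]$image))
      else segs[[nm]]$tumor$mask
      put(paste0(nm, "_tumor_mask.png"), write_mask_png, tm)
      rp <- region_properties(tm, phantom$pixel_spacing)
      metrics[[nm]] <- list(
        tumor_area_cm2 = rp$area_cm2, tumor_solidity = rp$solidity,
        dice_brain = dice(segs[[nm]]$brain$mask, exams[[nm]]$brain_mask),
        dice_tumor = dice(tm, exams[[nm]]$tumor_mask))
    }
    metrics$area_change_cm2 <- metrics$progression$tumor_area_cm2 -
      metrics$baseline$tumor_area_cm2
    holo <- build_comparative_hologram(
      segs$baseline$brain$gray_mask, segs$baseline$tumor$gray_mask,
      segs$progression$brain$gray_mask, segs$progression$tumor$gray_mask,
      gamma = gamma, optics = optics, pad_factor = pad_factor,
      max_iter = max_iter, epsilon = epsilon)
    put("hologram_phase.png", write_phase_png, holo$hologram$phase)
    recon <- fourier_reconstruct(holo$hologram)
    put("reconstruction.pgm", function(o, p)
      write_pgm16(normalize_intensity(o), p), recon$intensity)
    metrics$recon_scale_m_per_px <- recon$scale
  } else {
    series <- make_series(phantom, n_slices, tumor_slices)
    mrs <- normalize_series(as_mr_series(series))
    sg <- segment_brain_and_tumor(mrs, seg)
    detected <- which(vapply(sg$slices, `[[`, TRUE, "tumor_present"))
    if (!length(detected)) stopf("stage segmentation: no tumor slice detected")
    tmasks <- lapply(sg$slices[detected], function(s) s$tumor$mask)
    targets <- lapply(sg$slices[detected], function(s) s$tumor$gray_mask)
    for (i in seq_along(detected)) {
      put(sprintf("tumor_mask_%03d.png", detected[i]), write_mask_png,
          tmasks[[i]])
    }
    metrics$detected_slices <- detected
    metrics$dice_tumor <- vapply(seq_along(detected), function(i)
      dice(tmasks[[i]], series$tumor_masks[[detected[i]]]), 0)
    metrics$tumor_volume_cm3 <- tumor_volume(
      tmasks, phantom$pixel_spacing, phantom$slice_separation)
    built <- build_tumor_stack_hologram(
      targets, optics = optics, pad_factor = pad_factor,
      layer_spacing = layer_spacing, max_iter = max_iter,
      epsilon = epsilon)
    put("hologram_phase.png", write_phase_png, built$hologram$phase)
    tiles <- tile_hologram(built$hologram)
    support <- tile_support(tmasks, built$layers,
                            optics$slm_shape * pad_factor, pad_factor)
    r1 <- fourier_reconstruct(tiles[[1]])
    rm_ <- multiplexed_reconstruct(tiles)
    put("reconstruction_multiplexed.pgm", function(o, p)
      write_pgm16(normalize_intensity(o), p), rm_$intensity)
    metrics$n_tiles <- length(tiles)
    metrics$speckle_contrast_single <- speckle_contrast(r1$intensity, support)
    metrics$speckle_contrast_multiplexed <-
      speckle_contrast(rm_$intensity, support)
  }

  metrics_path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics, metrics_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, metrics_path)
  manifest <- manifest_entry(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE)
  invisible(manifest)
}

# ---------------------------------------------------------------------------
# command-line interface (thin dispatcher used by inst/cli/holoproj)

cli_options <- function(args) {
  opts <- list()
  pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3L))
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        opts[[key]] <- TRUE
        i <- i + 1L
      } else {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Dispatcher behind the `inst/cli/holoproj` script.  Subcommands:
#' `phantom` (write a synthetic dataset), `segment` (segment a DICOM or
#' raster directory), `run` (end-to-end `--scheme stack|compare`),
#' `evaluate` (Dice/BF/area report for a mask pair), `--version`.
#'
#' @param args character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
holoproj_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] == "--version") {
    cat("holoproj", as.character(utils::packageVersion("holoproj")), "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  parsed <- cli_options(args[-1])
  opts <- parsed$opts
  out <- opts$out
  if (cmd == "phantom") {
    if (is.null(out)) stopf("phantom: --out is required")
    cfg <- phantom_config(seed = cli_num(opts, "seed", 1),
                          noise_sigma = cli_num(opts, "noise_sigma", 0.01))
    n <- as.integer(cli_num(opts, "n_slices", 1))
    ts <- if (is.null(opts$tumor_slices)) seq_len(n)
          else as.integer(strsplit(opts$tumor_slices, ",")[[1]])
    run_phantom(cfg, out, n, ts)
  } else if (cmd == "segment") {
    if (is.null(opts$input) || is.null(out))
      stopf("segment: --input and --out are required")
    series <- read_input_series(opts$input)
    cfg <- segmentation_config(
      canny_high_1 = cli_num(opts, "canny_high1", 0.1),
      canny_high_2 = cli_num(opts, "canny_high2", 0.2),
      arrival_threshold = cli_num(opts, "arrival_threshold", 0.009),
      kappa = cli_num(opts, "kappa", 0.1))
    sg <- segment_brain_and_tumor(series, cfg)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    report <- list()
    for (i in seq_along(sg$slices)) {
      s <- sg$slices[[i]]
      write_mask_png(s$brain$mask,
                     file.path(out, sprintf("brain_%03d.png", i)))
      write_pgm16(s$brain$arrival$values,
                  file.path(out, sprintf("arrival_brain_%03d.pgm", i)))
      if (s$tumor_present)
        write_mask_png(s$tumor$mask,
                       file.path(out, sprintf("tumor_%03d.png", i)))
      report[[i]] <- list(
        slice = i, tumor_present = s$tumor_present,
        brain_area_px = sum(s$brain$mask),
        tumor_area_px = if (s$tumor_present) sum(s$tumor$mask) else 0,
        tumor_seed = if (s$tumor_present) as.vector(s$tumor_seed$points) else NULL)
    }
    jsonlite::write_json(report, file.path(out, "segmentation.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else if (cmd == "run") {
    if (is.null(out)) stopf("run: --out is required")
    slm <- if (is.null(opts$slm)) c(1080L, 1920L)
           else as.integer(strsplit(opts$slm, ",")[[1]])
    run_pipeline(
      scheme = if (is.null(opts$scheme)) "compare" else opts$scheme,
      out_dir = out,
      phantom = phantom_config(seed = cli_num(opts, "seed", 1)),
      optics = optics_config(slm_shape = slm),
      gamma = cli_num(opts, "gamma", 2),
      pad_factor = as.integer(cli_num(opts, "pad_factor", 4)),
      max_iter = as.integer(cli_num(opts, "max_iter", 200)),
      epsilon = cli_num(opts, "epsilon", 0.05))
  } else if (cmd == "evaluate") {
    if (is.null(opts$pred) || is.null(opts$truth))
      stopf("evaluate: --pred and --truth are required")
    pred <- read_mask_png(opts$pred)
    truth <- read_mask_png(opts$truth)
    rep_ <- metrics_report(pred_mask = pred, truth_mask = truth,
                           pixel_spacing = cli_num(opts, "pixel_spacing", 1))
    json <- jsonlite::toJSON(rep_, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    if (!is.null(opts$report)) writeLines(json, opts$report) else cat(json, "\n")
  } else {
    stopf("unknown subcommand '%s'", cmd)
  }
  invisible(0L)
}

# read a directory of DICOM files or rasters as a normalized series
read_input_series <- function(input) {
  if (!dir.exists(input)) stopf("input directory not found: %s", input)
  rasters <- sort(list.files(input, "\\.(png|pgm|tif|tiff)$",
                             full.names = TRUE))
  rasters <- rasters[!grepl("mask", basename(rasters))]
  if (length(rasters)) {
    meta <- list.files(input, "\\.ya?ml$", full.names = TRUE)
    spacing <- 1
    sep <- NA_real_
    if (length(meta)) {
      y <- yaml::read_yaml(meta[1])
      if (!is.null(y$pixel_spacing)) spacing <- y$pixel_spacing
      if (!is.null(y$slice_separation)) sep <- y$slice_separation
    }
    series <- mr_series(lapply(rasters, read_raster),
                        pixel_spacing = spacing, slice_separation = sep,
                        ids = basename(rasters))
    normalize_series(series)
  } else {
    read_dicom_series(input)
  }
}
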