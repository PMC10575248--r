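## End-to-end orchestration: configuration with per-default provenance,
## streaming frame processing, and the full assay workflow
## denoise -> median background -> subtract -> Hough -> refine ->
## size/luminance -> link -> enumerate -> threshold -> classify -> estimate.

## Registry of every pipeline default with its provenance: either a
## protocol constant of the reference platform or an explicit design
## choice documented in the methods vignette.
.pipelineDefaults <- function() {
  e <- function(section, key, value, provenance)
    list(section = section, key = key, value = value, provenance = provenance)
  list(
    e("colorimetry", "gamma", 2.2,
      "platform protocol: single-exponent gamma correction, gamma = 2.2"),
    e("colorimetry", "rgb_to_xyz_matrix", as.numeric(t(sRGBD65Matrix())),
      "design choice: sRGB/BT.709 primaries with D65 white point, the response consumer smartphone sensors target"),
    e("detection", "gaussian_kernel_px", 5L,
      "platform protocol: 5x5 denoising kernel (2-pixel radius)"),
    e("detection", "gaussian_sigma", 1.5,
      "platform protocol: Gaussian weighting with standard deviation 1.5"),
    e("detection", "hough_angular_res_deg", 1,
      "platform protocol: 1-degree angular resolution, read as the gradient-direction quantisation of centre voting"),
    e("detection", "hough_dist_res_px", 1,
      "platform protocol: 1-pixel distance resolution of radial voting"),
    e("detection", "se_radius_px", 2L,
      "platform protocol: circular structuring element of 2-pixel radius for erosion/dilation"),
    e("detection", "um_per_px", 0.5,
      "platform protocol: 0.5 micrometre-per-pixel conversion factor"),
    e("detection", "expected_diameter_um", 100,
      "study conditions: monodisperse droplets of nominal 100 um diameter"),
    e("detection", "radius_search_factors", c(0.4, 1.3),
      "design choice: radius window [0.4, 1.3] x expected diameter / 2; droplets span 100-200 um and the 300-um tubing bore bounds the maximum"),
    e("detection", "min_votes", NA_real_,
      "design choice: derived max(30, 0.25 x 2 pi r_min) so blank noise frames yield zero detections at the default noise level"),
    e("detection", "grad_threshold", 8,
      "design choice: edge gradient cutoff in 8-bit counts, above smoothed sensor noise, below the dimmest droplet rim gradient"),
    e("detection", "mask_factor", 1.2,
      "design choice: foreground within 1.2 x detected radius seeds the droplet mask before opening"),
    e("detection", "fg_fraction", 0.5,
      "design choice: half-maximum mask cutoff relative to the droplet's own interior amplitude, unbiased edge localisation under symmetric blur"),
    e("tracking", "flow_axis", "x",
      "design choice: droplets traverse the field of view along the tube axis, rendered horizontally"),
    e("tracking", "expected_dx_px", NA_real_,
      "design choice: per-frame flow displacement used for velocity-compensated gating; NA = take from the generator spec, else estimate from consecutive-frame detection displacements"),
    e("tracking", "max_displacement_px", NA_real_,
      "design choice: linking gate derived from the expected per-frame displacement"),
    e("tracking", "max_gap_frames", 1L,
      "design choice: tolerate one missed detection inside a track"),
    e("tracking", "counting_line_px", NA_real_,
      "design choice: census commit line at mid-frame along the flow axis"),
    e("quantification", "negative_statistic", "mean",
      "design choice: threshold = 2 x mean of negative-control luminances (median available), simplest reading of the twice-negative rule"),
    e("quantification", "volume_mode", "median_diameter",
      "design choice: V_d from the sphere volume of the median measured diameter; per-droplet mean volume available"),
    e("quantification", "vol_droplet_ul", NA_real_,
      "design choice: known droplet volume of the calibrated monodisperse emulsion, overriding measured sizing; NA = use volume_mode"),
    e("quantification", "ci_level", 0.95,
      "design choice: exact Clopper-Pearson binomial interval on f_p, standard digital-assay practice"),
    e("run", "chunk_size", 256L,
      "design choice: frames per processing window; the background median spans the window (full sequence when it fits)"),
    e("run", "seed", 1L, "design choice: run metadata, reproducibility"))
}

#' Pipeline configuration defaults and provenance
#'
#' Every numeric default of the pipeline carries provenance: either a
#' protocol constant of the reference platform or an explicit design
#' choice.
#'
#' @return data.frame with columns `section`, `key`, `provenance`.
#' @export
configProvenance <- function() {
  d <- .pipelineDefaults()
  data.frame(section = vapply(d, `[[`, "", "section"),
             key = vapply(d, `[[`, "", "key"),
             provenance = vapply(d, `[[`, "", "provenance"))
}

#' Build a resolved pipeline configuration
#'
#' Nested configuration (sections `colorimetry`, `detection`, `tracking`,
#' `quantification`, `run`); unknown sections or keys are rejected so
#' typos cannot silently fall back to defaults.
#'
#' @param overrides nested named list of overrides, e.g.
#'   `list(detection = list(um_per_px = 1))`.
#' @return nested named list, fully resolved.
#' @export
pipelineConfig <- function(overrides = list()) {
  cfg <- list()
  for (d in .pipelineDefaults()) cfg[[d$section]][[d$key]] <- d$value
  if (length(overrides)) {
    for (sec in names(overrides)) {
      if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
      for (key in names(overrides[[sec]])) {
        if (!key %in% names(cfg[[sec]]))
          stop("unknown config key: ", sec, "$", key)
        cfg[[sec]][[key]] <- overrides[[sec]][[key]]
      }
    }
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level sections mirror [pipelineConfig()].
#' @return resolved configuration list.
#' @export
readPipelineConfig <- function(path) {
  pipelineConfig(yaml::read_yaml(path))
}

.detectionParamsFromConfig <- function(cfg) {
  det <- cfg$detection
  detectionParams(
    expectedDiameterUm = det$expected_diameter_um, umPerPx = det$um_per_px,
    radiusRangePx = det$radius_search_factors * det$expected_diameter_um /
      det$um_per_px / 2,
    gaussianKernelPx = det$gaussian_kernel_px,
    gaussianSigma = det$gaussian_sigma,
    houghAngularResDeg = det$hough_angular_res_deg,
    houghDistResPx = det$hough_dist_res_px,
    seRadiusPx = det$se_radius_px, minVotes = det$min_votes,
    gradThreshold = det$grad_threshold, maskFactor = det$mask_factor,
    fgFraction = det$fg_fraction)
}

.colorTransformFromConfig <- function(cfg)
  colorTransform(gamma = cfg$colorimetry$gamma,
                 matrix = cfg$colorimetry$rgb_to_xyz_matrix)

#' Read video frames from a directory of PNG files
#'
#' Frames are PNG files read in lexicographic filename order (zero-padded
#' numbering preserves temporal order); indices are 0-based and timestamps
#' are `frame_index / fps`.
#'
#' @param path directory containing `.png` frames.
#' @param fps frame rate used for timestamps (default 60).
#' @return list of H x W x 3 arrays (0..255) with attributes
#'   `frame_index` and `timestamp` on each frame.
#' @export
readFrames <- function(path, fps = 60) {
  if (!dir.exists(path)) stop("frame directory not found: ", path)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no PNG frames in ", path)
  lapply(seq_along(files), function(i) {
    img <- tryCatch(png::readPNG(files[i]),
                    error = function(e) stop("undecodable frame ", i - 1L,
                                             " (", basename(files[i]), ")"))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
    fr <- round(img * 255)
    attr(fr, "frame_index") <- i - 1L
    attr(fr, "timestamp") <- (i - 1L) / fps
    fr
  })
}

#' Write frames as numbered PNG files
#'
#' @param frames list of H x W x 3 arrays (0..255).
#' @param path output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeFrames <- function(frames, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(frames), function(i) {
    f <- file.path(path, sprintf("frame_%06d.png", i - 1L))
    png::writePNG(frames[[i]] / 255, f)
    f
  }, "")
  invisible(paths)
}

## Resolve a frame input into chunked access: list of frames, a PNG
## directory, or a SyntheticAssay rendered lazily.
.frameSource <- function(input, fps = 60) {
  if (is(input, "SyntheticAssay"))
    list(n = input@nFrames,
         get = function(idx) renderFrames(input, idx))
  else if (is.character(input)) {
    frames <- readFrames(input, fps)
    list(n = length(frames), get = function(idx) frames[idx + 1L])
  } else if (is.list(input))
    list(n = length(input), get = function(idx) input[idx + 1L])
  else stop("unsupported frame input")
}

#' Detect, measure and enumerate droplets in a video
#'
#' Streaming front half of the pipeline: frames are processed in windows
#' (denoise, median-background subtraction within the window, Hough
#' detection, mask refinement, sizing and colour measurement), then all
#' per-frame detections are linked into tracks and committed at the
#' counting line.
#'
#' @param input frame input: list of H x W x 3 arrays, a PNG directory, or
#'   a [SyntheticAssay-class].
#' @param config resolved [pipelineConfig()] list.
#' @return list with `droplets` ([DropletSet-class]), `tracks`,
#'   `detections` (the per-frame detection table with track assignments),
#'   and `counts` (frames, detections, tracks, records, flagged).
#' @export
processVideo <- function(input, config = pipelineConfig()) {
  src <- .frameSource(input)
  params <- .detectionParamsFromConfig(config)
  ct <- .colorTransformFromConfig(config)
  chunk <- max(8L, as.integer(config$run$chunk_size))
  dets <- list()
  geom <- NULL
  for (start in seq(0L, src$n - 1L, by = chunk)) {
    idx <- start:min(src$n - 1L, start + chunk - 1L)
    frames <- src$get(idx)
    den <- lapply(frames, gaussianDenoise, params = params)
    rm(frames)
    bg <- medianBackground(den)
    geom <- dim(bg)
    for (k in seq_along(idx)) {
      fgf <- subtractBackground(den[[k]], bg)
      d <- detectDroplets(fgf, den[[k]], params, ct)
      if (nrow(d)) {
        d$frame <- idx[k]
        dets[[length(dets) + 1L]] <- d
      }
    }
  }
  detections <- if (length(dets)) do.call(rbind, dets) else
    data.frame(center_x = numeric(0), center_y = numeric(0),
               radius_px = numeric(0), votes = numeric(0),
               diameter_um = numeric(0), luminance = numeric(0),
               chrom_x = numeric(0), chrom_y = numeric(0),
               frame = integer(0))
  trk <- config$tracking
  edx <- trk$expected_dx_px
  if (is.na(edx))
    edx <- if (is(input, "SyntheticAssay"))
      input@spec@flowVelocityPxPerFrame
    else estimateFlowDisplacement(detections, trk$flow_axis)
  tparams <- trackingParams(flowAxis = trk$flow_axis, expectedDxPx = edx,
                            maxDisplacementPx = trk$max_displacement_px,
                            maxGapFrames = trk$max_gap_frames,
                            countingLinePx = trk$counting_line_px)
  linked <- linkDetections(detections, tparams)
  tracks <- summariseTracks(linked, tparams, frameWidth = geom[2],
                            frameHeight = geom[1])
  records <- enumerateDroplets(tracks, tparams, umPerPx = params@umPerPx)
  list(droplets = records, tracks = tracks, detections = linked,
       counts = list(frames = src$n, detections = nrow(detections),
                     tracks = nrow(tracks), records = nDroplets(records),
                     flagged = attr(records, "n_flagged")))
}

#' Run a complete ddLAMP assay analysis
#'
#' Executes the full workflow on a droplet video and a negative control:
#' detection and census as in [processVideo()], twice-negative
#' thresholding, classification, and Poisson concentration estimation with
#' an exact binomial interval. An empty detection set yields a report with
#' N_T = 0 and a warning rather than an error; a saturated assay (all
#' droplets positive) is flagged and left without a concentration
#' estimate.
#'
#' @param input frame input (list, PNG directory, or
#'   [SyntheticAssay-class]).
#' @param negativeLuminances numeric vector of negative-control droplet
#'   luminances (e.g. `droplets(...)$luminance` of a no-template run);
#'   alternatively supply `threshold` directly.
#' @param threshold stored luminance threshold, overriding
#'   `negativeLuminances`.
#' @param config resolved [pipelineConfig()] list.
#' @return an [AssayReport-class].
#' @export
runAssay <- function(input, negativeLuminances = NULL, threshold = NULL,
                     config = pipelineConfig()) {
  if (is.null(threshold)) {
    if (is.null(negativeLuminances))
      stop("supply a negative control (negativeLuminances) or a stored ",
           "threshold")
    threshold <- negativeThreshold(
      negativeLuminances, statistic = config$quantification$negative_statistic)
  }
  stage <- processVideo(input, config)
  warnings <- character(0)
  cls <- classifyDroplets(stage$droplets, threshold)
  est <- list()
  d <- droplets(cls@droplets)
  if (cls@nTotal == 0L) {
    warnings <- c(warnings, "no droplets detected (N_T = 0)")
  } else if (cls@nPositive == cls@nTotal) {
    warnings <- c(warnings,
                  "saturated assay: all droplets positive, concentration not quantifiable")
  } else {
    vd <- config$quantification$vol_droplet_ul
    if (is.na(vd))
      vd <- if (config$quantification$volume_mode == "median_diameter")
        dropletVolumeUl(median(d$diameter_um))
      else mean(dropletVolumeUl(d$diameter_um))
    est <- list(estimateConcentration(cls@nPositive, cls@nTotal, vd,
                                      level = config$quantification$ci_level))
  }
  new("AssayReport", classification = cls, estimate = est,
      stageCounts = stage$counts,
      tables = list(tracks = stage$tracks, detections = stage$detections),
      config = config, warnings = warnings)
}

#' Write assay outputs to a directory
#'
#' Writes `droplets.csv` (the classified droplet table), `tracks.csv`,
#' `detections.csv` (per-frame detections with track assignments),
#' `report.json` (summary: counts, threshold, f_p, V_d, concentration and
#' interval, saturation flag), `resolved_config.yaml`, and `log.txt` with
#' per-stage counts.
#'
#' @param report an [AssayReport-class].
#' @param path output directory (created if needed).
#' @return invisibly, the path.
#' @export
writeOutputs <- function(report, path) {
  stopifnot(is(report, "AssayReport"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cls <- report@classification
  write.csv(droplets(cls@droplets), file.path(path, "droplets.csv"),
            row.names = FALSE)
  write.csv(report@tables$tracks, file.path(path, "tracks.csv"),
            row.names = FALSE)
  if (!is.null(report@tables$detections))
    write.csv(report@tables$detections, file.path(path, "detections.csv"),
              row.names = FALSE)
  est <- if (length(report@estimate)) report@estimate[[1]] else NULL
  summary <- list(
    n_total = cls@nTotal, n_positive = cls@nPositive,
    fraction_positive = cls@fractionPositive, threshold = cls@threshold,
    vol_droplet_ul = if (!is.null(est)) est@volDropletUl else NA,
    conc_copies_per_ul = if (!is.null(est)) est@concCopiesPerUl else NA,
    ci_low = if (!is.null(est)) est@ciLow else NA,
    ci_high = if (!is.null(est)) est@ciHigh else NA,
    saturated = any(grepl("saturated", report@warnings)),
    warnings = report@warnings)
  jsonlite::write_json(summary, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  yaml::write_yaml(report@config, file.path(path, "resolved_config.yaml"))
  writeLines(c(sprintf("stage counts: %s",
                       paste(names(report@stageCounts),
                             unlist(report@stageCounts), sep = "=",
                             collapse = ", ")),
               sprintf("warnings: %s",
                       if (length(report@warnings))
                         paste(report@warnings, collapse = "; ")
                       else "none")),
             file.path(path, "log.txt"))
  invisible(path)
}

#' Reload an assay report summary
#'
#' @param path directory written by [writeOutputs()].
#' @return named list parsed from `report.json`.
#' @export
readReport <- function(path)
  jsonlite::read_json(file.path(path, "report.json"), simplifyVector = TRUE)
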