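#' Linear sRGB (BT.709/D65) to CIE XYZ matrix
#'
#' The default "direct linear model" matrix: BT.709 primaries, D65 white.
#' Row sums give the white point (X, Y, Z) with Y = 1.
#'
#' @return 3x3 numeric matrix.
#' @export
sRGBD65Matrix <- function() {
  matrix(c(0.4124564, 0.3575761, 0.1804375,
           0.2126729, 0.7151522, 0.0721750,
           0.0193339, 0.1191920, 0.9503041),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("X", "Y", "Z"), c("R", "G", "B")))
}

#' Construct a colour transform configuration
#'
#' @param gamma power-law exponent linearising raw channels (default 2.2).
#' @param matrix 3x3 linear-RGB to XYZ matrix; defaults to [sRGBD65Matrix()].
#' @return a [ColorTransform-class] object.
#' @examples
#' ct <- colorTransform()
#' rowSums(ct@matrix)  # the D65 white point; Y component is 1
#' @export
colorTransform <- function(gamma = 2.2, matrix = sRGBD65Matrix()) {
  if (is.numeric(matrix) && is.null(dim(matrix)) && length(matrix) == 9)
    matrix <- base::matrix(matrix, nrow = 3, byrow = TRUE)
  if (!is.numeric(matrix) || !identical(dim(matrix), c(3L, 3L)))
    stop("rgb_to_xyz matrix must be 3x3 (or 9 row-major values)")
  new("ColorTransform", gamma = gamma, matrix = matrix)
}

#' Construct droplet detection parameters
#'
#' Numeric defaults follow the smartphone protocol (5x5 Gaussian, sigma
#' 1.5; 1-degree / 1-pixel Hough resolution; 2-pixel disc opening; 0.5
#' um/px); the remaining defaults are derived from the expected droplet
#' diameter as documented in [DetectionParams-class].
#'
#' @param expectedDiameterUm expected droplet diameter used to derive the
#'   radius search range (default 100 um).
#' @param umPerPx micrometres per pixel (default 0.5).
#' @param radiusRangePx optional explicit radius search range in pixels,
#'   overriding the derived `[0.4, 1.3] * expected diameter / 2` window.
#' @param gaussianKernelPx,gaussianSigma Gaussian denoise kernel width and sd.
#' @param houghAngularResDeg,houghDistResPx Hough voting resolutions.
#' @param seRadiusPx structuring-element radius for the opening.
#' @param minVotes,minCenterDistPx accumulator peak threshold and minimum
#'   peak separation (`NA` = derive from the radius range).
#' @param gradThreshold edge gradient-magnitude cutoff, 8-bit counts.
#' @param maskFactor,fgFraction mask seeding radius factor and half-maximum
#'   foreground fraction.
#' @return a [DetectionParams-class] object.
#' @export
detectionParams <- function(expectedDiameterUm = 100, umPerPx = 0.5,
                            radiusRangePx = NULL,
                            gaussianKernelPx = 5L, gaussianSigma = 1.5,
                            houghAngularResDeg = 1, houghDistResPx = 1,
                            seRadiusPx = 2L, minVotes = NA_real_,
                            minCenterDistPx = NA_real_, gradThreshold = 8,
                            maskFactor = 1.2, fgFraction = 0.5) {
  dpx <- expectedDiameterUm / umPerPx
  if (is.null(radiusRangePx))
    radiusRangePx <- c(0.4, 1.3) * dpx / 2
  radiusRangePx <- c(max(2, floor(radiusRangePx[1])), ceiling(radiusRangePx[2]))
  if (is.na(minVotes))
    minVotes <- max(30, 0.25 * 2 * pi * radiusRangePx[1])
  if (is.na(minCenterDistPx))
    minCenterDistPx <- 1.5 * radiusRangePx[1]
  new("DetectionParams",
      gaussianKernelPx = as.integer(gaussianKernelPx),
      gaussianSigma = gaussianSigma,
      houghAngularResDeg = houghAngularResDeg,
      houghDistResPx = houghDistResPx,
      seRadiusPx = as.integer(seRadiusPx),
      radiusRangePx = as.numeric(radiusRangePx),
      minVotes = minVotes, minCenterDistPx = minCenterDistPx,
      gradThreshold = gradThreshold, maskFactor = maskFactor,
      fgFraction = fgFraction, umPerPx = umPerPx)
}

#' Construct tracking parameters
#'
#' @param flowAxis axis of droplet motion, `"x"` (default) or `"y"`.
#' @param expectedDxPx expected per-frame displacement along the flow axis
#'   (pixels); 0 disables velocity compensation.
#' @param maxDisplacementPx linking gate around the predicted position;
#'   `NA` derives `max(6, 0.15 * expectedDxPx)` — wide enough for detection
#'   position noise and flow jitter, well below the inter-droplet spacing.
#' @param maxGapFrames tolerated missed frames inside a track (default 1).
#' @param countingLinePx census line coordinate; `NA` = frame midline.
#' @return a [TrackingParams-class] object.
#' @export
trackingParams <- function(flowAxis = "x", expectedDxPx = 0,
                           maxDisplacementPx = NA_real_, maxGapFrames = 1L,
                           countingLinePx = NA_real_) {
  if (is.na(maxDisplacementPx))
    maxDisplacementPx <- max(6, 0.15 * expectedDxPx)
  new("TrackingParams", flowAxis = flowAxis, expectedDxPx = expectedDxPx,
      maxDisplacementPx = maxDisplacementPx,
      maxGapFrames = as.integer(maxGapFrames),
      countingLinePx = countingLinePx)
}

#' Construct a synthetic assay specification
#'
#' See [AssaySpec-class] for the meaning of each parameter. The defaults
#' describe the reference study conditions: monodisperse 100-um droplets
#' (spread well inside +/-5 um) imaged at 0.5 um/px and 60 fps in 300-um
#' tubing, dim negative vs bright positive luminance clusters with a wide
#' gap, and mild 8-bit sensor noise.
#'
#' @param concCopiesPerUl target concentration, copies/uL.
#' @param nDroplets number of droplets.
#' @param dropletDiameterUm nominal diameter, um.
#' @param diameterSdUm diameter standard deviation, um.
#' @param frameHeight,frameWidth frame geometry, pixels.
#' @param umPerPx micrometres per pixel.
#' @param tubeIdUm tubing inner diameter, um.
#' @param fps frames per second.
#' @param flowVelocityPxPerFrame advance per frame, pixels.
#' @param spacingPx centre spacing; `NA` derives 2.4x diameter in pixels.
#' @param posLumMean,posLumSd,negLumMean,negLumSd luminance clusters.
#' @param noiseSd sensor noise sd, 8-bit counts.
#' @param backgroundLevel static background, 8-bit counts.
#' @param seed integer seed.
#' @return an [AssaySpec-class] object.
#' @export
assaySpec <- function(concCopiesPerUl = 100, nDroplets = 50L,
                      dropletDiameterUm = 100, diameterSdUm = 1.5,
                      frameHeight = 256L, frameWidth = 256L,
                      umPerPx = 0.5, tubeIdUm = 300, fps = 60,
                      flowVelocityPxPerFrame = 60, spacingPx = NA_real_,
                      posLumMean = 0.5, posLumSd = 0.05,
                      negLumMean = 0.05, negLumSd = 0.01,
                      noiseSd = 2, backgroundLevel = 10, seed = 1L) {
  if (is.na(spacingPx))
    spacingPx <- 2.4 * dropletDiameterUm / umPerPx
  new("AssaySpec", concCopiesPerUl = concCopiesPerUl,
      nDroplets = as.integer(nDroplets),
      dropletDiameterUm = dropletDiameterUm, diameterSdUm = diameterSdUm,
      frameHeight = as.integer(frameHeight),
      frameWidth = as.integer(frameWidth),
      umPerPx = umPerPx, tubeIdUm = tubeIdUm, fps = fps,
      flowVelocityPxPerFrame = flowVelocityPxPerFrame, spacingPx = spacingPx,
      posLumMean = posLumMean, posLumSd = posLumSd,
      negLumMean = negLumMean, negLumSd = negLumSd,
      noiseSd = noiseSd, backgroundLevel = backgroundLevel,
      seed = as.integer(seed))
}

#' Construct PID gains
#'
#' @param kp,ki,kd non-negative proportional/integral/derivative gains.
#' @return a [PIDGains-class] object.
#' @export
pidGains <- function(kp = 0, ki = 0, kd = 0)
  new("PIDGains", kp = kp, ki = ki, kd = kd)

#' Reference heater PID gains
#'
#' The gains used on the smartphone ddLAMP heater platform this package
#' models (Kp = 0.68, Ki = 1.49, Kd = 0.06), shipped verbatim as a named
#' preset. Note they do not jointly satisfy any single row of the classic
#' Ziegler-Nichols table (see [znTune()]); they are provided as-is.
#'
#' @return a [PIDGains-class] object.
#' @export
ddlampHeaterGains <- function() pidGains(kp = 0.68, ki = 1.49, kd = 0.06)

#' Construct a thermal plant model
#'
#' Defaults (gain 60 C/unit duty, tau 40 s, dead time 2 s, ambient 22 C)
#' are a modelling fiction chosen so a 65 C setpoint is reachable at
#' duty ~0.7 and Ziegler-Nichols tuning is exercised.
#'
#' @param gain,timeConstant,deadTime,ambient see [ThermalPlant-class].
#' @return a [ThermalPlant-class] object.
#' @export
thermalPlant <- function(gain = 60, timeConstant = 40, deadTime = 2,
                         ambient = 22)
  new("ThermalPlant", gain = gain, timeConstant = timeConstant,
      deadTime = deadTime, ambient = ambient)

## ---- accessors and show methods ----

#' @describeIn DropletSet-class droplet table accessor.
#' @param x a `DropletSet`.
#' @export
droplets <- function(x) {
  stopifnot(is(x, "DropletSet"))
  x@droplets
}

#' @describeIn DropletSet-class number of droplets in the census.
#' @export
nDroplets <- function(x) {
  stopifnot(is(x, "DropletSet"))
  nrow(x@droplets)
}

#' @describeIn SyntheticAssay-class ground-truth table accessor.
#' @param assay a `SyntheticAssay`.
#' @export
assayTruth <- function(assay) {
  stopifnot(is(assay, "SyntheticAssay"))
  assay@truth
}

#' @describeIn ConcentrationEstimate-class point estimate accessor
#'   (copies/uL).
#' @param object a `ConcentrationEstimate`.
#' @export
concentration <- function(object) {
  stopifnot(is(object, "ConcentrationEstimate"))
  object@concCopiesPerUl
}

#' @describeIn ConcentrationEstimate-class confidence interval accessor.
#' @export
concentrationCI <- function(object) {
  stopifnot(is(object, "ConcentrationEstimate"))
  c(low = object@ciLow, high = object@ciHigh)
}

setMethod("show", "ColorTransform", function(object) {
  cat("ColorTransform: gamma =", object@gamma, "\n")
  print(round(object@matrix, 5))
})

setMethod("show", "DropletSet", function(object) {
  d <- object@droplets
  cat(sprintf("DropletSet with %d droplets (%.3g um/px)\n",
              nrow(d), object@umPerPx))
  if (nrow(d)) {
    cat(sprintf("  diameter_um: median %.1f [%.1f, %.1f]\n",
                median(d$diameter_um), min(d$diameter_um),
                max(d$diameter_um)))
    cat(sprintf("  luminance:   median %.4f [%.4f, %.4f]\n",
                median(d$luminance), min(d$luminance), max(d$luminance)))
    cat("  labels:", paste(names(table(d$label)), table(d$label),
                           sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf(
    "ClassificationResult: N_T = %d, N_P = %d, f_p = %.4g (threshold %.4g)\n",
    object@nTotal, object@nPositive, object@fractionPositive,
    object@threshold))
})

setMethod("show", "ConcentrationEstimate", function(object) {
  cat(sprintf(
    "ConcentrationEstimate: C_o = %.4g copies/uL [%.4g, %.4g] (%d%% CI)\n",
    object@concCopiesPerUl, object@ciLow, object@ciHigh,
    round(100 * object@level)))
  cat(sprintf("  from N_P/N_T = %d/%d, V_d = %.4g uL\n",
              object@nPositive, object@nTotal, object@volDropletUl))
})

setMethod("show", "SyntheticAssay", function(object) {
  cat(sprintf(
    "SyntheticAssay: %d droplets at %.4g copies/uL, %d frames (%dx%d px)\n",
    nrow(object@truth), object@spec@concCopiesPerUl, object@nFrames,
    object@spec@frameHeight, object@spec@frameWidth))
  cat(sprintf("  true positives: %d\n",
              sum(object@truth$label == "positive")))
})

setMethod("show", "AssayReport", function(object) {
  cat("AssayReport\n")
  show(object@classification)
  if (length(object@estimate)) show(object@estimate[[1]])
  cat("  stages:", paste(names(object@stageCounts),
                         unlist(object@stageCounts),
                         sep = "=", collapse = ", "), "\n")
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "PIDGains", function(object) {
  cat(sprintf("PIDGains: kp = %.4g, ki = %.4g, kd = %.4g\n",
              object@kp, object@ki, object@kd))
})

setMethod("show", "ThermalPlant", function(object) {
  cat(sprintf(
    "ThermalPlant: gain %.3g C/duty, tau %.3g s, dead time %.3g s, ambient %.3g C\n",
    object@gain, object@timeConstant, object@deadTime, object@ambient))
})

setMethod("show", "ControlTrace", function(object) {
  cat(sprintf("ControlTrace: %d samples, settling time %s s, band +/-%.2g C\n",
              nrow(object@trace),
              if (is.na(object@settlingTime)) "NA"
              else sprintf("%.1f", object@settlingTime), object@band))
})
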