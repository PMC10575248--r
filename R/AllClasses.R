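#' @import methods
#' @importFrom stats median rnorm rpois runif qbeta setNames
#' @importFrom utils head tail write.csv read.csv
NULL

## Central S4 classes of the ddLAMP analysis stack. Video frames themselves
## are plain H x W x 3 numeric arrays on the 0..255 scale (8-bit semantics);
## classes below hold configuration, droplet-level results and simulation
## state, each with a validity method and accessors.

#' Colour transform configuration
#'
#' Parameters of the raw-RGB to CIE-xyY conversion used for fluorescence
#' quantification: a gamma exponent that linearises the camera response and
#' a 3x3 linear RGB-to-XYZ matrix. The default matrix maps linear sRGB
#' (BT.709 primaries) to XYZ under the D65 white point, the response that
#' consumer smartphone sensors target; its middle (Y) row sums to 1 so that
#' reference white has luminance 1.
#'
#' @slot gamma positive exponent of the power-law linearisation (default 2.2).
#' @slot matrix 3x3 non-negative matrix taking linear (R,G,B) to (X,Y,Z).
#' @export
setClass("ColorTransform",
  representation(gamma = "numeric", matrix = "matrix"),
  prototype(gamma = 2.2))

setValidity("ColorTransform", function(object) {
  msg <- NULL
  if (length(object@gamma) != 1 || !is.finite(object@gamma) ||
      object@gamma <= 0)
    msg <- c(msg, "gamma must be a single positive number")
  m <- object@matrix
  if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)))
    msg <- c(msg, "matrix must be numeric 3x3")
  else {
    if (any(m < 0)) msg <- c(msg, "matrix coefficients must be non-negative")
    if (abs(sum(m[2, ]) - 1) > 1e-3)
      msg <- c(msg, "luminance (second) row of matrix must sum to 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' Droplet detection parameters
#'
#' Tunables of the per-frame droplet detector. Defaults follow the
#' smartphone imaging protocol: 5x5 Gaussian kernel (2-pixel radius) with
#' sigma 1.5, circle Hough transform at 1-degree angular and 1-pixel
#' distance resolution, a 2-pixel disc structuring element for the
#' morphological opening, and a 0.5 micrometre-per-pixel scale. The radius
#' search window defaults to [0.4, 1.3] times the expected droplet diameter
#' (in pixels, halved to radii); droplets are 100-200 um and the 300-um
#' tubing bore bounds the maximum.
#'
#' @slot gaussianKernelPx odd kernel width in pixels (default 5).
#' @slot gaussianSigma Gaussian standard deviation in pixels (default 1.5).
#' @slot houghAngularResDeg angular step of gradient-direction voting, degrees.
#' @slot houghDistResPx radial step of centre voting, pixels.
#' @slot seRadiusPx radius of the disc structuring element, pixels.
#' @slot radiusRangePx length-2 numeric, min and max circle radius in pixels.
#' @slot minVotes accumulator peak threshold (votes); `NA` derives
#'   `max(30, 0.25 * 2 * pi * min radius)` so blank noise frames stay empty.
#' @slot minCenterDistPx minimum centre-to-centre peak separation; `NA`
#'   derives 1.5x the minimum search radius.
#' @slot gradThreshold gradient-magnitude cutoff (8-bit counts) defining edge
#'   pixels that vote.
#' @slot maskFactor foreground pixels within `maskFactor` x radius of a
#'   detected centre seed the droplet mask (default 1.2).
#' @slot fgFraction fraction of the droplet's interior amplitude used as the
#'   half-maximum mask cutoff (default 0.5).
#' @slot umPerPx spatial calibration, micrometres per pixel (default 0.5).
#' @export
setClass("DetectionParams",
  representation(
    gaussianKernelPx = "integer", gaussianSigma = "numeric",
    houghAngularResDeg = "numeric", houghDistResPx = "numeric",
    seRadiusPx = "integer", radiusRangePx = "numeric",
    minVotes = "numeric", minCenterDistPx = "numeric",
    gradThreshold = "numeric", maskFactor = "numeric",
    fgFraction = "numeric", umPerPx = "numeric"))

setValidity("DetectionParams", function(object) {
  msg <- NULL
  if (object@gaussianKernelPx < 1L || object@gaussianKernelPx %% 2L == 0L)
    msg <- c(msg, "gaussianKernelPx must be odd and positive")
  if (object@gaussianSigma <= 0) msg <- c(msg, "gaussianSigma must be > 0")
  if (object@houghAngularResDeg <= 0 || object@houghDistResPx <= 0)
    msg <- c(msg, "Hough resolutions must be > 0")
  if (object@seRadiusPx < 1L) msg <- c(msg, "seRadiusPx must be >= 1")
  rr <- object@radiusRangePx
  if (length(rr) != 2 || any(rr <= 0) || rr[1] >= rr[2])
    msg <- c(msg, "radiusRangePx must be positive with min < max")
  if (object@umPerPx <= 0) msg <- c(msg, "umPerPx must be > 0")
  if (object@maskFactor < 1) msg <- c(msg, "maskFactor must be >= 1")
  if (object@fgFraction <= 0 || object@fgFraction >= 1)
    msg <- c(msg, "fgFraction must be in (0,1)")
  if (is.null(msg)) TRUE else msg
})

#' Droplet tracking parameters
#'
#' Configuration of cross-frame linking. Droplets move along one image axis
#' at near-constant flow velocity; per-frame detections are linked greedily
#' to the nearest active track after subtracting the expected per-frame
#' displacement, then committed to the census when the track crosses the
#' counting line.
#'
#' @slot flowAxis `"x"` or `"y"`, the axis of droplet motion.
#' @slot expectedDxPx expected per-frame displacement along the flow axis.
#' @slot maxDisplacementPx gating distance for linking around the
#'   predicted position; `NA` derives `max(6, 0.15 * expectedDxPx)`.
#' @slot maxGapFrames number of consecutive missed frames tolerated.
#' @slot countingLinePx flow-axis coordinate at which a track is counted;
#'   `NA` derives mid-frame.
#' @export
setClass("TrackingParams",
  representation(flowAxis = "character", expectedDxPx = "numeric",
    maxDisplacementPx = "numeric", maxGapFrames = "integer",
    countingLinePx = "numeric"))

setValidity("TrackingParams", function(object) {
  msg <- NULL
  if (!object@flowAxis %in% c("x", "y"))
    msg <- c(msg, "flowAxis must be 'x' or 'y'")
  if (object@expectedDxPx < 0) msg <- c(msg, "expectedDxPx must be >= 0")
  if (!is.na(object@maxDisplacementPx) && object@maxDisplacementPx <= 0)
    msg <- c(msg, "maxDisplacementPx must be > 0")
  if (object@maxGapFrames < 0L) msg <- c(msg, "maxGapFrames must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Synthetic ddLAMP assay specification
#'
#' Parameters of the synthetic assay generator: a monodisperse droplet
#' train carrying Poisson-partitioned target copies, rendered as
#' green-fluorescent anti-aliased discs flowing through the field of view
#' of an 8-bit RGB camera. Defaults emulate the reference platform:
#' 100-um droplets (spread well within +/-5 um), 0.5 um/px, 60 fps,
#' 300-um tubing, and bright/dim luminance clusters separated by a wide
#' gap so the twice-negative threshold splits them cleanly.
#'
#' @slot concCopiesPerUl target concentration C_o, copies/uL.
#' @slot nDroplets number of droplets in the train.
#' @slot dropletDiameterUm nominal droplet diameter, um (default 100).
#' @slot diameterSdUm per-droplet diameter standard deviation, um.
#' @slot frameHeight,frameWidth frame geometry, pixels.
#' @slot umPerPx spatial scale, micrometres per pixel.
#' @slot tubeIdUm tubing inner diameter, um (trajectories stay inside).
#' @slot fps frame rate, frames per second.
#' @slot flowVelocityPxPerFrame droplet advance per frame along x, pixels.
#' @slot spacingPx nominal centre-to-centre droplet spacing, pixels; `NA`
#'   derives 2.4x the droplet diameter in pixels.
#' @slot posLumMean,posLumSd luminance distribution of positive droplets.
#' @slot negLumMean,negLumSd luminance distribution of negative droplets.
#' @slot noiseSd additive Gaussian sensor noise, 8-bit counts.
#' @slot backgroundLevel static background level, 8-bit counts.
#' @slot seed integer random seed for reproducible assays.
#' @export
setClass("AssaySpec",
  representation(
    concCopiesPerUl = "numeric", nDroplets = "integer",
    dropletDiameterUm = "numeric", diameterSdUm = "numeric",
    frameHeight = "integer", frameWidth = "integer",
    umPerPx = "numeric", tubeIdUm = "numeric", fps = "numeric",
    flowVelocityPxPerFrame = "numeric", spacingPx = "numeric",
    posLumMean = "numeric", posLumSd = "numeric",
    negLumMean = "numeric", negLumSd = "numeric",
    noiseSd = "numeric", backgroundLevel = "numeric", seed = "integer"))

setValidity("AssaySpec", function(object) {
  msg <- NULL
  if (object@concCopiesPerUl < 0) msg <- c(msg, "concCopiesPerUl must be >= 0")
  if (object@nDroplets < 0L) msg <- c(msg, "nDroplets must be >= 0")
  if (object@dropletDiameterUm <= 0 ||
      object@dropletDiameterUm > object@tubeIdUm)
    msg <- c(msg, "dropletDiameterUm must be positive and fit the tubing bore")
  if (object@diameterSdUm < 0) msg <- c(msg, "diameterSdUm must be >= 0")
  if (object@frameHeight < 8L || object@frameWidth < 8L)
    msg <- c(msg, "frame geometry too small")
  if (object@umPerPx <= 0) msg <- c(msg, "umPerPx must be > 0")
  if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
  if (object@flowVelocityPxPerFrame <= 0)
    msg <- c(msg, "flowVelocityPxPerFrame must be > 0")
  if (object@posLumMean <= 2 * object@negLumMean)
    msg <- c(msg, paste("positive luminance mean must exceed twice the",
                        "negative mean so the threshold rule separates them"))
  if (object@posLumSd < 0 || object@negLumSd < 0)
    msg <- c(msg, "luminance sds must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  dpx <- object@dropletDiameterUm / object@umPerPx
  if (dpx > object@frameHeight - 4)
    msg <- c(msg, "droplet diameter in pixels exceeds the frame height")
  if (is.null(msg)) TRUE else msg
})

#' Synthetic assay with ground truth
#'
#' The realisation of an [AssaySpec]: per-droplet ground truth (copy count,
#' label, diameter, luminance, trajectory timing) plus everything needed to
#' render any frame on demand, so long videos never have to be held in
#' memory. Use [renderFrames()] to materialise frames and [assayTruth()] for
#' the truth table.
#'
#' @slot spec the generating [AssaySpec].
#' @slot truth data.frame, one row per droplet: `droplet_id`, `copy_count`,
#'   `label`, `diameter_um`, `luminance`, `x0_px`, `y_px`, `entry_frame`,
#'   `exit_frame`.
#' @slot nFrames number of frames in the full video.
#' @export
setClass("SyntheticAssay",
  representation(spec = "AssaySpec", truth = "data.frame",
                 nFrames = "integer"))

setValidity("SyntheticAssay", function(object) {
  need <- c("droplet_id", "copy_count", "label", "diameter_um", "luminance",
            "x0_px", "y_px", "entry_frame", "exit_frame")
  if (!all(need %in% names(object@truth)))
    return(paste("truth must contain columns:", paste(need, collapse = ", ")))
  tr <- object@truth
  if (nrow(tr) && any((tr$copy_count > 0) != (tr$label == "positive")))
    return("label must be 'positive' exactly when copy_count > 0")
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  TRUE
})

#' A census of physical droplets
#'
#' One row per unique droplet after cross-frame linking, carrying the
#' track-aggregated diameter (um), CIE-xyY luminance and chromaticity, and
#' a classification label (filled by [classifyDroplets()]).
#'
#' @slot droplets data.frame with columns `droplet_id`, `track_id`,
#'   `first_frame`, `last_frame`, `n_detections`, `diameter_um`,
#'   `luminance`, `chrom_x`, `chrom_y`, `label`.
#' @slot umPerPx spatial calibration the diameters were measured at.
#' @export
setClass("DropletSet",
  representation(droplets = "data.frame", umPerPx = "numeric"))

setValidity("DropletSet", function(object) {
  need <- c("droplet_id", "diameter_um", "luminance", "label")
  if (!all(need %in% names(object@droplets)))
    return(paste("droplets must contain columns:",
                 paste(need, collapse = ", ")))
  d <- object@droplets
  if (nrow(d) && any(d$diameter_um <= 0, na.rm = TRUE))
    return("diameter_um must be positive")
  if (nrow(d) && any(d$luminance < 0, na.rm = TRUE))
    return("luminance must be >= 0")
  TRUE
})

#' Positive/negative classification summary
#'
#' Result of thresholding droplet luminances: the cutoff, the labelled
#' droplets, and the counts N_T, N_P with the positive fraction
#' f_p = N_P / N_T.
#'
#' @slot threshold luminance cutoff (strictly-greater means positive).
#' @slot droplets the labelled [DropletSet].
#' @slot nTotal,nPositive droplet counts N_T and N_P.
#' @slot fractionPositive f_p = N_P / N_T (NaN when N_T = 0).
#' @export
setClass("ClassificationResult",
  representation(threshold = "numeric", droplets = "DropletSet",
    nTotal = "integer", nPositive = "integer", fractionPositive = "numeric"))

setValidity("ClassificationResult", function(object) {
  msg <- NULL
  if (object@nPositive < 0L || object@nPositive > object@nTotal)
    msg <- c(msg, "need 0 <= nPositive <= nTotal")
  if (object@nTotal > 0L &&
      abs(object@fractionPositive -
          object@nPositive / object@nTotal) > 1e-12)
    msg <- c(msg, "fractionPositive must equal nPositive/nTotal")
  if (is.null(msg)) TRUE else msg
})

#' Absolute concentration estimate
#'
#' Poisson-statistics estimate of the initial target concentration
#' C_o = -ln(1 - N_P/N_T) / V_d, with an exact (Clopper-Pearson) binomial
#' confidence interval on f_p transformed through the same relation.
#'
#' @slot concCopiesPerUl point estimate C_o, copies/uL.
#' @slot ciLow,ciHigh confidence bounds, copies/uL.
#' @slot level confidence level of the interval.
#' @slot nTotal,nPositive the counts the estimate is based on.
#' @slot fractionPositive f_p used.
#' @slot volDropletUl droplet volume V_d, uL.
#' @export
setClass("ConcentrationEstimate",
  representation(concCopiesPerUl = "numeric", ciLow = "numeric",
    ciHigh = "numeric", level = "numeric", nTotal = "integer",
    nPositive = "integer", fractionPositive = "numeric",
    volDropletUl = "numeric"))

setValidity("ConcentrationEstimate", function(object) {
  msg <- NULL
  if (object@volDropletUl <= 0) msg <- c(msg, "volDropletUl must be > 0")
  if (object@concCopiesPerUl < 0) msg <- c(msg, "concentration must be >= 0")
  if (object@ciLow > object@concCopiesPerUl + 1e-9 ||
      object@ciHigh < object@concCopiesPerUl - 1e-9)
    msg <- c(msg, "need ciLow <= estimate <= ciHigh")
  if (is.null(msg)) TRUE else msg
})

#' End-to-end assay report
#'
#' Everything [runAssay()] produces: the classification, the concentration
#' estimate (absent when saturated or empty), per-stage counts, the resolved
#' configuration, and warnings (e.g. saturation).
#'
#' @slot classification a [ClassificationResult].
#' @slot estimate a [ConcentrationEstimate] or `NULL` (list wrapper).
#' @slot stageCounts named list: frames read, detections, tracks, records.
#' @slot tables named list of data.frames (`tracks`, and optionally
#'   `detections`) for export.
#' @slot config resolved pipeline configuration echo (named list).
#' @slot warnings character vector of pipeline warnings.
#' @export
setClass("AssayReport",
  representation(classification = "ClassificationResult", estimate = "list",
    stageCounts = "list", tables = "list", config = "list",
    warnings = "character"))

#' PID controller gains
#'
#' Proportional, integral and derivative gains of the heater temperature
#' loop, in duty units per degree C of error (integral per second,
#' derivative times seconds).
#'
#' @slot kp,ki,kd non-negative gains.
#' @export
setClass("PIDGains",
  representation(kp = "numeric", ki = "numeric", kd = "numeric"))

setValidity("PIDGains", function(object) {
  if (any(c(object@kp, object@ki, object@kd) < 0))
    "gains must be >= 0" else TRUE
})

#' First-order-plus-dead-time thermal plant
#'
#' Desk-scale stand-in for the aluminium heating block: a first-order lag
#' with transport delay driven by a PWM duty in [0,1]. This plant is a
#' modelling fiction chosen so the 65 C setpoint is reachable and tuning is
#' exercised; it is not a measured model of any hardware.
#'
#' @slot gain steady-state temperature rise per unit duty, degrees C.
#' @slot timeConstant first-order time constant, s.
#' @slot deadTime input transport delay, s.
#' @slot ambient ambient temperature, degrees C.
#' @export
setClass("ThermalPlant",
  representation(gain = "numeric", timeConstant = "numeric",
    deadTime = "numeric", ambient = "numeric"))

setValidity("ThermalPlant", function(object) {
  msg <- NULL
  if (object@gain <= 0) msg <- c(msg, "gain must be > 0")
  if (object@timeConstant <= 0) msg <- c(msg, "timeConstant must be > 0")
  if (object@deadTime < 0) msg <- c(msg, "deadTime must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Closed-loop control trace
#'
#' Time series of a simulated heater run: setpoint, temperature and PWM
#' duty at each step, plus settling diagnostics.
#'
#' @slot trace data.frame with columns `t`, `setpoint`, `temperature`,
#'   `duty` (duty clamped to [0,1], PWM semantics).
#' @slot settlingTime first time after which the temperature stays within
#'   the band around the setpoint (NA if never).
#' @slot band half-width of the settling band, degrees C.
#' @slot maxDevPostSettling largest absolute deviation after settling.
#' @export
setClass("ControlTrace",
  representation(trace = "data.frame", settlingTime = "numeric",
    band = "numeric", maxDevPostSettling = "numeric"))

setValidity("ControlTrace", function(object) {
  need <- c("t", "setpoint", "temperature", "duty")
  if (!all(need %in% names(object@trace)))
    return(paste("trace needs columns:", paste(need, collapse = ", ")))
  if (nrow(object@trace) &&
      (any(object@trace$duty < -1e-9) || any(object@trace$duty > 1 + 1e-9)))
    return("duty must lie in [0,1]")
  TRUE
})
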