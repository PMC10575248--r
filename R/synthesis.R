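## Synthetic ddLAMP assay generation: Poisson-partitioned droplet trains
## rendered as green-fluorescent anti-aliased discs flowing through an
## 8-bit RGB field of view, with a per-droplet ground-truth channel.

## Run expr with a local, restored RNG state seeded by `seed`.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Draw Poisson-partitioned copy counts
#'
#' Independent Poisson draws of the target copies per droplet at mean
#' occupancy lambda = C_o V_d.
#'
#' @param concCopiesPerUl target concentration, copies/uL (>= 0).
#' @param volDropletUl droplet volume(s), uL; scalar or length-n vector.
#' @param n number of droplets.
#' @param seed integer seed (caller RNG state is untouched).
#' @return integer vector of n copy counts.
#' @export
drawCopyCounts <- function(concCopiesPerUl, volDropletUl, n, seed = 1L) {
  if (concCopiesPerUl < 0) stop("concentration must be >= 0")
  if (any(volDropletUl < 0)) stop("droplet volume must be >= 0")
  stopifnot(n > 0)
  .withSeed(seed, rpois(n, concCopiesPerUl * volDropletUl))
}

#' Droplet size versus continuous-phase flow rate
#'
#' Empirical flow-focusing model: at a fixed dispersed-phase flow rate
#' (Q_D = 5 uL/min) the droplet diameter falls monotonically as the
#' continuous-phase flow rate Q_C rises, from the channel-bound maximum of
#' ~200 um at very low Q_C (0.05 uL/min) down to ~100 um at 3 uL/min.
#' Only these two anchor points are from measurement; the intermediate
#' shape is a logarithmic interpolation chosen here, clamped to
#' [100, 200] um.
#'
#' @param qcUlPerMin continuous-phase flow rate(s), uL/min, > 0.
#' @param anchors data.frame with columns `qc` and `diameter` (um),
#'   monotone non-increasing in `qc`.
#' @return droplet diameter(s) in um.
#' @examples
#' diameterFromFlow(c(0.05, 3))  # ~200 then ~100 um
#' @export
diameterFromFlow <- function(qcUlPerMin,
                             anchors = data.frame(qc = c(0.05, 3),
                                                  diameter = c(200, 100))) {
  if (any(qcUlPerMin <= 0)) stop("flow rate must be > 0")
  o <- order(anchors$qc)
  anchors <- anchors[o, , drop = FALSE]
  if (is.unsorted(rev(anchors$diameter)))
    stop("anchor diameters must be monotone non-increasing in qc")
  d <- stats::approx(log(anchors$qc), anchors$diameter, xout = log(qcUlPerMin),
                     rule = 2)$y
  pmin(pmax(d, min(anchors$diameter)), max(anchors$diameter))
}

#' Assign endpoint luminances to droplets
#'
#' Droplets holding at least one target copy amplify and draw their
#' endpoint luminance from the bright (positive) cluster; empty droplets
#' draw from the dim (negative) cluster. Both are normal distributions
#' truncated at zero, and the configuration requires the positive mean to
#' exceed twice the negative mean so the twice-negative threshold rule
#' separates the clusters.
#'
#' @param copyCounts integer vector of per-droplet copy counts.
#' @param spec an [AssaySpec-class] (luminance cluster parameters are used).
#' @param seed integer seed.
#' @return numeric vector of luminances, same length as `copyCounts`.
#' @export
assignLuminance <- function(copyCounts, spec = assaySpec(), seed = 1L) {
  validObject(spec)
  if (spec@posLumMean <= 2 * spec@negLumMean)
    stop("positive luminance mean must exceed twice the negative mean")
  n <- length(copyCounts)
  .withSeed(seed, {
    pos <- copyCounts > 0
    l <- numeric(n)
    l[pos] <- rnorm(sum(pos), spec@posLumMean, spec@posLumSd)
    l[!pos] <- rnorm(sum(!pos), spec@negLumMean, spec@negLumSd)
    pmax(l, 0)
  })
}

## Raw RGB (0..1) of a droplet rendered at luminance L: a green-dominant
## colour with side channels at 15% of the green raw value. The factor
## below is the resulting luminance per unit linear green.
.lumCoef <- function(ct = colorTransform()) {
  s <- 0.15^ct@gamma
  ct@matrix[2, 2] + s * (ct@matrix[2, 1] + ct@matrix[2, 3])
}

.colorForLuminance <- function(L, ct = colorTransform()) {
  gLin <- pmin(L / .lumCoef(ct), 1)
  g <- gLin^(1 / ct@gamma)
  cbind(r = 0.15 * g, g = g, b = 0.15 * g)
}

#' Generate a synthetic assay
#'
#' Composes the generator chain: Poisson copy counts (per-droplet volumes),
#' truncated-normal diameters, endpoint luminances, and constant-velocity
#' trajectories along the tube axis with jittered spacing — everything
#' needed to render frames on demand and to evaluate the pipeline against
#' ground truth.
#'
#' @param spec an [AssaySpec-class].
#' @return a [SyntheticAssay-class]; frames come from [renderFrames()].
#' @export
generateAssay <- function(spec = assaySpec()) {
  validObject(spec)
  n <- spec@nDroplets
  v <- spec@flowVelocityPxPerFrame
  H <- spec@frameHeight; W <- spec@frameWidth
  if (n == 0L) {
    truth <- data.frame(droplet_id = integer(0), copy_count = integer(0),
                        label = character(0), diameter_um = numeric(0),
                        luminance = numeric(0), x0_px = numeric(0),
                        y_px = numeric(0), entry_frame = integer(0),
                        exit_frame = integer(0))
    return(new("SyntheticAssay", spec = spec, truth = truth, nFrames = 30L))
  }
  .withSeed(spec@seed, {
    diam <- pmax(rnorm(n, spec@dropletDiameterUm, spec@diameterSdUm),
                 spec@umPerPx)
    copies <- if (n > 0L)
      rpois(n, spec@concCopiesPerUl * dropletVolumeUl(diam))
    else integer(0)
    lum <- {
      pos <- copies > 0
      l <- numeric(n)
      l[pos] <- rnorm(sum(pos), spec@posLumMean, spec@posLumSd)
      l[!pos] <- rnorm(sum(!pos), spec@negLumMean, spec@negLumSd)
      pmax(l, 0)
    }
    rpx <- diam / spec@umPerPx / 2
    if (n > 0L && any(2 * rpx > spec@tubeIdUm / spec@umPerPx))
      stop("droplet diameter exceeds the tubing bore")
    gaps <- if (n > 1L) spec@spacingPx * runif(n - 1L, 0.9, 1.1) else numeric(0)
    x0 <- -(max(rpx, 0) + 2) - c(0, cumsum(gaps))
    yband <- pmax(0, pmin(spec@tubeIdUm / spec@umPerPx / 2 - rpx - 2,
                          H / 2 - rpx - 3)) * 0.5
    y <- H / 2 + runif(max(n, 1L), -1, 1) * yband
    if (n == 0L) y <- numeric(0)
    entry <- if (n > 0L) pmax(0L, ceiling((-rpx - x0) / v)) else integer(0)
    exitf <- if (n > 0L) ceiling((W + rpx - x0) / v) else integer(0)
    nFrames <- if (n > 0L) max(exitf) + 1L else 30L
    truth <- data.frame(
      droplet_id = seq_len(n), copy_count = copies,
      label = ifelse(copies > 0, "positive", "negative"),
      diameter_um = diam, luminance = lum,
      x0_px = x0, y_px = y,
      entry_frame = as.integer(entry), exit_frame = as.integer(exitf))
    if (n == 0L)
      truth <- truth[integer(0), , drop = FALSE]
    new("SyntheticAssay", spec = spec, truth = truth,
        nFrames = as.integer(nFrames))
  })
}

#' Render frames of a synthetic assay
#'
#' Draws each visible droplet as an anti-aliased green-dominant disc at its
#' trajectory position over the static background, adds Gaussian sensor
#' noise, and quantises to 8 bits. Rendering is deterministic per frame
#' (noise is seeded from the assay seed and the frame index), so any subset
#' of frames can be materialised lazily and repeatedly.
#'
#' @param assay a [SyntheticAssay-class] from [generateAssay()].
#' @param frames integer frame indices (0-based) to render; default all.
#' @return list of H x W x 3 arrays (0..255), named by frame index.
#' @export
renderFrames <- function(assay, frames = NULL) {
  stopifnot(is(assay, "SyntheticAssay"))
  spec <- assay@spec
  if (is.null(frames)) frames <- seq_len(assay@nFrames) - 1L
  if (any(frames < 0 | frames >= assay@nFrames))
    stop("frame index out of range")
  H <- spec@frameHeight; W <- spec@frameWidth
  tr <- assay@truth
  rpx <- tr$diameter_um / spec@umPerPx / 2
  cols255 <- 255 * .colorForLuminance(tr$luminance)
  baseSeed <- (spec@seed %% 1000003L) * 1009
  out <- lapply(frames, function(f) {
    fr <- array(spec@backgroundLevel, dim = c(H, W, 3))
    xs <- tr$x0_px + spec@flowVelocityPxPerFrame * f
    vis <- which(xs + rpx >= 0 & xs - rpx <= W - 1)
    for (i in vis) {
      r <- rpx[i]
      j0 <- max(0, floor(xs[i] - r - 1)); j1 <- min(W - 1, ceiling(xs[i] + r + 1))
      i0 <- max(0, floor(tr$y_px[i] - r - 1))
      i1 <- min(H - 1, ceiling(tr$y_px[i] + r + 1))
      if (j1 < j0 || i1 < i0) next
      dy <- (i0:i1) - tr$y_px[i]; dx <- (j0:j1) - xs[i]
      d <- sqrt(outer(dy^2, dx^2, "+"))
      cov <- pmin(pmax(r + 0.5 - d, 0), 1)
      for (ch in 1:3) {
        sub <- fr[(i0:i1) + 1L, (j0:j1) + 1L, ch]
        fr[(i0:i1) + 1L, (j0:j1) + 1L, ch] <-
          sub + cov * (cols255[i, ch] - sub)
      }
    }
    if (spec@noiseSd > 0)
      fr <- fr + .withSeed(baseSeed + f,
                           array(rnorm(length(fr), 0, spec@noiseSd), dim(fr)))
    array(round(pmin(pmax(fr, 0), 255)), dim = c(H, W, 3))
  })
  names(out) <- frames
  out
}
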