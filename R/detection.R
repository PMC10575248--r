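## Per-frame droplet detection. Frames are H x W x 3 numeric arrays on the
## 0..255 scale. All reported coordinates are 0-based with x = column,
## y = row, pixel-centre convention.

.checkFrame <- function(frame) {
  if (!is.numeric(frame) || length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("frame must be a numeric H x W x 3 array")
  invisible(dim(frame))
}

#' 2D Gaussian kernel
#'
#' Normalised (unit-sum) sampled Gaussian of odd width `k` and standard
#' deviation `sigma`, the denoising kernel of the preprocessing stage.
#'
#' @param k odd kernel width in pixels.
#' @param sigma standard deviation in pixels.
#' @return k x k numeric matrix summing to 1.
#' @export
gaussianKernel <- function(k = 5L, sigma = 1.5) {
  stopifnot(k >= 1, k %% 2 == 1, sigma > 0)
  r <- (k - 1L) / 2L
  d <- seq(-r, r)
  w <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  w / sum(w)
}

## 2D convolution with symmetric (reflect) padding, as repeated
## shift-multiply-adds; exact, no FFT wrap-around. Separable kernels
## (rank 1, e.g. Gaussians) are convolved row-wise then column-wise.
.convolve2 <- function(m, kernel) {
  k <- nrow(kernel)
  r <- (k - 1L) %/% 2L
  n <- nrow(m); p <- ncol(m)
  ri <- c(r:1, seq_len(n), n:(n - r + 1L))[seq_len(n + 2L * r)]
  ci <- c(r:1, seq_len(p), p:(p - r + 1L))[seq_len(p + 2L * r)]
  if (r == 0L) { ri <- seq_len(n); ci <- seq_len(p) }
  sv <- svd(kernel, nu = 1, nv = 1)
  if (k > 1 && sv$d[2] < 1e-12 * sv$d[1]) {
    kr <- sv$u[, 1] * sqrt(sv$d[1]); kc <- sv$v[, 1] * sqrt(sv$d[1])
    pad <- m[ri, , drop = FALSE]
    acc <- matrix(0, n, p)
    for (ki in seq_len(k)) if (kr[ki] != 0)
      acc <- acc + kr[ki] * pad[ki:(ki + n - 1L), , drop = FALSE]
    pad <- acc[, ci, drop = FALSE]
    acc <- matrix(0, n, p)
    for (kj in seq_len(k)) if (kc[kj] != 0)
      acc <- acc + kc[kj] * pad[, kj:(kj + p - 1L), drop = FALSE]
    return(acc)
  }
  pad <- m[ri, ci, drop = FALSE]
  acc <- matrix(0, n, p)
  for (ki in seq_len(k))
    for (kj in seq_len(k)) {
      w <- kernel[ki, kj]
      if (w != 0)
        acc <- acc + w * pad[ki:(ki + n - 1L), kj:(kj + p - 1L)]
    }
  acc
}

#' Gaussian denoising of a video frame
#'
#' Convolves each RGB channel with a normalised Gaussian kernel (default
#' 5x5, sigma 1.5, i.e. a 2-pixel radius around each target pixel), using
#' reflected edges so the frame geometry is preserved.
#'
#' @param frame numeric H x W x 3 array, 0..255.
#' @param params a [DetectionParams-class].
#' @return denoised frame, same shape.
#' @export
gaussianDenoise <- function(frame, params = detectionParams()) {
  .checkFrame(frame)
  kern <- gaussianKernel(params@gaussianKernelPx, params@gaussianSigma)
  out <- frame
  for (ch in 1:3) out[, , ch] <- .convolve2(frame[, , ch], kern)
  out
}

#' Median background frame
#'
#' Per-pixel, per-channel median across a frame sequence; with droplets
#' occupying any one pixel in under half the frames, the median is the
#' static background.
#'
#' @param frames non-empty list of H x W x 3 arrays of identical geometry.
#' @return one H x W x 3 array.
#' @export
medianBackground <- function(frames) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("need a non-empty list of frames")
  d <- dim(frames[[1]])
  .checkFrame(frames[[1]])
  for (f in frames)
    if (!identical(dim(f), d)) stop("frame geometry mismatch")
  if (length(frames) == 1L) return(frames[[1]])
  m <- vapply(frames, as.numeric, numeric(prod(d)))
  array(matrixStats::rowMedians(m), dim = d)
}

#' Background subtraction
#'
#' Subtracts the background model from a frame, clipping at zero (8-bit
#' floor), leaving droplets highlighted on a dark field.
#'
#' @param frame,background H x W x 3 arrays of identical geometry.
#' @return difference frame, clipped at 0.
#' @export
subtractBackground <- function(frame, background) {
  .checkFrame(frame)
  if (!identical(dim(frame), dim(background)))
    stop("frame geometry mismatch")
  pmax(frame - background, 0)
}

## Detection channel of a (background-subtracted) frame: green carries the
## fluorescence signal.
.fgChannel <- function(frame) {
  if (length(dim(frame)) == 3L) frame[, , 2] else frame
}

#' Hough transform circle detection
#'
#' Gradient-direction circle Hough transform: edge pixels (gradient
#' magnitude above `gradThreshold`) vote for candidate centres along their
#' inward gradient ray at every radius in the search range, stepping by the
#' distance resolution; gradient directions are quantised to the angular
#' resolution. Accumulator peaks above `minVotes` are kept after non-maximum
#' suppression at `minCenterDistPx`, and each peak's radius is the modal
#' edge-pixel distance. Centres are refined to sub-pixel by the local
#' accumulator centroid.
#'
#' @param foreground background-subtracted frame (H x W x 3 array, of which
#'   the green channel is used, or an H x W matrix).
#' @param params a [DetectionParams-class].
#' @return data.frame with columns `center_x`, `center_y` (0-based, pixel
#'   centre), `radius_px`, `votes`; zero rows on a blank frame.
#' @export
houghCircles <- function(foreground, params = detectionParams()) {
  fg <- .fgChannel(foreground)
  H <- nrow(fg); W <- ncol(fg)
  empty <- data.frame(center_x = numeric(0), center_y = numeric(0),
                      radius_px = numeric(0), votes = numeric(0))
  ## central-difference gradients (zero at the 1-px border)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  if (W >= 3) gx[, 2:(W - 1)] <- (fg[, 3:W] - fg[, 1:(W - 2)]) / 2
  if (H >= 3) gy[2:(H - 1), ] <- (fg[3:H, ] - fg[1:(H - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  sel <- which(mag > params@gradThreshold)
  if (length(sel) == 0L) return(empty)
  py <- (sel - 1L) %% H        # 0-based row (y)
  px <- (sel - 1L) %/% H       # 0-based col (x)
  ares <- params@houghAngularResDeg * pi / 180
  theta <- round(atan2(gy[sel], gx[sel]) / ares) * ares
  ux <- cos(theta); uy <- sin(theta)
  radii <- seq(params@radiusRangePx[1], params@radiusRangePx[2],
               by = params@houghDistResPx)
  nr <- length(radii); ne <- length(sel)
  ## inward votes (intensity rises toward the droplet centre)
  cx <- round(rep(px, nr) + rep(radii, each = ne) * rep(ux, nr))
  cy <- round(rep(py, nr) + rep(radii, each = ne) * rep(uy, nr))
  ok <- cx >= 0 & cx < W & cy >= 0 & cy < H
  if (!any(ok)) return(empty)
  acc <- matrix(tabulate(cx[ok] * H + cy[ok] + 1L, nbins = H * W), H, W)
  ## 3x3 consolidation
  accS <- .convolve2(acc, matrix(1, 3, 3))
  ## local maxima (strictly >= 8-neighbourhood) above the vote threshold
  nbrMax <- matrix(-Inf, H, W)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    src <- accS[max(1, 1 - di):min(H, H - di), max(1, 1 - dj):min(W, W - dj),
                drop = FALSE]
    ti <- max(1, 1 + di):min(H, H + di); tj <- max(1, 1 + dj):min(W, W + dj)
    nbrMax[ti, tj] <- pmax(nbrMax[ti, tj], src)
  }
  cand <- which(accS >= params@minVotes & accS >= nbrMax)
  if (length(cand) == 0L) return(empty)
  cand <- cand[order(accS[cand], decreasing = TRUE)]
  cyc <- (cand - 1L) %% H
  cxc <- (cand - 1L) %/% H
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (i == 1L) { keep[1] <- TRUE; next }
    d2 <- (cxc[i] - cxc[keep])^2 + (cyc[i] - cyc[keep])^2
    keep[i] <- all(d2 >= params@minCenterDistPx^2)
  }
  cxc <- cxc[keep]; cyc <- cyc[keep]; votes <- accS[cand[keep]]
  ## sub-pixel refinement + radius from the modal edge distance
  out <- lapply(seq_along(cxc), function(i) {
    x0 <- cxc[i]; y0 <- cyc[i]
    ii <- max(0, y0 - 2):min(H - 1, y0 + 2)
    jj <- max(0, x0 - 2):min(W - 1, x0 + 2)
    w <- accS[ii + 1, jj + 1, drop = FALSE]
    xs <- sum(rep(jj, each = length(ii)) * w) / sum(w)
    ys <- sum(rep(ii, times = length(jj)) * w) / sum(w)
    d <- sqrt((px - xs)^2 + (py - ys)^2)
    inR <- d >= radii[1] - 1 & d <= radii[nr] + 1
    if (!any(inR)) return(NULL)
    hb <- table(round(d[inR] / params@houghDistResPx))
    r <- as.numeric(names(hb)[which.max(hb)]) * params@houghDistResPx
    data.frame(center_x = xs, center_y = ys, radius_px = r,
               votes = votes[i])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Disc structuring element
#'
#' @param radius disc radius in pixels.
#' @return binary (2r+1) x (2r+1) matrix (EBImage disc brush).
#' @export
discSE <- function(radius = 2L) EBImage::makeBrush(2L * radius + 1L, "disc")

#' Morphological refinement of a droplet mask
#'
#' Opening (erosion then dilation) with a disc structuring element of the
#' configured radius, removing specks and smoothing the droplet contour.
#' Opening is idempotent; the result may be empty.
#'
#' @param mask logical or 0/1 matrix.
#' @param params a [DetectionParams-class] (`seRadiusPx` is used).
#' @return logical matrix, same geometry.
#' @export
morphRefine <- function(mask, params = detectionParams()) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  EBImage::opening(m, discSE(params@seRadiusPx)) > 0.5
}

#' Largest-chord droplet diameter
#'
#' The droplet diameter is the largest chord of the mask geometry: the
#' maximum pairwise pixel extent (centre distance plus one pixel) in any
#' direction, converted to micrometres by the pixel scale.
#'
#' @param mask non-empty logical matrix.
#' @param params a [DetectionParams-class] (`umPerPx` is used).
#' @return diameter in micrometres.
#' @export
measureDiameter <- function(mask, params = detectionParams()) {
  if (!any(mask)) stop("empty droplet mask")
  ## the maximum pairwise distance is attained on the boundary
  b <- .maskBoundary(mask)
  y <- b$y; x <- b$x
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  (sqrt(max(dx^2 + dy^2)) + 1) * params@umPerPx
}

.maskBoundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  interior <- matrix(FALSE, H, W)
  if (H > 2 && W > 2)
    interior[2:(H - 1), 2:(W - 1)] <-
      mask[2:(H - 1), 2:(W - 1)] &
      mask[1:(H - 2), 2:(W - 1)] & mask[3:H, 2:(W - 1)] &
      mask[2:(H - 1), 1:(W - 2)] & mask[2:(H - 1), 3:W]
  idx <- which(mask & !interior)
  list(y = (idx - 1L) %% H, x = (idx - 1L) %/% H)
}

## Grow a droplet mask from a detected circle: foreground pixels above half
## the droplet's own interior amplitude, within maskFactor x radius of the
## centre, connected to the centre, then opened. Returns NULL for
## degenerate seeds. Offsets are 0-based frame coordinates of the window.
.circleToMask <- function(fg, cx, cy, r, params) {
  H <- nrow(fg); W <- ncol(fg)
  R <- ceiling(params@maskFactor * r) + 2
  i0 <- max(0, round(cy) - R); i1 <- min(H - 1, round(cy) + R)
  j0 <- max(0, round(cx) - R); j1 <- min(W - 1, round(cx) + R)
  win <- fg[(i0:i1) + 1L, (j0:j1) + 1L, drop = FALSE]
  yy <- outer((i0:i1) - cy, rep(1, j1 - j0 + 1))
  xx <- outer(rep(1, i1 - i0 + 1), (j0:j1) - cx)
  d <- sqrt(xx^2 + yy^2)
  core <- win[d <= 0.6 * r]
  if (length(core) < 3L) return(NULL)
  amp <- median(core)
  if (amp < 2 * params@gradThreshold) return(NULL)  # not a real droplet
  mask <- win >= params@fgFraction * amp & d <= params@maskFactor * r
  if (!any(mask)) return(NULL)
  ## keep the component containing (or nearest) the centre
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  ci <- round(cy) - i0 + 1L; cj <- round(cx) - j0 + 1L
  if (ci < 1L || cj < 1L || ci > nrow(lab) || cj > ncol(lab)) return(NULL)
  lc <- lab[ci, cj]
  if (lc == 0) return(NULL)  # ghost peak: no foreground at the centre
  mask <- lab == lc
  mask <- morphRefine(mask, params)
  if (!any(mask)) return(NULL)
  ## clipped droplet? the seeded circle (with a 2-px guard) must lie fully
  ## inside the frame, and the mask must stay off the border rows/cols
  idx <- which(mask)
  my <- (idx - 1L) %% nrow(mask) + i0   # 0-based frame rows
  mx <- (idx - 1L) %/% nrow(mask) + j0  # 0-based frame cols
  atBorder <- any(my == 0L) || any(my == nrow(fg) - 1L) ||
    any(mx == 0L) || any(mx == ncol(fg) - 1L) ||
    cy - r < 2 || cy + r > nrow(fg) - 3 ||
    cx - r < 2 || cx + r > ncol(fg) - 3
  list(mask = mask, y0 = i0, x0 = j0, atBorder = atBorder)
}

#' Detect and measure droplets in one frame
#'
#' Full per-frame stage: circle Hough detection on the background-subtracted
#' frame, mask refinement by opening, largest-chord sizing, and CIE-xyY
#' luminance/chromaticity measured on the denoised frame over the eroded
#' mask interior (so anti-aliased rim pixels do not dilute the mean).
#'
#' @param foreground background-subtracted frame (H x W x 3).
#' @param denoised denoised original frame for colour measurement.
#' @param params a [DetectionParams-class].
#' @param colorConfig a [ColorTransform-class].
#' @return data.frame with one row per droplet: `center_x`, `center_y`,
#'   `radius_px`, `votes`, `diameter_um`, `luminance`, `chrom_x`,
#'   `chrom_y`, `at_border` (mask clipped by the frame edge: position from
#'   the Hough centre, size and colour not trusted for aggregation).
#' @export
detectDroplets <- function(foreground, denoised,
                           params = detectionParams(),
                           colorConfig = colorTransform()) {
  circles <- houghCircles(foreground, params)
  .emptyDet <- function() {
    d <- stats::setNames(
      as.data.frame(replicate(8, numeric(0), simplify = FALSE)),
      c("center_x", "center_y", "radius_px", "votes", "diameter_um",
        "luminance", "chrom_x", "chrom_y"))
    d$at_border <- logical(0)
    d
  }
  if (nrow(circles) == 0L) return(.emptyDet())
  fg <- .fgChannel(foreground)
  rows <- lapply(seq_len(nrow(circles)), function(i) {
    mk <- .circleToMask(fg, circles$center_x[i], circles$center_y[i],
                        circles$radius_px[i], params)
    if (is.null(mk)) return(NULL)
    diam <- measureDiameter(mk$mask, params)
    interior <- EBImage::erode(
      matrix(as.numeric(mk$mask), nrow(mk$mask), ncol(mk$mask)),
      discSE(params@seRadiusPx)) > 0.5
    if (!any(interior)) interior <- mk$mask
    idx <- which(interior)
    yy <- (idx - 1L) %% nrow(interior) + mk$y0 + 1L
    xx <- (idx - 1L) %/% nrow(interior) + mk$x0 + 1L
    px <- cbind(denoised[cbind(yy, xx, 1L)], denoised[cbind(yy, xx, 2L)],
                denoised[cbind(yy, xx, 3L)]) / 255
    px <- pmin(pmax(px, 0), 1)
    lum <- dropletLuminance(px, colorConfig, chromaticity = TRUE)
    midx <- which(mk$mask)
    ## clipped droplets keep the Hough centre (arc votes stay unbiased);
    ## complete droplets use the refined mask centroid
    cx <- if (mk$atBorder) circles$center_x[i]
          else mean((midx - 1L) %/% nrow(mk$mask)) + mk$x0
    cy <- if (mk$atBorder) circles$center_y[i]
          else mean((midx - 1L) %% nrow(mk$mask)) + mk$y0
    data.frame(center_x = cx, center_y = cy,
               radius_px = diam / params@umPerPx / 2,
               votes = circles$votes[i], diameter_um = diam,
               luminance = lum$L, chrom_x = lum$x, chrom_y = lum$y,
               at_border = mk$atBorder)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(.emptyDet())
  ## one detection per droplet: suppress centres closer than the minimum
  ## peak separation, keeping the strongest
  o <- order(out$votes, decreasing = TRUE)
  keep <- logical(nrow(out))
  for (i in o) {
    d2 <- (out$center_x[i] - out$center_x[keep])^2 +
      (out$center_y[i] - out$center_y[keep])^2
    keep[i] <- !any(d2 < params@minCenterDistPx^2)
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
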