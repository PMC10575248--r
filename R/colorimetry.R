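## RGB -> CIE-xyY colorimetry. Raw 8-bit channels are normalised by 255,
## linearised by a pure power law (single-exponent camera response), taken
## to XYZ by a linear matrix, and summarised as luminance L = Y plus
## chromaticity (x, y) = (X, Y) / (X + Y + Z).

.asPixelMatrix <- function(pixel) {
  if (is.null(dim(pixel))) {
    if (length(pixel) %% 3L != 0L)
      stop("pixel input must have 3 channels")
    pixel <- matrix(pixel, ncol = 3, byrow = length(pixel) == 3)
  }
  if (ncol(pixel) != 3L) stop("pixel matrix must have 3 columns (R,G,B)")
  pixel
}

#' Linearise gamma-encoded RGB channels
#'
#' Applies the power-law gamma correction `channel^gamma` to normalised
#' channel intensities, inverting the camera's gamma-encoded response
#' before any linear colour arithmetic.
#'
#' @param pixel numeric vector of length 3 or an n x 3 matrix of (R,G,B)
#'   values in [0,1] (raw 8-bit values divided by 255).
#' @param gamma positive exponent (default 2.2).
#' @return same shape as `pixel`, each channel raised to `gamma`.
#' @examples
#' linearizeRGB(c(128, 128, 128) / 255)  # ~0.2195 per channel
#' @export
linearizeRGB <- function(pixel, gamma = 2.2) {
  if (length(gamma) != 1 || !is.finite(gamma) || gamma <= 0)
    stop("gamma must be a single positive number")
  p <- .asPixelMatrix(pixel)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("channel values must lie in [0,1]")
  out <- p^gamma
  if (is.null(dim(pixel))) as.numeric(out) else out
}

#' Linear RGB to CIE XYZ tristimulus values
#'
#' Applies the linear ("direct linear model") transform
#' `(X,Y,Z) = M (R,G,B)` to already-linearised channels.
#'
#' @param linearPixel length-3 vector or n x 3 matrix of linear RGB.
#' @param config a [ColorTransform-class]; only the matrix is used here.
#' @return tristimulus values, same shape as the input.
#' @export
rgbToXYZ <- function(linearPixel, config = colorTransform()) {
  stopifnot(is(config, "ColorTransform"))
  validObject(config)
  p <- .asPixelMatrix(linearPixel)
  out <- p %*% t(config@matrix)
  colnames(out) <- c("X", "Y", "Z")
  if (is.null(dim(linearPixel))) setNames(as.numeric(out), c("X", "Y", "Z"))
  else out
}

#' XYZ to xyY chromaticity and luminance
#'
#' `x = X/(X+Y+Z)`, `y = Y/(X+Y+Z)`, `L = Y`. Chromaticity of an all-zero
#' (black) tristimulus is undefined and reported as `NA` rather than 0/0;
#' luminance is always defined.
#'
#' @param xyz length-3 vector or n x 3 matrix of (X, Y, Z), all >= 0.
#' @return data.frame with columns `x`, `y`, `L`.
#' @export
xyzToXyY <- function(xyz) {
  p <- .asPixelMatrix(xyz)
  if (any(p < 0)) stop("tristimulus values must be >= 0")
  s <- rowSums(p)
  x <- ifelse(s > 0, p[, 1] / s, NA_real_)
  y <- ifelse(s > 0, p[, 2] / s, NA_real_)
  data.frame(x = x, y = y, L = p[, 2])
}

#' Mean CIE luminance of a droplet's pixels
#'
#' Runs each raw pixel through linearise -> XYZ -> xyY and averages the
#' per-pixel luminances; the companion chromaticity mean skips pixels whose
#' chromaticity is undefined (black pixels).
#'
#' @param pixels n x 3 matrix (or length-3 vector) of raw RGB in [0,1],
#'   typically the interior pixels of one droplet mask.
#' @param config a [ColorTransform-class].
#' @param chromaticity if `TRUE` return a list with `L`, `x`, `y`;
#'   otherwise the scalar mean luminance.
#' @return mean luminance, or a list when `chromaticity = TRUE`.
#' @export
dropletLuminance <- function(pixels, config = colorTransform(),
                             chromaticity = FALSE) {
  p <- .asPixelMatrix(pixels)
  if (nrow(p) == 0L) stop("droplet pixel set is empty")
  xyY <- xyzToXyY(rgbToXYZ(linearizeRGB(p, config@gamma), config))
  if (!chromaticity) return(mean(xyY$L))
  ok <- !is.na(xyY$x)
  list(L = mean(xyY$L),
       x = if (any(ok)) mean(xyY$x[ok]) else NA_real_,
       y = if (any(ok)) mean(xyY$y[ok]) else NA_real_)
}
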