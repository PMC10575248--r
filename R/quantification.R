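## Digital quantification: threshold luminances into positive/negative
## classes and convert the positive fraction to an absolute concentration
## by Poisson statistics, C_o = -ln(1 - N_P/N_T) / V_d.

#' Sphere volume of a droplet in microlitres
#'
#' `V_d = (pi/6) d^3 * 1e-9` uL for a diameter `d` in micrometres; a 100-um
#' droplet holds about 5.24e-4 uL.
#'
#' @param diameterUm droplet diameter(s), um.
#' @return volume(s) in uL.
#' @export
dropletVolumeUl <- function(diameterUm) {
  stopifnot(all(diameterUm >= 0))
  pi / 6 * diameterUm^3 * 1e-9
}

#' Twice-negative classification threshold
#'
#' The luminance cutoff is twice the negative-control signal: 2 x the mean
#' (or, optionally, median) of the luminances of a no-template-control
#' droplet population.
#'
#' @param negativeLuminances non-empty numeric vector of negative-control
#'   droplet luminances, all >= 0.
#' @param statistic `"mean"` (default) or `"median"` summary of the
#'   negative signals.
#' @return luminance threshold.
#' @examples
#' negativeThreshold(c(0.05, 0.15))  # 0.2
#' @export
negativeThreshold <- function(negativeLuminances, statistic = c("mean",
                                                                "median")) {
  statistic <- match.arg(statistic)
  if (length(negativeLuminances) == 0L)
    stop("negative-control luminance set is empty")
  if (any(!is.finite(negativeLuminances)) || any(negativeLuminances < 0))
    stop("negative luminances must be finite and >= 0")
  2 * switch(statistic, mean = mean(negativeLuminances),
             median = median(negativeLuminances))
}

#' Classify droplets against a luminance threshold
#'
#' A droplet is positive iff its luminance strictly exceeds the threshold
#' (ties are negative); counts and the positive fraction f_p = N_P/N_T are
#' returned alongside the labelled droplets.
#'
#' @param records a [DropletSet-class].
#' @param threshold positive luminance cutoff.
#' @return a [ClassificationResult-class].
#' @export
classifyDroplets <- function(records, threshold) {
  stopifnot(is(records, "DropletSet"))
  if (length(threshold) != 1 || !is.finite(threshold) || threshold <= 0)
    stop("threshold must be a single positive number")
  d <- records@droplets
  d$label <- ifelse(d$luminance > threshold, "positive", "negative")
  records@droplets <- d
  nT <- nrow(d); nP <- sum(d$label == "positive")
  new("ClassificationResult", threshold = threshold, droplets = records,
      nTotal = as.integer(nT), nPositive = as.integer(nP),
      fractionPositive = if (nT > 0) nP / nT else NaN)
}

#' Poisson probability mass function
#'
#' P(k) = lambda^k e^(-lambda) / k!, the probability that a droplet holds
#' exactly k target copies when the mean occupancy is lambda. Evaluated in
#' log space for numerical stability.
#'
#' @param k non-negative integer copy count(s).
#' @param lam mean copies per droplet, lambda >= 0.
#' @return probability(ies).
#' @export
poissonPmf <- function(k, lam) {
  if (any(k < 0) || any(k != floor(k))) stop("k must be a non-negative integer")
  if (any(lam < 0)) stop("lambda must be >= 0")
  n <- max(length(k), length(lam))
  k <- rep_len(k, n); lam <- rep_len(lam, n)
  out <- numeric(n)
  z <- lam == 0
  out[z] <- as.numeric(k[z] == 0)
  out[!z] <- exp(k[!z] * log(lam[!z]) - lam[!z] - lgamma(k[!z] + 1))
  out
}

#' Expected positive fraction at a given concentration
#'
#' f_p = 1 - e^(-lambda) with lambda = C_o V_d: the Poisson probability
#' that a droplet contains at least one target copy.
#'
#' @param concCopiesPerUl target concentration C_o, copies/uL.
#' @param volDropletUl droplet volume V_d, uL.
#' @return expected positive fraction in [0, 1).
#' @examples
#' expectedFraction(10, dropletVolumeUl(100))  # ~0.0052
#' @export
expectedFraction <- function(concCopiesPerUl, volDropletUl) {
  if (any(concCopiesPerUl < 0) || any(volDropletUl < 0))
    stop("concentration and droplet volume must be >= 0")
  1 - exp(-concCopiesPerUl * volDropletUl)
}

#' Absolute concentration from positive-droplet counts
#'
#' Inverts the Poisson relation: C_o = -ln(1 - N_P/N_T) / V_d. Saturation
#' (N_P = N_T) is an error — the concentration is not quantifiable when
#' every droplet is positive.
#'
#' @param nPositive,nTotal positive and total droplet counts, N_P < N_T.
#' @param volDropletUl droplet volume V_d in uL.
#' @param level confidence level of the Clopper-Pearson interval.
#' @return a [ConcentrationEstimate-class].
#' @examples
#' estimateConcentration(52, 10000, dropletVolumeUl(100))  # ~9.96 copies/uL
#' @export
estimateConcentration <- function(nPositive, nTotal, volDropletUl,
                                  level = 0.95) {
  if (nTotal <= 0) stop("nTotal must be positive")
  if (nPositive < 0 || nPositive > nTotal)
    stop("need 0 <= nPositive <= nTotal")
  if (nPositive == nTotal)
    stop("saturated assay (all droplets positive): concentration is not ",
         "quantifiable by Poisson statistics")
  if (volDropletUl <= 0) stop("droplet volume must be positive")
  fp <- nPositive / nTotal
  co <- -log(1 - fp) / volDropletUl
  ci <- concentrationInterval(nPositive, nTotal, volDropletUl, level)
  new("ConcentrationEstimate", concCopiesPerUl = co, ciLow = ci[[1]],
      ciHigh = ci[[2]], level = level, nTotal = as.integer(nTotal),
      nPositive = as.integer(nPositive), fractionPositive = fp,
      volDropletUl = volDropletUl)
}

#' Confidence interval for the concentration estimate
#'
#' Exact binomial (Clopper-Pearson) interval on f_p, with each bound
#' transformed through C = -ln(1 - f) / V_d; when the upper f bound reaches
#' 1 the upper concentration bound is infinite.
#'
#' @inheritParams estimateConcentration
#' @return named numeric vector `c(low, high)` in copies/uL.
#' @export
concentrationInterval <- function(nPositive, nTotal, volDropletUl,
                                  level = 0.95) {
  if (nTotal <= 0) stop("nTotal must be positive")
  if (nPositive < 0 || nPositive > nTotal)
    stop("need 0 <= nPositive <= nTotal")
  if (volDropletUl <= 0) stop("droplet volume must be positive")
  a <- (1 - level) / 2
  fLow <- if (nPositive == 0) 0 else qbeta(a, nPositive, nTotal - nPositive + 1)
  fHigh <- if (nPositive == nTotal) 1 else
    qbeta(1 - a, nPositive + 1, nTotal - nPositive)
  c(low = -log(1 - fLow) / volDropletUl,
    high = if (fHigh >= 1) Inf else -log(1 - fHigh) / volDropletUl)
}
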