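vd100 <- dropletVolumeUl(100)

test_that("copy counts are Poisson with mean C_o V_d", {
  expect_true(all(drawCopyCounts(0, vd100, 500, seed = 1) == 0))
  k <- drawCopyCounts(1e4, vd100, 1e5, seed = 2)
  lam <- 1e4 * vd100
  expect_lt(abs(mean(k) - lam), 3 * sqrt(lam / 1e5))     # LLN
  expect_lt(abs(var(k) / mean(k) - 1), 0.03)             # dispersion ~ 1
  expect_identical(k, drawCopyCounts(1e4, vd100, 1e5, seed = 2))
  expect_false(identical(k, drawCopyCounts(1e4, vd100, 1e5, seed = 3)))
  expect_error(drawCopyCounts(-1, vd100, 10), ">= 0")
})

test_that("droplet size falls monotonically with continuous-phase flow", {
  expect_equal(diameterFromFlow(0.05), 200)
  expect_equal(diameterFromFlow(3), 100)
  expect_equal(diameterFromFlow(0.01), 200)   # clamped at the channel bound
  expect_equal(diameterFromFlow(10), 100)
  q <- sort(runif(20, 0.05, 3))
  d <- diameterFromFlow(q)
  expect_true(all(diff(d) <= 1e-9))
  expect_true(all(d >= 100 & d <= 200))
  expect_error(diameterFromFlow(0), "> 0")
})

test_that("luminance assignment separates the two clusters", {
  sp <- assaySpec()
  copies <- c(0, 0, 1, 3, 0, 2)
  l <- assignLuminance(copies, sp, seed = 5)
  expect_true(all(l[copies > 0] > 0.3))
  expect_true(all(l[copies == 0] < 0.1))
  # a mixed population is bimodal with a clear gap as in endpoint imaging
  set.seed(6)
  mixed <- assignLuminance(rbinom(500, 1, 0.4), sp, seed = 7)
  expect_equal(sum(mixed > 0.25 & mixed < 0.35), 0)  # the gap
  # degenerate sd gives exactly two values
  sp0 <- assaySpec(posLumSd = 0, negLumSd = 0)
  l0 <- assignLuminance(copies, sp0, seed = 8)
  expect_equal(sort(unique(l0)), c(sp0@negLumMean, sp0@posLumMean))
  # misordered clusters are a configuration error
  expect_error(assaySpec(posLumMean = 0.08, negLumMean = 0.05),
               "twice the negative")
})

test_that("ground truth is consistent and converges to the Poisson model", {
  a <- generateAssay(desk_spec(100, 40L, seed = 51))
  tr <- assayTruth(a)
  expect_equal(tr$label == "positive", tr$copy_count > 0)
  expect_true(all(tr$entry_frame <= tr$exit_frame))
  expect_true(all(tr$exit_frame < a@nFrames))
  # large-n positive fraction vs 1 - exp(-C_o V_d) (binomial 3 SE);
  # truth generation is cheap without rendering
  big <- generateAssay(assaySpec(concCopiesPerUl = 1000, nDroplets = 20000L,
                                 frameHeight = 256L, frameWidth = 256L,
                                 flowVelocityPxPerFrame = 60, seed = 52L))
  fp <- expectedFraction(1000, vd100)
  obs <- mean(assayTruth(big)$label == "positive")
  expect_lt(abs(obs - fp), 3 * sqrt(fp * (1 - fp) / 20000))
})

test_that("rendering is deterministic and respects geometry limits", {
  sp <- desk_spec(500, 5L, seed = 53)
  a1 <- generateAssay(sp); a2 <- generateAssay(sp)
  expect_identical(assayTruth(a1), assayTruth(a2))
  f1 <- renderFrames(a1, 0:3); f2 <- renderFrames(a2, 0:3)
  expect_identical(f1, f2)
  expect_true(all(vapply(f1, function(f) all(f >= 0 & f <= 255), TRUE)))
  # different seeds decorrelate
  a3 <- generateAssay(desk_spec(500, 5L, seed = 54))
  expect_false(identical(assayTruth(a1)$luminance, assayTruth(a3)$luminance))
  # droplets larger than the tubing bore are rejected
  expect_error(assaySpec(dropletDiameterUm = 320), "bore")
})

test_that("an empty assay yields an empty census", {
  sp <- assaySpec(concCopiesPerUl = 0, nDroplets = 0L, frameHeight = 48L,
                  frameWidth = 200L, umPerPx = 5,
                  flowVelocityPxPerFrame = 40, seed = 55L)
  a <- generateAssay(sp)
  expect_equal(nrow(assayTruth(a)), 0L)
  pv <- processVideo(a, desk_config())
  expect_equal(pv$counts$records, 0L)
  expect_equal(pv$counts$detections, 0L)
})

test_that("rendered droplets are found where the truth says they are", {
  sp <- desk_spec(2000, 5L, seed = 56, noiseSd = 0)
  a <- generateAssay(sp)
  pv <- processVideo(a, desk_config())
  expect_equal(pv$counts$records, 5L)
  # a fully-visible droplet's detected centre is within 2 px of truth
  tr <- assayTruth(a)
  params <- detectionParams(expectedDiameterUm = 100, umPerPx = 5)
  # frame where droplet 1 sits closest to mid-frame
  f <- which.min(abs(tr$x0_px[1] + sp@flowVelocityPxPerFrame *
                       (0:(a@nFrames - 1)) - sp@frameWidth / 2)) - 1L
  fr <- renderFrames(a, f)[[1]]
  den <- gaussianDenoise(fr, params)
  d <- detectDroplets(den - sp@backgroundLevel, den, params)
  x <- tr$x0_px[1] + sp@flowVelocityPxPerFrame * f
  i <- which.min(abs(d$center_x - x))
  expect_lt(abs(d$center_x[i] - x), 2)
  expect_lt(abs(d$center_y[i] - tr$y_px[1]), 2)
})
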