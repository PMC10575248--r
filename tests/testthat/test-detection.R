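test_that("Gaussian denoising matches the brute-force convolution", {
  params <- detectionParams()
  # constant frame is a fixed point of a unit-sum kernel
  fr <- array(37, dim = c(16, 20, 3))
  expect_equal(gaussianDenoise(fr, params), fr)
  # impulse response stamps the kernel
  fr <- array(0, dim = c(15, 15, 3))
  fr[8, 8, ] <- 1
  kern <- gaussianKernel(5, 1.5)
  out <- gaussianDenoise(fr, params)
  expect_equal(out[6:10, 6:10, 2], kern, tolerance = 1e-12)
  expect_equal(sum(out[, , 1]), 1, tolerance = 1e-12)
  # randomised frames against the double-loop reference, incl. edges
  set.seed(10)
  for (i in 1:4) {
    m <- matrix(runif(18 * 13, 0, 255), 18, 13)
    fr <- array(rep(m, 3), dim = c(18, 13, 3))
    expect_equal(gaussianDenoise(fr, params)[, , 1], brute_convolve(m, kern),
                 tolerance = 1e-9)
  }
  expect_error(gaussianDenoise(matrix(0, 4, 4)), "H x W x 3")
})

test_that("median background is the per-pixel median and rejects misuse", {
  fr <- array(runif(60, 0, 255), dim = c(5, 4, 3))
  expect_equal(medianBackground(list(fr, fr, fr)), fr)
  f1 <- f2 <- f3 <- array(0, dim = c(3, 3, 3))
  f1[2, 2, 1] <- 10; f2[2, 2, 1] <- 20; f3[2, 2, 1] <- 250
  expect_equal(medianBackground(list(f1, f2, f3))[2, 2, 1], 20)
  expect_error(medianBackground(list()), "non-empty")
  expect_error(medianBackground(list(f1, array(0, dim = c(4, 3, 3)))),
               "mismatch")
})

test_that("background subtraction clips at the 8-bit floor", {
  fr <- array(runif(48, 0, 255), dim = c(4, 4, 3))
  expect_equal(subtractBackground(fr, fr), array(0, dim = dim(fr)))
  zero <- array(0, dim = dim(fr))
  expect_equal(subtractBackground(fr, zero), fr)
  expect_true(all(subtractBackground(zero, fr) == 0))
  expect_error(subtractBackground(fr, array(0, dim = c(5, 4, 3))),
               "mismatch")
})

test_that("Hough transform finds rendered discs and ignores blank frames", {
  params <- detectionParams(expectedDiameterUm = 80, umPerPx = 1)
  blank <- array(0, dim = c(120, 260, 3))
  expect_equal(nrow(houghCircles(blank, params)), 0L)
  one <- disc_frame(120, 260, cbind(130, 60), 40, bg = 0)
  h1 <- houghCircles(one, params)
  expect_equal(nrow(h1), 1L)
  expect_lt(abs(h1$center_x - 130), 2)
  expect_lt(abs(h1$center_y - 60), 2)
  expect_lt(abs(h1$radius_px - 40), 2)
  two <- disc_frame(120, 260, rbind(c(50, 60), c(210, 60)), 40, bg = 0)
  h2 <- houghCircles(two, params)
  expect_equal(nrow(h2), 2L)
  expect_equal(sort(round(h2$center_x)), c(50, 210), tolerance = 1)
})

test_that("morphological opening matches the set-based oracle", {
  params <- detectionParams()
  se <- discSE(2)
  # large disc survives with at most 1 px boundary deviation
  dy <- outer((0:59) - 30, rep(1, 60)); dx <- t(dy)
  disc <- sqrt(dx^2 + dy^2) <= 25
  opened <- morphRefine(disc, params)
  expect_equal(opened, brute_open(disc, se))
  dist <- sqrt(dx^2 + dy^2)
  expect_true(all(dist[disc & !opened] > 24))  # only rim pixels may go
  # a single-pixel speck vanishes
  speck <- matrix(FALSE, 11, 11); speck[6, 6] <- TRUE
  expect_false(any(morphRefine(speck, params)))
  # idempotence and oracle agreement on random masks
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(runif(20 * 24) < 0.45, 20, 24)
    o1 <- morphRefine(m, params)
    expect_equal(o1, brute_open(m, se))
    expect_equal(morphRefine(o1, params), o1)
  }
})

test_that("largest-chord sizing follows the pairwise-extent oracle", {
  params <- detectionParams(umPerPx = 0.5)
  # a disc mask spanning exactly 200 px measures 100 um
  dy <- outer((0:209) - 104, rep(1, 210))
  dx <- t(outer((0:209) - 104.5, rep(1, 210)))
  disc <- sqrt(dx^2 + dy^2) <= 99.5
  expect_equal(max(which(colSums(disc) > 0)) - min(which(colSums(disc) > 0)) + 1,
               200)  # construction check
  expect_equal(measureDiameter(disc, params), 100)
  # single pixel has unit extent
  px1 <- matrix(FALSE, 5, 5); px1[3, 3] <- TRUE
  expect_equal(measureDiameter(px1, params), 0.5)
  # 3:2 axis-aligned ellipse: major axis extent
  dy <- outer((0:49) - 24.5, rep(1, 70)); dx <- t(outer((0:69) - 34.5, rep(1, 50)))
  ell <- (dx / 30)^2 + (dy / 20)^2 <= 1
  expect_equal(measureDiameter(ell, params), brute_chord_um(ell, 0.5))
  # random blobs against the exhaustive oracle
  set.seed(12)
  for (i in 1:5) {
    m <- matrix(runif(15 * 18) < 0.3, 15, 18)
    if (!any(m)) next
    expect_equal(measureDiameter(m, detectionParams(umPerPx = 1)),
                 brute_chord_um(m, 1))
  }
  expect_error(measureDiameter(matrix(FALSE, 3, 3), params), "empty")
})

test_that("clean frames are detected with perfect precision and recall", {
  # noise-free rendered scene: every fully-visible droplet found once
  sp <- desk_spec(1000, 12L, seed = 21, noiseSd = 0)
  a <- generateAssay(sp)
  params <- detectionParams(expectedDiameterUm = 100, umPerPx = 5)
  ct <- colorTransform()
  fr <- renderFrames(a)
  den <- lapply(fr, gaussianDenoise, params = params)
  bg <- medianBackground(den)
  tr <- assayTruth(a)
  rpx <- tr$diameter_um / 5 / 2
  nTrue <- 0; nHit <- 0; nFalse <- 0
  for (f in seq_len(a@nFrames)) {
    d <- detectDroplets(subtractBackground(den[[f]], bg), den[[f]], params, ct)
    d <- d[!d$at_border, , drop = FALSE]
    xs <- tr$x0_px + sp@flowVelocityPxPerFrame * (f - 1)
    full <- which(xs - rpx >= 4 & xs + rpx <= sp@frameWidth - 5)
    nTrue <- nTrue + length(full)
    for (i in full) {
      hit <- abs(d$center_x - xs[i]) < 3 & abs(d$center_y - tr$y_px[i]) < 3
      nHit <- nHit + sum(hit)  # exactly-once counting: sums duplicates too
    }
    # precision: every complete detection corresponds to some true droplet
    if (nrow(d))
      nFalse <- nFalse + sum(!vapply(seq_len(nrow(d)), function(k)
        any(abs(d$center_x[k] - xs) < 4 & abs(d$center_y[k] - tr$y_px) < 4),
        TRUE))
  }
  expect_gt(nTrue, 8)
  expect_equal(nHit, nTrue)   # recall 1.0
  expect_equal(nFalse, 0)     # precision 1.0
})

test_that("rendered disc diameters are measured within tolerance", {
  # |measured - true| <= (2 + 1) * um_per_px on noisy rendered discs
  sp <- desk_spec(0, 10L, seed = 22)
  a <- generateAssay(sp)
  pv <- processVideo(a, desk_config())
  d <- droplets(pv$droplets)
  tr <- assayTruth(a)
  expect_equal(nrow(d), 10L)
  dev <- abs(sort(d$diameter_um) - sort(tr$diameter_um))
  expect_true(all(dev <= 3 * 5))
  # with default noise, recall stays >= 0.95 (census complete here)
  expect_gte(nrow(d) / nrow(tr), 0.95)
})
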