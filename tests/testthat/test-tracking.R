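make_det <- function(frame, x, y, diam = 100, lum = 0.05, border = FALSE) {
  n <- length(frame)
  data.frame(frame = frame, center_x = x, center_y = y,
             radius_px = rep_len(diam / 2, n), votes = rep_len(100, n),
             diameter_um = rep_len(diam, n), luminance = rep_len(lum, n),
             chrom_x = rep_len(0.3, n), chrom_y = rep_len(0.59, n),
             at_border = rep_len(border, n))
}

test_that("linking joins one moving droplet into one track", {
  tp <- trackingParams(expectedDxPx = 10)
  empty <- linkDetections(make_det(integer(0), numeric(0), numeric(0)), tp)
  expect_equal(nrow(empty), 0L)
  d <- make_det(0:9, 5 + 10 * (0:9), 24)
  linked <- linkDetections(d, tp)
  expect_equal(length(unique(linked$track_id)), 1L)
  expect_equal(nrow(linked), 10L)
  tk <- summariseTracks(linked, tp, frameWidth = 200, frameHeight = 48)
  expect_equal(nrow(tk), 1L)
  expect_equal(tk$n_detections, 10L)
  expect_equal(tk$mean_velocity_px_per_frame, 10)
})

test_that("droplets separated beyond the gate form separate tracks", {
  tp <- trackingParams(expectedDxPx = 10, maxDisplacementPx = 8)
  d <- rbind(make_det(0:5, 10 + 10 * (0:5), 10),
             make_det(0:5, 10 + 10 * (0:5), 40))  # 30 px apart in y
  linked <- linkDetections(d, tp)
  expect_equal(length(unique(linked$track_id)), 2L)
  # and a detection jumping by more than the gate starts a new track
  d2 <- make_det(0:3, c(10, 20, 80, 90), 24)
  expect_equal(length(unique(linkDetections(d2, tp)$track_id)), 2L)
})

test_that("the counting line commits each physical droplet exactly once", {
  tp <- trackingParams(expectedDxPx = 10, countingLinePx = 100)
  # 5 droplets all traversing the line
  d <- do.call(rbind, lapply(0:4, function(i)
    make_det(0:19 + i, 10 * (0:19), 24 + i)))
  tk <- summariseTracks(linkDetections(d, tp), tp)
  recs <- enumerateDroplets(tk, tp)
  expect_equal(nDroplets(recs), 5L)
  expect_equal(attr(recs, "n_flagged"), 0L)
  # a track fully upstream of the line is flagged, not counted
  up <- make_det(0:5, 10 + 10 * (0:5), 24)   # never reaches x = 100
  tk2 <- summariseTracks(linkDetections(up, tp), tp)
  recs2 <- enumerateDroplets(tk2, tp)
  expect_equal(nDroplets(recs2), 0L)
  expect_equal(attr(recs2, "n_flagged"), 1L)
  # a droplet seen in 30 frames is still one record
  long <- make_det(0:29, 5 * (0:29), 24)
  tp2 <- trackingParams(expectedDxPx = 5, countingLinePx = 70)
  recs3 <- enumerateDroplets(summariseTracks(linkDetections(long, tp2), tp2),
                             tp2)
  expect_equal(nDroplets(recs3), 1L)
  expect_equal(droplets(recs3)$n_detections, 30L)
})

test_that("track aggregates are medians over complete detections", {
  tp <- trackingParams(expectedDxPx = 10, countingLinePx = 30)
  d <- make_det(0:4, 10 + 10 * (0:4), 24,
                diam = c(60, 98, 100, 102, 70),
                border = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  d$luminance <- c(0.2, 0.05, 0.06, 0.055, 0.3)
  tk <- summariseTracks(linkDetections(d, tp), tp)
  expect_equal(tk$n_complete, 3L)
  expect_equal(tk$diameter_um, 100)   # clipped sizes excluded
  expect_equal(tk$luminance, 0.055)
})

test_that("the census matches the generator ground truth", {
  a <- generateAssay(desk_spec(800, 25L, seed = 31))
  pv <- processVideo(a, desk_config())
  expect_equal(pv$counts$records, 25L)
  # stage chain consistency: records <= tracks <= detections
  expect_lte(pv$counts$records, pv$counts$tracks)
  expect_lte(pv$counts$tracks, pv$counts$detections)
})

test_that("the census is invariant to frame-rate oversampling", {
  # same physical scene sampled at 60 and at 30 fps
  sp60 <- assaySpec(concCopiesPerUl = 500, nDroplets = 12L,
                    frameHeight = 48L, frameWidth = 600L, umPerPx = 5,
                    fps = 60, flowVelocityPxPerFrame = 140, spacingPx = 76,
                    seed = 32L)
  sp30 <- assaySpec(concCopiesPerUl = 500, nDroplets = 12L,
                    frameHeight = 48L, frameWidth = 600L, umPerPx = 5,
                    fps = 30, flowVelocityPxPerFrame = 280, spacingPx = 76,
                    seed = 32L)
  a60 <- generateAssay(sp60); a30 <- generateAssay(sp30)
  # identical physical droplets, trajectories sampled twice as often
  expect_equal(assayTruth(a60)$x0_px, assayTruth(a30)$x0_px)
  c60 <- processVideo(a60, desk_config())$counts$records
  c30 <- processVideo(a30, desk_config())$counts$records
  expect_equal(c60, 12L)
  expect_equal(c30, c60)
})

test_that("the flow displacement is recoverable from raw detections", {
  # three droplets advancing 35 px/frame, unlinked detections only
  d <- do.call(rbind, lapply(c(0, 120, 260), function(x0)
    make_det(0:6, x0 + 35 * (0:6), 24)))
  expect_equal(estimateFlowDisplacement(d), 35, tolerance = 0.01)
  expect_equal(estimateFlowDisplacement(make_det(0L, 5, 5)), 0)
})
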