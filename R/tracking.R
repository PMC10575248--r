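## Cross-frame linking. The video records each physical droplet in many
## consecutive frames; linking detections into tracks and committing each
## track once at a counting line makes the census count physical droplets,
## not detections.

#' Estimate the per-frame flow displacement from raw detections
#'
#' Collects displacement candidates between detections in consecutive
#' frames along the flow axis and returns the mode of their distribution
#' (refined to the median within one bin of the mode). Self-pairs of the
#' same droplet dominate the candidates in a steady train, so the mode is
#' the flow velocity even before any linking; used when the expected
#' displacement is not configured and no generator spec supplies it.
#'
#' @param detections data.frame with `frame` and centre columns.
#' @param flowAxis `"x"` or `"y"`.
#' @param binPx histogram bin width, pixels.
#' @return displacement in px/frame, or 0 if too few candidates.
#' @export
estimateFlowDisplacement <- function(detections, flowAxis = "x",
                                     binPx = 4) {
  ax <- if (flowAxis == "x") "center_x" else "center_y"
  if (nrow(detections) < 4L) return(0)
  det <- detections[order(detections$frame), , drop = FALSE]
  fr <- sort(unique(det$frame))
  diffs <- numeric(0)
  for (i in seq_len(length(fr) - 1L)) {
    if (fr[i + 1L] - fr[i] != 1L) next
    u0 <- det[[ax]][det$frame == fr[i]]
    u1 <- det[[ax]][det$frame == fr[i + 1L]]
    diffs <- c(diffs, as.numeric(outer(u1, u0, "-")))
  }
  diffs <- diffs[diffs >= 0]
  if (length(diffs) < 3L) return(0)
  bins <- round(diffs / binPx)
  tab <- table(bins)
  modeBin <- as.numeric(names(tab)[which.max(tab)])
  median(diffs[abs(diffs - modeBin * binPx) <= binPx])
}

#' Link per-frame detections into droplet tracks
#'
#' Greedy nearest-neighbour linking frame to frame: each active track
#' predicts its next position by adding the expected per-frame flow
#' displacement (`expectedDxPx` along the flow axis) to its last position;
#' detections are assigned to the closest prediction within
#' `maxDisplacementPx` (closest pair first), and unassigned detections
#' start new tracks. Tracks survive up to `maxGapFrames` missed frames.
#'
#' @param detections data.frame with columns `frame`, `center_x`,
#'   `center_y` and any per-detection measurements (e.g. `diameter_um`,
#'   `luminance`), sorted or sortable by frame.
#' @param params a [TrackingParams-class].
#' @return the input with an added `track_id` column.
#' @export
linkDetections <- function(detections, params = trackingParams()) {
  validObject(params)
  if (nrow(detections) == 0L) {
    detections$track_id <- integer(0)
    return(detections)
  }
  det <- detections[order(detections$frame), , drop = FALSE]
  ax <- if (params@flowAxis == "x") "center_x" else "center_y"
  ay <- if (params@flowAxis == "x") "center_y" else "center_x"
  det$track_id <- NA_integer_
  ## active tracks: id, last position (flow/cross), last frame
  act <- data.frame(id = integer(0), u = numeric(0), v = numeric(0),
                    frame = integer(0))
  nextId <- 1L
  for (f in unique(det$frame)) {
    rows <- which(det$frame == f)
    act <- act[f - act$frame <= params@maxGapFrames + 1L, , drop = FALSE]
    u <- det[[ax]][rows]; v <- det[[ay]][rows]
    assigned <- rep(NA_integer_, length(rows))
    if (nrow(act) > 0L) {
      gap <- f - act$frame
      pu <- act$u + gap * params@expectedDxPx
      D <- sqrt(outer(u, pu, "-")^2 + outer(v, act$v, "-")^2)
      gate <- params@maxDisplacementPx
      repeat {
        m <- which.min(D)
        if (length(m) == 0L || D[m] > gate) break
        i <- (m - 1L) %% length(rows) + 1L
        j <- (m - 1L) %/% length(rows) + 1L
        assigned[i] <- act$id[j]
        act$u[j] <- u[i]; act$v[j] <- v[i]; act$frame[j] <- f
        D[i, ] <- Inf; D[, j] <- Inf
      }
    }
    fresh <- which(is.na(assigned))
    if (length(fresh)) {
      ids <- seq.int(nextId, length.out = length(fresh))
      nextId <- nextId + length(fresh)
      assigned[fresh] <- ids
      act <- rbind(act, data.frame(id = ids, u = u[fresh], v = v[fresh],
                                   frame = f))
    }
    det$track_id[rows] <- assigned
  }
  det
}

#' Summarise tracks
#'
#' One row per track with first/last frame, length, the median diameter and
#' luminance over member frames (robust to single-frame segmentation
#' glitches), mean velocity along the flow axis, and whether the track
#' crossed the counting line during the video.
#'
#' @param linked output of [linkDetections()].
#' @param params a [TrackingParams-class].
#' @param frameWidth,frameHeight frame geometry, used for the default
#'   (mid-frame) counting line.
#' @return data.frame with columns `track_id`, `first_frame`, `last_frame`,
#'   `n_detections`, `n_complete` (member detections not clipped by the
#'   frame border; aggregates use these), `diameter_um`, `luminance`,
#'   `chrom_x`, `chrom_y`, `mean_velocity_px_per_frame`, `crossed_line`.
#' @export
summariseTracks <- function(linked, params = trackingParams(),
                            frameWidth = NULL, frameHeight = NULL) {
  ax <- if (params@flowAxis == "x") "center_x" else "center_y"
  line <- params@countingLinePx
  if (is.na(line)) {
    ext <- if (params@flowAxis == "x") frameWidth else frameHeight
    if (is.null(ext)) {
      if (nrow(linked) == 0L) ext <- 0
      else ext <- max(linked[[ax]])
    }
    line <- ext / 2
  }
  if (nrow(linked) == 0L)
    return(data.frame(track_id = integer(0), first_frame = integer(0),
                      last_frame = integer(0), n_detections = integer(0),
                      n_complete = integer(0),
                      diameter_um = numeric(0), luminance = numeric(0),
                      chrom_x = numeric(0), chrom_y = numeric(0),
                      mean_velocity_px_per_frame = numeric(0),
                      crossed_line = logical(0)))
  sp <- split(linked, linked$track_id)
  out <- do.call(rbind, lapply(sp, function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    vel <- if (nrow(g) > 1L)
      (g[[ax]][nrow(g)] - g[[ax]][1]) / (g$frame[nrow(g)] - g$frame[1])
    else NA_real_
    ## aggregate size/colour over complete (unclipped) member detections
    clean <- if ("at_border" %in% names(g)) g[!g$at_border, , drop = FALSE]
             else g
    nClean <- nrow(clean)
    if (nClean == 0L) clean <- g
    data.frame(track_id = g$track_id[1], first_frame = min(g$frame),
               last_frame = max(g$frame), n_detections = nrow(g),
               n_complete = nClean,
               diameter_um = median(clean$diameter_um),
               luminance = median(clean$luminance),
               chrom_x = median(clean$chrom_x), chrom_y = median(clean$chrom_y),
               mean_velocity_px_per_frame = vel,
               crossed_line = min(g[[ax]]) <= line & max(g[[ax]]) >= line)
  }))
  rownames(out) <- NULL
  out[order(out$track_id), , drop = FALSE]
}

#' Enumerate physical droplets from tracks
#'
#' Commits each track that crossed the counting line and holds at least
#' one complete (unclipped) detection as one droplet record; tracks that
#' never cross the line (partial at the video ends) or were only ever seen
#' clipped by the frame border are flagged and excluded from the census.
#'
#' @param tracks output of [summariseTracks()].
#' @param params a [TrackingParams-class].
#' @param umPerPx spatial calibration carried into the [DropletSet-class].
#' @return a [DropletSet-class]; the number of flagged (uncounted) tracks
#'   is available as `metadata` attribute `n_flagged`.
#' @export
enumerateDroplets <- function(tracks, params = trackingParams(),
                              umPerPx = 0.5) {
  ok <- tracks$crossed_line &
    (if ("n_complete" %in% names(tracks)) tracks$n_complete > 0L else TRUE)
  counted <- tracks[ok, , drop = FALSE]
  d <- data.frame(droplet_id = seq_len(nrow(counted)),
                  track_id = counted$track_id,
                  first_frame = counted$first_frame,
                  last_frame = counted$last_frame,
                  n_detections = counted$n_detections,
                  diameter_um = counted$diameter_um,
                  luminance = counted$luminance,
                  chrom_x = counted$chrom_x, chrom_y = counted$chrom_y,
                  label = rep("unclassified", nrow(counted)))
  ds <- new("DropletSet", droplets = d, umPerPx = umPerPx)
  attr(ds, "n_flagged") <- nrow(tracks) - nrow(counted)
  ds
}
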