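## Independent brute-force oracles used to pin down the vectorised
## implementations on small randomised inputs.

# symmetric (reflect, edge-duplicated) index into 1..n
refl_idx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# O(N k^2) double-loop 2D convolution with reflect padding
brute_convolve <- function(m, kern) {
  k <- nrow(kern)
  r <- (k - 1) %/% 2
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m))) {
      s <- 0
      for (a in seq_len(k))
        for (b in seq_len(k))
          s <- s + kern[a, b] *
            m[refl_idx(i + a - r - 1, nrow(m)), refl_idx(j + b - r - 1, ncol(m))]
      out[i, j] <- s
    }
  out
}

# set-based binary erosion/dilation; out-of-bounds neighbours are ignored
# for erosion (treated as foreground) and for dilation (treated as
# background), matching the border convention of the implementation
brute_erode <- function(mask, se) {
  r <- (nrow(se) - 1) %/% 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask)))
    for (j in seq_len(ncol(mask))) {
      ok <- TRUE
      for (a in -r:r)
        for (b in -r:r) {
          if (!se[a + r + 1, b + r + 1]) next
          ii <- i + a; jj <- j + b
          if (ii < 1 || jj < 1 || ii > nrow(mask) || jj > ncol(mask)) next
          if (!mask[ii, jj]) ok <- FALSE
        }
      out[i, j] <- ok
    }
  out
}

brute_dilate <- function(mask, se) {
  r <- (nrow(se) - 1) %/% 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask)))
    for (j in seq_len(ncol(mask))) {
      hit <- FALSE
      for (a in -r:r)
        for (b in -r:r) {
          if (!se[a + r + 1, b + r + 1]) next
          ii <- i + a; jj <- j + b
          if (ii < 1 || jj < 1 || ii > nrow(mask) || jj > ncol(mask)) next
          if (mask[ii, jj]) hit <- TRUE
        }
      out[i, j] <- hit
    }
  out
}

brute_open <- function(mask, se) brute_dilate(brute_erode(mask, se), se)

# exhaustive pairwise largest chord over ALL mask pixels (no boundary
# shortcut), pixel extent convention: max centre distance + 1
brute_chord_um <- function(mask, um_per_px) {
  idx <- which(mask)
  H <- nrow(mask)
  y <- (idx - 1) %% H
  x <- (idx - 1) %/% H
  best <- 0
  for (i in seq_along(idx))
    for (j in seq_along(idx)) {
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d > best) best <- d
    }
  (best + 1) * um_per_px
}

# reference positional PID recurrence (derivative on measurement,
# conditional integration, output clamp), written as a plain loop
brute_pid_trace <- function(kp, ki, kd, errors, meas, dt) {
  integ <- 0
  prev <- NA_real_
  duty <- numeric(length(errors))
  for (t in seq_along(errors)) {
    d <- if (!is.na(prev)) -(meas[t] - prev) / dt else 0
    cand <- integ + errors[t] * dt
    u <- kp * errors[t] + ki * cand + kd * d
    if (u > 1 || u < 0) {
      if ((u > 1 && cand < integ) || (u < 0 && cand > integ)) integ <- cand
      else u <- kp * errors[t] + ki * integ + kd * d
    } else integ <- cand
    prev <- meas[t]
    duty[t] <- min(max(u, 0), 1)
  }
  duty
}

# single-frame scene: anti-aliased green discs on a flat background,
# built directly (independent of the package renderer)
disc_frame <- function(H, W, centers, radius, value = 200, bg = 10) {
  fr <- array(bg, dim = c(H, W, 3))
  g <- fr[, , 2]
  for (k in seq_len(nrow(centers))) {
    dy <- outer((seq_len(H) - 1) - centers[k, 2], rep(1, W))
    dx <- outer(rep(1, H), (seq_len(W) - 1) - centers[k, 1])
    cov <- pmin(pmax(radius + 0.5 - sqrt(dx^2 + dy^2), 0), 1)
    g <- g + cov * (value - g)
  }
  fr[, , 2] <- g
  fr[, , 1] <- fr[, , 1] + 0.15 * (g - bg)
  fr[, , 3] <- fr[, , 3] + 0.15 * (g - bg)
  round(fr)
}

# desk-scale assay spec used across pipeline-level tests
desk_spec <- function(conc, n, seed, noiseSd = 2, ...) {
  assaySpec(concCopiesPerUl = conc, nDroplets = n, frameHeight = 48L,
            frameWidth = 600L, umPerPx = 5, flowVelocityPxPerFrame = 280,
            spacingPx = 76, noiseSd = noiseSd, seed = seed, ...)
}

desk_config <- function(...) {
  over <- list(...)
  base <- list(detection = list(um_per_px = 5))
  for (s in names(over)) base[[s]] <- utils::modifyList(
    if (is.null(base[[s]])) list() else base[[s]], over[[s]])
  pipelineConfig(base)
}
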