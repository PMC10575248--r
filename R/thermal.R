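## Desk-scale simulation of the isothermal heater control loop: positional
## PID with conditional-integration anti-windup and derivative on the
## measurement, driving a first-order-plus-dead-time thermal plant, plus
## Ziegler-Nichols tuning from a critical-gain sweep.

#' Initial PID controller state
#'
#' @return list with zeroed integral and an empty previous measurement.
#' @export
pidState <- function() list(integral = 0, prevMeas = NA_real_)

#' One PID controller step
#'
#' Positional PID: `duty = kp * e + ki * integral(e) - kd * d(meas)/dt`,
#' clamped to [0,1] (PWM semantics). The derivative acts on the measurement
#' (not the error) to avoid setpoint kick; when no measurement is supplied
#' the derivative term is zero. Anti-windup is by conditional integration:
#' the integral is frozen whenever the unclamped output is saturated and
#' integrating would push it further into saturation.
#'
#' @param gains a [PIDGains-class].
#' @param error setpoint minus measurement, degrees C.
#' @param state controller state from [pidState()] or a previous step.
#' @param dt time step, s (> 0).
#' @param measurement current measurement for the derivative term
#'   (optional).
#' @return list with `duty` in [0,1] and the updated `state`.
#' @export
pidStep <- function(gains, error, state = pidState(), dt,
                    measurement = NA_real_) {
  stopifnot(is(gains, "PIDGains"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be > 0")
  deriv <- if (!is.na(measurement) && !is.na(state$prevMeas))
    -(measurement - state$prevMeas) / dt else 0
  candInt <- state$integral + error * dt
  u <- gains@kp * error + gains@ki * candInt + gains@kd * deriv
  if (u > 1 || u < 0) {
    uFrozen <- gains@kp * error + gains@ki * state$integral + gains@kd * deriv
    ## integrate only if it brings the output back toward the [0,1] band
    if ((u > 1 && candInt < state$integral) ||
        (u < 0 && candInt > state$integral)) {
      state$integral <- candInt
    } else {
      u <- uFrozen
    }
  } else {
    state$integral <- candInt
  }
  state$prevMeas <- measurement
  list(duty = min(max(u, 0), 1), state = state)
}

#' Initial plant state
#'
#' @param plant a [ThermalPlant-class].
#' @param dt simulation step, s.
#' @return list with the starting temperature and the duty delay buffer.
#' @export
plantState <- function(plant, dt) {
  stopifnot(is(plant, "ThermalPlant"))
  nDelay <- max(0L, as.integer(round(plant@deadTime / dt)))
  list(temperature = plant@ambient, buffer = rep(0, nDelay), ptr = 1L)
}

#' One thermal plant step
#'
#' Forward Euler step of the first-order lag
#' `dT/dt = (ambient + gain * u_delayed - T) / tau`, where the applied duty
#' is the input delayed by the transport dead time (ring buffer quantised
#' to the step).
#'
#' @param plant a [ThermalPlant-class].
#' @param duty commanded duty in [0,1].
#' @param state plant state from [plantState()] or a previous step.
#' @param dt time step, s (> 0, well below the time constant).
#' @return list with `temperature` and the updated `state`.
#' @export
plantStep <- function(plant, duty, state, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be > 0")
  if (length(state$buffer)) {
    uApplied <- state$buffer[state$ptr]
    state$buffer[state$ptr] <- duty
    state$ptr <- if (state$ptr == length(state$buffer)) 1L else state$ptr + 1L
  } else uApplied <- duty
  target <- plant@ambient + plant@gain * uApplied
  state$temperature <- state$temperature +
    dt * (target - state$temperature) / plant@timeConstant
  list(temperature = state$temperature, state = state)
}

#' Ziegler-Nichols PID gains from the ultimate gain and period
#'
#' Classic closed-loop Ziegler-Nichols table: `kp = 0.6 kc`,
#' `ki = 2 kp / pc`, `kd = kp pc / 8`. Variants trade responsiveness for
#' overshoot: `"some-overshoot"` uses `kp = kc/3`, `kd = kp pc / 3`;
#' `"no-overshoot"` uses `kp = 0.2 kc`, `kd = kp pc / 3`.
#'
#' @param kc critical (ultimate) proportional gain, > 0.
#' @param pc oscillation period at the critical gain, s, > 0.
#' @param variant tuning table row, default `"classic"`.
#' @return a [PIDGains-class].
#' @examples
#' znTune(1, 1)  # kp 0.6, ki 1.2, kd 0.075
#' @export
znTune <- function(kc, pc, variant = c("classic", "some-overshoot",
                                       "no-overshoot")) {
  variant <- match.arg(variant)
  if (kc <= 0 || pc <= 0) stop("kc and pc must be > 0")
  kp <- switch(variant, classic = 0.6 * kc, `some-overshoot` = kc / 3,
               `no-overshoot` = 0.2 * kc)
  kd <- switch(variant, classic = kp * pc / 8, kp * pc / 3)
  pidGains(kp = kp, ki = 2 * kp / pc, kd = kd)
}

## P-only closed-loop trace used by the ultimate-gain sweep. The loop is
## started at its (unsaturated) proportional equilibrium with a small
## perturbation so the stability boundary is probed in the small-signal
## regime, away from the duty saturation.
.pOnlyTrace <- function(plant, kp, setpoint, duration, dt, perturb = 0.1) {
  n <- ceiling(duration / dt)
  tEq <- (plant@ambient + plant@gain * kp * setpoint) /
    (1 + plant@gain * kp)
  dutyEq <- min(max(kp * (setpoint - tEq), 0), 1)
  ps <- plantState(plant, dt)
  ps$temperature <- tEq + perturb
  if (length(ps$buffer)) ps$buffer[] <- dutyEq
  temp <- numeric(n)
  tcur <- ps$temperature
  for (i in seq_len(n)) {
    duty <- min(max(kp * (setpoint - tcur), 0), 1)
    st <- plantStep(plant, duty, ps, dt)
    tcur <- st$temperature; ps <- st$state
    temp[i] <- tcur
  }
  list(temp = temp, tEq = tEq)
}

## Decay ratio (successive oscillation peak amplitude ratio, about the
## equilibrium) and period of a trace; NA when fewer than 4 peaks are found.
.oscillationStats <- function(temp, dt, discardFrac = 0.05, center = NULL) {
  n <- length(temp)
  x <- temp[ceiling(discardFrac * n):n]
  x <- x - (if (is.null(center)) mean(x) else center)
  pk <- which(diff(sign(diff(x))) < 0) + 1L
  pk <- pk[x[pk] > 1e-9]
  if (length(pk) < 4L) return(list(ratio = NA_real_, period = NA_real_))
  amp <- x[pk]
  ratios <- amp[-1] / amp[-length(amp)]
  list(ratio = exp(mean(log(pmax(ratios, 1e-12)))),
       period = mean(diff(pk)) * dt)
}

#' Find the ultimate gain and period of a plant
#'
#' Emulates the manual tuning procedure: with integral and derivative
#' gains at zero, the proportional gain is swept upward until the closed
#' loop sustains a constant-amplitude oscillation; the smallest such gain
#' is the critical gain `kc` and the oscillation period is `pc`. The sweep
#' brackets the stability boundary (oscillation decay ratio crossing 1) on
#' a geometric grid and refines it by bisection. A plant that cannot
#' sustain oscillation (e.g. first order with zero dead time) returns
#' `NULL`.
#'
#' @param plant a [ThermalPlant-class].
#' @param setpoint loop setpoint, degrees C (default 65).
#' @param kpMin,kpMax sweep bounds for the proportional gain.
#' @param dt simulation step, s.
#' @param duration trace length per candidate gain, s; `NA` chooses
#'   ~40 dead times + 6 time constants.
#' @param tol relative bisection tolerance on `kc`.
#' @return list with `kc` and `pc`, or `NULL` if no sustained oscillation
#'   occurs within the sweep range.
#' @export
findUltimate <- function(plant, setpoint = 65, kpMin = 1e-3, kpMax = 1e3,
                         dt = 0.01, duration = NA_real_, tol = 0.005) {
  stopifnot(is(plant, "ThermalPlant"))
  if (plant@deadTime <= 0) return(NULL)
  if (is.na(duration))
    duration <- 40 * plant@deadTime + 6 * plant@timeConstant
  ratioAt <- function(kp) {
    tr <- .pOnlyTrace(plant, kp, setpoint, duration, dt)
    .oscillationStats(tr$temp, dt, center = tr$tEq)
  }
  ## geometric sweep for a bracket [decaying, growing]
  grid <- exp(seq(log(kpMin), log(kpMax), length.out = 25))
  lo <- NA_real_; hi <- NA_real_
  for (kp in grid) {
    st <- ratioAt(kp)
    if (!is.na(st$ratio) && st$ratio >= 1) { hi <- kp; break }
    lo <- kp
  }
  if (is.na(hi) || is.na(lo)) return(NULL)
  while (hi / lo - 1 > tol) {
    mid <- sqrt(lo * hi)
    st <- ratioAt(mid)
    if (!is.na(st$ratio) && st$ratio >= 1) hi <- mid else lo <- mid
  }
  kc <- sqrt(lo * hi)
  trHi <- .pOnlyTrace(plant, hi, setpoint, duration, dt)
  list(kc = kc,
       pc = .oscillationStats(trHi$temp, dt, center = trHi$tEq)$period)
}

#' Simulate the closed temperature loop
#'
#' Full PID loop on the modeled plant from ambient to the setpoint,
#' reporting the trace, the settling time into the given band, and the
#' largest post-settling deviation. All results are properties of the
#' simulated plant model, not hardware measurements.
#'
#' @param plant a [ThermalPlant-class].
#' @param gains a [PIDGains-class].
#' @param setpoint target temperature, degrees C (default 65).
#' @param duration simulated time, s.
#' @param dt step, s.
#' @param band settling band half-width, degrees C (default 0.8).
#' @return a [ControlTrace-class].
#' @export
simulateClosedLoop <- function(plant, gains, setpoint = 65, duration = 600,
                               dt = 0.05, band = 0.8) {
  stopifnot(is(plant, "ThermalPlant"), is(gains, "PIDGains"))
  n <- ceiling(duration / dt)
  ps <- plantState(plant, dt)
  cs <- pidState()
  temp <- numeric(n); duty <- numeric(n)
  tcur <- plant@ambient
  for (i in seq_len(n)) {
    out <- pidStep(gains, setpoint - tcur, cs, dt, measurement = tcur)
    cs <- out$state
    st <- plantStep(plant, out$duty, ps, dt)
    tcur <- st$temperature; ps <- st$state
    temp[i] <- tcur; duty[i] <- out$duty
  }
  tt <- seq_len(n) * dt
  dev <- abs(temp - setpoint)
  outside <- dev > band
  settleIdx <- if (any(outside)) max(which(outside)) + 1L else 1L
  settling <- if (settleIdx <= n) tt[settleIdx] else NA_real_
  new("ControlTrace",
      trace = data.frame(t = tt, setpoint = setpoint, temperature = temp,
                         duty = duty),
      settlingTime = settling, band = band,
      maxDevPostSettling = if (!is.na(settling) && settleIdx <= n)
        max(dev[settleIdx:n]) else NA_real_)
}
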