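---
title: "Methods: smartphone ddLAMP video analysis and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone ddLAMP video analysis and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddlampr)
```

## The assay and what the package computes

Digital droplet LAMP (ddLAMP) partitions an isothermal amplification
reaction into thousands of monodisperse water-in-oil droplets. Each
droplet is an independent yes/no compartment: if it received at least one
target DNA copy, amplification drives a fluorescent reporter bright; if it
received none, it stays dim. Counting the fraction of positive droplets
`f_p = N_P / N_T` and inverting the Poisson occupancy model

\[
P(k) = \frac{\lambda^k e^{-\lambda}}{k!},\qquad
\lambda = C_o V_d,\qquad
f_p = 1 - e^{-\lambda}
\quad\Longrightarrow\quad
C_o = \frac{-\ln(1 - f_p)}{V_d}
\]

turns a count into an absolute concentration, with no calibration curve.
`ddlampr` implements the complete analysis used by a smartphone-based
continuous-flow ddLAMP platform — droplets flowing through transparent
300-µm tubing are filmed at 1080×1920/60 fps, detected per frame, tracked
across frames, measured in CIE-xyY luminance, classified against a
negative-control threshold, and quantified — together with a synthetic
video generator and a desk-scale model of the heater control loop, so the
entire chain is testable without hardware.

## Colorimetry

Raw 8-bit RGB values are normalised by 255 and linearised with a single
power-law exponent, `channel^2.2`. The platform states one exponent, so
the pure power law is used rather than the piecewise sRGB curve. The
"direct linear model" matrix taking linear RGB to CIE XYZ is not published
with the protocol; we adopt the standard BT.709-primaries/D65-white
matrix (`sRGBD65Matrix()`), which is what consumer smartphone sensors
target, and make it configurable (`rgb_to_xyz_matrix`, 9 row-major
floats). Luminance is `L = Y`; chromaticity is `(x, y) = (X, Y)/(X+Y+Z)`,
reported as `NA` for black pixels rather than 0/0, and droplet-level
chromaticity means skip such pixels. A droplet's luminance is the mean
over its mask interior *after* eroding the refined mask once more with the
2-px disc, so anti-aliased rim pixels do not dilute the mean; whether the
original platform averaged all droplet pixels or a central subregion is
not stated, and this choice is ours.

## Detection

Each channel is denoised with a 5×5 Gaussian (2-pixel radius,
σ = 1.5), implemented as an exact separable shift-add convolution with
reflected edges (reflection is our choice; the protocol does not state the
edge rule). The per-pixel median across the processed window is the
background and is subtracted with an 8-bit floor.

Droplets are found with a gradient-voting circle Hough transform: edge
pixels (gradient magnitude above `grad_threshold`, default 8 counts) vote
along their inward gradient ray at 1-pixel radial steps across the radius
search window, with directions quantised to 1°. The published "1-degree
angular resolution" is, strictly, a line-Hough parameter; we read it as
the angular quantisation of boundary-normal voting and keep it
configurable. The radius window defaults to [0.4, 1.3]× the expected
diameter (halved to radii): droplets are 100–200 µm and the tubing bore
bounds the maximum. The vote threshold (`max(30, 0.25·2πr_min)`) and the
minimum peak separation (1.5 r_min) are unpublished; the defaults were
chosen once so that blank frames at the default noise level yield zero
detections, and are verified by test.

A detected circle seeds a mask: foreground pixels within 1.2× the radius
whose value exceeds half the droplet's *own* interior amplitude (median
within 0.6 r). The half-maximum cutoff localises the edge of a
symmetrically blurred disc at the true boundary irrespective of droplet
brightness, so dim negative and bright positive droplets are sized
identically. The mask's connected component at the centre is refined by
morphological opening with a 2-pixel disc, per the protocol. The diameter
is the largest chord — the maximum pairwise pixel extent (centre distance
plus one pixel) — times 0.5 µm/px. On rendered discs this convention runs
about +1 px (+0.5 µm at native scale); sub-pixel edge interpolation could
remove it but would depart from the stated chord definition.

Detections whose circle or mask touches the frame border are kept for
tracking (their Hough centre is retained, as arc voting stays accurate
under clipping) but flagged `at_border` and excluded from size and
luminance aggregation.

## Tracking and the census

The protocol records continuously flowing droplets but does not describe
de-duplication across frames; counting per frame would overcount each
droplet by its track length. This module is therefore deliberate artifact
plumbing, the largest gap we fill. Detections are linked greedily to the
nearest active track after subtracting the expected per-frame flow
displacement; the gate (default `max(6, 0.15·v)`) needs to absorb only
position noise and flow jitter, which keeps linking unambiguous even when
droplets advance by more than their spacing per frame. When the
displacement is not configured and no generator spec supplies it (frames
read from disk), it is estimated before linking as the mode of the
consecutive-frame displacement candidates over all detection pairs
(`estimateFlowDisplacement()`) — in a steady train the self-pairs of each
droplet dominate that distribution. Tracks tolerate one
missed frame. A track is committed to the census exactly once, when it
crosses a counting line (default mid-frame); tracks that never cross
(partial at the video ends) or were only ever seen clipped are flagged and
not counted. Per-track diameter and luminance are medians over unclipped
member detections, robust to single-frame glitches. Whether the original
platform counted per frame or per physical droplet cannot be determined
from its description; the census approach is our decision.

## Quantification

The classification threshold is twice the negative-control signal; the
summary statistic is not stated, so the mean of the negative-control
droplet luminances is the default with the median available
(`negative_statistic`). Positivity is strict (`luminance > threshold`;
ties negative). `V_d` defaults to the sphere volume of the median measured
diameter; a per-droplet mean-volume variant and a known calibrated volume
(`vol_droplet_ul`) are config options — the latter mirrors practice, where
the droplet size is set by the chip and flow rates rather than re-measured
per video, and sidesteps the +1 px chord convention at coarse rendering
scales. Saturation (`N_P = N_T`) is an explicit error, not infinity.
Uncertainty (absent from the platform's reports) is a Clopper–Pearson
exact binomial interval on `f_p` transformed through the inversion —
standard digital-assay practice. At 10⁴ copies/µL the model predicts
`f_p ≈ 0.995` whereas the platform measured 0.95, a divergence its
developers attribute to Poisson-independence breaking down at high
occupancy; the package reports the model value and documents the
discrepancy rather than inventing a correction factor.

## The synthetic-data generator

`generateAssay()` realises the study conditions: `nDroplets` droplets of
nominal 100 µm diameter (per-droplet SD 1.5 µm, keeping the spread well
inside the ±5 µm monodispersity of the real chip), Poisson copy counts at
`λ = C_o·V_d(d_i)`, and endpoint luminances from two truncated normals —
negatives at 0.05 ± 0.01, positives at 0.5 ± 0.05 on the L scale. The
platform publishes no numeric luminance values for the two clusters; these
are synthetic defaults chosen to reproduce a wide, clean gap (the
configuration requires the positive mean to exceed twice the negative mean
so the threshold rule can separate them). Trajectories move at constant
velocity along the tube axis with ±10% spacing jitter and no droplet
interactions, as appropriate for a stable monodisperse train. Frames are
rendered as anti-aliased green-dominant discs (side channels at 15% of
green) over a flat background of 10 counts, plus Gaussian sensor noise
(SD 2 counts) and 8-bit quantisation; rendering is deterministic per frame
index so long videos are materialised lazily. The droplet-size versus
continuous-phase-flow model interpolates logarithmically between the two
measured anchors (0.05 µL/min → 200 µm, 3 µL/min → 100 µm, at
Q_D = 5 µL/min) and clamps to [100, 200] µm; the intermediate shape is
explicitly not from measurement.

What the generator does *not* emulate: motion blur, rolling shutter,
illumination drift, droplet merging or deformation, out-of-focus light,
and camera-specific colour response. Passing tests therefore demonstrate
the correctness of the algorithms under the stated image model, not
performance on any particular phone's footage.

## Thermal control simulation

The heater loop is simulated desk-scale: a positional PID (derivative on
the measurement to avoid setpoint kick; conditional-integration anti-windup;
output clamped to [0,1] PWM duty) drives a first-order-plus-dead-time
plant stepped by forward Euler with a duty delay buffer. The plant
(gain 60 °C/duty, τ = 40 s, dead time 2 s, ambient 22 °C) is a modelling
fiction chosen so 65 °C is reachable at ~0.72 duty and tuning is
exercised; it is not fitted to hardware, and no hardware temperature
figure is claimed reproduced. `findUltimate()` emulates manual
Ziegler–Nichols tuning — integral and derivative off, proportional gain
swept upward until oscillation is sustained — probing the boundary in the
small-signal regime around the proportional equilibrium (a 0.1 °C
perturbation) so duty saturation does not mask it; the recovered critical
gain and period match the analytic phase-crossover solution for the
default plant within 5%. `znTune()` implements the classic table
(`kp = 0.6 kc`, `ki = 2kp/pc`, `kd = kp·pc/8`) plus the some/no-overshoot
variants; which variant the platform used is unstated, so classic is the
default. The platform's published gains (0.68, 1.49, 0.06) do not jointly
satisfy any single row of the table; they ship verbatim as
`ddlampHeaterGains()` and are not "re-derived". On the default plant the
tuned loop settles into the ±0.8 °C band around 65 °C — a model property
standing in for the hardware-bound result.

## Numerical and scale choices

Tests and examples run at reduced geometry for speed; the scientific
conditions (droplet size, optics scale where stated, luminance clusters,
noise) are unchanged:

* unit and oracle tests use frames ≤ 64×64 and randomised small inputs;
* census/tracking suites use 48×600 px frames at 5 µm/px (20-px droplets);
* sizing-fidelity checks render at the native 0.5 µm/px (200-px droplets),
  40 droplets in the routine suite, 200 in the acceptance script;
* end-to-end concentration recovery uses N_T = 2000 droplets per assay at
  5 µm/px across C_o ∈ {10, 10², 10³} copies/µL, ten seeded replicates,
  with the known emulsion volume supplied to the estimator.

Generator spacing defaults to 2.4 droplet diameters; test geometries use
up to 3.8 so that any one pixel is droplet-covered in well under half the
frames and the median background stays clean (blur widens the effective
footprint by ~5 px, which matters for small rendered droplets). The
background median is computed per processing window (`chunk_size`, default
256 frames — the full sequence when it fits), the streaming analogue of
the full-video median; a sliding-window option was considered and dropped
as the backgrounds are static here.

Degenerate inputs are explicit: empty detection sets produce an `N_T = 0`
report with a warning, not an error; saturated assays are flagged;
chromaticity of black pixels is `NA`; an all-zero mask after opening
discards the detection.

## Known limitations

Sizing carries the +1 px largest-chord convention noted above. Greedy
nearest-neighbour linking assumes an approximately constant flow velocity
and non-overlapping droplets; merging or reversing droplets are out of
scope. The Hough stage assumes bright circular droplets on a dark
background — strongly deformed droplets would need a different detector.
The Poisson inversion assumes monodisperse droplets; a polydisperse-aware
maximum-likelihood estimator is a documented non-goal. Colour calibration
across phone models is not attempted.
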