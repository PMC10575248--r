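# ddlampr

Analysis and simulation toolkit for **smartphone-based digital droplet
LAMP (ddLAMP)** assays: fluorescence video of droplets flowing through
transparent tubing goes in, an absolute target-DNA concentration with an
exact confidence interval comes out.

ddLAMP partitions an isothermal amplification reaction into thousands of
monodisperse droplets. Each droplet that received at least one target
copy amplifies and glows; empty droplets stay dim. With Poisson
partitioning the fraction of positive droplets determines the absolute
concentration with no calibration curve:

    P(k) = lambda^k e^(-lambda) / k!,   lambda = C_o * V_d
    f_p  = N_P / N_T = 1 - e^(-lambda)
    C_o  = -ln(1 - f_p) / V_d

where `N_T` and `N_P` are total and positive droplet counts and `V_d` is
the droplet volume (5.24e-4 µL for a 100-µm sphere).

The package is aimed at developers of low-cost digital assays who need
the full smartphone image-analysis chain as tested, scriptable code:

* **colorimetry** — gamma correction (γ = 2.2), linear RGB→CIE XYZ
  ("direct linear model", sRGB/D65 default), xyY luminance and
  chromaticity per droplet;
* **detection** — Gaussian denoise (5×5, σ 1.5), median-frame background
  subtraction, gradient-voting circle Hough transform (1°/1 px), mask
  refinement by 2-px disc opening, largest-chord sizing at 0.5 µm/px;
* **tracking** — velocity-compensated nearest-neighbour linking and a
  counting line, so each physical droplet in the continuous flow is
  counted exactly once;
* **quantification** — twice-negative-control threshold, strict
  classification, Poisson inversion with Clopper–Pearson intervals;
* **synthesis** — a generator that renders Poisson-partitioned droplet
  trains as anti-aliased fluorescence video with per-droplet ground
  truth, so every stage is testable without hardware;
* **thermal_sim** — a desk-scale model of the 65 °C heater loop: PID with
  anti-windup, first-order-plus-dead-time plant, Ziegler–Nichols tuning
  from a simulated critical-gain sweep.

## Worked example

Simulate an assay at 1000 copies/µL, analyse it against a no-template
control, and read off the concentration:

```r
library(ddlampr)

spec  <- assaySpec(concCopiesPerUl = 1000, nDroplets = 60L,
                   frameHeight = 48L, frameWidth = 600L, umPerPx = 5,
                   flowVelocityPxPerFrame = 280, spacingPx = 76, seed = 7L)
assay <- generateAssay(spec)
assay
#> SyntheticAssay: 60 droplets at 1000 copies/uL, 20 frames (48x600 px)
#>   true positives: 30

cfg <- pipelineConfig(list(detection = list(um_per_px = 5)))
ntc <- generateAssay(assaySpec(concCopiesPerUl = 0, nDroplets = 40L,
  frameHeight = 48L, frameWidth = 600L, umPerPx = 5,
  flowVelocityPxPerFrame = 280, spacingPx = 76, seed = 8L))
negLum <- droplets(processVideo(ntc, cfg)$droplets)$luminance

report <- runAssay(assay, negativeLuminances = negLum, config = cfg)
report
#> AssayReport
#> ClassificationResult: N_T = 60, N_P = 30, f_p = 0.5 (threshold 0.09686)
#> ConcentrationEstimate: C_o = 1194 copies/uL [790.9, 1722] (95% CI)
#>   from N_P/N_T = 30/60, V_d = 0.0005803 uL
#>   stages: frames=20, detections=133, tracks=62, records=60, flagged=2
```

All 60 rendered droplets are recovered as exactly 60 census records (133
per-frame detections collapse into 62 tracks; the 2 flagged tracks are
partial appearances at the video ends and are not counted). The threshold
is twice the mean no-template luminance; 30 of 60 droplets exceed it, and
inverting the Poisson relation with the measured median droplet volume
gives 1194 copies/µL with the true 1000 inside the 95% interval.

Counts alone work too:

```r
estimateConcentration(52, 10000, dropletVolumeUl(100))
#> ConcentrationEstimate: C_o = 9.957 copies/uL [7.436, 13.06] (95% CI)
#>   from N_P/N_T = 52/10000, V_d = 0.0005236 uL
```

A thin CLI wrapper over the same functions is installed at
`inst/scripts/ddlamp` (`simulate`, `run`, `quantify`, `thermal-sim`
subcommands); frames travel as numbered PNG directories, tables as CSV,
reports as JSON, configuration as YAML.

## Documentation

The methods vignette (`vignettes/ddlamp-methods.Rmd`) describes the
model, every tunable default and its provenance, what the synthetic
generator does and does not emulate, the numerical choices, and known
limitations.
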