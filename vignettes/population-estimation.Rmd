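---
title: "Dual field-of-view spectral processing and plant-population estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual field-of-view spectral processing and plant-population estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specpop)
```

## The measurement model

A dual field-of-view spectrometer alternates between two fibres feeding one
detector: a bare upwelling fibre (400 um, 25 degree view) looking at the
canopy, and a cosine-corrected downwelling fibre (600 um) looking at the sky.
One spectral sample is a four-frame sequence — upwelling dark, upwelling
target, downwelling target, downwelling dark — acquired within well under a
second, so both channels see essentially the same sky. Because the target
signal and the illumination are measured near-simultaneously by the same
detector, their ratio cancels any change in illumination magnitude. That is
the core design claim this package exercises: relative reflectance should be
the same under clear and overcast skies without any white-reference panel.

The committed reflectance equation is

$$R(\lambda) = K \cdot
  \frac{(C_{up} - C_{up,dark}) / (t_{up}\, g_{up})}
       {(C_{down} - C_{down,dark}) / (t_{down}\, g_{down})},$$

with integration times $t$ in ms and channel throughputs $g$ proportional to
fibre cross-sectional area, $g_{down}/g_{up} = (600/400)^2 = 2.25$ by
default. The upstream instrument literature defines this correction but the
exact geometry factor of the cosine fore optic versus the bare fibre is not
quantified here; it is absorbed into the single system constant `K`
(default 1). Relative reflectance only needs internal consistency — every
statistical step downstream (plot averaging, NDSI, PLSR) is invariant to a
global scale — so `K` matters only if results must be compared against an
absolutely calibrated instrument. `throughput_model()` exposes both `K` and
a direct override of the throughput ratio.

Two further radiometric choices:

* **Negative net counts are preserved, not clamped.** Under heavy cloud the
  dark-subtracted signal in weak bands fluctuates around small values;
  clamping at zero would bias plot means upward. Strongly negative bands
  (beyond 3 estimated dark standard deviations) are flagged instead.
* **Dark frames are per-sequence** (frames 1 and 4), never interpolated from
  neighbouring sequences, mirroring the acquisition order.

Bands whose net downwelling signal falls at or below `min_irradiance`
(default 1 count) become missing; bands outside 400–900 nm are flagged as
noisy detector edges and trimmed during preprocessing.

## Preprocessing

The native grid is idealised as exactly uniform: 513 samples at 1.33 nm from
340 nm. Spectra are (1) linearly interpolated to 1 nm, (2) smoothed with a
Savitzky–Golay filter, window 5, polynomial order 2, and (3) aggregated to
5 nm block means on 400, 405, ..., 900 nm (101 bands), then averaged per
plot. On a 1 nm grid a "5 nm" filter and a 5-point filter coincide, which is
why interpolation precedes smoothing; the committed order is smooth first,
then aggregate, and a regression test pins it (swapping the two changes the
output). Linear rather than spline interpolation: the 1.33 to 1 nm
upsampling is mild, and linear interpolation cannot ring at the red edge.
The Savitzky–Golay implementation uses the classic interior convolution
((-3, 12, 17, 12, -3)/35 for window 5, order 2) and fits the truncated
window at the edges, so quadratic spectra pass through unchanged everywhere.
Missing bands are dropped from whichever window or 5 nm block they fall in,
with a `partial` flag.

Both rows sampled per plot are pooled into a single plot mean ("averaged per
plot"); sequences failing QC (saturation, implausible up/down ratio,
out-of-range integration times, widespread negative irradiance) are excluded
before averaging. No step in this chain reads the sky-condition label — a
test shuffles the labels and asserts identical output.

## Statistical models

**NDSI screen.** For every canonical pair $i < j$ of the 101 analysis bands
(5050 pairs), the normalized difference $(R_i - R_j)/(R_i + R_j)$ is
regressed against measured plant population by ordinary least squares.
"Quality of correlation" is committed as the $r^2$ of that fit; ranking by
$|r|$ would order pairs identically, and $r^2$ is directly comparable with
the PLSR reporting. Ties break lexicographically (smaller $i$, then $j$) so
ranks are deterministic. A pair whose NDSI is constant gets $r^2 = 0$ and a
degenerate flag; a pair missing on more than 20 % of plots is excluded from
ranking.

**PLSR ensemble.** The regression core is PLS1 (NIPALS); with as many
components as the centred predictor matrix has rank it reproduces ordinary
least squares, which the tests verify against a normal-equations oracle and
against an independent implementation. The resampling topology is:

1. per iteration, a random 75 % / 25 % split into a calibration +
   cross-validation pool and a validation hold-out;
2. within the pool, a further random 75/25 calibration/cross-validation
   split; the component count (1..15) minimises cross-validation RMSE, with
   numerical near-ties resolved to the smaller model;
3. the model is refit on the full pool at the selected size and predicts the
   hold-out plots.

This runs for 100 iterations; each plot's predictions are averaged over the
iterations in which it was held out (about 25 of 100), and the averaged
estimates are regressed against the measured values to give the reported
validation $R^2$ and RMSE (likewise for the calibration and
cross-validation roles). The source description of this procedure admits a
second reading — one fixed validation set with 100 calibration/
cross-validation shuffles — so `topology = "fixed-validation"` implements it
as a config option; results from the two topologies are never merged.
Whether the final model should be refit on calibration only is equally open;
`refit = "cal"` switches it. The component cap (15) and the argmin-RMSE rule
are package choices: spectra this smooth rarely support more than a handful
of latent directions, and the cap mainly bounds compute.

$R^2$ is the squared Pearson correlation of predicted versus measured (the
two vectors "regressed"), not $1 - SS_{res}/SS_{tot}$; with the OLS fit
between them the two differ only when predictions are biased, and the
RMSE — reported in plants × 10^4 ha^-1 — carries the bias information.

**Study orchestration.** `run_study()` partitions plots into the three
canonical model families: treatment level (stage × row spacing × tillage ×
replicate = 32 groups of 28, cultivars pooled), development stage (4 groups
of 224), and all data together (1 × 896). The printed count of 32 admits
other factorisations (cultivar instead of replicate); `build_groups()`
accepts any factor subset, and the committed choice is just the default.
Stages whose two replicates were measured under opposite skies (V1 and V3
under the default schedule) are additionally cross-validated in both
directions — train sunny, predict cloudy, and vice versa — and stage-level
ensembles get a residual-versus-condition permutation check (999
permutations). That check is a package addition: the underlying claim was
reported informally, and the permutation test makes it auditable.
Everything derives from one master seed through a counter, so any single
iteration, sequence, or group is reproducible in isolation and rerunning a
study writes a byte-identical report.

## The synthetic trial generator

No field data accompany this package, so the generator has to supply data
with the statistical structure the analysis assumes. What it emulates:

* **Design**: 2 replicates × 4 vegetative stages (VC–V3) × 2 row spacings
  (0.38, 0.76 m) × 2 tillages × 2 cultivars × 14 seeding rates
  (3.7 × (1..14), i.e. 3.7–51.8 seeds × 10^4 ha^-1), 13 sequences per row
  and 2 rows per plot (26 per plot record). Measured population is seeding
  rate times an emergence draw, Normal(0.85, 0.08) truncated to (0, 1],
  shared by the four stage records of a physical plot. The emergence
  parameters are simulator conventions — no emergence data were available —
  and are exposed as `trial_design()` arguments, never asserted as truth in
  tests.
* **Canopy**: a linear soil–vegetation mixture with fractional cover
  $f = 1 - \exp(-(c_s p)^k)$, $k = 1$ and $c_s$ = 0.008, 0.012, 0.025, 0.040
  (plants × 10^4 ha^-1)^-1 for VC–V3. The saturating law reproduces both
  reported behaviours: near-linear, noise-sensitive response at V1 (small
  $c_s p$) and compression above ~30 × 10^4 ha^-1 at V3, where overlapping
  foliage makes a linear model underestimate. Endmembers are parametric
  analytic curves (Gaussian green peak, logistic red edge to an NIR plateau;
  soil a gentle ramp) so the package ships no spectral libraries.
* **Stage-dependent variability**: early seedlings are small relative to the
  0.13 m footprint, so plot-level plant-size CV (0.18, 0.15, 0.10, 0.08 for
  VC–V3) and within-plot sequence-to-sequence cover CV (0.50, 0.40, 0.25,
  0.15) both shrink with stage. These are the realism choices that make V1
  models genuinely worse than V3 on default trials. Soil varies per plot
  (brightness CV 0.06 plus a smooth 6-bump shape perturbation, sd 0.04) and
  by treatment (tillage brightness 1.10/0.88; row-spacing cover factors
  0.95/1.05; cultivar NIR factors 1.00/1.03), which is what makes pooled
  models measurably worse than treatment-specific ones.
* **Illumination**: a 5800 K blackbody shape normalised to peak 1. Sunny:
  magnitude 1, 1 % per-sequence jitter. Cloudy: magnitude drawn per sequence
  from U[0.1, 0.5] ("scattered to full cloud cover") with 5 % jitter. An
  optional NIR shape perturbation (up to +3 % beyond ~750 nm) emulates the
  mild spectral divergence of overcast skies; it is off by default, so by
  default the sky condition affects illumination only and any cross-condition
  asymmetry in results is sampling noise.
* **Sensor**: Poisson shot noise on expected counts, dark current
  150 ± 5 counts, 16-bit full well, integration times drawn from 13–15 ms
  (up) and 4–6 ms (down), counts scaling with irradiance × time × fibre
  area. If the predicted signal would saturate, the integration time is
  re-drawn once, then the frame is flagged and excluded by QC.

What it does **not** emulate: radiative-transfer canopy structure (BRDF, row
shadowing geometry), sensor spectral response beyond the uniform-grid
idealisation, wavelength miscalibration, stray light, or the systematic V1
overestimation bias caused by seedlings escaping the footprint (the
generator degrades V1 by variance, not bias). Passing tests therefore show
that the processing chain and statistics behave correctly under the assumed
data-generating mechanism — illumination invariance, stage ordering,
pooling penalties — not that field data of this kind will reach any
particular accuracy.

## Numerical choices and degenerate inputs

* Seeds: every stochastic routine takes an explicit seed; child seeds come
  from a linear-congruential mix (`derive_seed`) and stay below 2^31.
* NDSI denominators at or below 1e-6 produce missing values rather than
  blow-ups; net downwelling signal at or below 1 count likewise.
* PLS deflation stops when the residual covariance is numerically exhausted
  (relative tolerance 1e-12), truncating rank-deficient fits with a warning.
* Component selection resolves RMSE near-ties (within 1e-8 relative) to the
  smaller model, so noise-free signals select their true dimension.
* All-dark illumination, all-saturated sequences, plots with no QC-passing
  sequences, and train/test overlap in cross-condition validation are hard
  errors naming the offending object.

## Problem sizes

The test suite and the acceptance script run the generator at the full
default design (896 plot records, 23 296 sequences, 513 native bands):
stage-level ensembles use 100 iterations, the screening comparisons 50, and
the end-to-end determinism check 5 (determinism is a seeding property, not a
function of iteration count). Monte-Carlo checks use 200 replicate
sequences; oracle comparisons use 50–100 random draws. These sizes are the
package's chosen balance between statistical resolution and a test suite
that stays pleasant to run.
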