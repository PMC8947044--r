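---
title: "Quantifying lateral flow assays from strip images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lateral flow assays from strip images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfaquant)
```

## The measurement problem

A lateral flow assay (LFA) develops one or more colored or fluorescent
bands whose darkness (or brightness) carries the analyte concentration.
Turning a photograph of a strip into a concentration estimate requires
four steps, each of which this package implements as an explicit,
replayable operation:

1. **Geometry** — locate the bands with a rectangular grid;
2. **Background correction** — separate band pixels from membrane
   background by an intensity threshold;
3. **Calibration** — fit the relationship between known concentrations
   and the extracted band signal;
4. **Inverse prediction** — solve that relationship for unknown samples,
   with detection-limit flags.

All pixel arithmetic happens on a single intensity scale $[0, 1]$:
8- and 16-bit images are divided by their type maximum at load time, so
thresholds and offsets mean the same thing regardless of the camera.

## Grid geometry

The user supplies a region of interest, the number of signal lines $L$
per strip and the number of strips $S$ in the image. The region is
divided into $S$ equal-width columns and $2L - 1$ equal-height rows:
between every pair of adjacent lines an extra rectangle is inserted and
labelled *background*. These inter-line rectangles are pure membrane by
construction and are what the quantile background method samples. Two
lines on three strips therefore produce a $3 \times 3$ grid whose middle
row is background.

Coordinates are 0-based, row-major, origin at the top-left pixel, with
half-open rectangles $[r_0, r_1) \times [c_0, c_1)$ — stated once and
used everywhere. Equal subdivision assigns remainder pixels to the last
row/column; irregular band spacing is supported through explicit
boundary fractions in the configuration. An interactive tool would let
the user drag grid lines instead; headless operation needs a
deterministic rule, and equal subdivision is that rule.

## Background correction

Four threshold methods are provided, chosen per strip:

* **Otsu** — exhaustive search over the 255 interior boundaries of a
  256-bin histogram for the split maximizing the between-class variance
  $\omega_0\omega_1(\mu_0-\mu_1)^2$. Best for bimodal histograms
  (strong bands). Ties break to the smallest threshold.
* **Li** — minimum cross-entropy, via the fixed-point iteration
  $t' = (\mu_{\le t} - \mu_{>t}) / (\ln \mu_{\le t} - \ln \mu_{>t})$
  started from the global mean and stopped when the step falls below
  `tol` ($10^{-6}$ by default, 100-iteration cap). Because the update
  takes logarithms of class means, images containing zeros are shifted
  up by $1/512$ (half an 8-bit grey level) and the shift is removed from
  the result.
* **Quantile** — an empirical quantile (R's default linear-interpolation
  definition) of the background-rectangle intensities of the selected
  strip; the default probability is 0.75, a deliberately conservative
  upper-quartile background estimate. Requires $L \ge 2$.
* **Triangle** — geometric search suited to unimodal, skewed
  histograms: a line is drawn from the histogram peak to the farthest
  nonzero tail bin on the longer side, and the threshold is the bin with
  maximal perpendicular distance below that line. Since perpendicular
  distance depends on axis scaling, counts are normalized by the peak
  count and bin positions by the peak-to-tail span before the search.

Otsu/Li/triangle pool **all** pixels of the selected strip (line and
background cells); the quantile method by definition uses only the
background cells. An additive offset, clipped back to $[0,1]$, refines
any computed threshold. Histograms use 256 bins for comparability with
8-bit imagers; this is configurable.

### Line signal statistics

For each line cell, pixels above the threshold are the signal; the
threshold is subtracted and the mean and median of the subtracted
values are reported together with the above-threshold count
(`n_above`). Two variants sit behind a switch:

* `statistic_on = "raw"` skips the subtraction;
* `statistic_on = "subtracted_all"` averages the clipped subtraction
  $\max(p - t, 0)$ over *all* cell pixels.

The distinction matters for a subtle reason. The default survivor-only
mean is **not** exactly monotone in the threshold: raising $t$ both
shrinks each surviving pixel's value (pushing the mean down) and evicts
the weakest survivors (pushing the mean of the remainder up). On
realistic strip renders the net effect is monotone at practical offset
granularity (0.05 steps), but fine threshold sweeps can show up-ticks on
the order of $10^{-3}$. Two related quantities are exactly monotone and
are the ones the test suite pins down as theorems: the per-line *total*
signal $\sum_{p>t}(p-t)$, and the `subtracted_all` clipped mean. Users
who need a strictly monotone per-line statistic should use the clipped
variant; the default matches the natural reading of "mean intensity of
the pixels above the threshold".

Bright-band assays (fluorescent labels) are handled by inversion
($p \mapsto 1-p$) before thresholding, making bright-band and dark-band
analyses exactly dual.

## Calibration

Responses are built from per-line signals of a wide (one row per
strip) table. The supported forms are the ones in field use: a single
line (`tl`), a ratio (`tl/cl`, `cl/tl` — ratios cancel run-to-run
intensity variation), and the normalized fraction `tl/(tl+cl)`. Rows
with zero denominators are dropped and counted rather than propagated
as infinities. Ratios are computed per row first and averaged across
technical replicates afterwards (switchable), since the ratio of means
and the mean of ratios differ under replicate variation.

Three model families cover the practical range:

| kind              | engine                 | when to use                          |
|-------------------|------------------------|--------------------------------------|
| `linear`          | ordinary least squares | short concentration ranges           |
| `local_poly`      | degree-2 loess, span 0.75 | smooth curvature, enough points   |
| `spline_additive` | penalized cubic regression spline, GCV | flexible monotone-ish curves |

$R^2$ is reported for the linear family only — for the smoothers it is
not a meaningful goodness-of-fit summary. An optional $\log_{10}$
concentration axis serves calibrations spanning decades; blanks are
excluded from a log fit but still feed the detection limits. The
smoother needs at least 5 distinct concentrations, the line at least 2.

### Detection limits

The limits are computed in the response domain from blank replicates
and mapped to concentrations through the fitted curve:

$$\mathrm{LOB}_y = \bar y_{blank} + 1.645\, s_{blank}, \qquad
  \mathrm{LOD}_y = \mathrm{LOB}_y + 1.645\, s_{low}, \qquad
  \mathrm{LOQ}_y = \bar y_{blank} + 10\, s_{blank},$$

with $s_{low}$ the SD of the replicates at the lowest nonzero
concentration (falling back to $s_{blank}$). 1.645 is the one-sided 95%
normal quantile; 10 is the conventional signal-to-noise requirement for
quantification. Both multipliers are configurable. Three deliberate
design choices:

* For calibrations that *decrease* with concentration (`cl/tl`-style
  responses) the multiples are applied downwards, so the limit
  responses always lie in the direction of increasing concentration —
  the literal "add" would place them outside the curve's reach.
* The LOQ is floored at the LOD: with few replicates the SD at the
  lowest concentration can exceed five times the blank SD, which would
  put the raw LOQ below the LOD; quantification is never claimed below
  detection.
* A limit whose response falls beyond the calibrated range is reported
  as `"> x_max"` rather than extrapolated.

At least two blank replicates and a strictly monotone fitted curve are
required; otherwise the limits are reported unavailable, never guessed.

## Inverse prediction

The linear model inverts in closed form. Smoothers are inverted by
bisection on the calibrated range to $10^{-8}(x_{max}-x_{min})$ —
valid because inversion is refused for curves that are not strictly
monotone there (checked on a 201-point grid). Out-of-range responses
are clamped to the nearest endpoint and flagged (`above_range` /
`extrapolated`) instead of extrapolated — the conservative behaviour
for a diagnostics context; responses below the detection limits carry
the implication-ordered flags `below_LOB ⊆ below_LOD ⊆ below_LOQ`.

Models serialize to a small JSON document. The linear model stores its
coefficients; smoothers store their training points and
hyperparameters and are refit on load, which is deterministic and
reproduces predictions exactly, unlike attempting to freeze fitted
internal state.

## The synthetic strip generator

Real assay images from the development of this kind of system are not
redistributable, so validation runs on synthetic strips with known
ground truth: a uniform background $b$, horizontal bands with Gaussian
cross-section ($\mathrm{pixel} = b \pm \sum_j a_j
e^{-(r-c_j)^2/2\sigma^2} + \varepsilon$), additive Gaussian pixel noise,
clipping to $[0,1]$, and bit-identical reproducibility from a seed.

Defaults, chosen once as a plausible phone-camera crop of a two-line
strip: 90 × 30 px per strip, band $\sigma$ = 3 px, band centers at the
centers of the grid's line rows, background 0.10, pixel noise SD 0.02
(about 5 grey levels of an 8-bit camera), bright bands. Calibration
series use a linear amplitude response of 0.07 per concentration unit
over concentrations 0–8 (peak amplitude 0.56, comfortably below
clipping), 3 replicates, and a between-replicate amplitude jitter of
SD 0.005 emulating run-to-run variation.

The generator reproduces the features the analysis depends on — band
geometry, monotone amplitude response, pixel noise, polarity, optional
RGB tint — and deliberately not those it does not: membrane texture,
flow fronts, lighting gradients, perspective distortion. Passing tests
therefore demonstrate the correctness of the *analysis chain*, not
robustness to photographic artifacts; the editing operations (rotate,
flip, crop) exist precisely because real photographs need manual
geometric normalization first.

## Validation scale and numerical choices

The test suite validates each stage against independent oracles:
thresholds against exhaustive brute-force searches (100 random 64 × 64
images for Otsu/triangle, exact bin agreement), Li against its
closed-form fixed point on a two-level image
($t = -0.6/\ln(0.25) \approx 0.4328$), calibration against simulated
parameter recovery (100 runs of 8 concentrations × 3 replicates at
noise SD 0.05: mean absolute slope error, 95% CI coverage), and the
full simulate → analyze → calibrate → quantify chain against its own
ground truth (noise-free: $R^2 \ge 0.999$, median concentration error
below 1%; default noise: below 10% at mid-range). These problem sizes
keep a full run in the order of a minute on one CPU while leaving the
Monte Carlo margins wide relative to the assertions.

Tie-breaks and degenerate inputs are fixed deterministically: Otsu and
triangle break ties towards the smaller threshold; constant images are
a refusal (no separating threshold exists), not a silent zero; lines
with no above-threshold pixel report zero signal and are logged;
single-line grids make the quantile method unavailable by construction.

## Known limitations

* No automatic band/strip detection — the grid is user-specified, as in
  interactive practice.
* No local/adaptive thresholding or illumination-gradient correction.
* No nonlinear parametric calibration (4PL/5PL) and no weighting or
  outlier rejection; use the smoothers where the response saturates.
* No uncertainty propagation onto estimated concentrations.
* JPEG input is supported but lossy; PNG/TIFF round-trip exactly.
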