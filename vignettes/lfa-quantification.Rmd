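---
title: "Quantifying lateral flow assay strips from images: methods and design"
author: "lfaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lateral flow assay strips from images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfaquant)
```

## The measurement problem

A lateral flow assay (LFA) strip develops two coloured bands: a test line
whose darkness increases with the captured analyte — here modelled on
active neutrophil elastase (NE) in sputum, a biomarker whose high levels
flag patients at risk of respiratory exacerbations — and a control line
that must always form for the test to be valid. Visual reading is
semi-quantitative at best; a grayscale image from a low-cost CMOS reader
lets the band darkness be measured, calibrated and inverted into a
concentration estimate.

`lfaquant` implements this chain and, because no public image set exists
for the target assay, ships a synthetic phantom generator that renders
strips with known ground truth. Every stage is therefore testable at desk
scale, and all empirical statements in this vignette are recomputed by the
package's own test suite.

## Image analysis

**Profile extraction.** The image is converted to grayscale (RGB inputs
use BT.601 luminance weights 0.299/0.587/0.114, rounded half-up; the
native capture mode of the emulated readers is grayscale, so any fixed
standard works and this one is documented), cropped to a region of
interest (0-based, half-open coordinates — an unambiguous slicing
contract), and collapsed into a 1-D profile by averaging the transverse
pixels at each position along the flow axis. Averaging `h` pixels shrinks
independent pixel noise by `1/sqrt(h)`; with the default RoI height of 40
and pixel noise sd 2 counts, the profile noise sd is ≈ 0.32 counts.

The flow axis defaults to the image width (profiles run left to right,
test line upstream of control); a flag flips it for rotated mounts.

**Smoothing.** A centered moving average (default window 5 px, clipped at
the edges) is applied before minimum search. Whether the original onboard
readers smoothed beyond transverse averaging is not documented anywhere we
know of; smoothing is therefore exposed as configuration, with window 1
disabling it. Smoothing shrinks a Gaussian dip of sd 6 px by ≈ 2.7%, which
cancels in the Test-Control ratio (both bands shrink alike) but slightly
raises the other two ratios; tests that check quantisation-exact values run
unsmoothed.

**Line detection.** The control line is the profile minimum inside a
configurable search band (default fractions 0.55–0.95 of the profile
length). A global minimum scan would be simpler, but above the
concentration where the test band becomes darker than the control band it
would lock onto the wrong line; restricting the scan is justified by the
mechanically fixed strip position in a reader. The test line is then the
minimum of a window centered a fixed offset upstream of the detected
control line (default offset 60 px, half-width 15 px). Ties break to the
smallest position, making detection deterministic; a profile that is
constant across the control search band aborts the measurement, since a
missing control line invalidates the strip.

The line *value* is the single minimum sample, not an average over the
band — the literal reading of a minimum-scan algorithm. On blank strips
this makes the windowed minimum biased slightly low in noise; the bias is
bounded in tests rather than corrected, and is small relative to the
replicate-to-replicate amplitude variation that dominates the error
budget.

**Background and ratios.** The background is the mean profile value
strictly between the two lines, excluding a margin (default 18 px = 3 band
sigmas) around each so band tails do not leak in; at least 5 positions
must remain. The three ratios are

* `ratio_tb = test_value / background_mean`
* `ratio_cb = control_value / background_mean`
* `ratio_tc = test_value / control_value`

so `ratio_tc = ratio_tb / ratio_cb` identically. Ratios are invariant
under any multiplicative illumination change (all three numerators and
denominators scale together) — the practical reason strip readers report
ratios rather than raw minima. Visible lines give ratios below 1 that
decrease as lines darken.

## Calibration and inverse prediction

Per-concentration replicate ratios are summarised by their mean and sample
standard deviation (n − 1; zero for singletons), and an unweighted
least-squares quadratic `r(c) = a0 + a1 c + a2 c²` is fitted to the means
(a weighted fit is available behind a flag). Only calibration points
inside the requested working range enter the fit; the default range is
[0, 600] ng/ml, the span over which the dose-response is close to linear
before it plateaus. Plateau-region points would drag the quadratic and
bias low-concentration inversion, so they are excluded.

**The decreasing-limb rule.** A quadratic fitted to a saturating response
is typically an upward-opening parabola whose vertex — the point where the
fitted curve stops decreasing — can fall *inside* the requested range
(with the default phantom it lands near 440–480 ng/ml). Inversion beyond
the vertex is meaningless, so the stored working range is trimmed to the
vertex and inversion is restricted to the decreasing limb. A fit that is
not decreasing at the lower end of the range is rejected outright
(`non_monotone_calibration`): that is not a saturation artifact but a
response that cannot calibrate a darkening line. The trimmed bound is
reported by `print()` so the operating range is never silent.

**Inverse prediction.** A measured ratio is mapped through the quadratic
formula to the unique root on the working range. Ratios lighter than the
curve's blank value are censored `below_working_range` (estimate clamped
to the lower bound); ratios darker than the curve value at the upper bound
are censored `saturated` (clamped to the bound) rather than extrapolated —
in the saturation region the response carries almost no concentration
information, and a clamp with an explicit censoring label is more honest
than an extrapolated number. Near-zero curvature (|a2| < 1e-14) falls back
to the linear solution.

**Limit of detection.** The package operationalises the qualitative
"replicate spreads stop overlapping" criterion as: the smallest grid
concentration whose ratio separates from the blank by more than
`k · σ_r`, with defaults `k = 2` and `σ_r = 0.07` (a typical
replicate-ratio sd for this class of strip and reader). On noise-free
default phantoms over the grid {0, 25, 50, 100, 200, 400, 800} ng/ml the
rule returns 100 ng/ml: the gap at 50 ng/ml is ≈ 0.11 < 0.14 while the
gap at 100 ng/ml is ≈ 0.19 > 0.14. Both constants are configuration; the
rule is monotone in each.

**Risk and bands.** Clinically, NE above 250–300 ng/ml marks high
exacerbation risk; the package takes the floor, 250 ng/ml, inclusive, as
its default threshold. Visual band boundaries (negative < 109, low
109–370, high ≥ 370 ng/ml) are an invented interpolation: they are the
midpoints of the gaps between the vendor's stated visual groups (negative
up to 87, low 131–296, high from 444 ng/ml), and are configurable.

## The synthetic phantom

The generator renders
`background + illumination ramp − control band − test band`, each band a
Gaussian cross-section along the flow axis, constant transversely. The
test-band depth follows a saturating (Langmuir) law
`amp_max · c / (c + k_half)` — the simplest law that is proportional to
concentration at low `c` (colour formation proportional to captured
analyte) and plateaus at high `c`, as real strips do.

Defaults and the reasoning behind them:

| parameter | default | why |
|---|---|---|
| image | 640 × 480 px, 8-bit grayscale | the emulated sensor's capture mode |
| RoI | 200 × 40 px (flow × transverse), centered | strip window at this working distance |
| background_level | 200 counts | bright unstained membrane, headroom below 255 |
| band_sigma | 6 px | sharp but resolvable band at this scale |
| line_spacing | 60 px | well-separated bands with a usable background stretch |
| amp_max / control_amplitude / k_half | 160 / 80 / 300 ng/ml | makes the test band exactly as deep as the control band at 300 ng/ml, reproducing the field observation that a Test-Control ratio of 1 sits at ≈ 300 ng/ml |
| pixel_noise_sd | 2 counts | shot/read noise; profile sd ≈ 0.32 after averaging |
| strip_jitter_sd | 0.07 | strip-to-strip line-intensity variability; one multiplicative factor per strip applied to both bands |

All geometry is invented: the assay vendor publishes no band widths,
spacings or intensity depths, so these are plausible values, chosen once
for testability and clearly labelled as synthetic. The default
concentration ladder (0, 39, 58, 87, 131, 197, 296, 444, 667, 1000 ng/ml)
is a 1.5-fold dilution series reconstructed to pass through every
concentration the vendor's visual grouping names.

**What the phantom emulates:** the concentration-darkness law with
saturation, per-strip amplitude variability, pixel noise, quantisation,
optional illumination ramp and misalignment.
**What it does not:** membrane texture and wicking artifacts, non-Gaussian
band shapes, correlated (structured) noise, independent test/control
variability (the jitter factor is shared, so Test-Control ratios are
somewhat cleaner in the phantom than on real strips), and colour-channel
physics. Passing tests therefore demonstrate the *algorithm* is correct
and robust under the modelled perturbations — not that a particular real
reader meets these error bounds.

## Numerical choices

* Quantisation is round-half-up, then clipping to [0, 255]; `base::round`'s
  half-to-even rule is deliberately not used for counts.
* All coordinates are 0-based and half-open; profile positions are
  relative to the analysed RoI.
* Minimum-search ties break to the smallest index (determinism).
* Per-strip seeds in a dilution series derive from a stable arithmetic
  hash of (root seed, concentration index, replicate index), so series are
  reproducible element-wise and extending the ladder never reshuffles
  existing strips.
* The per-strip jitter factor is a truncated normal on (0, 2] drawn by
  rejection; at the default sd (0.07) truncation is inconsequential.
* Degenerate inputs fail with classed conditions (`no_control_line`,
  `test_window_out_of_profile`, `background_too_small`,
  `non_monotone_calibration`), and the full-strip analyser tags failures
  with the stage name.

## Problem sizes

The simulated study uses the 10-point ladder with 5 replicates
(50 strips), matching a realistic bench protocol. Monte-Carlo checks in
the test suite use 50–100 seeds on a reduced sensor
(260 × 50 px with the same RoI geometry), 1000 random profiles for the
detection oracle, and a recovery experiment of 50 calibration plus 80
quantification strips — sizes chosen so the full suite exercises every
stochastic claim while remaining a sub-minute run.

## Known limitations

* v1 detects exactly one test line; multiplex strips would need the
  windowed search repeated per expected line.
* No rotation/perspective correction: the phantom's misalignment knobs
  exist to *create* such data, but the analyser assumes an aligned strip.
* The quadratic is a local empirical calibration; a four-parameter
  logistic would extend the usable range into the plateau but is out of
  scope here.
* Quantification above the (possibly trimmed) working range is reported
  only as `saturated`; users needing the 600–1000 ng/ml region should
  calibrate with a model that does not flatten there.
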