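---
title: "Methods: pulsatility and clearance quantification in pvq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulsatility and clearance quantification in pvq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices and numerical
decisions behind `pvq`, in the spirit of a methods section: what each
quantity means, what the implementation assumes, and where a design was
genuinely open, why we chose what we chose.

```{r setup, message = FALSE}
library(pvq)
```

## Vascular pulsatility

### Model

A line scan placed orthogonal to a vessel produces a kymograph: rows are
positions along the scan line, columns are successive time lines. With an
intravascular dye the lumen is bright, so at each time line the diameter
D(t) is the width of the bright band. From D(t) and its moving-average
baseline d(t) we compute, per 3000-ms epoch,

$$\textrm{PI} = \int_0^{3000} |D(t) - d(t)|\,dt \quad [\mu m \cdot ms],
\qquad
\textrm{rPI} = \int_0^{3000} \left|\frac{D(t) - d(t)}{\overline{D}}\right| dt
\quad [ms],$$

where $\overline{D}$ is the static mean diameter over the whole record. PI
captures the absolute extent of wall movement without encoding vessel size
(important when the pathology itself changes diameters); rPI expresses the
same movement relative to caliber. Multiple complete epochs are averaged;
an incomplete trailing epoch is discarded. How several epochs should
combine is an open choice; the mean is the least surprising and keeps the
unit of the per-epoch quantity.

Assumptions: the lumen is brighter than the background (angiography
convention); wall motion is slow relative to the line rate; the pulse lives
in the cardiac band (≈5–10 Hz in mouse) well below the line rate.

### Wall detection

Per time line, the spatial profile is smoothed with a 1-px gaussian and the
diameter is the distance between the two crossings of the half-maximum
level (midway between the profile's min and max), with linear sub-pixel
interpolation between pixel centers. Half-maximum is the right level for a
blurred edge: symmetric blurring of a step does not move its half-maximum
crossing, so the estimate is robust to moderate defocus. A fixed-level
threshold method is available as an alternative. Lines without a crossing
pair are flagged invalid, never imputed; a trace with more than 20% invalid
lines is rejected with a diagnostic. Within an epoch, invalid samples are
excluded with the time base renormalized if they are under 5% of the epoch,
otherwise the epoch is rejected.

### Smoothing

High-frequency content (photon noise propagated through edge detection) is
removed from D(t) by a zero-phase 2nd-order Butterworth low-pass, default
cutoff 25 Hz — far above the mouse cardiac band, so the pulse is untouched.
Zero-phase (forward–backward) filtering avoids lag that would otherwise
bias |D − d|. The trace is extended at both ends by odd (point-symmetric)
reflection before filtering; this keeps value and slope continuous at the
boundary and suppresses the edge transients that plain or even-reflection
padding produce.

### Moving-average baseline and its edge policy

The baseline d(t) is a centered moving average, default window 500 ms —
several cardiac periods, long enough to be flat across the pulse, short
enough to track slow drift (vasomotion, focus drift). The window is
recorded in the result because the index depends on it.

Near the record ends the full window does not fit. We evaluated shrinking
the window there and found it leaks pulse phase into the baseline: the
truncated window no longer averages whole pulse cycles, so d(t) oscillates
with the pulse near the edges and |D − d| is biased over a region the size
of half a window at each end. The default policy therefore **holds** the
baseline at the nearest full-window value, which keeps d(t) free of
cardiac-band content everywhere; the `"shrink"` policy is retained for
comparison, and the policy in force is recorded in the trace provenance.
With the hold policy, the discrete integral of a noiseless unit sinusoid
over 3000 ms reproduces the analytic value $3 \cdot (2/\pi) \cdot 1000$
µm·ms to well under 1% (the acceptance suite asserts 3%), and both indices
are invariant under time reversal of whole-epoch records.

### Discretization

The integral is a rectangle (Riemann) sum with Δt equal to the line period.
The test suite compares it against an independent trapezoidal integration;
on records of thousands of samples the two differ by well under 0.1%, which
bounds the discretization error.

## Immunofluorescence quantification

Vessel wall masks are formed by merging the SMA and MX04 channels —
pixel-wise maximum by default, so the wall is outlined whether it retains
smooth muscle or has been replaced by amyloid — and thresholding inside the
freehand vessel ROI. Coverage of a channel is the percentage of mask pixels
positive in that channel. Vascular density is the collagen-IV-positive
percentage of a fixed 0.4 mm × 0.4 mm square, size-standardized so it is
comparable across images. Plaque burden is the thresholded fraction of the
background-subtracted MX04 channel over a brain region, times 100.

Thresholds are policy objects — fixed value, Otsu, or a quantile — and the
resolved value is always recorded in the result. For cross-image
comparability (plaque burden across a cohort) a fixed value is the right
choice; Otsu is convenient within a single image. Whether one threshold
should apply per image or globally across animals is a genuinely open
choice in such analyses, so both modes are expressible and the recorded
value makes either auditable. Background subtraction uses the median of a
designated background region (outside the brain mask, or user-supplied);
the median of a plaque-sparse region reads the parenchymal floor robustly.

Masks follow the pixel-center rule (a pixel belongs to a polygon if its
center is inside), which is deterministic and matches the rasterization
used by the synthetic generator. Line profiles are sampled by bilinear
interpolation at ≤ 0.5 px steps.

## Clearance mapping

**Tracer-positive artery counts.** Connected components of the thresholded
SMA channel, above a minimum area (default 20 px), are accepted when at
least 30% of their pixels are tracer-positive. The original criterion in
this kind of analysis is a manual judgment; 30% colocalization and the area
floor are declared, configurable stand-ins, and the per-component audit
table (area, overlap fraction, accepted) is returned so any threshold can
be revisited. Counts are monotone non-increasing in every threshold, which
the tests assert.

**Whole-slice influx.** The brain slice is one ROI; the mean and integrated
background-subtracted tracer intensity are both reported, since whether
"signal" should be mean or integrated intensity is ambiguous — emitting
both costs nothing. Estimating background from within the image makes the
result invariant to a constant offset, which the tests assert.

**Penetrating vessels.** The two tracer channels are merged (max),
thresholded within the cortical band, and components are accepted when
elongated (aspect ratio ≥ 2, from second central moments with a 1/12 pixel
variance correction) and oriented within ±30° of the local cortical normal
(the radial direction at the component centroid). "Perpendicular to the
cortex" is again a manual criterion in practice; ±30° and aspect 2 are the
declared defaults, both configurable.

**Regional analysis.** The cortical band is split at two landmark angles
measured from the dorsal midline — stand-ins for the anatomical boundaries
at the primary somatosensory and piriform cortex. Landmark placement is an
input, not inferred: automatic atlas registration is out of scope, and an
explicit angle pair makes the partition deterministic and testable (the
three masks are asserted to be a pixel-exact disjoint cover of the band).
Linearization unrolls the band along arclength from the midline and
averages each channel in angular bins, turning a dorsoventral gradient into
a 1-D profile.

## Regression and summaries

The burden–influx relation is fit by OLS of influx on burden over all
slice × region rows, pooled — each slice contributes its three regions as
separate points. Pooling is the interpretation that matches a cohort of
7 slices × 3 regions per animal; a stratified per-region mode is also
provided since the pooled fit mixes between-region and within-region
variation. `glance()` reports slope, intercept, slope SE, R², p, residual
sd and n; the 0.05 significance convention is reported downstream, never
used to drop data. Group summaries emit mean ± SEM and n per group and
leave inferential testing (ANOVA, post hoc corrections) to standard
routines.

## The synthetic-data module

The generators define the study conditions under which the pipeline is
verified:

- **Kymographs** — D(t) = baseline + amplitude·sin(2πft) + drift·t,
  rendered as an area-weighted bright band (edge pixels carry the exact
  sub-pixel overlap fraction, so sub-pixel tracking is testable), optional
  gaussian wall blur, gaussian or Poisson noise. Defaults: 10 µm baseline,
  7 Hz pulse, 1 ms line period (≈1 kHz line rate, typical for two-photon
  line scans), 0.25 µm pixels. A sinusoid at cardiac frequency is the
  minimal waveform that exercises both indices; real pulse waveforms are
  not sinusoidal, and no hemodynamic model is attempted.
- **Slice images** — ring vessels whose SMA arc covers a specified fraction
  of the wall and MX04 the complementary arc (mimicking amyloid replacing
  smooth muscle), a random-segment collagen network drawn to a target area
  fraction, random-disk plaques to a target burden, tracer-filled vessels,
  and vertical penetrating-vessel stripes. The achieved (pixel-counted)
  fractions are returned as ground truth, so recovery tests compare against
  what was actually rasterized.
- **Coronal slices** — a disk brain with an annular cortical band carrying
  region-constant tracer plateaus (ventral > lateral > dorsal by default),
  per-region plaque targets running the opposite way (dorsal 4%, lateral
  2.5%, ventral 1%), radial tracer stripes crossing the band, and a uniform
  background floor over the whole canvas so the outside-brain region is a
  faithful background reference.
- **Regional tables** — per slice × region draws around region means
  (3-kDa influx 30/20/10 a.u. ventral/lateral/dorsal, 40-kDa 24/16/8,
  within-region sd 2 a.u.; burden means as above, sd 0.4 pp; 7 slices),
  values clipped at zero with the clip count flagged. These values are in
  arbitrary units chosen once to give gradients comfortably larger than
  noise, as in a well-powered tracer experiment; `generative_slope()`
  exposes the implied population regression slope as the recovery oracle.

All generated images are quantized to a 16-bit grid at generation time, so
TIFF serialization round-trips losslessly and repeated runs under one seed
are bit-identical. Every generator routes randomness through its spec's
seed without disturbing the caller's RNG state.

What passing tests do **not** show: the generators use piecewise-constant
region plateaus, circular geometry, sinusoidal pulses and
gaussian/Poisson noise. Real slices have anatomy-dependent gradients,
autofluorescence structure, uneven illumination and registration error;
real kymographs have motion artefacts and flowing-cell shadows. Recovery
on synthetic data validates the arithmetic and the geometry of the
pipeline, not its robustness to those artefacts.

## Problem sizes and degenerate inputs

The test suite runs on deliberately small instances: 3000–7500-sample
traces, 50 random traces for the integration oracle, 400×400 px slices,
360×360 px coronal slices, cohorts of 3–7 slices, and regional tables up to
300 slices for the permutation null. These sizes keep the full suite under
a couple of minutes while leaving every tolerance comfortably binding.

Degenerate inputs are contracts, not surprises: an all-zero kymograph or
one with >20% undetectable lines is rejected with a diagnostic; a window
longer than the record, an empty vessel mask, a zero-length polyline,
landmarks out of order, zero-variance burden and traces shorter than one
epoch are all errors naming the violated requirement; landmark placements
that empty a region warn and flag rather than fail.

## Known limitations

- Wall detection assumes a single bright lumen per scan line; vessels
  crossing the line twice need separate ROIs upstream.
- The cortical partition assumes a band parameterizable by angle around a
  center point; strongly folded cortex would need a curvilinear
  parameterization.
- The pooled regression treats slice × region rows as exchangeable;
  per-animal random effects are out of scope.
- No automated vessel segmentation, atlas registration, z-stack handling,
  or spectral (vasomotion-band) analysis.
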