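---
title: "Methods: granule quantification and RNA decay kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: granule quantification and RNA decay kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mitogranule)
```

This vignette is the package's account of its methods: the models, the
parameters that matter, the numerical choices, and what the synthetic data
do and do not establish about real data.

## The problem

Arresting mitochondrial transcription makes mitochondrial mRNAs collapse
from a diffuse distribution along the mitochondrial network into discrete
clusters ("inhibition granules"), and changes their degradation kinetics.
Two independent measurement arms capture this:

1. an **imaging arm** that turns RNA-FISH fields into per-cell granularity
   statistics and condition-level tests, and
2. a **counts arm** that turns transcript count time courses into early/late
   half-lives, a decay-mode classification, and 4sU labeling summaries.

Both arms are driven end-to-end by a synthetic-data generator with exported
ground truth, which is what the test suite and the acceptance script run on.

## Imaging arm

### Flat-field correction and projection

Empty-well fields acquired with the sample's settings are averaged
pixelwise; the camera error is handled as a dark offset `dark` (scalar or
frame, default 0) subtracted from both the sample and the averaged flat
before division:

    corrected = (sample − dark) / max(flat − dark, ε),   ε = 1e-6 · max(flat)

Whether the original acquisition subtracted a measured dark frame or a
constant camera bias is not recoverable; both are supported and neither is
asserted. Pixels clamped at ε are counted in the `clamped_px` attribute.
Correction is applied per z-slice and per channel before the sum
z-projection, which conserves total intensity to machine precision. All
arithmetic is double precision regardless of input bit depth; TIFF I/O uses
a fixed counts scale (stored sample = value / 65535) at 16 bits for count
images and label maps and 32 bits for corrected images.

### Segmentation

The RNA channel is rescaled to [0, 1] over its full intensity range and the
detection chain is:

1. **Kirsch compass enhancement** — maximum over the 8 rotations of
   `[[5,5,5],[−3,0,−3],[−3,−3,−3]]` correlated with the image, reflect
   padding, negatives clamped to 0. The test suite checks exact agreement
   with a naive 8-kernel loop oracle.
2. **Minimum cross-entropy (Li) threshold** on the enhanced image, after
   Gaussian smoothing with σ = `smoothing_scale / 1.3488` px — the scale
   convention of the original analysis software, so the default scale
   1.3488 means σ = 1 px. The iteration starts at the image mean, updates
   `t ← (μ_b − μ_f)/(log μ_b − log μ_f)` with μ_b, μ_f the means below and
   above `t`, and stops at |Δt| < 0.5/65535 (max 200 iterations). The
   estimate is multiplied by the correction factor (default 1) and clamped
   to the bounds (default (0, 1)). Tests require the iterative estimate to
   sit within one 8-bit gray level of exhaustive minimisation of the
   cross-entropy objective over 256 candidates. Thresholding the
   *enhanced* image detects edge rings; hole filling (below) recovers spot
   interiors. That ordering is an assumption — the source description
   enhances borders and then detects primary objects.
3. **Declumping** — seeds are local maxima of the Gaussian-smoothed
   intensity inside the mask, thinned to a minimum mutual distance; labels
   grow from the seeds by intensity-weighted propagation, so dividing lines
   fall along intensity valleys. The declumping intensity defaults to the
   enhanced image (the same image that drove detection); the original
   channel is available via `declump_on = "original"`.
4. **Hole filling** — per object, then for background enclosed jointly by
   several objects (a clump split into arcs) by growing the surrounding
   labels inward.
5. **Measurement** on the *original* channel: pixel-count area, integrated
   intensity, intensity-weighted 0-based centroid. No size gate by default.

"Automatic" declumping parameters are not reproducible from the original
description. The package default resolves them to σ = 1 px and minimum seed
distance `max(2, 0.5 · median equivalent diameter of the mask components)`.
That rule is sensible for blob-like objects but overestimates the distance
when several diffraction-limited spots chain into one thresholded component
— the component diameter then reflects the clump, not the spot. For
puncta-scale work `puncta_segmentation_config()` therefore fixes the seed
distance at 3 px (about half a spot diameter at this pixel size), and the
simulator-facing pipeline uses it by default. Results on real data may
differ from the original software, whose automatic rule is unknown; both
parameters are explicit and overridable.

Objects are assigned to the cell of maximal pixel overlap (ties: larger
fraction of the cell covered, then smaller label); unassigned objects get
parent 0 and are excluded from per-cell metrics. Cell masks are hand-drawn
imports or simulator truth — automated cell segmentation is out of scope.

### Per-cell metrics and tests

- fraction of cellular area occupied = Σ child object areas / cell area;
- skewness g1 = m3 / m2^(3/2) with population central moments over all
  pixels of the cell mask (the convention of the common ImageJ measurement);
- normalized intensity = Σ child integrated intensities / cell area.

Cells with zero objects are retained with metric 0: dropping them would
bias the treated condition, where signal concentrates into few objects.
Constant-intensity cells have undefined skewness (NA with warning).

Comparisons are one-sided two-sample t-tests on the **raw** metric values
(log10 axes are display-only), area with alternative "less" and skewness
with "greater" for treated vs control, no multiple-testing adjustment. The
original wrapper's variance assumption is not recoverable; the default here
is Welch, with `var_equal = TRUE` for the pooled form — at the per-group
sizes used (dozens of cells) the two agree to the digits reported.
Skewness can be negative, so it is plotted on a linear axis by default;
raw values are always stored.

## Counts arm

### Model and estimator

Counts are normalized per sample to a reference transcript (GAPDH for the
decay series; c-MYC or spike-ins where appropriate), replicates are
averaged per timepoint *before* regression, and each window is fit by OLS
of log10(relative abundance) on time with a free intercept, the anchor
(first window timepoint, set to 100%) included in the fit:

    t_half = (log10 0.5 − log10 1) / slope = −log10(2) / slope

Windows: early {0, 2, 5} h anchored at 0 h; late {5, 8, 24} h anchored at
5 h. The measured timepoints were 0, 2, 5, 8 and 24 h and only the late
anchor is named in the source description, so the remaining points defining
the late window are an inference. Negative half-lives (increasing series)
are reported as-is, never clamped; a zero slope gives +Inf.

**Two-point fallback.** One published early fit used only the 0- and 5-h
points because the 2-h measurement increased. Algebra makes the trigger
worth documenting: for OLS over {0, 2, 5} anchored at 0, the slope sign is
the sign of `8·log10(y5) − log10(y2)`, so a raised 2-h point alone can
never produce a positive slope (negative half-life) while the 5-h point is
below the anchor. The package therefore attempts the fallback when the
three-point half-life is negative *or* an interior early timepoint lies
above the anchor, and adopts the two-point {0, 5} refit only if its
half-life is positive (`fallback_applied = TRUE`). A monotonically
increasing series fails the refit too and stays negative ("increasing").

**Classification.** "two-state" iff both half-lives are positive and
`t_late / t_early ≥ 4`; "increasing" if the early half-life stays negative;
"unstable" if only the late one is negative; otherwise "one-state". The
published call is qualitative; the ratio threshold 4 is a package choice
that separates the transcripts named as biphasic from the rest in the
EtBr series, and it is a visible, configurable parameter — not a published
constant. At that threshold the IMT1B series additionally classifies
MT-CYB (ratio 4.25) as two-state beyond the five transcripts named.

A reference table of published early/late half-lives for both inhibitors
ships in `inst/extdata/reference_halflives_published.csv`. The raw counts
behind it are not distributed, so `synthetic_counts_from_halflives()`
inverts the two-window model analytically (including a raised 2-h point for
the fallback row) to produce a *synthetic* count table whose fits must
reproduce every printed value within rounding; this round trip is part of
the test suite and the acceptance script. It validates the estimator
end-to-end, not the original raw data.

### 4sU labeling

The transient-transcription metagene is the mean over panel transcripts of
labeled count / labeled reference (mean of ratios — the literal reading of
"averaged relative counts"), per replicate and timepoint, then averaged
across replicates; a regression test pins the mean-of-ratios choice. The
95% ribbon uses the t-distribution across replicate means (df = n − 1);
the original ribbon's construction is not stated, and an across-transcript
alternative would be wider at these n. The panel defaults to the 13
mt-mRNAs as measured. The unlabeled (preexisting) pool is normalized to
the unlabeled spike-in (ERCC-00048 role) per sample and averaged across
replicates; log10 is display-only. Biotinylation-efficiency and
cross-contamination corrections are out of scope.

## Synthetic-data generator

The image forward model emulates, per field: non-overlapping cells as
radial-harmonic perturbed disks (harmonics 3–5, total amplitude ≤ 25% of
the radius, rejection-sampled placement); a nucleus disk at 35% of the
cell radius; a mitochondrial network as persistent random walks from the
nucleus boundary dilated to the configured width (only the 1-D support
topology matters for the metrics); RNA puncta on the network — uniformly
with a 5-px minimum separation in the diffuse state (resolvable
single-molecule spots), or scattered (σ = 3 px) around Poisson-many granule
centres in the granular state; signal scaled by a decay factor; then the
camera: Gaussian PSF (σ = 1.3 px) → multiplicative low-order illumination
field (radial, amplitude 0.2) → dark offset (100 counts) → Poisson shot
noise → Gaussian read noise (σ = 3 counts), written as 16-bit counts. One
RNG stream per generator call, seeded explicitly; identical parameters and
seed are bit-identical. Defaults (8 cells of radius 45–60 px per 512×512
field at 0.108 µm/px, 30 puncta per cell, ~2000-count spots) were chosen
once as typical of spinning-disk FISH acquisitions at 60×.

No published generative model of these granules exists; every forward-model
choice here is a stand-in. The generator does **not** emulate 3-D PSFs,
photobleaching, nucleoid or processing-granule biology, spot-intensity
heterogeneity beyond Poisson statistics, or cell-to-cell expression
variability; passing tests therefore show the *pipeline* is correct and
discriminative under controlled conditions, not that real images will
reach the same effect sizes. Count simulation follows
`A·(f·2^(−t/h_fast) + (1−f)·2^(−t/h_slow))·exp(ε)` with lognormal replicate
noise and constant reference/spike-in rows; the exported truth's
"effective" window half-lives come from closed-form OLS on the noiseless
curve, independent of the package's fitting code.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 200 simulated transcripts
(3 replicates, σ = 0.1) for parameter recovery; 6 fields of 512×512 px per
condition (≥ 40 cells each) for the discrimination tests; 20 seeded 64×64
images for the Kirsch/Li oracle checks; one 512×512 diffuse field (240
puncta) for detection scoring. Unit tests run on 192–256 px fields, where
the generator behaves identically. Other fixed choices: Li iteration
tolerance 0.5/65535; flat-field guard ε = 1e-6·max(flat); declump seed
ties broken by intensity order; 0-based (row, col) coordinates; areas in
pixel counts; 16-bit output clamped at 65535.

## Known limitations

- The original software's automatic declumping parameters are unknown;
  real-data segmentations may differ in clump splitting.
- Whether declumping used the enhanced or original intensities is not
  stated; the default (enhanced) is configurable.
- The two-state ratio threshold is a package convention; only the named
  transcript sets constrain it, and one additional transcript crosses it
  in the IMT1B series.
- The published-table round trip validates the estimator, not the original
  raw counts, which are not distributed with the package.
- Imaging statistics are property-based by necessity: the published
  per-cell tables are computed on real images not reproducible from text.
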