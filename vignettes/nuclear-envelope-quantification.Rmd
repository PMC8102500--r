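---
title: "Quantifying nuclear-envelope enrichment, FRAP mobility, colocalization and nuclear foci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear-envelope enrichment, FRAP mobility, colocalization and nuclear foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rimfrap)
```

# Scope and motivation

`rimfrap` implements the image-quantification readouts used to study the
redistribution of inner-nuclear-membrane proteins (such as the lamin B
receptor, LBR) between the nuclear envelope and the nucleoplasm in
differentiating muscle cells, together with the companion readouts that
typically accompany that question: FRAP mobility of envelope proteins,
per-cell Pearson colocalization with a 90° rotation control,
chromocenter counting in DAPI z-stacks, and proximity-ligation (PLA)
focus counting. Raw microscopy of the original experiments is not
publicly deposited, so the package ships a synthetic-microscopy
generator that produces ground-truthed inputs for every stage. Every
estimator can therefore be validated against known truth, which is what
the test suite and `scripts/acceptance.R` do.

The generator is a first-class module, not a test fixture: its defaults
encode the acquisition conditions the pipeline is designed for, and all
verification below is run at those conditions.

# The NE:nucleoplasm ratio

For each nucleus the marker intensity is averaged over two disjoint
pixel sets derived from the segmented nucleus mask:

* the **rim band** — pixels whose Euclidean distance to the background
  lies in `(d, d + w]`, with rim offset `d = 0` px and width `w = 3` px
  by default;
* the **nucleoplasm core** — pixels at distance `> d + w`.

The readout is `ratio = mean(rim) / mean(nucleoplasm)`. Ratios strictly
above 1.2 classify a nucleus as *Nuclear envelope enriched*; everything
else, including a ratio of exactly 1.2, is *diffuse in the nucleus*.
The tie goes to "diffuse" because the enrichment rule is stated as a
strict "above"; the package documents and tests this convention rather
than leaving equality unassigned.

Numerical properties worth knowing:

* The ratio is invariant under multiplication of the intensity channel
  by any positive constant (both means scale alike) and is therefore
  insensitive to detector gain.
* Adding a positive offset (uncorrected camera background) moves the
  ratio monotonically toward 1. Background subtraction is **off** by
  default and available via the `background` argument; with a correct
  offset estimate it restores the gain-invariant ratio.
* Replicate aggregation happens before dispersion: the reported s.e.m.
  of the enriched fraction is computed across biological replicates
  (n = replicates, not cells).

Nucleus segmentation uses a global Otsu threshold on the DAPI channel by
default (a fixed threshold can be supplied), hole filling, 8-connected
labeling, a minimum-area filter and optional border exclusion. The
commercial software used originally is proprietary; Otsu was chosen as a
reproducible, assumption-light stand-in for a global intensity
detection. The rim band is anchored on whichever channel the caller
segments — DAPI for nucleus-anchored bands, a lamin channel for
envelope-anchored bands — since both anchorings are in routine use.

Verification runs 200 synthetic nuclei per contrast
`r` ∈ {1.0, 1.2, 1.5, 2.0, 3.0} at a signal-to-noise ratio of 10
(nucleoplasm level 100 a.u., Gaussian noise σ = 10 a.u.), 128×128 px
scenes with four nuclei each, through the full
segment-partition-measure pipeline, and requires the mean estimated
ratio within 5% of `r` and ≥ 95% classification accuracy whenever the
truth sits at least 0.2 from the 1.2 cutoff.

# FRAP analysis

## The double normalization

Traces are per-frame arithmetic means over three regions: the bleached
ROI, the entire fluorescent structure, and a camera-offset background
region. The normalized recovery is

$$N(t) \;=\; \frac{(I_\mathrm{bleach}(t) - I_\mathrm{bg}(t))\,/\,(I_\mathrm{bleach}(t_0) - I_\mathrm{bg}(t_0))}
                 {(I_\mathrm{total}(t) - I_\mathrm{bg}(t))\,/\,(I_\mathrm{total}(t_0) - I_\mathrm{bg}(t_0))}.$$

Dividing by the whole-structure trace cancels acquisition bleaching
exactly when bleaching is spatially uniform, and makes `N` invariant to
affine intensity rescaling of the acquisition. The reference `t0` is the
mean over all prebleach frames by default (lower variance); the single
last prebleach frame is available via `t0 = "last_prebleach"`, in which
case `N` at that frame is exactly 1. The background is subtracted
per frame, not as a single constant. Frames whose total-signal
denominator is not positive are excluded and counted, never silently
dropped.

## Recovery model

The fit family is a single-exponential, reaction-limited recovery

$$N(t) = D + (\mathrm{plateau} - D)\,(1 - e^{-kt}), \qquad
  M = \frac{\mathrm{plateau} - D}{1 - D},$$

with `D` the immediate postbleach depth, `k` the recovery rate (1/s),
`t_half = ln 2 / k`, and `M` the mobile fraction, bounded to [0, 1].
A single exponential is the simplest family consistent with monotone
saturating recovery curves and keeps `M` and `k` identifiable at the
default acquisition length (300 postbleach frames at 1 s). `D` is fixed
at the first postbleach value by default; co-fitting is available
(`fix_depth = FALSE`). Bleach-pulse frames are never fitted (the
generator acquires no frames during the pulse). A perfectly flat
postbleach trace is returned as `M = 0` with an undefined rate rather
than forcing a degenerate optimization.

One bias is inherent to the double normalization and documented rather
than hidden: the whole-structure denominator also carries the signal
destroyed by the bleach pulse, which inflates `N` by the factor
`1 / (1 - f(1 - D/P))` where `f` is the bleached fraction of the
structure. For the small bleach regions this pipeline targets
(`f ≈ 0.02` of the structure, mirroring a ~2.4 µm square in a whole
cell), the resulting bias on `M` is below one percentage point and well
inside the accepted recovery tolerance. Parameter recovery is verified
over 50 simulated series per condition, `M` ∈ {0.2, 0.5, 0.9} ×
`k` ∈ {0.01, 0.05, 0.2}/s, 2% trace noise, acquisition bleaching
alternating between 0 and 0.001/s: the median absolute error on `M`
must stay ≤ 0.05 and the median relative error on `k` ≤ 10%.

## Flow accounting and conservation

`flow_metric()` quantifies recovery of the bleached area *at the cost
of* the unbleached region: both ROI traces are background-corrected,
divided by the whole-structure bleaching factor, scaled by their pixel
areas, and the gain of the bleached ROI is matched frame-by-frame
against the loss of the unbleached remainder. In the generator, the
unbleached signal is constructed from exact conservation of the total,
so the residual `gain − loss` is pure floating-point error
(< 10⁻⁹ in the verification); on real data it measures how well the two
ROIs actually tile the structure. Whether "flow" means the normalized
curve or this transfer statistic is ambiguous in routine practice, so
both are emitted.

Drift is corrected before extraction by integer translation
registration (FFT cross-correlation on mean-subtracted frames against
the first frame). Pure-noise frames still get an offset, flagged by a
low-confidence warning.

# Colocalization with a rotation null

`compute_pcc()` is the sample Pearson coefficient over masked pixel
pairs; a minimum of 50 mask pixels bounds its sampling variance, and a
constant channel is an explicit error (the coefficient is undefined).
The null control rotates channel 2 by 90°: the channel is cropped to the
mask's bounding box, rotated about the box center by pure index
permutation (no interpolation, so histograms are preserved exactly and
four successive rotations restore the observed coefficient bit for
bit), and the coefficient is recomputed over the intersection of the
original mask with the rotated crop's footprint. The rotation center
and overlap rule are a package convention — deterministic and
interpolation-free — since rotating a non-square cell footprint admits
several geometries.

The generator's correlated pairs mix two smoothed Gaussian fields,
`z2' = ρ z1 + √(1−ρ²) z2`, then rescale affinely to non-negative
intensities; affine maps preserve the Pearson coefficient, so the
within-mask correlation equals ρ up to sampling error (exactly ρ for
|ρ| = 1, where the independent field is unused). With
`anisotropy = TRUE` the fields are smoothed far more strongly along `y`
than `x`, producing the elongated texture that makes the rotation null
informative: verification requires a median attenuation of the rotated
coefficient exceeding 0.3 over 50 seeds at ρ = 0.8. The paired
observed-vs-rotated comparison is a two-tailed paired t test; when every
pair is identical the p-value is reported as undefined with a note.

# Chromocenters and PLA foci

Chromocenter segmentation thresholds each nucleus at the 99.5th
percentile of its within-nucleus voxel histogram (whole-stack histogram
by flag), labels voxels strictly above the threshold with 26-connected
components, and keeps components with voxel volume in the inclusive
window [7, 2000]. Both bounds are inclusive and tested at exactly 7 and
exactly 2000; the inclusive reading was chosen because the filter is
stated as a min/max pair without strictness. The voxel calibration
(x = 0.075, y = 0.075, z = 0.029, "pixel" units) is carried as opaque
configuration and used only to report calibrated volumes next to raw
voxel counts — the filter itself operates in voxels, and the package
does not reinterpret the calibration's internal inconsistency with a
0.3 µm z-step.

A percentile threshold is scale-free (counting survives any intensity
rescaling) but has one structural consequence worth stating: objects
can only be isolated cleanly when they occupy less than
`100 − percentile` percent of the histogram voxels. Synthetic stacks
used for verification are sized accordingly; on real data, a nucleus
whose chromocenters exceed ~0.5% of its volume needs a lower
percentile, which is why the percentile is exposed.

PLA foci are counted per cell on 2D images (thin z-stacks are
maximum-projected first), with cells segmented from the reporter
channel; spots are 8-connected suprathreshold components passed through
an inclusive 2D area window. Two spots closer than the connectivity
resolution merge and count once — a documented limitation of
component-based counting. Counts are normalized by the mean count of a
single-antibody control condition, so the control's mean fold is 1 by
construction.

# Group statistics

`compare_groups()` exposes exactly the three designs used by these
readouts: two-group Student's t (Welch unequal-variance by default —
the equal-variance assumption is rarely defensible and never stated in
practice; `var_equal = TRUE` restores the classical test), one-way
ANOVA followed by all pairwise t tests with Holm step-down adjustment,
and Kruskal–Wallis for non-normal data. Normality is never auto-tested;
the caller chooses, and pairing keys are the caller's responsibility.
Stars follow *P* < 0.05 / 0.01 / 0.001. `holm_adjust()` validates and
delegates to the standard step-down implementation; the test suite
checks it against a definition-based oracle on all permutations of up
to five p-values, and calibrates the two-group test's type-I error on
1000 null replicates against the [0.04, 0.06] band at α = 0.05.

# What the synthetic data does and does not show

The generator emulates: elliptical nuclei with sharp boundaries on a
dark background; a rim shell of controllable width and contrast;
photobleach-and-recovery series with a mobile fraction, recovery rate,
acquisition bleaching and frame drift; channel pairs with controllable
correlation and anisotropy; and punctate foci of exact voxel volumes.
Noise is additive Gaussian by default with optional Poisson shot noise
(both regimes are testable; Gaussian keeps closed-form tolerances), and
identical specs with identical seeds are bit-identical.

It deliberately does **not** simulate a point-spread function, 3D light
propagation, chromatin texture, intensity gradients across the field,
or touching nuclei. Passing tests therefore demonstrate estimator
correctness — unbiasedness, invariances, exact geometry, calibrated
error rates — under the stated conditions; they do not demonstrate
robustness to blur-induced rim spreading or segmentation of confluent
fields, and the package makes no claim to reproduce the original
study's condition-specific percentages, which require the original
images. Touching nuclei merge into one object and should be removed via
the `max_area` filter; watershed splitting is out of scope.

Problem sizes in the standard verification run (chosen to exercise each
property at meaningful sample sizes): 1000 nuclei for ratio recovery,
450 FRAP series for parameter recovery, 50 seeds for the rotation null,
100 random stacks for the labeling oracle, 1000 replicates for the
type-I calibration.

# Worked example

```{r example, eval = FALSE}
# an enriched condition (rim contrast 1.6) vs a diffuse one (1.05)
measure_scene <- function(r, seed, condition, replicate) {
  sp <- scene_spec(n_nuclei = 6, rim_contrast = r, seed = seed)
  sc <- make_nucleus_scene(sp)
  lab <- segment_objects(get_plane(sc$image, channel = 1), min_area = 80)
  m <- measure_all_nuclei(get_plane(sc$image, channel = 2), lab,
                          condition = condition)
  m$replicate <- replicate
  m
}
meas <- dplyr::bind_rows(
  lapply(1:3, function(i) measure_scene(1.05, i, "control", i)),
  lapply(1:3, function(i) measure_scene(1.60, 10 + i, "depleted", i)))
summarize_condition(meas)$summary

# FRAP: simulate, normalize, fit
g <- make_frap_series(frap_spec(mobile_fraction = 0.7, rate = 0.05,
                                noise_sigma_frac = 0.02, seed = 1))
fit_recovery(double_normalize(g$trace))
```
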