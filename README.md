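# rimfrap

Quantification of nuclear-envelope biology readouts from fluorescence
microscopy: rim enrichment of inner-nuclear-membrane proteins, FRAP
mobility, Pearson colocalization with a 90° rotation control, and
nuclear foci (chromocenters, proximity-ligation spots) — plus a
ground-truthed synthetic-microscopy generator so that every estimator
in the pipeline is verifiable without access to raw images.

## Who this is for

Cell biologists quantifying the redistribution of proteins such as the
lamin B receptor (LBR) between the nuclear envelope (NE) and the
nucleoplasm — a readout of the LBR/lamin-A chromatin "tether switch"
during differentiation — and the supporting measurements that travel
with that question: protein mobility by fluorescence recovery after
photobleaching (FRAP), per-cell colocalization of channel pairs, and
counts of punctate nuclear structures in confocal stacks.

## The core measurements

**NE:nucleoplasm ratio.** Nuclei are segmented from the DAPI channel
(global Otsu threshold by default), and each nucleus is partitioned at
fixed pixel distances from its boundary into a rim band (Euclidean
distance to background in `(d, d+w]`, default `d = 0`, `w = 3` px) and
a nucleoplasm core (distance `> d+w`). The readout for nucleus *i* is

    ratio_i = mean(I_rim) / mean(I_nucleoplasm)

with `ratio > 1.2` classifying the nucleus as *Nuclear envelope
enriched* (ties go to *diffuse in the nucleus*). Enriched fractions are
aggregated per biological replicate; the s.e.m. is across replicates.

**FRAP.** After drift correction (translation registration), ROI traces
are double-normalized,

    N(t) = [(I_bleach − I_bg) / (I_bleach(t0) − I_bg(t0))] /
           [(I_total  − I_bg) / (I_total(t0)  − I_bg(t0))]

which cancels uniform acquisition bleaching, and fitted with a bounded
single-exponential recovery `N(t) = D + (plateau − D)(1 − e^{−kt})`,
reporting the mobile fraction `M = (plateau − D)/(1 − D)`, the rate `k`
and `t½ = ln2/k`. A flow statistic matches the bleached-ROI gain
against the unbleached-region loss in conserved signal units.

**Colocalization.** Per-cell Pearson coefficient within a mask, with a
null control that rotates one channel by 90° about its bounding-box
center (pure index permutation) and re-correlates over the overlap; a
paired t test compares observed vs rotated across cells.

**Foci.** Chromocenters: threshold each nucleus at the 99.5th
percentile of its voxel histogram, 26-connected components, inclusive
voxel-volume window [7, 2000]. PLA spots: per-cell 2D component counts,
normalized to the mean count of an antibody-only control.

**Statistics.** Two-group Student's t (Welch default), one-way ANOVA
with Holm-adjusted pairwise tests, Kruskal–Wallis; stars at
*P* < 0.05 / 0.01 / 0.001.

## Worked example

Two conditions of six-nucleus synthetic scenes — a diffuse one (true
rim contrast 1.05) and an enriched one (1.60) — pushed through the full
segment → partition → measure → summarize → test pipeline:

```r
library(rimfrap)

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
#> # A tibble: 2 × 5
#>   condition n_cells n_replicates fraction_enriched   sem
#>   <chr>       <int>        <int>             <dbl> <dbl>
#> 1 control        18            3                 0     0
#> 2 depleted       18            3                 1     0

compare_groups(as.data.frame(meas), "ratio", "condition")
#>   test  group1  group2   statistic        p stars
#> 1 t     control depleted     -234. 5.69e-47 ***
```

Every control nucleus measures below the 1.2 cutoff and every
"depleted" nucleus above it, and the per-cell ratios separate sharply
(at these noise levels the estimator's spread around the true contrast
is far smaller than the 0.55 gap between conditions).

A FRAP series with a 70% mobile pool recovering at 0.05/s, simulated
with 2% noise, normalized and fitted:

```r
g <- make_frap_series(frap_spec(mobile_fraction = 0.7, rate = 0.05,
                                noise_sigma_frac = 0.02, seed = 1))
fit_recovery(double_normalize(g$trace))
#> <frap_fit> M = 0.7021 | k = 0.04776 /s | t_half = 14.51 s | plateau = 0.8049 | D = 0.3449 | rms resid = 0.0276
```

The fitted mobile fraction (0.702) and rate (0.048/s) recover the
generating parameters within the tolerances the test suite enforces.

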