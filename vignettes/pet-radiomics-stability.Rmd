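---
title: "Measuring PET radiomic feature stability across scanners with synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring PET radiomic feature stability across scanners with synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrad)
library(dplyr)
```

## The measurement problem

When the same tumor is imaged on two PET scanners — say an early whole-body
PET/CT scan followed by a delayed regional PET/MR scan — the quantitative
image differs for several reasons at once: tracer uptake keeps rising between
the two time points, MR-based attenuation correction omits bone and
underestimates uptake, the two scanners reconstruct onto different voxel
grids (4 × 4 × 2 mm vs 4 × 4 × 2.78 mm), and shorter acquisition windows are
noisier. A radiomic feature is only useful across such a protocol if its
value survives these perturbations.

`petrad` implements the full measurement chain used in this kind of
test–retest stability study — adaptive threshold segmentation, fixed-bound
intensity discretization, and extraction of eight conventional, histogram and
textural features — together with a phantom simulator that reproduces the
paired three-condition design, so every stage can be validated without
patient data.

## The measurement chain

### Adaptive threshold segmentation

The tumor VOI is delineated with a contrast-oriented adaptive threshold

$$T = \beta \cdot I_{70} + I_{bgd}, \qquad \beta = 0.3,$$

where $I_{70}$ is the mean uptake of the connected region of voxels above
70 % of the local maximum and $I_{bgd}$ the mean background uptake in a shell
2 voxels thick, 6 voxels away from that core, restricted to voxels below
2.5 SUV. The VOI is the 26-connected component above $T$ containing the
hottest voxel. $\beta = 0.3$ is the standard Jaszczak-phantom calibration of
this algorithm family and is taken as given, not re-derived.

Numerical conventions we had to fix because "distance in voxels" admits
several readings:

* **Connectivity** is 26-neighbor (3³ neighborhood) throughout, and the
  shell distance is counted in Chebyshev dilation steps: the shell is the set
  of voxels at dilation distance in $(\mathrm{gap}, \mathrm{gap} +
  \mathrm{thickness}]$ from the core. Dilation steps are the natural
  voxel-unit reading and are exactly reproducible; both gap and thickness are
  configurable in `segmentation_params()`.
* **Strict inequality** (`>`) is used both for the 70 % contour and the final
  threshold, following the wording "greater than". A consequence worth
  noting: a constant positive region is entirely above 70 % of its own
  maximum, so its core is the whole region, while a region of zeros has an
  empty core and raises a degenerate-input error.
* The 2.5-SUV cap applies only to shell voxels, never to the VOI.
* The search region is a required input (`search_box_around()` builds one
  from any reference mask). The original operator chose the tumor visually;
  requiring an explicit box avoids whole-body false maxima and makes runs
  reproducible.

### Fixed-bound discretization

VOI intensities are mapped to integer gray levels by absolute resampling
with fixed bounds,

$$R(x) = \mathrm{round}\!\left[\,\mathrm{bins} \times
  \frac{I(x) - \mathrm{lower}}{\mathrm{upper} - \mathrm{lower}}\,\right],$$

with bounds 0–25 SUV and 8, 64 or 256 bins (bin widths ≈ 3.1, 0.4 and
0.1 SUV). Fixed bounds keep the bin width identical across lesions and scans;
per-lesion min–max resampling is deliberately not offered because it ties the
discretization to lesion contrast and volume.

Two details are implementation choices that texture software rarely states:

* The formula as written yields levels $0..\mathrm{bins}$; we clamp level 0
  into level 1 so levels index standard matrices $1..\mathrm{bins}$. Only
  voxels within half a bin of the lower bound are affected, which a tumor VOI
  essentially never contains.
* Rounding is half-away-from-zero, stated explicitly because IEEE
  half-to-even would move isolated voxels by one level. Intensities outside
  the bounds are clipped (and counted), not errored: the 25-SUV upper bound
  is a cohort-specific maximum, not a physical limit.

### The eight features

Conventional features are computed on raw SUV: `suv_mean`, and `tmr`, the
tumor-to-muscle ratio against a reference muscle region (gluteal muscles for
pelvic tumors, posterior neck muscles for head-and-neck). Histogram features
(`skewness`, `kurtosis`) and textural features are computed on the
discretized levels. From the gray-level co-occurrence matrix (GLCM):
entropy $-\sum p\,\log_2 p$ and homogeneity $\sum p/(1+|i-j|)$. From the
run-length matrix (GLRLM): short-run emphasis
$\frac{1}{N_r}\sum r(i,j)/j^2$ and long-run emphasis
$\frac{1}{N_r}\sum r(i,j)\,j^2$.

Conventions, each exposed as a configuration switch because more than one is
in circulation:

* **Direction handling.** Both matrices are built per direction over the 13
  unique 3-D offsets at Chebyshev distance 1; each index is computed per
  direction and averaged (`aggregation = "average"`). Pooling counts into one
  merged matrix first is available as `aggregation = "merged"`.
* **Entropy base** is 2 (bits) by default; `entropy_base` accepts `exp(1)`
  or 10.
* **Kurtosis is non-excess** ($m_4/m_2^2$, Gaussian value 3) with
  population (divisor-$N$) moments — the convention under which reported
  tumor kurtosis values near 2–2.4 make sense; excess kurtosis would sit
  near 0.
* **Neighborhoods are voxel-unit**, with no millimeter correction for
  anisotropic spacing — the conventional texture-matrix definition; the
  spacing is carried in the containers for everything else.
* Histogram moments are computed on discretized levels by default
  (`histogram_on = "suv"` switches to raw SUV).

A VOI with zero gray-level variance is degenerate for skewness and kurtosis;
`extract_features()` returns them as `NA` with a warning and flags the row,
while entropy (0) and homogeneity (1) remain exact.

## The phantom simulator

`generate_phantom()` builds a spherical tumor with a smooth heterogeneity
texture in a uniform background, plus a disjoint muscle reference box. The
texture is a seeded white-noise field smoothed to a stated correlation length
(default 8 mm FWHM), standardized over the tumor and scaled to a requested
SUV amplitude — a tunable, realistic texture model that keeps GLCM/GLRLM
features non-degenerate.

`apply_condition()` turns ground truth into one simulated acquisition, in a
fixed order: tumor uptake scaling → global AC bias → additive Gaussian noise
→ Gaussian post-smoothing → trilinear resampling to the condition grid →
clipping of negatives (counted). The order is fixed so outputs are
reproducible; with all-neutral parameters the map is the identity, exactly.

The default three conditions (`study_conditions()`) emulate the paired
protocol: an early scan on a 4 × 4 × 2 mm grid with CT-based AC, and two
delayed reconstructions (short and long acquisition windows) on a
4 × 4 × 2.78 mm grid with MR-based AC, all with a 4-mm Gaussian post-filter.
Parameter choices:

* **Delayed uptake multiplier 1.3** — FDG uptake in tumors keeps rising for
  an hour or more after injection; a 30 % increase between an early and a
  one-hour-later delayed scan is typical of reported delayed-scan increases.
* **MR-AC bias 0.9** — the magnitude of bone-related underestimation is not
  published as a number for this protocol, so it is a free parameter, not an
  asserted value; 10 % is a plausible middle of the reported range for
  pelvic sites.
* **Noise** — additive Gaussian in SUV with SD scaling as
  $1/\sqrt{\mathrm{duration}}$, the standard count-statistics surrogate: the
  2-min window has $\sqrt{5}$ times the SD of the 10-min window (defaults
  0.45 vs 0.2 SUV; early whole-body 0.3 SUV).
* **Phantom defaults** (15-mm radius, tumor 9 SUV, background 1 SUV, muscle
  0.7 SUV, heterogeneity 1.5 SUV) give a tumor of ~450 voxels with
  tumor-to-muscle ratio ≈ 13 and ~10:1 contrast — the scale of a
  gynecological primary on this grid.

`generate_cohort()` draws per-subject log-normal random effects on tumor
size, uptake and heterogeneity that are **shared across that subject's
conditions**, which is what induces the cross-condition correlation a
repeated-measures analysis relies on. Seeds are derived per
(subject, condition, stage) from the master seed by a counter scheme, so
adding a subject never changes another subject's data.

What the simulator does *not* emulate: sinograms, reconstruction (TOF, PSF,
OSEM), scatter and randoms, spatially varying AC error, irregular tumor
shapes, or partial-volume effects beyond Gaussian smoothing. Passing tests
therefore show that the measurement chain is correct and that its stability
ordering behaves as designed under these idealized perturbations — not that
real cross-scanner harmonization is solved.

## Comparison statistics

`stability_report()` computes, per feature and bin count: Pearson
correlations between condition pairs (two-sided p from the t transform,
$n-2$ df), a one-way repeated-measures ANOVA across conditions, paired
post-hoc t-tests, and mean absolute percent differences
($100\,(b-a)/a$, stored at full precision, rounded to integer percent only
in reports).

The ANOVA partitions $SS_{total} = SS_{subjects} + SS_{conditions} +
SS_{error}$ with $F = \frac{SS_{cond}/(k-1)}{SS_{err}/((n-1)(k-1))}$.
Sphericity is assumed (no Greenhouse–Geisser correction) and the report says
so. Degenerate layouts are resolved in favor of the clean null: zero
condition sum of squares gives $F = 0$, $p = 1$ even when the error stratum
is also empty (identical conditions), and a perfectly consistent nonzero
effect with zero error gives $F = \infty$, $p = 0$. The post-hoc adjustment
is Bonferroni by default (`holm` and `none` available); the choice is a
documented convention, since pairwise p-values in this literature are often
reported without naming the adjustment.

## A small end-to-end run

```{r study, eval = FALSE}
cfg <- run_config(n_subjects = 8, bins = c(8L, 64L, 256L), seed = 1)
res <- run_study(cfg)
res$report$ranking
autoplot(res$report, bins = 64)
```

With the default design (8 subjects × 3 conditions × 3 bin configurations =
72 feature rows) this takes a few seconds. The test suite exercises the same
chain at reduced sizes — 24³ phantom grids, 2–3 subjects, and brute-force
texture oracles on VOIs up to 5×5×5 voxels with 100 random repetitions —
chosen so each property is checked at a scale where the independent oracle
is exhaustive.

## Known limitations

* Tumors are spheres; shape features and shape-dependent segmentation
  behavior are out of scope.
* The AC bias is a single scalar per condition; real Dixon-AC error is
  spatially structured around bone.
* NIfTI is the supported volume format (masks as 0/1 volumes); DICOM series
  are not read.
* The per-direction average is the default aggregation; merged-matrix values
  differ slightly and should not be mixed within one analysis.
* With 8 subjects the ANOVA has limited power; the report flags
  significance, but percent differences and correlations carry most of the
  stability information at this sample size.
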