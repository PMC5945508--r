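# petrad

Radiomic features promise quantitative tumor phenotyping from PET images,
but a feature is only usable across a clinical workflow if its value
survives a change of scanner, attenuation-correction method, scan time
point and acquisition duration. `petrad` is an R implementation of the
measurement chain used in paired-scanner stability studies of
<sup>18</sup>F-FDG PET radiomics — for imaging scientists who want to
reproduce, probe or extend that chain on fully synthetic data.

The package implements:

- **Contrast-oriented adaptive threshold segmentation** of the tumor
  volume of interest (VOI):
  `T = β·I₇₀ + I_bgd` with β = 0.3, where I₇₀ is the mean uptake of the
  connected region above 70 % of the local maximum and I_bgd the mean
  background in a shell 2 voxels thick, 6 voxels from that core, using
  only shell voxels below 2.5 SUV.
- **Fixed-bound (absolute) discretization**
  `R(x) = round[bins · (I(x) − lower)/(upper − lower)]` with bounds
  0–25 SUV and 8 / 64 / 256 gray levels (bin widths ≈ 3.1 / 0.4 / 0.1 SUV).
- **Eight radiomic features** per VOI and bin configuration: SUVmean and
  tumor-to-muscle ratio (TMR) on raw SUV; skewness and kurtosis of the
  gray-level histogram; entropy and homogeneity from the 3-D gray-level
  co-occurrence matrix (GLCM); short- and long-run emphasis (SRE, LRE)
  from the gray-level run-length matrix (GLRLM), each computed over the 13
  unique 3-D directions and averaged.
- **A paired-scanner phantom simulator**: spherical tumors with smooth
  heterogeneity texture, imaged under an early 4×4×2 mm condition and
  delayed 4×4×2.78 mm conditions with delayed-uptake scaling, a global
  MR-AC bias multiplier, duration-dependent Gaussian noise, 4-mm Gaussian
  post-smoothing and trilinear grid resampling.
- **Comparison statistics**: Pearson correlations between conditions,
  one-way repeated-measures ANOVA, Bonferroni-adjusted paired post-hoc
  tests, and percent differences, assembled into a stability report with
  `tidy()` / `glance()` / `autoplot()` methods.

## Worked example

Simulate one subject, segment the tumor on a simulated early scan, and
extract the eight features at 64 bins:

```r
library(petrad)

ph   <- generate_phantom(phantom_spec(seed = 1))
scan <- apply_condition(ph$volume, ph$tumor, study_conditions()$early, seed = 2)
voi  <- segment_tumor(scan, search_box_around(ph$tumor, pad = 5))

attr(voi, "threshold")   # 3.99  = 0.3 * I70 (9.948) + Ibgd (1.005)
mask_size(voi)           # 468 voxels; Dice vs ground truth 0.999

extract_features(scan, voi, ph$muscle, discretization_config(bins = 64))
#>   suv_mean   tmr skewness kurtosis entropy homogeneity   sre   lre
#> 1    8.289 11.64    0.009    2.226   7.463       0.349 0.945 1.264
```

The threshold 3.99 is the adaptive cut between a ~10-SUV tumor and a 1-SUV
background; SUVmean 8.3 is below the 10-SUV plateau because smoothing
dilutes edge voxels, and TMR ≈ 12 is the tumor-to-muscle contrast. Entropy
(7.5 bits) and homogeneity (0.35) quantify the simulated intratumoral
texture; SRE near 1 and LRE near 1.3 say runs of equal gray level are
short, as expected at a 0.4-SUV bin width.

A full paired study — 8 subjects × 3 conditions × 3 bin configurations —
runs in seconds and ends in a stability ranking (mean absolute percent
difference across condition pairs, smaller = more stable):

```r
res <- run_study(run_config(n_subjects = 8, seed = 1))
dplyr::filter(res$report$ranking, bins == 64)
#>       feature bins mean_abs_pct_diff
#> 1         sre   64               1.5
#> 2     entropy   64               3.4
#> 3    kurtosis   64               5.5
#> 4         lre   64               5.9
#> 5    suv_mean   64               9.2
#> 6 homogeneity   64              10.1
#> 7         tmr   64              18.1
#> 8    skewness   64             131.9
```

Under the default simulated protocol the textural features SRE, entropy
and LRE move less between conditions than SUVmean, which absorbs the
delayed-uptake and AC-bias effects directly; skewness, computed from a
near-zero baseline, is unstable in percent terms. `res$report$anova`
holds the repeated-measures tests and `autoplot(res$report, bins = 64)`
plots per-condition means.

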