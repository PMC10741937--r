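---
title: "Methods: quantifying inter-reader contour variability on synthetic multi-reader cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying inter-reader contour variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When several readers outline the same prostate lesion on multiparametric MRI
(mpMRI), their 3D contours disagree — and the amount of disagreement depends
on which sequence (T2, ADC, high-b diffusion, dynamic contrast-enhanced) they
were looking at. `segvar` implements the full analysis pipeline for
quantifying that inter-reader variability: geometric agreement metrics
between pairs of 3D binary masks, post-hoc union combination of per-sequence
contours, cohort-level aggregation, and the statistical comparison layer.
Because multi-reader delineation datasets are rarely shareable, the package
also ships a calibrated synthetic cohort generator so that every stage of the
pipeline can be exercised, tested and benchmarked end-to-end without patient
data.

## Agreement metrics

For two masks $A, B$ on a shared voxel grid the package computes

* **Dice similarity coefficient** $\mathrm{DSC} = 2|A\cap B|/(|A|+|B|)$,
* **Jaccard index** $J = |A\cap B|/|A\cup B|$ (algebraically
  $J = \mathrm{DSC}/(2-\mathrm{DSC})$ for any single pair),
* **Hausdorff distance (HD)** — the exact symmetric 100th-percentile
  Hausdorff distance between the boundary voxel-centre point sets, in mm,
* **mean distance to agreement (MDA)** — the average of the two directed
  mean boundary distances (the "average symmetric surface distance"
  convention; a pooled-surface variant is available via `pooled = TRUE`).

Design choices worth spelling out:

* **Boundaries** are mask voxels with at least one of six face-adjacent
  neighbours outside the mask; set voxels on the array border count as
  boundary. Distances are measured between boundary voxel centres —
  no sub-voxel surface mesh — which makes every value reproducible and
  checkable against an exhaustive all-pairs oracle (the test suite does this
  on hundreds of random mask pairs to 1e-9 mm).
* **Anisotropic spacing** is honored exactly: the surface distances use an
  exact Euclidean distance transform (separable lower-envelope algorithm)
  with per-axis spacing in mm, so a (0.5, 0.5, 3.0) mm grid behaves
  correctly.
* **HD is not percentile-trimmed.** "Hausdorff distance" is read literally;
  HD95-style variants are out of scope.
* **Empty masks.** If exactly one mask is empty, the overlap metrics are 0
  (defined) and the distance metrics are recorded as missing and excluded
  from aggregation; two empty masks are an error. Silent imputation would
  bias the distance summaries.
* **No resampling.** All masks of a case must arrive on one compatible grid
  (equal shape and spacing, origins within 1e-6 mm); incompatible inputs are
  rejected. Registration is assumed to have happened upstream.

## Sequence labels and union sets

Twelve lesion labels are tracked per reader: eight *delineated* sets (T2,
ADC, T2ADC, B2000, T2ADCB2000, DCE, T2ADCDCE, ALL — where e.g. "T2ADC" means
the reader saw the combined display and drew one contour) and four *derived
union* sets (T2+ADC, T2+ADC+B2000, T2+ADC+DCE, T2+ADC+B2000+DCE) built by
voxelwise OR of the single-sequence contours. The jointly-read "T2ADC" and
the post-hoc union "T2+ADC" are deliberately distinct labels everywhere,
including file names (`dil_T2ADC.nii.gz` vs `dil_T2_ADC_union.nii.gz`).

## The DCE parametric map

Rather than asking readers to pick one phase of a dynamic contrast-enhanced
acquisition, the pipeline supports a semi-quantitative parametric map: the
initial area under the gadolinium curve (IAUCG). `compute_iaucg()`
integrates the *relative* enhancement $(S(t) - S_0)/S_0$ voxelwise by the
trapezoidal rule on the actual frame timestamps, from the bolus-arrival
frame over a configurable window (default 60 s). The window and the
baseline-normalized convention are stated explicitly because several IAUCG
conventions circulate; the choice only affects how the simulated DCE
delineations look, not the metric pipeline. Zero-baseline voxels are flagged
missing; negative enhancement is integrated as computed.

## Statistical layer

* **Between-sequence comparison**: two-sided Student t-tests of per-case DSC
  (the mean over the three reader pairs of a case) between every pair of the
  12 labels, emitted as a symmetric p-value matrix with unit diagonal. The
  default is the *paired* test, since the same cases are delineated under
  every sequence; an unpaired option exists. No multiple-testing correction
  is applied by default (an optional Holm flag exists) — the comparison
  matrix mirrors common practice of reporting raw p-values for this design.
* **PI-RADS group comparison**: unpaired two-sided t-test of per-case DSC
  between PI-RADS 5 and PI-RADS < 5 cases, per sequence.
* **Feature screen**: Spearman rank correlation (average-rank ties,
  asymptotic p-values) of age, prostate volume, lesion volume and PI-RADS
  against per-case mean DSC pooled over the eight delineated labels.
* **Multivariate logistic regression** on the Spearman-significant features.
  The regressed outcome is not fully determined by the study description, so
  the package adopts — and records in `outcome_definition` — the per-case
  mean DSC dichotomized at the cohort median. The grade enters the
  regression as the PI-RADS 5 vs < 5 indicator, the same dichotomy the group
  comparison uses (an ordinal 3/4/5 coding would impose a linear trend the
  generative group effect does not have). Separation and non-convergence are
  flagged and suppress the coefficient table.
* **Design power**: `design_power()` is the standard two-sample
  noncentral-t power (via `power.t.test`) for a DSC difference of
  `mean_a - mean_b` at common SD; the reference design (0.55 vs 0.50,
  SD 0.08, n = 64/group, two-sided alpha 0.05) yields power about 0.94,
  comfortably above the 80% planning value.

## The synthetic cohort generator

The generator is a first-class module, not a test fixture. Its defaults *are*
the study conditions the pipeline is designed around: 64 cases, 3 readers,
PI-RADS counts 7/12/45, gland volumes Normal(42, 8) mL, lesion volumes
log-normal with mean 3 mL (sdlog 0.45), per-sequence target mean pairwise
DSC {T2 0.51, ADC 0.50, T2ADC 0.54, B2000 0.52, T2ADCB2000 0.54, DCE 0.35,
T2ADCDCE 0.55, ALL 0.53}, prostate 0.90 and TZ 0.77, on a 96 x 96 x 24 grid
at (0.5, 0.5, 3.0) mm — a typical prostate T2 protocol resolution; the
through-plane spacing intentionally dominates, as in practice.

**Anatomy.** The gland is a superellipsoid (exponent 2.2-3.0) with sampled
volume; the transition zone is a concentric scaled copy (volume fraction
~0.35); the peripheral zone is the set difference. Lesions are ellipsoids
with a low-order (degree-2 spherical-harmonic) radial perturbation, placed
at an interior voxel of the PZ (70%) or TZ (30%) and clipped to the gland.

**Reader model.** A reader's contour of a truth shape is produced by (i) a
reader-level random translation (SD 0.5 mm per axis) and isotropic log-scale
jitter (SD 0.02) shared across all structures of that reader, and (ii) a
spatially correlated Gaussian random field (correlation length 5 mm) added
to the truth signed-distance function and thresholded at zero, keeping the
largest 6-connected component. Per-reader fields share about a third of
their variance across that reader's sequences (`field_share = 0.35`), which
reproduces the
empirical pattern that one reader's T2-bearing contours resemble each other
more than they resemble their DCE contour. The affine jitter was chosen as
large as possible subject to the prostate DSC target of 0.90 remaining
reachable: affine disagreement alone already costs glands a few DSC points,
so larger jitters would make 0.90 unattainable at any field amplitude.
Random fields are synthesized on a coarse lattice (node spacing ~2 mm,
i.e. correlation/2.5) and trilinearly upsampled — the field is band-limited
at the correlation length, so this loses essentially nothing while cutting
the cost several-fold.

**Calibration.** The field amplitude (in mm) is the single dial that sets
expected pairwise DSC for a given shape family, and it is found by bisection
on the mean pairwise DSC of Monte-Carlo reader pairs
(`calibrate_noise()`). Two implementation points matter:

1. *Common random numbers.* Each replicate's transformed signed-distance
   fields and unit noise fields are precomputed once and re-thresholded at
   every candidate amplitude, making DSC(amplitude) smooth and monotone so
   bisection is reliable.
2. *Cohort-matched calibration.* Inside `generate_cohort()` the replicates
   are not a generic shape family but the cohort's own truth lesions
   combined with the exact seeded reader draws the simulator will use. The
   realized per-sequence cohort mean then matches its target up to the
   bisection tolerance (0.015 DSC by default; empirically within ~0.005),
   rather than up to Monte-Carlo sampling error — which at n = 64 would
   otherwise consume most of a +-0.03 verification band.

**PI-RADS structure.** PI-RADS is assigned by lesion-volume rank with
log-normal rank jitter (sdlog 0.7) and the exact configured counts, so
volume and grade associate positively but not deterministically (a
deterministic quantile assignment would make the multivariate regression
degenerate by perfect collinearity). A mean-preserving DSC boost separates
PI-RADS 5 from other cases by 0.16 on every label except DCE (group targets
t + b·19/64 and t − b·45/64 keep the per-sequence cohort mean at t). The
boost size, the rank jitter and the amplitude-volume exponent below were
chosen together so that the generated cohort exhibits the qualitative
structure the pipeline is designed to detect: a positive marginal
volume-agreement correlation, grade-group separation on every boosted
label, and a multivariate stage in which the grade — not the volume —
retains the effect. Smaller boosts or tighter volume-grade coupling let the
continuous volume term absorb the group effect entirely. DCE is excluded
from the boost, mirroring the empirical pattern that perfusion-only
contours show no grade effect.

**Volume-agreement coupling.** At a *fixed* field amplitude, larger lesions
have smaller surface-to-volume ratio and therefore mechanically higher
expected DSC — a continuous effect so strong that, in a multivariate model,
it absorbs the grade effect entirely. The generator therefore partially
scales each case's lesion amplitude with lesion size
(`amplitude_volume_exponent = 0.2`; 1/3 would make expected DSC fully
size-invariant within a grade group, 0 restores the raw geometric effect).
The retained moderate direct effect keeps the marginal Spearman
volume-agreement correlation clearly positive, while the grade boost
carries the dominant conditional signal, so the multivariate stage
attributes the effect to the grade.

**What the simulator does *not* emulate.** Real image intensities (only
contours and a stylized DCE series are generated), reader bias (systematic
over- or under-segmentation), intra-reader variability, inter-case
correlation of reader behaviour, non-ellipsoidal anatomy (seminal vesicles,
extraprostatic extension), and registration error between sequences. Tests
passing on this cohort therefore validate the *pipeline arithmetic and its
statistical behaviour* under a controlled generative model — they do not
certify performance on any real dataset.

## Numerical choices and degenerate inputs

* Distance transforms are exact (no chamfer approximation); the brute-force
  all-pairs oracle agrees to 1e-9 mm.
* The paired t-test of a label against itself (or any zero-variance pair)
  is reported as p = 1 and counted in a `n_degenerate` attribute instead of
  erroring the whole matrix.
* Spearman screening of a constant feature yields a flagged undefined
  correlation for that feature only.
* Logistic separation is detected (fitted probabilities pinned at 0/1, or
  runaway coefficients) and reported as non-convergence without
  coefficients.
* An empty reader delineation is regenerated once with a fresh field and
  then flagged with a warning; cases missing a reader are skipped with a
  warning and recorded in the run manifest, never silently dropped.
* Masks that would not fit the grid (oversized glands) are redrawn a bounded
  number of times, then truncated with a warning.

## Problem sizes

Unit tests run on a coarse 48 x 48 x 16 grid at (1, 1, 3) mm with 3-4 case
cohorts; the coarse grid cannot reach very low DSC targets, so the test
fixture uses milder targets than the study defaults. Cohort-level
verification runs the full default configuration — 64 cases, 3 readers,
96 x 96 x 24 at (0.5, 0.5, 3.0) mm, 2,880 pairwise comparisons — in a few
minutes on one CPU; `scripts/acceptance.R` repeats that computation from
scratch at a caller-supplied seed.

## Known limitations

* The peripheral zone is derived per reader as gland minus TZ, so its
  agreement level is emergent, not independently calibratable.
* Calibration targets mean DSC only; the per-case DSC *distribution* (and
  hence HD/MDA levels) follows from the noise model rather than being
  matched to any external reference.
* The logistic stage regresses a median split of mean DSC; other outcome
  definitions (continuous beta regression, per-sequence outcomes) are out
  of scope.
* The IAUCG window/normalization convention is configurable but the package
  takes no position on which convention a given scanner vendor uses.
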