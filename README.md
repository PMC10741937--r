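# segvar

Inter-reader variability analysis of multi-sequence MRI lesion contours.

## What this package is for

Focal dose escalation to the dominant prostate lesion requires readers to
agree on where the lesion is — and multi-reader studies show they often
don't, with the level of agreement depending on which mpMRI sequence the
contour was drawn on. `segvar` is a reusable R pipeline for quantifying that
inter-reader variability: it takes per-case, per-reader, per-sequence 3D
binary masks (NIfTI, on a shared registered grid) plus a small metadata
table, and produces the standard agreement tables and statistics. Because
multi-reader contour datasets are rarely shareable, the package also ships a
calibrated synthetic cohort generator so the whole pipeline runs end-to-end
without patient data.

It is aimed at researchers in medical image analysis and radiation oncology
who need reproducible contour-agreement numbers (or a controlled testbed for
them), not at clinical use.

## What it computes

For two masks $A, B$ on a shared anisotropic voxel grid:

- **DSC** $= 2|A\cap B| / (|A| + |B|)$
- **Jaccard** $= |A\cap B| / |A\cup B|$
- **Hausdorff distance** (exact, symmetric, in mm): with $S_A, S_B$ the
  boundary voxel-centre sets,
  $\mathrm{HD} = \max\{\max_{p\in S_A} d(p,S_B),\ \max_{q\in S_B} d(q,S_A)\}$
- **Mean distance to agreement**:
  $\mathrm{MDA} = \tfrac12\left(\overline{d}(S_A \to S_B) + \overline{d}(S_B \to S_A)\right)$

computed via an exact anisotropic Euclidean distance transform and verified
against an exhaustive all-pairs oracle in the test suite. Around the
metrics: union combination of per-sequence contours (T2+ADC, ...),
per-sequence / per-reader-pair cohort summaries, a between-sequence paired
t-test matrix, PI-RADS 5 vs < 5 comparisons, a Spearman feature screen,
multivariate logistic regression, two-sample power computations, and an
IAUCG parametric-map module for DCE series.

## Worked example

Simulate a small 3-reader cohort, analyze it, and read the headline table:

```r
library(segvar)

cfg <- simulation_config(n_cases = 16, seed = 11,
                         pirads_counts = c(`3` = 2, `4` = 3, `5` = 11))
res <- simulate_and_analyze(cfg)

summ <- res$sequence_summary
summ[summ$reader_a == "ALL" & summ$group %in% delineated_sequence_labels(),
     c("group", "dsc_mean", "dsc_sd", "hd_mm_mean", "mda_mm_mean")]
```

```
        group dsc_mean dsc_sd hd_mm_mean mda_mm_mean
16         T2    0.509  0.134      11.13        2.56
20        ADC    0.502  0.131      10.59        2.63
24      T2ADC    0.542  0.161       8.78        2.08
28      B2000    0.518  0.184       9.30        2.33
32 T2ADCB2000    0.537  0.159       9.14        2.13
36        DCE    0.347  0.171      13.97        3.97
40   T2ADCDCE    0.550  0.122       9.33        2.15
44        ALL    0.532  0.161       9.25        2.24
```

Each row pools all (case, reader-pair) comparisons for one delineation set:
mean pairwise DSC around 0.50-0.55 for T2/ADC-bearing sets, a clearly less
reproducible perfusion-only (DCE) contour at 0.35, and surface distances in
the 9-14 mm (HD) and 2-4 mm (MDA) range. The same run's config targets were
{T2 0.51, ADC 0.50, T2ADC 0.54, B2000 0.52, T2ADCB2000 0.54, DCE 0.35,
T2ADCDCE 0.55, ALL 0.53} — the generator calibrates its reader-noise
amplitudes so the realized means land on these targets. And

```r
res$spearman
#              feature         rho      p_value  n
# 1                age -0.05743747 0.8326638072 16
# 2 prostate_volume_ml -0.32058824 0.2260454222 16
# 3   lesion_volume_ml  0.30000000 0.2589364526 16
# 4             pirads  0.80001818 0.0001984549 16
```

shows the expected positive volume and PI-RADS agreement coupling (at this
demonstration size only the grade association is individually significant;
at the default 64-case scale both are).

For file-based workflows: `run_simulate(cfg, dir)` writes the NIfTI cohort
layout (`{case}/{reader}/{structure}_{sequence}.nii.gz` + `meta.csv`),
`run_analyze(dir, out)` writes the report bundle (pairwise and summary CSVs,
t-test matrix, PI-RADS tests, Spearman, logistic, power, manifest), and
`run_report(out)` prints a human-readable summary. A thin CLI wrapper lives
in `inst/cli/segvar.R`.

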