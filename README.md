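# cemorph

Can cortical thickness be measured reliably from **contrast-enhanced (CE)**
T1-weighted MRI? Clinical archives are full of gadolinium-enhanced scans
without a matching non-enhanced acquisition, and whether those images are
usable for retrospective morphometry hinges on how well CE-derived
thickness agrees with the same-session non-enhanced measurement. `cemorph`
is an R package for running that evaluation end to end, aimed at
neuroimaging methodologists who want the statistical machinery without the
image processing:

* **Paired agreement** — Pearson *r*, the consistency intraclass
  correlation for the mean of two ratings
  (ICC(C,2) = (MS<sub>BS</sub> − MS<sub>E</sub>)/MS<sub>BS</sub> from the
  two-way mixed-effects ANOVA), and Bland–Altman bias with limits of
  agreement (bias ± 1.96·SD of differences), plus subject-wise
  cross-region correlations and a bootstrap test for comparing two
  dependent correlations.
* **Longitudinal atrophy rates** — per-patient OLS slope of thickness on
  age (mm/year) with a ≥3-time-point filter, group means for primary
  progressive (PPMS) vs relapsing-remitting (RRMS) multiple sclerosis, and
  pooled-SD Cohen's *d* effect sizes.
* **Structural covariance networks** — age-residualized region-wise
  thickness, inter-regional correlation matrices, binary graphs over a
  0.01-step threshold grid, global efficiency
  E<sub>glob</sub> = Σ<sub>i≠j</sub> d<sub>ij</sub><sup>−1</sup> / (N(N−1))
  (finite on disconnected graphs), and 80%-subsampling ±1 SD error bands.
* **A seeded synthetic-cohort generator** — longitudinal thickness tables
  with group-specific atrophy slopes, latent-factor cross-region
  covariance, method-specific measurement noise, CE bias, and processing
  failures, so every stage is testable against known ground truth.
* **Readers** for FreeSurfer `?h.aparc.stats` files and per-subject
  result CSVs, and a `runPipeline()` orchestrator that writes the full
  artifact set.

## Worked example

```r
library(cemorph)

dsc   <- defaultStudyConfig(seed = 1)          # study-calibrated defaults
truth <- generateTrueCohort(dsc$config)        # noise-free cohort
obs   <- simulateMeasurements(truth, dsc$models, seed = 1)
obs
#> MorphTable: 110144 rows, 75 subjects, 64 regions
#>   methods: DL, FS
#>   image types: CE, pre

reliabilityReport(obs)
#>   method           subset n_pairs n_dropped pearson_r icc_c2 ba_bias ...
#> 1     DL              all     434         0     0.977  0.988  0.0571
#> 2     DL identical-params     211         0     0.980  0.990  0.0574
#> 3     FS              all     419        15     0.905  0.950  0.1595
#> 4     FS identical-params     204         7     0.894  0.944  0.1623
```

The deep-learning-like method ("DL", lower measurement noise) shows higher
pre-vs-CE agreement than the FreeSurfer-like method ("FS"), and each
method's Bland–Altman bias recovers its configured CE overestimation
(0.06 mm and 0.17 mm); the 15 dropped FS pairs are simulated CE processing
failures.

```r
gc <- groupContrast(obs, tauStar = 0.5, methods = "DL")
attr(gc, "comparison")
#>   method image_type e_ppms e_rrms ppms_gt_rrms
#> 1     DL         CE  0.675  0.158         TRUE
#> 2     DL        pre  0.724  0.161         TRUE
```

The PPMS group's structural covariance network is more efficient at the
reference threshold 0.5 — the direction built into the generator's
stronger PPMS factor loadings.

`runPipeline("out/", seed = 1)` chains simulate → reliability → atrophy →
networks and writes `cohort.csv`, `reliability.csv/json`, `rates.csv`,
`table1.csv`, `regional_rates.csv`, `scn_curves.csv` and `manifest.json`,
all stamped with the seed and a config hash so reruns are byte-identical.
A thin command-line wrapper lives at `inst/scripts/cemorph-cli.R`.

## Vignette

`vignettes/contrast-enhanced-morphometry.Rmd` documents the cohort model
and its assumptions, every default parameter with units and rationale,
what the generator does and does not emulate, the statistical and
numerical conventions, and known limitations.
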