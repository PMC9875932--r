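---
title: "Evaluating cortical-thickness reliability on contrast-enhanced MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating cortical-thickness reliability on contrast-enhanced MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cemorph)
```

## The problem

Brain morphometry pipelines expect non-enhanced T1-weighted MRI, but
clinical archives often hold only gadolinium contrast-enhanced (CE)
acquisitions. Whether cortical thickness measured from a CE image agrees
with the same-session non-enhanced measurement decides whether those
archives are usable for retrospective morphometry. `cemorph` implements the
three analysis stages such an evaluation needs, together with a synthetic
cohort generator that supplies ground truth for all of them:

1. **Paired agreement** between image types: Pearson *r*, the consistency
   intraclass correlation for the mean of two ratings, ICC(C,2), and
   Bland–Altman bias with limits of agreement.
2. **Longitudinal atrophy rates**: a per-patient ordinary least-squares
   slope of thickness on age (mm/year), group summaries for primary
   progressive (PPMS) versus relapsing-remitting (RRMS) multiple sclerosis,
   and Cohen's *d* effect sizes.
3. **Structural covariance networks (SCN)**: age-residualized region-wise
   thickness, inter-regional correlation, binary graphs over a threshold
   grid, global efficiency, and subsampling error bands.

## The synthetic cohort model

Real MRI from such clinical cohorts is not redistributable, so the package
generates cohorts with the same statistical shape. True thickness of
subject $i$, session $j$, region $r$ is

$$T_{ijr} = \mu_r + b_i + \beta_i\,(a_{ij} - a_{i0})
  + \lambda_{g}\textstyle\sum_f L_{if} w_{rf} + u_{ir},$$

with $\mu_r$ the region's mean thickness (Desikan–Killiany-style labels, 64
regions, typical adult values between 1.6 and 3.3 mm), $b_i \sim
N(0, \sigma_s^2)$ a global subject offset ($\sigma_s = 0.10$ mm),
$\beta_i$ the subject's annual slope drawn from its group's distribution,
$L_{if}$ standard-normal latent factor scores with fixed non-negative
weights $w_{rf}$, and $u_{ir} \sim N(0, 0.05^2)$ mm a subject-by-region
offset giving realistic within-subject cross-region correlation.

Measurements add, per method and image type, noise
$\varepsilon \sim N(0, \sigma_e^2)$ per region and — on CE images only — a
systematic thickness bias $\delta_i \sim N(\delta, \sigma_\delta^2)$ drawn
once per subject and model, so that Bland–Altman spread reflects
between-subject bias variability. CE sessions can additionally drop out
with a failure probability, emulating surface-reconstruction failures on
contrast images.

### Default study conditions

The defaults in `defaultStudyConfig()` encode the evaluated study design:

* 9 PPMS and 66 RRMS subjects; visits every ~1 year (PPMS) and ~6 months
  (RRMS). Session counts are drawn as $3 + \mathrm{Poisson}(3)$ per
  subject, giving a mean of six sessions. This guarantees the three-time-
  point filter is usually passed and puts the expected number of
  same-session image pairs near 450, matching the evaluated cohort's 454
  pairs from 75 patients (about six sessions per patient).
* Slope means $-0.012$ (PPMS) and $-0.003$ (RRMS) mm/year, both with SD
  $0.0296$ mm/year — the values the atrophy stage should recover.
* Two methods: "DL" (deep-learning-like) and "FS" (FreeSurfer-like).
  Per-region noise SDs are $8\times 0.0295$ and $8\times 0.0577$ mm, so the
  64-region global mean carries per-image noise of 0.0295 mm and 0.0577 mm
  respectively. Through the attenuation identity
  $r = \sigma_T^2/(\sigma_T^2 + \sigma_e^2)$ with latent SD 0.10 mm these
  produce pre-vs-CE correlations of 0.92 and 0.75 for the global mean.
* CE bias means 0.06 mm (DL) and 0.17 mm (FS), with between-subject SDs
  0.02 and 0.05 mm; the FS CE model drops sessions at rate $17/454$.
* About 47% of sessions are flagged as acquired with identical sequence
  parameters (the subset analysed separately; rate $213/454$).
* Latent covariance: three factors, loading scale 0.20 mm (RRMS) versus
  0.30 mm (PPMS). The 1.5-fold stronger PPMS loading is a modelling choice
  (not a measured quantity) that makes the PPMS network denser, so the
  group contrast has a known expected direction.

```{r defaults}
dsc <- defaultStudyConfig(seed = 1)
dsc$config
```

### What the generator does and does not emulate

It reproduces group sizes, visit schedules, the magnitude of between- and
within-subject variation, measurement noise and CE bias calibrated to the
published global-mean agreement statistics, processing failures, and a
cross-region covariance structure that differs by group. It does **not**
model lesions, scanner or field-strength effects, sequence-parameter
variation beyond a session flag, spatially structured (neighbouring-region)
noise, or any image content at all. Passing recovery tests on this cohort
therefore shows the *statistics* are implemented and calibrated correctly —
not that any segmentation tool behaves well on real contrast images.

## Statistical choices

**ICC variant.** ICC(C,2) follows the McGraw–Wong consistency definition
for the mean of $k=2$ ratings, computed from closed-form balanced two-way
ANOVA mean squares: $(MS_{BS} - MS_E)/MS_{BS}$. The test suite cross-checks
this against `stats::aov` mean squares and against the Spearman–Brown
closed form $2r/(1+r)$ on equal-variance pairs. The absolute-agreement
form ICC(A,k) is exported but not used in reports.

**Comparing dependent correlations.** To compare the pre/CE correlation of
two methods measured on the same sessions, the default is a subject-level
bootstrap (5000 resamples, seeded) of the difference on the Fisher-z scale;
it makes no normality assumption. Steiger's z (Pearson–Filon covariance
with the pooled correlation) is available via `method = "steiger"` as a
parametric cross-check.

**Atrophy rates.** Age, not session index, is the regressor, and pre and
CE series are fitted separately. Series with fewer than three time points
are discarded (boundary inclusive), counted per (subject, method, image
type) so that simulated CE failures can remove a CE series while the pre
series survives. Cohen's *d* uses the classic pooled-SD formula for both
the group contrast and the pre-vs-CE contrast; a paired variant of the
latter exists behind `pairedImageTypes = TRUE` because the published
layout does not say which was used.

**Networks.** Thresholding uses the signed correlation — an edge requires
$r \ge \tau$ with $\tau \in [0,1]$ — so negative correlations never create
edges. Global efficiency is computed from breadth-first-search shortest
paths with $1/\infty = 0$, making it finite on disconnected graphs; the
test suite verifies it exactly against an exhaustive Floyd–Warshall oracle
on 200 random graphs. Every *image* (subject-session observation) is one
network observation, so within-subject correlation across sessions is
deliberately ignored, and subsampling bands draw 80% of the images without
replacement (floor rounding), 1000 times by default, reporting ±1 SD.
Age residualization is fitted within each network's own image set
(`residualize = "per-group"`) so group mean offsets cannot masquerade as
covariance; a pooled mode is provided because the original analysis scope
is ambiguous on this point, and neither mode is asserted as "the" published
choice.

## Numerical and degenerate-input conventions

* Zero variance on either side of a paired series, zero between-subjects
  mean square, zero pooled SD, and constant ages are all errors, never
  silent 0/1 results; absent cells in the effect-size table are reported
  as `NA`, not 0.
* All randomness flows from one master seed through counter-based
  substreams (`splitSeed`), one per subject, model, or replicate: outputs
  are byte-identical across reruns and enlarging a cohort never perturbs
  existing subjects.
* Generated thickness is clamped at 0.001 mm; with the default parameters
  the clamp is never active in practice (values sit ~10 SDs above zero),
  it only guards the positivity invariant under extreme user parameters.
* CSV artifacts serialize numbers at 6 significant digits and carry a
  `# seed=... config=<md5>` header; JSON artifacts keep full precision.

## Problem sizes used by the shipped checks

The test-suite recovery experiments use 454 pairs averaged over 100 seeded
replicates for the agreement calibration, 50,000 draws per group for the
effect sizes, 10,000 pairs for the ICC closed-form agreement, cohorts of
up to 2,000 subjects for generator convergence, and 100 default-sized
cohorts for the direction of the network group contrast — sizes chosen so
Monte-Carlo error sits well inside each stated tolerance while the whole
suite runs in about a minute.

## A worked example

```{r example, eval = FALSE}
dsc <- defaultStudyConfig(seed = 1)
truth <- generateTrueCohort(dsc$config)
obs <- simulateMeasurements(truth, dsc$models, seed = 1)

reliabilityReport(obs)
rates <- computeAtrophyRates(obs)
groupEffectTable(rates)$effects
groupContrast(obs, tauStar = 0.5, methods = "DL")
```

`runPipeline(outDir, seed)` chains all stages and writes `cohort.csv`,
`reliability.csv/json`, `rates.csv`, `table1.csv`, `regional_rates.csv`,
`scn_curves.csv` and a manifest.

## Known limitations

* The generator's cross-region covariance is a low-rank factor model; real
  structural covariance has richer (e.g. spatially contiguous, lobar)
  structure, so absolute efficiency values are not comparable to real SCN
  studies — only recovery behaviour and directions are meaningful.
* End-to-end generator reliability of the global mean is higher than the
  calibration targets because the latent factors add shared variance on
  top of $\sigma_s$; the calibration experiments therefore use the direct
  latent-pair simulation (`simulateAttenuationPairs`), where the
  attenuation identity holds exactly.
* With 9 PPMS subjects (~54 images), PPMS correlation matrices are noisy;
  part of the group's higher efficiency at moderate thresholds reflects
  that sampling noise, which is also true of any equally small real group.
* No mixed-effects longitudinal model, no graph metrics beyond global
  efficiency, and no statistical test between group efficiency curves.
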