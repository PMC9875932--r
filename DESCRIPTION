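Package: cemorph
Title: Reliability of Brain Morphometry from Contrast-Enhanced MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluation pipeline for cortical-thickness morphometry derived
    from contrast-enhanced versus non-enhanced T1-weighted MRI. Provides
    paired agreement statistics (Pearson correlation, consistency intraclass
    correlation for the mean of two ratings, Bland-Altman bias and limits of
    agreement), per-patient longitudinal atrophy-rate estimation with group
    effect sizes (Cohen's d), and structural covariance network analysis
    (age residualization, correlation thresholding, global efficiency,
    subsampling error bands). A synthetic-cohort generator emulates the
    statistical structure of a longitudinal multiple-sclerosis morphometry
    study (PPMS and RRMS subgroups, same-session image pairs, two
    measurement methods differing in noise and contrast-induced bias) so
    that every analysis stage is verifiable against known ground truth.
    Includes readers for FreeSurfer aparc surface-statistics files and
    per-subject morphometry result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
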