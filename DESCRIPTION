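Package: gammarep
Title: Repetition Dynamics of the Visual Gamma Response
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies stimulus-induced gamma-band (35-100 Hz) responses from
    multi-sensor MEG trial epochs and models their repetition-related dynamics.
    Provides multitaper time-frequency estimation, baseline normalisation,
    posterior-sensor selection, two-thirds-of-peak gamma power and
    centre-of-gravity frequency metrics, single-trial gamma series with
    interquartile-range cleaning and within-condition z-scoring, dual-process
    (exponential decay plus linear trend) and broken-line repetition models,
    per-subject plasticity slopes, heart-rate-variability metrics (HFnu) from
    ECG, and a group-level statistical battery (trial-level linear mixed
    models with Satterthwaite degrees of freedom, mixed ANOVA with
    Greenhouse-Geisser correction and partial eta squared, rank tests,
    Spearman correlations, noncentral-t/F power and sensitivity calculators).
    Includes a synthetic cohort generator emulating a two-group
    (visual snow syndrome vs control) MEG study for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    lme4,
    lmerTest,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'dynamics.R'
    'hrv.R'
    'pipeline.R'
    'spectral.R'
    'stats.R'
    'synthetic.R'
    'utils.R'
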