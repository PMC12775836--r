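# gammarep

Repetition dynamics of the stimulus-induced visual gamma response, from
multi-sensor MEG trial epochs to group-level statistics.

## What it is for

High-contrast drifting gratings induce narrow-band gamma oscillations
(35–100 Hz) in early visual cortex. Across hundreds of repeated
presentations the gamma response (GR) follows a biphasic law: a fast
habituation over the first ~15 trials and then a slow, near-linear,
plasticity-like increase. In visual snow syndrome (VSS) this
repetition-related increase is steeper than in controls, and its
per-subject slope covaries with autonomic balance (HFnu, the normalised
high-frequency heart-rate variability). `gammarep` is for
neurophysiologists who want to quantify this phenomenology: it implements
the complete analysis chain, and a synthetic two-group cohort generator so
that every estimator can be validated by parameter recovery.

The core models:

* **GR metrics** — relative power `100·(stim − baseline)/baseline` on a
  2.5 Hz multitaper grid; GR power = mean of spectrum values exceeding
  `2/3` of the 35–100 Hz peak; GR frequency = centre of gravity of those
  values; sensors chosen by the 80%-of-maximum rule over posterior
  gradiometers (1–4 sensors).
* **Dual-process repetition model** — `y ~ A·exp(−trialN/τ) + B·trialN + C`
  fitted to the grand-average z-scored single-trial GR power; a
  broken-line (segmented) fit estimates the inflection ψ between
  habituation and increase.
* **Trial-level mixed model** —
  `GR_power ~ trialN·group + (1 + trialN | subject) + (1 + trialN | condition)`
  with Satterthwaite dfs, giving per-100-trial slopes per group.
* **HRV** — R-peak detection, R-R artefact correction, Welch spectrum of
  the R-R series, `HFnu = HF/(HF + LF)·100`.
* **Statistical battery** — mixed ANOVA with Greenhouse–Geisser ε and
  partial η², rank tests with `r = Z/√N`, Spearman correlations,
  noncentral-t power and minimal-detectable-η² calculators.

## Worked example

```r
library(gammarep)

cfg <- generatorConfig(nVss = 8, nControl = 8, seed = 1)  # small demo cohort
coh <- simulateCohort(cfg, ecg = FALSE)
st  <- singleTrialTable(coh)            # trials 1-137, IQR-cleaned, z-scored
crs <- grandAverageCourse(st)

fitDualProcess(crs$trialN, crs$z)
#> DualProcessFit: y ~ 0.8542 * exp(-n/7.42) + 0.007155 * n + -0.5352 (R2adj 0.490)
fitBrokenLine(crs$trialN, crs$z)
#> BrokenLineFit: inflection at 13.00 trials (slopes -0.05063 -> 0.006813)

lmm <- fitRepetitionLMM(st, "power")    # trials 15-137
round(lmm$slopes, 3)
#>     VSS control
#>   0.405   0.166
```

Reading the output: the early habituation decays with a time constant of
7.4 trials and the broken-line inflection lands at trial 13, after which
the z-scored response rises linearly. The mixed model estimates the
repetition-related power increase at 0.405 relative-power units per 100
trials in the VSS group versus 0.166 in controls — the generator's truth
for these group means is 0.45 and 0.19, so an 8+8-subject demo cohort
already recovers the ordering and approximate magnitudes (a 26+27 cohort
recovers them more tightly).

Closed-form design calculators:

```r
round(100 * powerTwoSampleT(0.74, 26, 27, sided = "one"), 1)  # 84.4 (% power)
round(minDetectableEtaP2(1, 50, 53), 3)                       # 0.133
```

An end-to-end run (`runPipeline()`, or
`Rscript inst/scripts/run_pipeline.R --seed 1 --out run1`) writes the GR
table, single-trial table, model fits, subject slopes, HRV table, a
statistics report and a JSON manifest, and `validateAcceptance()` checks
the run against the package's reference intervals.

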