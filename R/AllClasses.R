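#' @import methods
NULL

#' Configuration of the synthetic MEG/ECG cohort generator
#'
#' Holds every parameter of the simulated two-group (VSS vs control) visual
#' gamma experiment: design sizes, sampling, the condition tuning of gamma
#' frequency and power, the repetition-dynamics law, noise levels and the
#' autonomic (HRV) coupling.  Construct with [generatorConfig()].
#'
#' The generative law for the relative gamma power of trial \eqn{n} in
#' condition \eqn{c} is
#' \deqn{P(n, c) = base \cdot tuning(c) \cdot (1 + A e^{-n/\tau} + s\, n/100)}
#' where \eqn{s} is the subject's latent plasticity slope (per 100 trials) and
#' the gamma centre frequency is \eqn{f(c) + drift \cdot n / 100}.
#'
#' @slot nVss,nControl number of subjects per group.
#' @slot nTrialsPerCondition trials per drift-rate condition (default 90).
#' @slot conditions drift rates in degrees/s.
#' @slot fs MEG sampling rate (Hz).
#' @slot epochWindow epoch limits in seconds relative to stimulus onset.
#' @slot nSensors number of planar-gradiometer-like channels.
#' @slot posteriorSensors indices of the posterior subset carrying signal.
#' @slot gammaFreqTuning named numeric, condition -> gamma centre frequency
#'   (Hz); strictly increasing in drift rate.
#' @slot gammaPowerTuning named numeric, condition -> relative-power
#'   multiplier; bell-shaped with maximum at 1.2 deg/s.
#' @slot tauDecay time constant (trials) of the early gamma decrease.
#' @slot ampEarly amplitude A of the early decrease (relative units).
#' @slot slopeVss,slopeControl group means of the latent plasticity slope,
#'   relative-power units per 100 trials.
#' @slot slopeSd between-subject SD of the latent slope.
#' @slot freqDrift gamma frequency drift, Hz per 100 trials.
#' @slot baseRelativePower baseline-normalised response magnitude, percent
#'   over baseline, before condition tuning.
#' @slot noiseCv trial-to-trial coefficient of variation of gamma power
#'   (lognormal multiplicative noise).
#' @slot binNoiseSd additive per-frequency-bin noise on relative spectra
#'   (percent units; spectrum-level mode).
#' @slot noiseExponent spectral exponent of the 1/f^a background noise.
#' @slot evokedAmp amplitude of the evoked onset transient (noise-SD units).
#' @slot gammaBandwidth bandwidth of the narrowband gamma burst (Hz).
#' @slot hrvCoupling target rank correlation between the latent plasticity
#'   slope and HFnu.
#' @slot hfnuMean,hfnuSd population mean and SD of the target HFnu (percent).
#' @slot ecgFs,ecgDuration ECG sampling rate (Hz) and trace length (s).
#' @slot level `"spectra"` to simulate per-trial relative spectra directly,
#'   `"epochs"` for full time-domain multi-sensor epochs.
#' @slot seed integer RNG seed (NA for no seeding).
#' @export
setClass("GeneratorConfig", representation(
  nVss = "numeric", nControl = "numeric",
  nTrialsPerCondition = "numeric", conditions = "numeric",
  fs = "numeric", epochWindow = "numeric",
  nSensors = "numeric", posteriorSensors = "numeric",
  gammaFreqTuning = "numeric", gammaPowerTuning = "numeric",
  tauDecay = "numeric", ampEarly = "numeric",
  slopeVss = "numeric", slopeControl = "numeric", slopeSd = "numeric",
  freqDrift = "numeric", baseRelativePower = "numeric",
  noiseCv = "numeric", binNoiseSd = "numeric",
  noiseExponent = "numeric", evokedAmp = "numeric",
  gammaBandwidth = "numeric",
  hrvCoupling = "numeric", hfnuMean = "numeric", hfnuSd = "numeric",
  ecgFs = "numeric", ecgDuration = "numeric",
  level = "character", seed = "numeric"))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  k <- object@conditions
  ft <- object@gammaFreqTuning[as.character(k)]
  pt <- object@gammaPowerTuning[as.character(k)]
  if (anyNA(ft) || anyNA(pt))
    msg <- c(msg, "gammaFreqTuning/gammaPowerTuning must name every condition")
  o <- order(k)
  if (!anyNA(ft) && any(diff(ft[o]) <= 0))
    msg <- c(msg, "gammaFreqTuning must be strictly increasing in drift rate")
  if (!anyNA(pt)) {
    if (any(pt <= 0)) msg <- c(msg, "all power multipliers must be > 0")
    pk <- k[o][which.max(pt[o])]
    if (1.2 %in% k && pk != 1.2)
      msg <- c(msg, "gammaPowerTuning must peak at 1.2 deg/s")
  }
  if (object@tauDecay <= 0) msg <- c(msg, "tauDecay must be > 0")
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (object@baseRelativePower <= 0)
    msg <- c(msg, "baseRelativePower must be > 0")
  if (object@nVss + object@nControl < 1)
    msg <- c(msg, "at least one subject required")
  if (!object@level %in% c("spectra", "epochs"))
    msg <- c(msg, "level must be 'spectra' or 'epochs'")
  if (length(msg)) msg else TRUE
})

#' A single multi-sensor MEG trial epoch
#'
#' The atomic unit of the pipeline: one trial's sensors x samples array with
#' its condition label and overall trial order number.  Time zero is stimulus
#' onset; `t0` gives the time of the first sample.
#'
#' @slot data numeric matrix, sensors x samples.
#' @slot fs sampling rate (Hz).
#' @slot t0 time of first sample (s) relative to stimulus onset.
#' @slot condition drift rate (deg/s).
#' @slot trialN 1-based overall trial order number.
#' @slot subjectId,group subject identifier and group label.
#' @export
setClass("TrialEpoch", representation(
  data = "matrix", fs = "numeric", t0 = "numeric",
  condition = "numeric", trialN = "numeric",
  subjectId = "character", group = "character"))

setValidity("TrialEpoch", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (object@trialN < 1) msg <- c(msg, "trialN must be >= 1")
  if (length(object@group) == 1 && !object@group %in% c("VSS", "control"))
    msg <- c(msg, "group must be 'VSS' or 'control'")
  if (length(msg)) msg else TRUE
})

#' Time-frequency representation of one epoch
#'
#' Multitaper power on a uniform frequency grid (2.5 Hz resolution) and a
#' uniform time grid (2 ms step by default).
#'
#' @slot values sensors x frequencies x times array of power.
#' @slot freqs frequency grid (Hz).
#' @slot times time-window centres (s).
#' @slot units `"power"` (raw) or `"pct"` (percent change over baseline).
#' @export
setClass("TFR", representation(
  values = "array", freqs = "numeric", times = "numeric",
  units = "character"))

setValidity("TFR", function(object) {
  msg <- character()
  df <- diff(object@freqs)
  if (length(df) && (any(df <= 0) || diff(range(df)) > 1e-9))
    msg <- c(msg, "freqs must be strictly increasing and uniform")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "power values must be finite")
  if (object@units == "pct" && any(object@values < -100 - 1e-9))
    msg <- c(msg, "normalised values must be >= -100%")
  if (length(msg)) msg else TRUE
})

#' Baseline-normalised stimulus-window power spectrum
#'
#' Relative power, `100 * (stim - baseline) / baseline` percent, per
#' frequency bin, for one or more sensors (rows).  A sensor-averaged
#' spectrum has a single row.
#'
#' @slot relPower sensors x frequencies matrix of percent change.
#' @slot freqs frequency grid (Hz).
#' @slot sensors sensor labels (row names of `relPower`).
#' @export
setClass("RelativeSpectrum", representation(
  relPower = "matrix", freqs = "numeric", sensors = "character"))

setValidity("RelativeSpectrum", function(object) {
  msg <- character()
  if (ncol(object@relPower) != length(object@freqs))
    msg <- c(msg, "relPower columns must match freqs")
  if (any(object@relPower < -100 - 1e-9, na.rm = TRUE))
    msg <- c(msg, "relative power must be >= -100%")
  if (length(msg)) msg else TRUE
})

#' Per-trial relative gamma spectra for one subject
#'
#' Sensor-averaged, baseline-normalised single-trial spectra (trials x
#' frequency bins) together with trial metadata.  Produced either by the
#' spectral pipeline from time-domain epochs or directly by the generator in
#' spectrum-level mode.
#'
#' @slot relPower trials x frequencies matrix (percent change).
#' @slot freqs frequency grid (Hz).
#' @slot info data.frame with one row per trial: `condition`, `trialN`.
#' @slot subjectId,group subject identifier and group label.
#' @export
setClass("TrialSpectra", representation(
  relPower = "matrix", freqs = "numeric", info = "data.frame",
  subjectId = "character", group = "character"))

setValidity("TrialSpectra", function(object) {
  msg <- character()
  if (nrow(object@relPower) != nrow(object@info))
    msg <- c(msg, "relPower rows must match info rows")
  if (ncol(object@relPower) != length(object@freqs))
    msg <- c(msg, "relPower columns must match freqs")
  tn <- object@info$trialN
  if (anyDuplicated(tn)) msg <- c(msg, "trialN must be unique within subject")
  if (length(msg)) msg else TRUE
})

#' Gamma-response summary metrics of one averaged spectrum
#'
#' GR power is the mean of spectrum values exceeding 2/3 of the in-band peak
#' (35--100 Hz); GR frequency is the centre of gravity of those same values.
#'
#' @slot grPower percent change (mean of supra-threshold bins); NA if no
#'   positive peak.
#' @slot grFreq centre-of-gravity frequency (Hz); NA if no positive peak.
#' @slot peakFreq frequency of the in-band peak (Hz).
#' @slot nBinsUsed number of supra-threshold bins.
#' @slot sensorsUsed sensors averaged into the spectrum.
#' @slot ok FALSE when the spectrum has no positive in-band response.
#' @export
setClass("GRMetrics", representation(
  grPower = "numeric", grFreq = "numeric", peakFreq = "numeric",
  nBinsUsed = "numeric", sensorsUsed = "character", ok = "logical"))

#' Dual-process fit of a repetition time course
#'
#' Parameters of `y ~ A * exp(-trialN / tau) + B * trialN + C`: a fast
#' exponential decay (habituation) plus a slow linear trend.
#'
#' @slot A,tau,B,C fitted parameters.
#' @slot r2Adj adjusted R squared.
#' @slot tauCi 95% bootstrap CI for tau (NA when not requested/identifiable).
#' @slot flags character vector of diagnostics (e.g. "tau_unidentifiable").
#' @slot n number of points fitted.
#' @export
setClass("DualProcessFit", representation(
  A = "numeric", tau = "numeric", B = "numeric", C = "numeric",
  r2Adj = "numeric", tauCi = "numeric", flags = "character", n = "numeric"),
  prototype(A = NA_real_, tau = NA_real_, B = NA_real_, C = NA_real_,
            r2Adj = NA_real_, tauCi = c(NA_real_, NA_real_),
            flags = character(0), n = NA_real_))

setValidity("DualProcessFit", function(object) {
  msg <- character()
  if (!is.na(object@tau) && object@tau <= 0) msg <- c(msg, "tau must be > 0")
  if (!is.na(object@r2Adj) && object@r2Adj > 1 + 1e-12)
    msg <- c(msg, "r2Adj must be <= 1")
  if (length(msg)) msg else TRUE
})

#' Broken-line (segmented) fit of a repetition time course
#'
#' Continuous two-segment linear fit; `psi` is the inflection (breakpoint)
#' trial number separating the early decrease from the later increase.
#'
#' @slot psi inflection trial.
#' @slot slopePre,slopePost segment slopes (units of y per trial).
#' @slot psiCi 95% bootstrap CI for psi.
#' @slot flags diagnostics (e.g. "weak_break", "boundary").
#' @export
setClass("BrokenLineFit", representation(
  psi = "numeric", slopePre = "numeric", slopePost = "numeric",
  psiCi = "numeric", flags = "character"))

#' Synthetic single-lead ECG trace
#'
#' @slot samples numeric vector of field values.
#' @slot fs sampling rate (Hz).
#' @slot trueRTimes ground-truth R-peak times (s), for validation only.
#' @export
setClass("EcgTrace", representation(
  samples = "numeric", fs = "numeric", trueRTimes = "numeric"))

setValidity("EcgTrace", function(object) {
  msg <- character()
  rt <- object@trueRTimes
  if (length(rt) && any(diff(rt) <= 0))
    msg <- c(msg, "trueRTimes must be strictly increasing")
  if (length(rt) && (any(rt < 0) ||
      any(rt > length(object@samples) / object@fs)))
    msg <- c(msg, "trueRTimes must lie within the trace")
  if (length(msg)) msg else TRUE
})

#' Series of R-R intervals
#'
#' @slot intervals interbeat intervals (ms).
#' @slot tStart time of the first beat (s).
#' @slot corrected logical flag per interval (TRUE if artefact-corrected).
#' @export
setClass("RRSeries", representation(
  intervals = "numeric", tStart = "numeric", corrected = "logical"))

#' Heart-rate and heart-rate-variability metrics
#'
#' @slot bpm mean heart rate (beats/min).
#' @slot sdnn,rmssd time-domain HRV (ms).
#' @slot hf,lf spectral power of the R-R series in 0.15--0.40 and
#'   0.04--0.15 Hz (ms^2); NA when the series is too short.
#' @slot hfnu normalised high-frequency power, `100 * hf / (hf + lf)`.
#' @slot flags diagnostics (e.g. "too_short_for_spectral", "unreliable").
#' @export
setClass("HRVMetrics", representation(
  bpm = "numeric", sdnn = "numeric", rmssd = "numeric",
  hf = "numeric", lf = "numeric", hfnu = "numeric", flags = "character"))

setValidity("HRVMetrics", function(object) {
  msg <- character()
  if (!is.na(object@hfnu) && (object@hfnu < 0 || object@hfnu > 100))
    msg <- c(msg, "hfnu must be within [0, 100]")
  if (any(c(object@hf, object@lf) < 0, na.rm = TRUE))
    msg <- c(msg, "band powers must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A simulated cohort: subjects' trial data, ECG and ground truth
#'
#' @slot subjects named list, one element per subject; each holds
#'   `$spectra` (a [TrialSpectra-class]) or `$epochs` (list of
#'   [TrialEpoch-class]), and optionally `$ecg` (an [EcgTrace-class]).
#' @slot truth data.frame with one row per subject: `subject_id`, `group`,
#'   `slope` (latent plasticity slope, per 100 trials), `hfnu_target`.
#' @slot config the [GeneratorConfig-class] used.
#' @export
setClass("GammaCohort", representation(
  subjects = "list", truth = "data.frame", config = "GeneratorConfig"))

setValidity("GammaCohort", function(object) {
  if (length(object@subjects) != nrow(object@truth))
    "subjects and truth table must have the same length" else TRUE
})
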