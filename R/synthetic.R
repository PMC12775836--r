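#' @include AllClasses.R
NULL

# canonical analysis frequency grid: 5-120 Hz at the 2.5 Hz resolution of the
# spectral pipeline
.default_freqs <- seq(5, 120, by = 2.5)

#' Create a synthetic-cohort generator configuration
#'
#' Returns a validated [GeneratorConfig-class] describing the simulated
#' experiment: a two-group cohort (VSS patients vs controls) viewing drifting
#' annular gratings at five drift rates (90 interleaved trials each), with an
#' uninterrupted first block of 137 trials.  The gamma response follows a
#' biphasic trial law (exponential early decrease, time constant `tauDecay`,
#' plus a linear repetition-related increase whose group means differ) and a
#' bell-shaped drift-rate tuning of power with monotonically increasing
#' frequency tuning; ECG traces carry an HF/LF balance coupled to the
#' subject's plasticity slope.
#'
#' Dynamics defaults are calibrated to the full-sample estimates the pipeline
#' is meant to recover: `tauDecay = 7.8` trials, group slopes 0.45 (VSS) and
#' 0.19 (control) relative-power units per 100 trials, gamma frequency drift
#' 0.43 Hz per 100 trials.  Condition tuning defaults are qualitative only:
#' frequencies 48/51/55/62/68 Hz and power multipliers 0.7/0.9/1.0/0.75/0.5
#' at drift rates 0/0.6/1.2/3.6/6.0 deg/s.
#'
#' @param nVss,nControl subjects per group (defaults 26 and 27).
#' @param nTrialsPerCondition trials per condition (default 90).
#' @param conditions drift rates, deg/s.
#' @param fs MEG sampling rate, Hz.
#' @param epochWindow epoch limits (s) relative to stimulus onset.
#' @param nSensors,posteriorSensors channel count and signal-carrying subset.
#' @param gammaFreqTuning,gammaPowerTuning named numeric vectors
#'   (names = conditions).
#' @param tauDecay,ampEarly early-decrease time constant (trials) and
#'   amplitude (relative units).
#' @param slopeVss,slopeControl,slopeSd latent plasticity slope distribution,
#'   relative-power units per 100 trials.
#' @param freqDrift gamma frequency drift, Hz per 100 trials.
#' @param baseRelativePower baseline response magnitude, percent over
#'   baseline (before condition tuning).  The default 130% makes the
#'   condition-average response approximately 100% over baseline (1.0
#'   proportion units), so that per-100-trial slopes are expressed relative
#'   to the initial response.
#' @param noiseCv trial-to-trial CV of single-trial gamma power.
#' @param binNoiseSd additive spectral noise per bin, percent units.
#' @param noiseExponent 1/f^a background exponent (time-domain mode).
#' @param evokedAmp evoked transient amplitude, noise-SD units.
#' @param gammaBandwidth gamma burst bandwidth, Hz.
#' @param hrvCoupling target rank correlation between plasticity slope and
#'   HFnu.
#' @param hfnuMean,hfnuSd population distribution of the HFnu target (%).
#' @param ecgFs,ecgDuration ECG sampling rate (Hz) and duration (s).
#' @param level `"spectra"` (fast; simulate per-trial relative spectra
#'   directly) or `"epochs"` (full time-domain multi-sensor epochs).
#' @param seed RNG seed used by [simulateCohort()].
#' @return a [GeneratorConfig-class] object.
#' @examples
#' cfg <- generatorConfig(nVss = 2, nControl = 2, seed = 1)
#' cfg
#' @export
generatorConfig <- function(nVss = 26, nControl = 27,
                            nTrialsPerCondition = 90,
                            conditions = c(0, 0.6, 1.2, 3.6, 6.0),
                            fs = 1000, epochWindow = c(-1.2, 1.2),
                            nSensors = 24,
                            posteriorSensors = seq(nSensors - 9, nSensors),
                            gammaFreqTuning = NULL, gammaPowerTuning = NULL,
                            tauDecay = 7.8, ampEarly = 0.35,
                            slopeVss = 0.45, slopeControl = 0.19,
                            slopeSd = 0.15,
                            freqDrift = 0.43, baseRelativePower = 130,
                            noiseCv = 0.3, binNoiseSd = 12,
                            noiseExponent = 1, evokedAmp = 2,
                            gammaBandwidth = 8,
                            hrvCoupling = 0.5, hfnuMean = 50, hfnuSd = 15,
                            ecgFs = 250, ecgDuration = 300,
                            level = c("spectra", "epochs"), seed = NA_real_) {
  level <- match.arg(level)
  if (is.null(gammaFreqTuning))
    gammaFreqTuning <- stats::setNames(c(48, 51, 55, 62, 68),
                                       c(0, 0.6, 1.2, 3.6, 6.0))
  if (is.null(gammaPowerTuning))
    gammaPowerTuning <- stats::setNames(c(0.7, 0.9, 1.0, 0.75, 0.5),
                                        c(0, 0.6, 1.2, 3.6, 6.0))
  new("GeneratorConfig",
      nVss = nVss, nControl = nControl,
      nTrialsPerCondition = nTrialsPerCondition, conditions = conditions,
      fs = fs, epochWindow = epochWindow, nSensors = nSensors,
      posteriorSensors = posteriorSensors,
      gammaFreqTuning = gammaFreqTuning, gammaPowerTuning = gammaPowerTuning,
      tauDecay = tauDecay, ampEarly = ampEarly,
      slopeVss = slopeVss, slopeControl = slopeControl, slopeSd = slopeSd,
      freqDrift = freqDrift, baseRelativePower = baseRelativePower,
      noiseCv = noiseCv, binNoiseSd = binNoiseSd,
      noiseExponent = noiseExponent, evokedAmp = evokedAmp,
      gammaBandwidth = gammaBandwidth,
      hrvCoupling = hrvCoupling, hfnuMean = hfnuMean, hfnuSd = hfnuSd,
      ecgFs = ecgFs, ecgDuration = ecgDuration,
      level = level, seed = seed)
}

# generative law: expected relative power (proportion of baseline) and gamma
# centre frequency (Hz) for one trial
.gamma_law <- function(config, slope, trialN, condition) {
  key <- as.character(condition)
  tune_p <- config@gammaPowerTuning[key]
  tune_f <- config@gammaFreqTuning[key]
  if (is.na(tune_p) || is.na(tune_f))
    stop("unknown condition: ", condition)
  mod <- 1 + config@ampEarly * exp(-trialN / config@tauDecay) +
    slope * trialN / 100
  # a gamma response cannot go negative: subjects whose (rare) strongly
  # negative latent slope would extinguish the response floor at 5% of the
  # baseline magnitude instead
  mod <- pmax(mod, 0.05)
  p <- config@baseRelativePower / 100 * unname(tune_p) * mod
  list(p = p, fc = unname(tune_f) + config@freqDrift * trialN / 100)
}

# one trial's relative spectrum (percent units) on the canonical grid:
# Gaussian gamma bump calibrated so that the mean relative power over the
# +/-15 Hz band around fc equals 100 * p, plus additive bin noise
.simulate_trial_spectrum <- function(config, p, fc,
                                     freq_grid = .default_freqs) {
  sigma <- config@gammaBandwidth / 2
  g <- exp(-(freq_grid - fc)^2 / (2 * sigma^2))
  # calibration band anchored at the nearest grid bin, matching the
  # +/-15 Hz analysis band around the condition-average grid peak
  fc_grid <- freq_grid[which.min(abs(freq_grid - fc))]
  band <- abs(freq_grid - fc_grid) <= 15 + 1e-9
  amp <- 100 * p * sum(band) / sum(g[band])
  amp * g + stats::rnorm(length(freq_grid), 0, config@binNoiseSd)
}

# fraction of unit-variance 1/f^a noise power falling in [lo, hi] Hz for an
# n-sample record at fs Hz
.pink_band_fraction <- function(n, fs, exponent, lo, hi) {
  f <- seq_len(n %/% 2) * fs / n
  w <- f^(-exponent)
  sum(w[f >= lo & f <= hi]) / sum(w)
}

# default fixed sensor gains over the posterior subset: one dominant sensor,
# neighbours at 60-90%
.posterior_gains <- function(np) {
  if (np == 1) return(1)
  c(1, seq(0.9, 0.6, length.out = np - 1))
}

#' Simulate one multi-sensor trial epoch
#'
#' Time-domain realisation of the generative law: 1/f background noise on all
#' sensors, an evoked transient at stimulus onset and a narrowband
#' amplitude-modulated gamma burst (centre frequency set by the condition
#' tuning plus slow trial drift; relative power set by the biphasic trial
#' law) projected onto the posterior sensors with fixed gains.
#'
#' @param config a [GeneratorConfig-class].
#' @param subjectSlope latent plasticity slope, relative units per 100
#'   trials.
#' @param trialN 1-based overall trial number.
#' @param condition drift rate (must be one of `config@conditions`).
#' @param seed optional integer; identical seeds give identical epochs.
#' @param gains optional per-posterior-sensor gains (default: one dominant
#'   sensor, neighbours at 60--90%).
#' @return a [TrialEpoch-class].
#' @examples
#' cfg <- generatorConfig(nSensors = 4, posteriorSensors = 3:4, fs = 500)
#' ep <- simulateTrialEpoch(cfg, 0.45, trialN = 1, condition = 1.2, seed = 1)
#' dim(ep@data)
#' @export
simulateTrialEpoch <- function(config, subjectSlope, trialN, condition,
                               seed = NULL, gains = NULL) {
  if (trialN < 1) stop("trialN must be >= 1")
  if (!condition %in% config@conditions)
    stop("unknown condition: ", condition)
  if (!is.null(seed)) set.seed(seed)
  law <- .gamma_law(config, subjectSlope, trialN, condition)
  fs <- config@fs
  nsamp <- round(diff(config@epochWindow) * fs)
  t <- config@epochWindow[1] + (seq_len(nsamp) - 1) / fs
  ns <- config@nSensors
  post <- config@posteriorSensors
  if (is.null(gains)) gains <- .posterior_gains(length(post))

  dat <- t(vapply(seq_len(ns),
                  function(i) pink_noise(nsamp, config@noiseExponent),
                  numeric(nsamp)))

  # evoked transient: 10 Hz Gabor peaking ~120 ms after onset
  ev <- config@evokedAmp * exp(-(t - 0.12)^2 / (2 * 0.03^2)) *
    sin(2 * pi * 10 * (t - 0.12))
  dat[post, ] <- dat[post, ] + outer(gains, ev)

  # narrowband gamma burst during stimulation, calibrated so that the
  # +/-15 Hz band power relative to the baseline noise equals law$p (with
  # lognormal trial-to-trial noise) at the dominant sensor
  cv <- config@noiseCv
  sl <- sqrt(log(1 + cv^2))
  p_trial <- law$p * stats::rlnorm(1, -sl^2 / 2, sl)
  band_var <- .pink_band_fraction(nsamp, fs, config@noiseExponent,
                                  law$fc - 15, law$fc + 15)
  # complex Gaussian envelope band-limited to ~sigma_b Hz
  sigma_b <- config@gammaBandwidth / 2
  nf <- nsamp
  fgrid <- c(0, seq_len(nf - 1)) * fs / nf
  fgrid <- pmin(fgrid, fs - fgrid)
  shape <- exp(-fgrid^2 / (2 * sigma_b^2))
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf))
  env <- stats::fft(stats::fft(z) * shape, inverse = TRUE) / nf
  carrier <- Re(env * exp(2i * pi * law$fc * t))
  carrier <- carrier / stats::sd(carrier)
  on <- t >= 0 & t <= 1.2
  ramp <- pmin(1, pmax(0, (t / 0.05))) * pmin(1, pmax(0, (1.2 - t) / 0.05))
  burst <- carrier * ramp * on
  burst <- burst * sqrt(p_trial * band_var) /
    max(stats::sd(burst[t >= 0.3 & t <= 1.2]), 1e-12)
  dat[post, ] <- dat[post, ] + outer(gains, burst)

  new("TrialEpoch", data = dat, fs = fs, t0 = config@epochWindow[1],
      condition = condition, trialN = trialN,
      subjectId = "sim", group = "control")
}

#' Simulate a synthetic ECG trace with a target HF/LF balance
#'
#' R-R intervals are a base interval modulated by an LF (0.1 Hz) and an HF
#' (0.25 Hz) sinusoid plus white jitter; the HF/LF amplitude ratio is set so
#' that the HF fraction of modulation power equals `hfnuTarget`.  QRS
#' complexes are Gaussian templates placed at the beat times.
#'
#' @param config a [GeneratorConfig-class] (uses `ecgFs`, `ecgDuration`).
#' @param hfnuTarget target HFnu, percent in (0, 100).
#' @param seed optional integer seed.
#' @return an [EcgTrace-class] with ground-truth R times.
#' @export
simulateEcg <- function(config, hfnuTarget = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config@ecgFs
  dur <- config@ecgDuration
  base <- 800                       # ms
  sd_mod <- 40                      # ms, total sinusoidal modulation SD
  h <- max(min(hfnuTarget / 100, 0.99), 0.01)
  a_hf <- sd_mod * sqrt(2) * sqrt(h)
  a_lf <- sd_mod * sqrt(2) * sqrt(1 - h)
  ph_lf <- stats::runif(1, 0, 2 * pi)
  ph_hf <- stats::runif(1, 0, 2 * pi)
  tk <- 0.5
  beats <- numeric(0)
  while (tk < dur - 0.5) {
    beats <- c(beats, tk)
    rr <- base + a_lf * sin(2 * pi * 0.1 * tk + ph_lf) +
      a_hf * sin(2 * pi * 0.25 * tk + ph_hf) + stats::rnorm(1, 0, 5)
    tk <- tk + rr / 1000
  }
  t <- (seq_len(round(dur * fs)) - 1) / fs
  x <- stats::rnorm(length(t), 0, 0.02)
  for (b in beats)
    x <- x + exp(-(t - b)^2 / (2 * 0.01^2))
  new("EcgTrace", samples = x, fs = fs, trueRTimes = beats)
}

#' Simulate one subject's trials and ECG
#'
#' Draws the subject's latent plasticity slope around the group mean (VSS
#' mean exceeding control mean), interleaves the five drift-rate conditions
#' in random order (90 trials each) and generates either per-trial relative
#' spectra (`level = "spectra"`) or full time-domain epochs
#' (`level = "epochs"`).  The subject's HFnu target is coupled to the latent
#' slope through a Gaussian copula with rank correlation `hrvCoupling`.
#'
#' @param config a [GeneratorConfig-class].
#' @param subjectId subject identifier.
#' @param group `"VSS"` or `"control"`.
#' @param seed optional integer seed.
#' @param ecg logical; simulate the ECG trace (default TRUE).
#' @return a list with elements `spectra` (a [TrialSpectra-class]) or
#'   `epochs` (list of [TrialEpoch-class]), `ecg`, `slope` (latent slope) and
#'   `hfnuTarget`.
#' @examples
#' cfg <- generatorConfig(nVss = 1, nControl = 1, nTrialsPerCondition = 4)
#' s <- simulateSubject(cfg, "s01", "VSS", seed = 1, ecg = FALSE)
#' s$spectra
#' @export
simulateSubject <- function(config, subjectId, group = c("VSS", "control"),
                            seed = NULL, ecg = TRUE) {
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  mu <- if (group == "VSS") config@slopeVss else config@slopeControl
  slope <- stats::rnorm(1, mu, config@slopeSd)

  # HFnu target rank-coupled to the latent slope (Gaussian copula); the
  # slope is standardised against the pooled cohort distribution
  n_tot <- config@nVss + config@nControl
  pv <- config@nVss / n_tot
  mu_pool <- pv * config@slopeVss + (1 - pv) * config@slopeControl
  sd_pool <- sqrt(config@slopeSd^2 +
                  pv * (1 - pv) * (config@slopeVss - config@slopeControl)^2)
  rho <- 2 * sin(pi * config@hrvCoupling / 6)
  zs <- (slope - mu_pool) / sd_pool
  zh <- rho * zs + sqrt(1 - rho^2) * stats::rnorm(1)
  hfnu_target <- max(min(config@hfnuMean + config@hfnuSd * zh, 95), 5)

  conds <- sample(rep(config@conditions, each = config@nTrialsPerCondition))
  n_trials <- length(conds)
  info <- data.frame(condition = conds, trialN = seq_len(n_trials),
                     block1 = seq_len(n_trials) <= 137)

  out <- list(slope = slope, hfnuTarget = hfnu_target)
  if (config@level == "spectra") {
    sl <- sqrt(log(1 + config@noiseCv^2))
    mat <- matrix(0, n_trials, length(.default_freqs))
    for (i in seq_len(n_trials)) {
      lw <- .gamma_law(config, slope, info$trialN[i], info$condition[i])
      p_noisy <- lw$p * stats::rlnorm(1, -sl^2 / 2, sl)
      mat[i, ] <- .simulate_trial_spectrum(config, p_noisy, lw$fc)
    }
    colnames(mat) <- .default_freqs
    out$spectra <- new("TrialSpectra", relPower = mat,
                       freqs = .default_freqs, info = info,
                       subjectId = subjectId, group = group)
  } else {
    gains <- .posterior_gains(length(config@posteriorSensors))
    out$epochs <- lapply(seq_len(n_trials), function(i) {
      ep <- simulateTrialEpoch(config, slope, info$trialN[i],
                               info$condition[i], gains = gains)
      ep@subjectId <- subjectId
      ep@group <- group
      ep
    })
  }
  if (ecg) out$ecg <- simulateEcg(config, hfnu_target)
  out
}

#' Simulate a full synthetic cohort
#'
#' Generates `nVss + nControl` subjects under `config` and records every
#' latent parameter in a truth table for recovery testing.  Identical seeds
#' yield identical cohorts.
#'
#' @param config a [GeneratorConfig-class]; `config@seed` seeds the run.
#' @param ecg logical; simulate ECG traces (default TRUE).
#' @return a [GammaCohort-class].
#' @examples
#' cfg <- generatorConfig(nVss = 1, nControl = 1, nTrialsPerCondition = 3,
#'                        seed = 7)
#' coh <- simulateCohort(cfg, ecg = FALSE)
#' truthTable(coh)
#' @export
simulateCohort <- function(config, ecg = TRUE) {
  if (config@nVss + config@nControl < 1) stop("zero subjects requested")
  if (!is.na(config@seed)) set.seed(config@seed)
  ids <- sprintf("S%02d", seq_len(config@nVss + config@nControl))
  groups <- c(rep("VSS", config@nVss), rep("control", config@nControl))
  subjects <- vector("list", length(ids))
  names(subjects) <- ids
  truth <- data.frame(subject_id = ids, group = groups,
                      slope = NA_real_, hfnu_target = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    s <- simulateSubject(config, ids[i], groups[i], ecg = ecg)
    subjects[[i]] <- s
    truth$slope[i] <- s$slope
    truth$hfnu_target[i] <- s$hfnuTarget
  }
  new("GammaCohort", subjects = subjects, truth = truth, config = config)
}
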