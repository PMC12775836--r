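#' @include AllClasses.R
NULL

#' Subtract condition-average evoked responses from single trials
#'
#' Removes the phase-locked (evoked) component by subtracting, per stimulus
#' condition, the time-domain average across that condition's trials from
#' every trial.  What remains is the induced (non-phase-locked) activity.
#' Trial count and ordering are preserved; conditions with fewer than two
#' trials are passed through unmodified with a warning and flagged via
#' `attr(, "unsubtracted_conditions")`.
#'
#' @param epochs list of [TrialEpoch-class] (any mixture of conditions).
#' @return list of [TrialEpoch-class] in the input order.
#' @export
subtractEvoked <- function(epochs) {
  conds <- vapply(epochs, function(e) e@condition, numeric(1))
  out <- epochs
  skipped <- numeric(0)
  for (cn in unique(conds)) {
    idx <- which(conds == cn)
    if (length(idx) < 2) {
      warning("condition ", cn, " has < 2 trials; evoked not subtracted")
      skipped <- c(skipped, cn)
      next
    }
    avg <- Reduce(`+`, lapply(epochs[idx], function(e) e@data)) / length(idx)
    for (i in idx) out[[i]]@data <- out[[i]]@data - avg
  }
  if (length(skipped)) attr(out, "unsubtracted_conditions") <- skipped
  out
}

#' Multitaper time-frequency decomposition of one epoch
#'
#' Sliding-window multitaper power with a 10 Hz bandwidth (half-bandwidth
#' 5 Hz), 2.5 Hz frequency resolution (0.4 s window) and a 2 ms time step.
#' Those printed parameters jointly fix the taper count: 2 T W - 1 = 3 DPSS
#' tapers.
#'
#' @param epoch a [TrialEpoch-class]; must cover at least -0.9 to 1.2 s.
#' @param fmin,fmax frequency range (Hz); `fs >= 2 * fmax` required.
#' @param timeStep spacing of window centres (s), default 0.002.
#' @param windowLength sliding-window length (s), default 0.4 (sets the
#'   2.5 Hz frequency resolution).
#' @return a [TFR-class] with raw power values.
#' @export
multitaperTFR <- function(epoch, fmin = 5, fmax = 120, timeStep = 0.002,
                          windowLength = 0.4) {
  fs <- epoch@fs
  if (fs < 2 * fmax) stop("fs must be >= 2 * fmax")
  nsamp <- ncol(epoch@data)
  t_end <- epoch@t0 + (nsamp - 1) / fs
  if (epoch@t0 > -0.9 + 1e-9 || t_end < 1.2 - 2 / fs)
    stop("epoch too short: must cover [-0.9, 1.2] s")
  n_win <- round(windowLength * fs)
  if (n_win > nsamp) stop("epoch shorter than the analysis window")
  hbw <- 5                                  # half-bandwidth, Hz
  nw <- windowLength * hbw                  # time-bandwidth product
  k <- max(1, floor(2 * nw - 1))
  tap <- dpss_tapers(n_win, nw, k)

  df <- 1 / windowLength
  kmin <- ceiling(fmin / df - 1e-9)
  kmax <- floor(fmax / df + 1e-9)
  fidx <- (kmin:kmax) + 1L                  # FFT bin indices (1-based)
  freq <- (kmin:kmax) * df

  centres <- seq(epoch@t0 + windowLength / 2, t_end - windowLength / 2,
                 by = timeStep)
  ns <- nrow(epoch@data)
  vals <- array(0, dim = c(ns, length(freq), length(centres)))
  # taper-expanded data matrix: for each centre, one FFT over n_win x (ns*k)
  tap_big <- tap[, rep(seq_len(k), ns), drop = FALSE]
  sensor_of <- rep(seq_len(ns), each = k)
  for (ci in seq_along(centres)) {
    i0 <- round((centres[ci] - windowLength / 2 - epoch@t0) * fs) + 1L
    seg <- t(epoch@data[, i0:(i0 + n_win - 1L), drop = FALSE])
    X <- stats::mvfft(seg[, sensor_of, drop = FALSE] * tap_big)
    pw <- Mod(X[fidx, , drop = FALSE])^2
    for (si in seq_len(ns))
      vals[si, , ci] <- rowMeans(pw[, sensor_of == si, drop = FALSE])
  }
  new("TFR", values = vals, freqs = freq, times = centres, units = "power")
}

#' Baseline-normalise a TFR into a relative stimulus-window spectrum
#'
#' Per sensor and frequency bin, averages power over the stimulation window
#' and the pre-stimulus baseline window and forms
#' `100 * (stimulation - baseline) / baseline` percent.
#'
#' @param tfr a [TFR-class] with raw power.
#' @param baseline,stim analysis windows in seconds (defaults -0.9--0 and
#'   0.3--1.2); windows are truncated to the available window centres
#'   (sliding windows cannot be centred within half a window of the epoch
#'   edges).
#' @return a [RelativeSpectrum-class] with one row per sensor.
#' @export
normalizeToBaseline <- function(tfr, baseline = c(-0.9, 0),
                                stim = c(0.3, 1.2)) {
  tt <- tfr@times
  # sliding windows cannot be centred closer than half a window to the
  # epoch edges; windows are truncated to the available centres
  bsel <- tt >= baseline[1] & tt <= baseline[2]
  ssel <- tt >= stim[1] & tt <= stim[2]
  if (!any(bsel) || !any(ssel))
    stop("analysis windows do not overlap the TFR time range")
  b <- apply(tfr@values[, , bsel, drop = FALSE], c(1, 2), mean)
  s <- apply(tfr@values[, , ssel, drop = FALSE], c(1, 2), mean)
  if (any(b <= 0))
    stop("zero baseline power at ", sum(b <= 0),
         " sensor x frequency bin(s); cannot normalise")
  rel <- 100 * (s - b) / b
  sens <- if (!is.null(rownames(tfr@values))) rownames(tfr@values)
          else sprintf("MEG%02d", seq_len(nrow(rel)))
  rownames(rel) <- sens
  new("RelativeSpectrum", relPower = rel, freqs = tfr@freqs, sensors = sens)
}

#' Select gamma-responsive sensors around the maximal sensor
#'
#' From the posterior sensor subset, finds the sensor with the largest
#' average normalised power in `band` (default 35--80 Hz) and keeps every
#' posterior sensor whose band average exceeds `frac` (default 80%) of that
#' maximum, up to `maxN` sensors (the largest are kept; ties broken by
#' sensor order).  The maximal sensor is always included.  If no posterior
#' sensor has a positive band average, the maximal sensor alone is returned
#' with a warning.
#'
#' @param spectra a [RelativeSpectrum-class] with one row per sensor.
#' @param posteriorSet sensor names or row indices defining the posterior
#'   subset.
#' @param band selection band (Hz).
#' @param frac fraction of the maximal sensor's band average.
#' @param maxN maximum number of sensors.
#' @return character vector of selected sensor names.
#' @export
selectSensors <- function(spectra, posteriorSet, band = c(35, 80),
                          frac = 0.8, maxN = 4) {
  if (length(posteriorSet) == 0) stop("posteriorSet must be non-empty")
  rp <- spectra@relPower
  if (is.numeric(posteriorSet)) posteriorSet <- spectra@sensors[posteriorSet]
  posteriorSet <- intersect(posteriorSet, spectra@sensors)
  fsel <- spectra@freqs >= band[1] & spectra@freqs <= band[2]
  if (!any(fsel)) stop("selection band outside the frequency grid")
  avg <- rowMeans(rp[posteriorSet, fsel, drop = FALSE])
  imax <- which.max(avg)
  if (avg[imax] <= 0) {
    warning("no positive band-average power; returning maximal sensor only")
    return(posteriorSet[imax])
  }
  qualifies <- avg > frac * avg[imax]       # strict: "exceeded"
  qualifies[imax] <- TRUE
  cand <- which(qualifies)
  if (length(cand) > maxN)
    cand <- cand[order(-avg[cand], cand)][seq_len(maxN)]
  posteriorSet[sort(cand)]
}

#' Gamma-response power and frequency of an averaged spectrum
#'
#' GR power is the mean of the spectrum values exceeding 2/3 of the peak
#' value in the 35--100 Hz band; GR frequency is the centre of gravity
#' (power-weighted mean frequency) of those same values.  A spectrum with no
#' positive in-band peak is flagged as "no response" and both metrics are
#' reported missing.
#'
#' @param spectrum a [RelativeSpectrum-class] (rows averaged if several) or
#'   a numeric vector with a `freqs` attribute / accompanying `freqs`
#'   argument.
#' @param band analysis band (Hz), default 35--100.
#' @param frac peak fraction threshold, default 2/3.
#' @param freqs frequency grid when `spectrum` is a bare numeric vector.
#' @return a [GRMetrics-class].
#' @examples
#' m <- computeGRMetrics(c(10, 20, 10), freqs = c(40, 50, 60))
#' grPower(m); grFreq(m)
#' @export
computeGRMetrics <- function(spectrum, band = c(35, 100), frac = 2 / 3,
                             freqs = NULL) {
  sensors <- character(0)
  if (is(spectrum, "RelativeSpectrum")) {
    freqs <- spectrum@freqs
    sensors <- spectrum@sensors
    spectrum <- colMeans(spectrum@relPower)
  }
  if (is.null(freqs)) stop("freqs required for a bare numeric spectrum")
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("band outside the frequency grid")
  f <- freqs[sel]
  p <- spectrum[sel]
  peak <- max(p)
  if (peak <= 0)
    return(new("GRMetrics", grPower = NA_real_, grFreq = NA_real_,
               peakFreq = f[which.max(p)], nBinsUsed = 0,
               sensorsUsed = sensors, ok = FALSE))
  inc <- p > frac * peak                    # strict: "exceeded"
  new("GRMetrics",
      grPower = mean(p[inc]),
      grFreq = sum(f[inc] * p[inc]) / sum(p[inc]),
      peakFreq = f[which.max(p)],
      nBinsUsed = sum(inc), sensorsUsed = sensors, ok = TRUE)
}

#' Reduce time-domain epochs to selected-sensor single-trial spectra
#'
#' Full sensor-level spectral pipeline for one subject: evoked subtraction
#' per condition, multitaper TFR per trial, baseline normalisation, sensor
#' selection (80%-of-maximum rule on the trial-average spectrum over the
#' posterior subset) and averaging over the selected sensors.
#'
#' @param epochs list of [TrialEpoch-class] for one subject.
#' @param posteriorSensors sensor indices (or names) forming the posterior
#'   subset.
#' @param timeStep multitaper window-centre step (s); the printed analysis
#'   uses 0.002, coarser steps give near-identical window averages faster.
#' @param ... further arguments to [multitaperTFR()].
#' @return a list: `spectra` (a [TrialSpectra-class], selected-sensor
#'   average), `sensors` (selected sensor names), `sensorAverage`
#'   (the per-sensor trial-average [RelativeSpectrum-class]).
#' @export
epochsToTrialSpectra <- function(epochs, posteriorSensors,
                                 timeStep = 0.01, ...) {
  stopifnot(length(epochs) >= 1)
  clean <- subtractEvoked(epochs)
  rels <- lapply(clean, function(e)
    normalizeToBaseline(multitaperTFR(e, timeStep = timeStep, ...)))
  fr <- rels[[1]]@freqs
  avg <- Reduce(`+`, lapply(rels, function(r) r@relPower)) / length(rels)
  avg_spec <- new("RelativeSpectrum", relPower = avg, freqs = fr,
                  sensors = rels[[1]]@sensors)
  sens <- selectSensors(avg_spec, posteriorSensors)
  mat <- t(vapply(rels, function(r)
    colMeans(r@relPower[sens, , drop = FALSE]), numeric(length(fr))))
  info <- data.frame(
    condition = vapply(epochs, function(e) e@condition, numeric(1)),
    trialN = vapply(epochs, function(e) e@trialN, numeric(1)))
  spectra <- new("TrialSpectra", relPower = mat, freqs = fr, info = info,
                 subjectId = epochs[[1]]@subjectId,
                 group = epochs[[1]]@group)
  list(spectra = spectra, sensors = sens, sensorAverage = avg_spec)
}

#' Condition-average gamma-response table for a cohort
#'
#' Averages each subject's single-trial relative spectra within condition
#' and summarises them with [computeGRMetrics()].  The natural logarithm of
#' GR power (used downstream by the mixed ANOVA to normalise the
#' distribution) is included; non-positive GR power yields a missing
#' log value and a diagnostic `ok = FALSE`.
#'
#' @param cohort a [GammaCohort-class] (spectrum-level, or epochs already
#'   reduced with [epochsToTrialSpectra()]).
#' @param trials optional restriction of trial numbers (e.g. `1:137`).
#' @return data.frame: subject_id, group, condition, gr_power_pct,
#'   log_gr_power, gr_freq_hz, peak_freq_hz, n_bins, ok.
#' @export
grTable <- function(cohort, trials = NULL) {
  rows <- list()
  for (sid in names(cohort@subjects)) {
    sp <- .subject_spectra(cohort, sid)
    info <- sp@info
    keep <- if (is.null(trials)) rep(TRUE, nrow(info))
            else info$trialN %in% trials
    for (cn in sort(unique(info$condition))) {
      idx <- keep & info$condition == cn
      if (!any(idx)) next
      avg <- colMeans(sp@relPower[idx, , drop = FALSE])
      m <- computeGRMetrics(avg, freqs = sp@freqs)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, group = sp@group, condition = cn,
        gr_power_pct = m@grPower,
        log_gr_power = if (m@ok && m@grPower > 0) log(m@grPower)
                       else NA_real_,
        gr_freq_hz = m@grFreq, peak_freq_hz = m@peakFreq,
        n_bins = m@nBinsUsed, ok = m@ok, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# fetch (or lazily compute) a subject's TrialSpectra
.subject_spectra <- function(cohort, sid) {
  s <- cohort@subjects[[sid]]
  if (!is.null(s$spectra)) return(s$spectra)
  if (!is.null(s$epochs))
    return(epochsToTrialSpectra(
      s$epochs, cohort@config@posteriorSensors)$spectra)
  stop("subject ", sid, " has neither spectra nor epochs")
}
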