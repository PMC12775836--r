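#' @include AllClasses.R
NULL

#' Detect R peaks in an ECG trace
#'
#' Moving-average QRS detector: the trace is band-passed 5--25 Hz, squared,
#' smoothed with a 120 ms moving-average envelope and thresholded
#' adaptively; local envelope maxima become candidate beats, a 200 ms
#' refractory period suppresses double detections, and each beat is refined
#' to the nearby absolute maximum of the band-passed signal.  Detection is
#' invariant to amplitude scaling.
#'
#' @param ecg an [EcgTrace-class]; `fs >= 250` Hz recommended.
#' @return integer vector of peak sample indices (empty, with a warning, on
#'   flat input).
#' @export
detectRPeaks <- function(ecg) {
  x <- ecg@samples
  fs <- ecg@fs
  if (stats::sd(x) == 0) {
    warning("flat input; no R peaks")
    return(integer(0))
  }
  bf <- signal::butter(2, c(5, 25) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x)
  env <- moving_average(xb^2, round(0.12 * fs))
  thr <- stats::median(env) + 2 * stats::mad(env)
  refr <- round(0.2 * fs)
  above <- env > thr
  if (!any(above)) {
    warning("no envelope excursions above threshold")
    return(integer(0))
  }
  # rising edges of supra-threshold segments
  starts <- which(diff(c(FALSE, above)) == 1)
  ends <- which(diff(c(above, FALSE)) == -1)
  peaks <- integer(0)
  half <- round(0.05 * fs)
  for (i in seq_along(starts)) {
    seg <- starts[i]:ends[i]
    cand <- seg[which.max(env[seg])]
    w <- max(1, cand - half):min(length(x), cand + half)
    pk <- w[which.max(abs(xb[w]))]
    if (length(peaks) == 0 || pk - peaks[length(peaks)] >= refr)
      peaks <- c(peaks, pk)
  }
  peaks
}

#' Convert peak indices to an R-R interval series
#'
#' @param peaks peak sample indices.
#' @param fs sampling rate (Hz).
#' @return an [RRSeries-class] (intervals in ms, none corrected).
#' @export
peaksToRR <- function(peaks, fs) {
  if (length(peaks) < 2) stop("need at least 2 peaks")
  new("RRSeries", intervals = diff(peaks) / fs * 1000,
      tStart = peaks[1] / fs, corrected = logical(length(peaks) - 1))
}

#' Correct artefactual R-R intervals
#'
#' Compares every interval to the local median (centred window of 11):
#' intervals at least twice the local median are treated as missed beats
#' and split into equal sub-intervals (duration conserved); intervals at
#' most half the local median are treated as extra detections and merged
#' with their successor; remaining ectopic values (outside 0.7--1.3 of the
#' local median) are replaced by the local median.  If more than 20%
#' of intervals need correction the series is flagged unreliable.
#'
#' @param rr an [RRSeries-class] with at least 3 intervals.
#' @return a corrected [RRSeries-class]; corrected intervals are flagged,
#'   and `attr(, "unreliable")` is TRUE when > 20% were corrected.
#' @export
correctRR <- function(rr) {
  x <- rr@intervals
  if (length(x) < 3) stop("need at least 3 intervals")
  locmed <- function(v, i) {
    w <- max(1, i - 5):min(length(v), i + 5)
    stats::median(v[setdiff(w, i)])
  }
  out <- numeric(0); corr <- logical(0)
  n_corrected <- 0L
  i <- 1L
  while (i <= length(x)) {
    m <- locmed(x, i)
    xi <- x[i]
    if (xi >= 2 * m) {                      # missed beat(s): split
      kk <- max(2L, round(xi / m))
      out <- c(out, rep(xi / kk, kk)); corr <- c(corr, rep(TRUE, kk))
      n_corrected <- n_corrected + 1L
    } else if (xi <= 0.5 * m && i < length(x)) { # extra beat: merge pair
      out <- c(out, xi + x[i + 1L]); corr <- c(corr, TRUE)
      n_corrected <- n_corrected + 1L
      i <- i + 1L
    } else if (xi < 0.7 * m || xi > 1.3 * m) {   # ectopic: local median
      out <- c(out, m); corr <- c(corr, TRUE)
      n_corrected <- n_corrected + 1L
    } else {
      out <- c(out, xi); corr <- c(corr, FALSE)
    }
    i <- i + 1L
  }
  res <- new("RRSeries", intervals = out, tStart = rr@tStart,
             corrected = corr)
  if (n_corrected / length(x) > 0.2) {
    warning("more than 20% of intervals corrected; metrics unreliable")
    attr(res, "unreliable") <- TRUE
  }
  res
}

#' Heart-rate and HRV metrics from an R-R series
#'
#' Time-domain: `bpm = 60000 / mean(interval)`, SDNN (SD of intervals) and
#' RMSSD (root-mean-square of successive differences).  Frequency-domain:
#' the R-R series is resampled to a uniform 4 Hz grid by cubic spline
#' interpolation, linearly detrended, and its Welch spectrum (120 s
#' segments, 50% overlap, Hann window) is integrated over the LF
#' (0.04--0.15 Hz) and HF (0.15--0.40 Hz) bands;
#' `HFnu = HF / (HF + LF) * 100`.  Series spanning less than 120 s (or
#' fewer than 30 intervals) report time-domain metrics only.
#'
#' @param rr an [RRSeries-class] (intervals in ms).
#' @return an [HRVMetrics-class].
#' @examples
#' rr <- new("RRSeries", intervals = rep(800, 50), tStart = 0,
#'           corrected = logical(50))
#' hrvMetrics(rr)@bpm  # 75
#' @export
hrvMetrics <- function(rr) {
  x <- rr@intervals
  bpm <- 60000 / mean(x)
  sdnn <- if (length(x) > 1) stats::sd(x) else 0
  rmssd <- if (length(x) > 1) sqrt(mean(diff(x)^2)) else 0
  flags <- character(0)
  hf <- lf <- hfnu <- NA_real_
  tbeat <- cumsum(x) / 1000                  # beat times, s
  span <- tbeat[length(tbeat)] - tbeat[1]
  if (length(x) >= 30 && span >= 120) {
    fs_r <- 4
    tg <- seq(tbeat[1], tbeat[length(tbeat)], by = 1 / fs_r)
    xi <- stats::spline(tbeat, x, xout = tg)$y
    xi <- stats::resid(stats::lm(xi ~ tg))
    ps <- welch_psd(xi, fs_r, nseg = min(length(xi), 120 * fs_r))
    lf <- band_power(ps$freq, ps$psd, 0.04, 0.15)
    hf <- band_power(ps$freq, ps$psd, 0.15, 0.40)
    if (hf + lf > 0) hfnu <- 100 * hf / (hf + lf)
  } else flags <- "too_short_for_spectral"
  if (isTRUE(attr(rr, "unreliable"))) flags <- c(flags, "unreliable")
  new("HRVMetrics", bpm = bpm, sdnn = sdnn, rmssd = rmssd,
      hf = hf, lf = lf, hfnu = hfnu, flags = flags)
}

#' End-to-end HRV analysis of an ECG trace
#'
#' [detectRPeaks()] then [correctRR()] then [hrvMetrics()].
#'
#' @param ecg an [EcgTrace-class].
#' @return an [HRVMetrics-class].
#' @export
analyzeEcg <- function(ecg) {
  peaks <- detectRPeaks(ecg)
  if (length(peaks) < 4) stop("too few R peaks detected")
  hrvMetrics(correctRR(peaksToRR(peaks, ecg@fs)))
}

#' Cohort HRV table
#'
#' Runs the full ECG chain for every subject with an ECG trace.
#'
#' @param cohort a [GammaCohort-class].
#' @return data.frame: subject_id, group, bpm, sdnn, rmssd, hf, lf, hfnu.
#' @export
hrvTable <- function(cohort) {
  rows <- list()
  for (sid in names(cohort@subjects)) {
    s <- cohort@subjects[[sid]]
    if (is.null(s$ecg)) next
    m <- analyzeEcg(s$ecg)
    grp <- cohort@truth$group[cohort@truth$subject_id == sid]
    rows[[sid]] <- data.frame(subject_id = sid, group = grp, bpm = m@bpm,
                              sdnn = m@sdnn, rmssd = m@rmssd, hf = m@hf,
                              lf = m@lf, hfnu = m@hfnu,
                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
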