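# shared fixture builders (everything generated in code; no stored data)

make_epoch <- function(data, fs = 1000, t0 = -1.2, condition = 1.2,
                       trialN = 1, subjectId = "t", group = "control") {
  new("TrialEpoch", data = data, fs = fs, t0 = t0, condition = condition,
      trialN = trialN, subjectId = subjectId, group = group)
}

# one-sensor epoch holding a given time-series function of t
signal_epoch <- function(f, fs = 1000, t0 = -1.2, tlen = 2.4, ...) {
  t <- t0 + (seq_len(round(tlen * fs)) - 1) / fs
  make_epoch(matrix(f(t), nrow = 1), fs = fs, t0 = t0, ...)
}

make_spectra <- function(mat, freqs, condition = rep(1.2, nrow(mat)),
                         trialN = seq_len(nrow(mat)), subjectId = "t",
                         group = "control") {
  new("TrialSpectra", relPower = mat, freqs = freqs,
      info = data.frame(condition = condition, trialN = trialN),
      subjectId = subjectId, group = group)
}

make_rel_spectrum <- function(mat, freqs) {
  rownames(mat) <- sprintf("MEG%02d", seq_len(nrow(mat)))
  new("RelativeSpectrum", relPower = mat, freqs = freqs,
      sensors = rownames(mat))
}

# small, fast spectrum-level cohort configuration
small_config <- function(...) {
  generatorConfig(nVss = 3, nControl = 3, nTrialsPerCondition = 4,
                  seed = 42, ...)
}

# independent brute-force oracle for the 2/3-of-peak GR metrics:
# an explicit loop over bins, written independently of computeGRMetrics
gr_metrics_bruteforce <- function(freqs, power, band = c(35, 100),
                                  frac = 2 / 3) {
  peak <- -Inf
  for (i in seq_along(freqs))
    if (freqs[i] >= band[1] && freqs[i] <= band[2] && power[i] > peak)
      peak <- power[i]
  if (peak <= 0) return(list(gr_power = NA_real_, gr_freq = NA_real_))
  s_p <- 0; s_fp <- 0; n <- 0
  for (i in seq_along(freqs)) {
    if (freqs[i] < band[1] || freqs[i] > band[2]) next
    if (power[i] > frac * peak) {
      s_p <- s_p + power[i]
      s_fp <- s_fp + freqs[i] * power[i]
      n <- n + 1
    }
  }
  list(gr_power = s_p / n, gr_freq = s_fp / s_p)
}

# constructed R-R series with sinusoidal modulation at a given frequency
modulated_rr <- function(f_mod, amp = 40, base = 800, dur = 300) {
  tk <- 0; iv <- numeric(0)
  while (tk < dur) {
    rr <- base + amp * sin(2 * pi * f_mod * tk)
    iv <- c(iv, rr)
    tk <- tk + rr / 1000
  }
  new("RRSeries", intervals = iv, tStart = 0,
      corrected = logical(length(iv)))
}
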