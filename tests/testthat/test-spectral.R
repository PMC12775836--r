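test_that("evoked subtraction removes the per-condition mean exactly", {
  set.seed(1)
  # two identical epochs: both become all-zero
  x <- matrix(rnorm(2 * 2400), 2)
  eps <- list(make_epoch(x), make_epoch(x, trialN = 2))
  out <- subtractEvoked(eps)
  expect_equal(out[[1]]@data, x * 0)
  expect_equal(out[[2]]@data, x * 0)

  # {x, -x}: the mean is already zero, trials unchanged
  eps <- list(make_epoch(x), make_epoch(-x, trialN = 2))
  out <- subtractEvoked(eps)
  expect_equal(out[[1]]@data, x)
  expect_equal(out[[2]]@data, -x)

  # 10 random epochs in two conditions: stacked means vanish, order kept
  eps <- lapply(1:10, function(i)
    make_epoch(matrix(rnorm(2 * 100), 2), condition = c(0, 1.2)[i %% 2 + 1],
               trialN = i))
  out <- subtractEvoked(eps)
  for (cn in c(0, 1.2)) {
    sel <- out[vapply(out, function(e) e@condition == cn, logical(1))]
    m <- Reduce(`+`, lapply(sel, function(e) e@data)) / length(sel)
    expect_lt(max(abs(m)), 1e-10)
  }
  expect_equal(vapply(out, function(e) e@trialN, numeric(1)), 1:10)

  # a lone trial in a condition passes through with a warning
  expect_warning(
    out <- subtractEvoked(list(make_epoch(x),
                               make_epoch(x, trialN = 2),
                               make_epoch(x, condition = 6, trialN = 3))),
    "< 2 trials")
  expect_equal(out[[3]]@data, x)
})

test_that("multitaper TFR localises a pure tone and returns the 2.5 Hz grid", {
  ep <- signal_epoch(function(t) sin(2 * pi * 60 * t))
  tfr <- multitaperTFR(ep, timeStep = 0.05)
  expect_equal(diff(freqs(tfr))[1], 2.5)
  expect_equal(diff(tfr@times)[1], 0.05)
  expect_true(all(tfr@values >= 0))
  spec <- apply(tfr@values[1, , ], 1, mean)
  expect_equal(freqs(tfr)[which.max(spec)], 60)
  # energy concentrated within the +/-5 Hz half-bandwidth
  inband <- abs(freqs(tfr) - 60) <= 5
  expect_gt(sum(spec[inband]) / sum(spec), 0.95)

  # zero signal: all-zero power
  ep0 <- signal_epoch(function(t) 0 * t)
  expect_true(all(multitaperTFR(ep0, timeStep = 0.2)@values == 0))

  # too-short epoch rejected
  epS <- signal_epoch(function(t) t, t0 = -0.5, tlen = 1.0)
  expect_error(multitaperTFR(epS), "too short")
})

test_that("white-noise multitaper spectrum is flat over the gamma band", {
  set.seed(7)
  spec <- 0
  for (i in 1:100) {
    ep <- signal_epoch(function(t) rnorm(length(t)))
    tfr <- multitaperTFR(ep, timeStep = 0.2)
    spec <- spec + apply(tfr@values[1, , ], 1, mean)
  }
  f <- seq(5, 120, 2.5)
  band <- spec[f >= 35 & f <= 100] / mean(spec[f >= 35 & f <= 100])
  expect_lt(max(abs(band - 1)), 0.2)
})

test_that("baseline normalisation implements 100*(stim-baseline)/baseline", {
  # hand-built 3-bin TFR: baseline {1,2,4}, stim {2,2,6} -> {100, 0, 50} %
  vals <- array(0, c(1, 3, 4))
  vals[1, , 1:2] <- c(1, 2, 4)              # baseline times
  vals[1, , 3:4] <- c(2, 2, 6)              # stimulation times
  tfr <- new("TFR", values = vals, freqs = c(40, 50, 60),
             times = c(-0.8, -0.4, 0.5, 1.0), units = "power")
  rel <- normalizeToBaseline(tfr)
  expect_equal(as.numeric(relPower(rel)), c(100, 0, 50))

  # statistically identical windows -> near 0%
  set.seed(2)
  vals2 <- array(rexp(1 * 3 * 2000), c(1, 3, 2000))
  tfr2 <- new("TFR", values = vals2, freqs = c(40, 50, 60),
              times = seq(-0.9, 1.2, length.out = 2000), units = "power")
  expect_lt(max(abs(relPower(normalizeToBaseline(tfr2)))), 15)

  # zero baseline power rejected with a diagnostic
  vals[1, 2, 1:2] <- 0
  tfr3 <- new("TFR", values = vals, freqs = c(40, 50, 60),
              times = c(-0.8, -0.4, 0.5, 1.0), units = "power")
  expect_error(normalizeToBaseline(tfr3), "baseline power")
})

test_that("sensor selection applies the 80%-of-maximum rule with a cap of 4", {
  f <- seq(35, 80, 2.5)
  flat <- function(v) matrix(rep(v, each = 1) %o% rep(1, length(f)),
                             ncol = length(f))
  # band averages {100, 85, 79, 10}: only {100, 85} exceed 80% of max
  sp <- make_rel_spectrum(flat(c(100, 85, 79, 10)), f)
  expect_equal(selectSensors(sp, 1:4), c("MEG01", "MEG02"))
  # five near-ties: capped at the top four
  sp <- make_rel_spectrum(flat(c(100, 99, 98, 97, 96)), f)
  expect_equal(selectSensors(sp, 1:5),
               c("MEG01", "MEG02", "MEG03", "MEG04"))
  # single posterior sensor: itself
  sp <- make_rel_spectrum(flat(c(100, 85)), f)
  expect_equal(selectSensors(sp, 2), "MEG02")
  # all-negative band: maximal sensor only, with warning
  sp <- make_rel_spectrum(flat(c(-5, -1, -9)), f)
  expect_warning(out <- selectSensors(sp, 1:3), "maximal sensor")
  expect_equal(out, "MEG02")
})

test_that("GR metrics implement the 2/3-peak mean and centre of gravity", {
  # single supra-threshold bin
  m <- computeGRMetrics(c(10, 20, 10), freqs = c(40, 50, 60))
  expect_equal(grPower(m), 20)
  expect_equal(grFreq(m), 50)
  expect_equal(m@nBinsUsed, 1)
  # all bins included
  m <- computeGRMetrics(c(15, 20, 15), freqs = c(40, 50, 60))
  expect_equal(grPower(m), 50 / 3)
  expect_equal(grFreq(m), (40 * 15 + 50 * 20 + 60 * 15) / 50)
  # flat spectrum: power = value, frequency = grid midpoint
  f <- seq(35, 100, 2.5)
  m <- computeGRMetrics(rep(7, length(f)), freqs = f)
  expect_equal(grPower(m), 7)
  expect_equal(grFreq(m), mean(range(f)))
  # no positive peak: flagged, metrics missing (not zero)
  m <- computeGRMetrics(c(-3, -1, -2), freqs = c(40, 50, 60))
  expect_false(m@ok)
  expect_true(is.na(grPower(m)) && is.na(grFreq(m)))
})

test_that("GR metrics agree with a brute-force oracle on random spectra", {
  set.seed(11)
  f27 <- seq(35, 100, 2.5)
  for (i in 1:1000) {
    p <- rnorm(27, mean = runif(1, -5, 30), sd = runif(1, 1, 20))
    m <- computeGRMetrics(p, freqs = f27)
    o <- gr_metrics_bruteforce(f27, p)
    if (is.na(o$gr_power)) {
      expect_false(m@ok)
    } else {
      expect_equal(grPower(m), o$gr_power, tolerance = 1e-12)
      expect_equal(grFreq(m), o$gr_freq, tolerance = 1e-12)
    }
  }
})

test_that("GR metrics are scale-equivariant and track spectral shifts", {
  set.seed(3)
  f <- seq(5, 120, 2.5)
  for (i in 1:25) {
    p <- rnorm(length(f), 5, 10)
    m1 <- computeGRMetrics(p, freqs = f)
    if (!m1@ok) next
    c_ <- runif(1, 0.1, 10)
    m2 <- computeGRMetrics(c_ * p, freqs = f)
    expect_equal(grFreq(m2), grFreq(m1), tolerance = 1e-12)
    expect_equal(grPower(m2), c_ * grPower(m1), tolerance = 1e-12)
  }
  # +10 Hz shift of a Gaussian bump moves the centre of gravity by +10
  bump <- function(mu) 100 * exp(-(f - mu)^2 / (2 * 4^2))
  g1 <- grFreq(computeGRMetrics(bump(55), freqs = f))
  g2 <- grFreq(computeGRMetrics(bump(65), freqs = f))
  expect_lt(abs((g2 - g1) - 10), 2.5)
})

test_that("epoch pipeline recovers the injected gamma response", {
  cfg <- generatorConfig(nVss = 1, nControl = 0, nTrialsPerCondition = 4,
                         nSensors = 4, posteriorSensors = 3:4, fs = 500,
                         level = "epochs")
  s <- simulateSubject(cfg, "s1", "VSS", seed = 5, ecg = FALSE)
  res <- epochsToTrialSpectra(s$epochs, cfg@posteriorSensors,
                              timeStep = 0.05)
  # selected sensors are drawn from the posterior subset only
  expect_true(all(res$sensors %in% c("MEG03", "MEG04")))
  expect_true(length(res$sensors) >= 1 && length(res$sensors) <= 4)
  # condition-average peak frequencies follow the monotone tuning
  pk <- conditionPeaks(res$spectra)
  expect_true(all(diff(pk[order(as.numeric(names(pk)))]) > 0))
})
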