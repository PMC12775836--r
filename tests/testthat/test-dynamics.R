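test_that("single-trial band metrics match hand computation", {
  f <- seq(5, 120, 2.5)
  # symmetric spectrum about the peak: weighted frequency = the peak
  pk <- 55
  spec <- 100 * exp(-(f - pk)^2 / (2 * 16))
  sp <- make_spectra(rbind(spec), f)
  st <- singleTrialGR(sp, peaks = c("1.2" = pk))
  band <- abs(f - pk) <= 15
  expect_equal(sum(band), 13)              # +/-15 Hz at 2.5 Hz: 13 bins
  expect_equal(st$st_power, mean(spec[band]))
  expect_equal(st$st_freq, sum(f[band] * spec[band]) / sum(spec[band]))
  expect_equal(st$st_freq, pk, tolerance = 1e-6)

  # asymmetric spectrum: hand-computed weighted mean
  spec2 <- pmax(0, 100 - 3 * abs(f - 60) - 20 * (f > 60))
  sp2 <- make_spectra(rbind(spec2), f)
  st2 <- singleTrialGR(sp2, peaks = c("1.2" = 60))
  b2 <- abs(f - 60) <= 15
  expect_equal(st2$st_freq, sum(f[b2] * spec2[b2]) / sum(spec2[b2]))

  # all-nonpositive band: power reported, frequency missing
  sp3 <- make_spectra(rbind(rep(-5, length(f))), f)
  st3 <- singleTrialGR(sp3, peaks = c("1.2" = 60))
  expect_equal(st3$st_power, -5)
  expect_true(is.na(st3$st_freq))
})

test_that("IQR exclusion follows the k = 2 quartile rule", {
  # {1,2,3,4,100}: Q1 = 2, Q3 = 4 -> keep [-2, 8], so 100 goes
  expect_equal(iqrExclude(c(1, 2, 3, 4, 100)),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # constant series: bounds collapse onto the constant, all kept
  expect_equal(iqrExclude(rep(7, 10)), rep(TRUE, 10))
  # short series: kept with a warning
  expect_warning(out <- iqrExclude(c(1, 2, 100)), "fewer than 4")
  expect_equal(out, rep(TRUE, 3))
  # clean Gaussian samples of n = 137: exclusions are rare (< 1%)
  set.seed(5)
  rate <- mean(replicate(1000, mean(!iqrExclude(rnorm(137)))))
  expect_lt(rate, 0.01)
})

test_that("IQR exclusion bounds are monotone in k", {
  set.seed(9)
  for (i in 1:20) {
    x <- rt(60, df = 3)
    kept_prev <- iqrExclude(x, k = 0.5)
    for (k in c(1, 2, 4, 8)) {
      kept <- iqrExclude(x, k = k)
      expect_true(all(kept[kept_prev]))    # larger k never excludes more
      kept_prev <- kept
    }
  }
})

test_that("z-scoring normalises kept trials and ignores affine shifts", {
  expect_equal(zscoreSeries(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  x <- rnorm(137)
  z <- zscoreSeries(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(zscoreSeries(3.2 * x - 7), z, tolerance = 1e-12)
  # excluded trials get missing z; kept ones renormalised
  kept <- rep(TRUE, 137); kept[10] <- FALSE
  z2 <- zscoreSeries(x, kept)
  expect_true(is.na(z2[10]))
  expect_lt(abs(mean(z2, na.rm = TRUE)), 1e-12)
  expect_warning(zscoreSeries(rep(1, 10)), "zero SD")
})

test_that("grand averaging respects trial order and missing data", {
  tab <- data.frame(trialN = rep(1:5, 2), z = c(rep(0, 5), rep(0, 5)))
  expect_equal(grandAverageCourse(tab)$z, rep(0, 5))
  # one subject: the curve is that subject's values
  tab <- data.frame(trialN = 1:5, z = c(1, 2, NA, 4, 5))
  crs <- grandAverageCourse(tab)
  expect_equal(crs$trialN, c(1, 2, 4, 5))  # missing point skipped
  expect_equal(crs$z, c(1, 2, 4, 5))
  expect_equal(crs$n, rep(1, 4))
})

test_that("dual-process fit is exact on noiseless model data", {
  n <- 1:137
  y <- 0.5 * exp(-n / 8) + 0.004 * n - 0.3
  fit <- fitDualProcess(n, y)
  expect_equal(fit@A, 0.5, tolerance = 1e-6)
  expect_equal(fit@tau, 8, tolerance = 1e-6)
  expect_equal(fit@B, 0.004, tolerance = 1e-6)
  expect_equal(fit@C, -0.3, tolerance = 1e-6)
  expect_equal(fit@r2Adj, 1, tolerance = 1e-9)
})

test_that("dual-process fit flags an unidentifiable decay on a pure line", {
  n <- 1:60
  y <- 0.01 * n + 2
  fit <- fitDualProcess(n, y)
  expect_true("tau_unidentifiable" %in% fit@flags)
  expect_equal(fit@B, 0.01, tolerance = 1e-8)
  expect_equal(fit@C, 2, tolerance = 1e-8)
  # constraining A to zero reduces to OLS
  ols <- lm(y ~ n)
  expect_equal(fit@B, unname(coef(ols)[2]), tolerance = 1e-8)
})

test_that("dual-process bootstrap gives a tau interval containing the truth", {
  set.seed(4)
  n <- 1:137
  y <- 1 * exp(-n / 8) + 0.005 * n + rnorm(137, 0, 0.1)
  fit <- fitDualProcess(n, y, nBoot = 200, seed = 4)
  expect_false(anyNA(fit@tauCi))
  # the bootstrap interval brackets the point estimate and is informative
  expect_lte(fit@tauCi[1], fit@tau)
  expect_gte(fit@tauCi[2], fit@tau)
  expect_lt(diff(fit@tauCi), 15)
  expect_lt(abs(fit@tau - 8), 2)
})

test_that("broken-line fit recovers a known breakpoint", {
  n <- 1:137
  y <- ifelse(n < 15, 1 - 0.05 * (n - 15), 1 + 0.004 * (n - 15))
  fit <- fitBrokenLine(n, y)
  expect_lt(abs(fit@psi - 15), 0.5)
  expect_equal(fit@slopePre, -0.05, tolerance = 1e-3)
  expect_equal(fit@slopePost, 0.004, tolerance = 1e-3)

  # straight line: no real break; slopes agree and the fit is flagged
  y2 <- 0.003 * n + 1
  fit2 <- suppressWarnings(fitBrokenLine(n, y2, nBoot = 100, seed = 1))
  expect_equal(fit2@slopePre, fit2@slopePost, tolerance = 1e-6)
  expect_true("weak_break" %in% fit2@flags)
})

test_that("broken-line profile beats every integer breakpoint (oracle)", {
  n <- 1:137
  y <- 0.5 * exp(-n / 8) + 0.004 * n - 0.3
  fit <- fitBrokenLine(n, y)
  expect_gt(fit@psi, 10)
  expect_lt(fit@psi, 25)
  rss <- function(psi) {
    x2 <- pmax(n - psi, 0)
    sum(resid(lm(y ~ n + x2))^2)
  }
  best <- rss(fit@psi)
  for (psi in 3:135) expect_gte(rss(psi), best - 1e-12)
})

test_that("per-subject slopes average condition-wise OLS coefficients", {
  conds <- rep(c(0, 0.6, 1.2, 3.6, 6.0), each = 25)
  tn <- rep(seq(15, 135, 5), 5)
  tab <- data.frame(subject_id = "s1", group = "VSS", condition = conds,
                    trialN = tn, st_power = 0,
                    kept = TRUE, z = 0.002 * tn)
  sl <- subjectSlope(tab)
  expect_equal(sl$coef, 0.002, tolerance = 1e-12)
  expect_equal(sl$coef_per100, 0.2, tolerance = 1e-12)
  expect_equal(sl$n_conditions, 5)

  # trial-independent z: slope indistinguishable from zero
  set.seed(6)
  tab$z <- rnorm(nrow(tab))
  sl0 <- subjectSlope(tab)
  se <- 1 / (sd(tn[1:25]) * sqrt(25)) / sqrt(5)
  expect_lt(abs(sl0$coef), 3 * se)

  # sparse condition dropped with a warning
  tab2 <- tab[!(tab$condition == 6 & tab$trialN > 30), ]
  expect_warning(sl2 <- subjectSlope(tab2), "omitted")
  expect_equal(sl2$n_conditions, 4)
})

test_that("cohort single-trial table keeps z normalised within condition", {
  coh <- simulateCohort(small_config(), ecg = FALSE)
  st <- singleTrialTable(coh, trials = 1:20)
  for (sid in unique(st$subject_id)) {
    for (cn in unique(st$condition)) {
      z <- st$z[st$subject_id == sid & st$condition == cn & st$kept]
      z <- z[!is.na(z)]
      if (length(z) >= 2) {
        expect_lt(abs(mean(z)), 1e-9)
        expect_lt(abs(sd(z) - 1), 1e-9)
      }
    }
  }
})
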