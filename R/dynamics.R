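#' @include AllClasses.R
NULL

#' Peak gamma frequency per condition from condition-average spectra
#'
#' For each condition, averages the subject's single-trial relative spectra
#' and returns the frequency of the in-band (35--100 Hz) peak, which anchors
#' the +/-15 Hz single-trial band.
#'
#' @param spectra a [TrialSpectra-class].
#' @param trials optional restriction of trial numbers.
#' @param band peak-search band (Hz).
#' @return named numeric vector, condition -> peak frequency (Hz).
#' @export
conditionPeaks <- function(spectra, trials = NULL, band = c(35, 100)) {
  info <- spectra@info
  keep <- if (is.null(trials)) rep(TRUE, nrow(info))
          else info$trialN %in% trials
  conds <- sort(unique(info$condition))
  out <- stats::setNames(numeric(length(conds)), conds)
  for (i in seq_along(conds)) {
    idx <- keep & info$condition == conds[i]
    avg <- colMeans(spectra@relPower[idx, , drop = FALSE])
    m <- computeGRMetrics(avg, band = band, freqs = spectra@freqs)
    out[i] <- m@peakFreq
  }
  out
}

#' Single-trial gamma power and frequency
#'
#' For every trial, averages the relative power over +/-15 Hz around the
#' condition-specific average peak frequency (`st_power`) and computes the
#' power-weighted mean frequency in that band (`st_freq`).  Negative bins
#' are ignored in the frequency weighting; a trial with no positive band
#' power gets a missing `st_freq` (its `st_power` is still reported).
#'
#' @param spectra a [TrialSpectra-class].
#' @param peaks named numeric of condition peak frequencies, as from
#'   [conditionPeaks()] (computed from `spectra` when omitted).
#' @param halfWidth half-width of the single-trial band (Hz), default 15.
#' @return data.frame: subject_id, group, condition, trialN, st_power,
#'   st_freq.
#' @export
singleTrialGR <- function(spectra, peaks = NULL, halfWidth = 15) {
  if (is.null(peaks)) peaks <- conditionPeaks(spectra)
  info <- spectra@info
  f <- spectra@freqs
  st_power <- st_freq <- rep(NA_real_, nrow(info))
  for (cn in unique(info$condition)) {
    pk <- peaks[as.character(cn)]
    if (is.na(pk)) stop("no peak frequency for condition ", cn)
    band <- abs(f - pk) <= halfWidth + 1e-9
    if (!any(band)) stop("single-trial band outside the frequency grid")
    idx <- which(info$condition == cn)
    sub <- spectra@relPower[idx, band, drop = FALSE]
    st_power[idx] <- rowMeans(sub)
    w <- pmax(sub, 0)
    tot <- rowSums(w)
    sf <- as.numeric(w %*% f[band]) / tot
    sf[tot <= 0] <- NA_real_
    st_freq[idx] <- sf
  }
  data.frame(subject_id = spectra@subjectId, group = spectra@group,
             condition = info$condition, trialN = info$trialN,
             st_power = st_power, st_freq = st_freq,
             stringsAsFactors = FALSE)
}

#' Interquartile-range outlier exclusion
#'
#' Keeps values inside `[Q1 - k * IQR, Q3 + k * IQR]` with type-7 (linear
#' interpolation) quartiles and multiplication coefficient `k = 2`.  Series
#' with fewer than four values are kept entirely, with a warning.
#'
#' @param x numeric values (e.g. a subject's single-trial gamma power).
#' @param k IQR multiplier, default 2.
#' @return logical vector of kept flags.
#' @examples
#' iqrExclude(c(1, 2, 3, 4, 100))  # excludes 100
#' @export
iqrExclude <- function(x, k = 2) {
  ok <- !is.na(x)
  if (sum(ok) < 4) {
    warning("fewer than 4 values; nothing excluded")
    return(ok)
  }
  q <- stats::quantile(x[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  ok & x >= q[1] - k * iqr & x <= q[2] + k * iqr
}

#' z-score a trial series over its kept trials
#'
#' Sample-SD z-transform over kept values; excluded trials get missing z.
#' A zero-SD series yields all-missing z with a warning.
#'
#' @param x numeric series.
#' @param kept logical kept flags (default: all).
#' @return numeric z-scores aligned to `x`.
#' @export
zscoreSeries <- function(x, kept = rep(TRUE, length(x))) {
  z <- rep(NA_real_, length(x))
  v <- x[kept]
  if (sum(!is.na(v)) < 2 || stats::sd(v, na.rm = TRUE) == 0) {
    warning("zero SD or too few kept values; z undefined")
    return(z)
  }
  z[kept] <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  z
}

#' Cohort-level single-trial gamma table
#'
#' Runs [singleTrialGR()] for every subject on the uninterrupted first block
#' (trials 1--137 by default), excludes extreme trials per subject by the
#' IQR rule (pooled over conditions by default, optionally per condition)
#' and z-transforms the kept series separately for each subject and
#' condition.
#'
#' @param cohort a [GammaCohort-class].
#' @param trials trial numbers to analyse (default `1:137`).
#' @param k IQR multiplier (default 2).
#' @param perCondition logical; apply the IQR rule within each condition
#'   instead of pooled over the subject's trials.
#' @return data.frame: subject_id, group, condition, trialN, st_power,
#'   st_freq, kept, z.
#' @export
singleTrialTable <- function(cohort, trials = 1:137, k = 2,
                             perCondition = FALSE) {
  out <- lapply(names(cohort@subjects), function(sid) {
    sp <- .subject_spectra(cohort, sid)
    tab <- singleTrialGR(sp)
    tab <- tab[tab$trialN %in% trials, , drop = FALSE]
    if (perCondition) {
      tab$kept <- FALSE
      for (cn in unique(tab$condition)) {
        i <- tab$condition == cn
        tab$kept[i] <- iqrExclude(tab$st_power[i], k)
      }
    } else tab$kept <- iqrExclude(tab$st_power, k)
    tab$z <- NA_real_
    for (cn in unique(tab$condition)) {
      i <- tab$condition == cn
      tab$z[i] <- zscoreSeries(tab$st_power[i], tab$kept[i])
    }
    tab
  })
  do.call(rbind, out)
}

#' Grand-average repetition course
#'
#' Averages z-scored single-trial gamma power across all subjects and
#' conditions according to the trial order number.
#'
#' @param stTable output of [singleTrialTable()] (needs `trialN` and `z`).
#' @return data.frame: trialN, z (mean), n (values averaged); trial numbers
#'   without any data are absent.
#' @export
grandAverageCourse <- function(stTable) {
  ok <- !is.na(stTable$z)
  if (!any(ok)) stop("no z values available")
  ag <- stats::aggregate(z ~ trialN, data = stTable[ok, ], FUN = mean)
  n <- stats::aggregate(z ~ trialN, data = stTable[ok, ], FUN = length)
  data.frame(trialN = ag$trialN, z = ag$z, n = n$z)
}

#' Fit the dual-process repetition model
#'
#' Nonlinear least-squares fit of
#' `y ~ A * exp(-trialN / tau) + B * trialN + C`: a fast exponential decay
#' (early habituation, time constant `tau`) plus a linear repetition trend.
#' Starting values come from a multi-start grid over
#' `tau in {2, 5, 10, 20, 40}` with `A` seeded by the early-minus-late mean
#' difference and `B`, `C` by OLS on the last two-thirds of trials; the best
#' converged fit (lowest RSS) is returned, making the fit deterministic
#' given the data.  If the exponential term does not improve on a straight
#' line the fit is flagged `tau_unidentifiable` and the linear OLS
#' coefficients are reported.
#'
#' @param trialN trial order numbers.
#' @param y response (e.g. grand-average z-scored gamma power).
#' @param nBoot bootstrap replicates for the tau CI (0 = none; 1000 for the
#'   reported CIs).
#' @param seed RNG seed for the bootstrap.
#' @return a [DualProcessFit-class].
#' @examples
#' n <- 1:137
#' y <- 0.5 * exp(-n / 8) + 0.004 * n - 0.3
#' fitDualProcess(n, y)
#' @export
fitDualProcess <- function(trialN, y, nBoot = 0, seed = 1) {
  ok <- is.finite(trialN) & is.finite(y)
  n <- trialN[ok]; yy <- y[ok]
  if (length(n) < 20) stop("need >= 20 points to fit the dual-process model")
  fit <- .fit_dp_core(n, yy)
  npts <- length(n)
  ols <- stats::lm(yy ~ n)
  rss_line <- sum(stats::resid(ols)^2)
  flags <- character(0)
  if (is.null(fit) || fit$rss >= rss_line * (1 - 1e-8)) {
    flags <- "tau_unidentifiable"
    co <- stats::coef(ols)
    sst <- sum((yy - mean(yy))^2)
    r2 <- if (sst > 0) 1 - rss_line / sst else NA_real_
    return(.dual_process_fit(0, NA_real_, unname(co[2]), unname(co[1]),
                             1 - (1 - r2) * (npts - 1) / (npts - 4),
                             c(0, Inf), flags, npts))
  }
  sst <- sum((yy - mean(yy))^2)
  r2 <- if (sst > 0) 1 - fit$rss / sst else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0) {
    set.seed(seed)
    taus <- rep(NA_real_, nBoot)
    for (b in seq_len(nBoot)) {
      idx <- sample.int(length(n), replace = TRUE)
      fb <- .fit_dp_core(n[idx], yy[idx], start = fit$par)
      if (!is.null(fb)) taus[b] <- fb$par[["tau"]]
    }
    ci <- stats::quantile(taus, c(0.025, 0.975), na.rm = TRUE,
                          names = FALSE)
  }
  .dual_process_fit(fit$par[["A"]], fit$par[["tau"]], fit$par[["B"]],
                    fit$par[["C"]],
                    1 - (1 - r2) * (npts - 1) / (npts - 4),
                    ci, flags, npts)
}

# slot-wise constructor: a slot named "C" cannot be passed to new(), whose
# Class formal would partially match it
.dual_process_fit <- function(A, tau, B, C, r2Adj, tauCi, flags, n) {
  obj <- new("DualProcessFit")
  obj@A <- A; obj@tau <- tau; obj@B <- B; obj@C <- C
  obj@r2Adj <- r2Adj; obj@tauCi <- tauCi; obj@flags <- flags; obj@n <- n
  validObject(obj)
  obj
}

# multi-start nonlinear core; returns list(par, rss) or NULL
.fit_dp_core <- function(n, y, start = NULL) {
  o <- order(n)
  n <- n[o]; y <- y[o]
  early <- y[seq_len(max(3, round(length(y) * 0.1)))]
  late_i <- seq.int(ceiling(length(y) / 3), length(y))
  ols <- stats::lm(y[late_i] ~ n[late_i])
  b0 <- unname(stats::coef(ols)[2]); c0 <- unname(stats::coef(ols)[1])
  a0 <- mean(early) - (c0 + b0 * mean(n[seq_along(early)]))
  starts <- lapply(c(2, 5, 10, 20, 40), function(tau0)
    list(A = a0, tau = tau0, B = b0, C = c0))
  if (!is.null(start)) starts <- c(list(as.list(start)), starts)
  best <- NULL
  for (s in starts) {
    f <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      y ~ A * exp(-n / tau) + B * n + C, start = s,
      lower = c(A = -Inf, tau = 0.1, B = -Inf, C = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::resid(f)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = stats::coef(f), rss = rss)
  }
  best
}

#' Fit a broken-line (segmented) model
#'
#' Continuous two-segment linear fit
#' `y ~ b0 + b1 * n + b2 * max(n - psi, 0)`.  The breakpoint `psi` is found
#' by profiling the residual sum of squares over integer candidate
#' breakpoints and refining the best one by local optimisation; its 95% CI
#' comes from a nonparametric bootstrap over trials.  A breakpoint on the
#' profile boundary is flagged `"boundary"`; an insignificant slope change
#' is flagged `"weak_break"`.
#'
#' @param trialN trial order numbers.
#' @param y response values.
#' @param nBoot bootstrap replicates for the psi CI (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return a [BrokenLineFit-class].
#' @export
fitBrokenLine <- function(trialN, y, nBoot = 0, seed = 1) {
  ok <- is.finite(trialN) & is.finite(y)
  n <- trialN[ok]; yy <- y[ok]
  if (length(n) < 20) stop("need >= 20 points to fit the broken-line model")
  res <- .fit_bl_core(n, yy)
  flags <- character(0)
  if (res$boundary) flags <- c(flags, "boundary")
  if (!is.na(res$t2) && abs(res$t2) < 2) flags <- c(flags, "weak_break")
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0) {
    set.seed(seed)
    psis <- rep(NA_real_, nBoot)
    for (b in seq_len(nBoot)) {
      idx <- sample.int(length(n), replace = TRUE)
      if (length(unique(n[idx])) < 6) next
      psis[b] <- .fit_bl_core(n[idx], yy[idx])$psi
    }
    ci <- stats::quantile(psis, c(0.025, 0.975), na.rm = TRUE,
                          names = FALSE)
    if (!anyNA(ci) && diff(ci) > 0.8 * diff(range(n)))
      flags <- c(flags, "weak_break")
  }
  new("BrokenLineFit", psi = res$psi, slopePre = res$b1,
      slopePost = res$b1 + res$b2, psiCi = ci, flags = unique(flags))
}

.fit_bl_core <- function(n, y) {
  rng <- range(n)
  grid <- seq(ceiling(rng[1]) + 2, floor(rng[2]) - 2)
  rss_at <- function(psi) {
    x2 <- pmax(n - psi, 0)
    sum(stats::resid(stats::lm(y ~ n + x2))^2)
  }
  prof <- vapply(grid, rss_at, numeric(1))
  i <- which.min(prof)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(rss_at, c(lo, hi))
  psi <- opt$minimum
  x2 <- pmax(n - psi, 0)
  fit <- stats::lm(y ~ n + x2)
  co <- summary(fit)$coefficients
  t2 <- if (nrow(co) >= 3) co[3, 3] else NA_real_
  list(psi = psi, b1 = unname(stats::coef(fit)[2]),
       b2 = unname(stats::coef(fit)[3]), t2 = t2,
       boundary = i == 1 || i == length(grid))
}

#' Per-subject plasticity slopes
#'
#' For each subject and condition, fits an ordinary least-squares regression
#' of the z-scored single-trial gamma power on the trial number within the
#' analysis window (trials 15--137 by default) and averages the coefficients
#' across conditions.  Conditions with fewer than five usable trials are
#' omitted from the average and flagged.
#'
#' @param stTable output of [singleTrialTable()].
#' @param window inclusive trial-number window, default `c(15, 137)`.
#' @param minTrials minimum usable trials per condition (default 5).
#' @return data.frame: subject_id, group, coef (z-units per trial),
#'   coef_per100 (per 100 trials), n_conditions, dropped_conditions.
#' @export
subjectSlope <- function(stTable, window = c(15, 137), minTrials = 5) {
  out <- list()
  for (sid in unique(stTable$subject_id)) {
    tab <- stTable[stTable$subject_id == sid & stTable$kept &
                   !is.na(stTable$z) &
                   stTable$trialN >= window[1] &
                   stTable$trialN <= window[2], , drop = FALSE]
    coefs <- c(); dropped <- 0L
    for (cn in sort(unique(stTable$condition[stTable$subject_id == sid]))) {
      sub <- tab[tab$condition == cn, ]
      if (nrow(sub) < minTrials) { dropped <- dropped + 1L; next }
      coefs <- c(coefs, unname(stats::coef(
        stats::lm(z ~ trialN, data = sub))[2]))
    }
    if (dropped > 0)
      warning("subject ", sid, ": ", dropped,
              " condition(s) with < ", minTrials, " usable trials omitted")
    grp <- stTable$group[stTable$subject_id == sid][1]
    out[[sid]] <- data.frame(
      subject_id = sid, group = grp,
      coef = if (length(coefs)) mean(coefs) else NA_real_,
      coef_per100 = if (length(coefs)) 100 * mean(coefs) else NA_real_,
      n_conditions = length(coefs), dropped_conditions = dropped,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
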