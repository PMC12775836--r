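#' @include AllClasses.R
NULL

#' Trial-level linear mixed model of repetition effects
#'
#' Fits the repetition model to single-trial responses within the analysis
#' window.  For `response = "power"` the model is
#' `power ~ trialN * group + (1 + trialN | subject) + (1 + trialN | condition)`
#' with power expressed as a proportion of baseline (`st_power` % / 100) so
#' that slopes are in relative-power units; for `"freq"` it is
#' `freq ~ trialN + (1 + trialN | subject) + (1 | condition)`; for
#' `"baseline"` it is `baseline ~ trialN * group + (1 + trialN | subject)`.
#' `trialN` enters scaled by 1/100, so fixed-effect estimates are
#' per-100-trial effects directly (the per-trial coefficient is reported
#' alongside).  The VSS group is the reference level, so the
#' `trialN x group` interaction is the control-minus-VSS slope difference
#' (negative when VSS is steeper).  Satterthwaite degrees of freedom are
#' used for the fixed-effect t tests.  A singular random-effects fit
#' triggers an automatic simplification ladder (condition slope dropped,
#' then the condition intercept), recorded in `$simplifications`.
#'
#' @param table data.frame with columns `subject_id`, `group`, `condition`,
#'   `trialN` and the response (`st_power` %, `st_freq` Hz or
#'   `baseline_power`).
#' @param response `"power"`, `"freq"` or `"baseline"`.
#' @param window inclusive trialN window, default `c(15, 137)`.
#' @param nBoot parametric-bootstrap replicates for fixed-effect CIs
#'   (0 = none; 1000 for reported CIs).
#' @param seed bootstrap seed.
#' @param REML logical, REML fit (default TRUE).
#' @return list: `model` (lmerMod), `fixed` (term, estimate_per100,
#'   estimate_per_trial, se, t, df, p), `slopes` (per-100-trial slope per
#'   group, for power/baseline), `aic`, `bic`, `logLik`, `bootCi`
#'   (percentile CIs of the per-100-trial fixed effects, if requested) and
#'   `simplifications`.
#' @export
fitRepetitionLMM <- function(table, response = c("power", "freq",
                                                 "baseline"),
                             window = c(15, 137), nBoot = 0, seed = 1,
                             REML = TRUE) {
  response <- match.arg(response)
  col <- switch(response, power = "st_power", freq = "st_freq",
                baseline = "baseline_power")
  if (!col %in% names(table)) stop("column ", col, " missing")
  d <- table[table$trialN >= window[1] & table$trialN <= window[2] &
             is.finite(table[[col]]), , drop = FALSE]
  d$resp <- if (response == "power") d[[col]] / 100 else d[[col]]
  d$tn <- d$trialN / 100
  d$grp <- factor(d$group, levels = c("VSS", "control"))
  d$subj <- factor(d$subject_id)
  d$cond <- factor(d$condition)
  multi_cond <- nlevels(d$cond) >= 2

  forms <- switch(response,
    power = c(
      if (multi_cond)
        "resp ~ tn * grp + (1 + tn | subj) + (1 + tn | cond)",
      if (multi_cond) "resp ~ tn * grp + (1 + tn | subj) + (1 | cond)",
      "resp ~ tn * grp + (1 + tn | subj)"),
    freq = c(
      if (multi_cond) "resp ~ tn + (1 + tn | subj) + (1 | cond)",
      "resp ~ tn + (1 + tn | subj)"),
    baseline = "resp ~ tn * grp + (1 + tn | subj)")

  fit <- NULL; simplifications <- character(0)
  for (fm in forms) {
    fit <- tryCatch(suppressMessages(lmerTest::lmer(
      stats::as.formula(fm), data = d, REML = REML,
      control = lme4::lmerControl(
        optimizer = "bobyqa",
        check.conv.singular = lme4::.makeCC(action = "ignore",
                                            tol = 1e-4)))),
      error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-4)) break
    simplifications <- c(simplifications,
                         paste("singular or failed:", fm))
  }
  if (is.null(fit)) stop("all mixed-model fits failed")

  co <- stats::coef(summary(fit))
  fixed <- data.frame(term = rownames(co),
                      estimate_per100 = co[, "Estimate"],
                      estimate_per_trial = co[, "Estimate"] / 100,
                      se = co[, "Std. Error"], t = co[, "t value"],
                      df = co[, "df"], p = co[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  # intercept-like terms are not per-trial effects; blank their rescaling
  not_slope <- !grepl("tn", fixed$term)
  fixed$estimate_per_trial[not_slope] <- NA_real_

  slopes <- NULL
  if (response %in% c("power", "baseline")) {
    b <- lme4::fixef(fit)
    inter <- if ("tn:grpcontrol" %in% names(b)) b[["tn:grpcontrol"]] else 0
    slopes <- c(VSS = unname(b[["tn"]]),
                control = unname(b[["tn"]]) + inter)
  }

  bootCi <- NULL
  if (nBoot > 0) {
    set.seed(seed)
    bs <- suppressMessages(lme4::bootMer(fit, lme4::fixef, nsim = nBoot,
                                         use.u = FALSE, type = "parametric"))
    bootCi <- t(apply(bs$t, 2, stats::quantile, c(0.025, 0.975),
                      na.rm = TRUE))
    colnames(bootCi) <- c("lo95", "hi95")
  }
  list(model = fit, fixed = fixed, slopes = slopes,
       aic = stats::AIC(fit), bic = stats::BIC(fit),
       logLik = as.numeric(stats::logLik(fit)),
       bootCi = bootCi, simplifications = simplifications)
}

#' Mixed ANOVA with Greenhouse-Geisser correction and partial eta squared
#'
#' Repeated-measures ANOVA with a within-subject `condition` factor, a
#' between-subject `group` factor and an optional between-subject covariate
#' (e.g. normalised age).  The within-subject machinery (type-III sums of
#' squares, Greenhouse-Geisser epsilon) is computed via
#' `car::Anova` on a multivariate linear model; partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.  Subjects with an incomplete
#' condition grid are dropped with a message.
#'
#' @param subjectTable data.frame: `subject_id`, `group`, `condition`,
#'   `value` (one row per subject x condition; e.g. log GR power), plus the
#'   covariate column if used.
#' @param covariate optional name of a between-subject covariate column.
#' @return data.frame: effect, F, df1, df2, p, gg_epsilon, p_gg, eta_p2
#'   (epsilon/p_gg are NA for between-subject effects).
#' @export
mixedAnovaGG <- function(subjectTable, covariate = NULL) {
  d <- subjectTable
  conds <- sort(unique(d$condition))
  wide <- stats::reshape(
    d[, c("subject_id", "condition", "value")],
    idvar = "subject_id", timevar = "condition", direction = "wide")
  scols <- c("subject_id", "group", covariate)
  subj <- unique(d[, scols, drop = FALSE])
  wide <- merge(subj, wide, by = "subject_id")
  wide$grp <- factor(wide$group, levels = unique(wide$group))
  vcols <- paste0("value.", conds)
  complete <- stats::complete.cases(wide[, vcols])
  if (any(!complete)) {
    message(sum(!complete), " subject(s) with incomplete grids dropped")
    wide <- wide[complete, , drop = FALSE]
  }
  Y <- as.matrix(wide[, vcols])
  rhs <- if (is.null(covariate)) "grp" else paste("grp +", covariate)
  # sum-to-zero contrasts so that type-III sums of squares are meaningful
  oc <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(oc), add = TRUE)
  mlm <- stats::lm(stats::as.formula(paste("Y ~", rhs)), data = wide)
  idata <- data.frame(condition = factor(conds))
  av <- car::Anova(mlm, idata = idata, idesign = ~condition, type = "III")
  # suppress car's note about Huynh-Feldt epsilon exceeding 1
  sm <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- sm$univariate.tests
  adj <- sm$pval.adjustments

  eff <- rownames(ut)
  eff <- eff[eff != "(Intercept)"]
  out <- lapply(eff, function(e) {
    ss <- ut[e, "Sum Sq"]; sse <- ut[e, "Error SS"]
    eps <- pgg <- NA_real_
    if (!is.null(adj) && e %in% rownames(adj)) {
      eps <- adj[e, "GG eps"]
      pgg <- adj[e, "Pr(>F[GG])"]
    }
    if (grepl("condition", e) && length(conds) == 2 && is.na(eps)) {
      # two within levels: sphericity holds trivially, epsilon = 1
      eps <- 1
      pgg <- ut[e, "Pr(>F)"]
    }
    data.frame(effect = e, F = ut[e, "F value"],
               df1 = ut[e, "num Df"], df2 = ut[e, "den Df"],
               p = ut[e, "Pr(>F)"], gg_epsilon = eps, p_gg = pgg,
               eta_p2 = ss / (ss + sse), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mann-Whitney / Wilcoxon rank-sum test with effect sizes
#'
#' Reports the rank-sum statistic U, the tie-corrected normal-approximation
#' Z, a p value (exact when there are no ties and both samples have at most
#' 50 observations, otherwise from Z) and the effect sizes
#' `r = Z / sqrt(n1 + n2)` and its Cohen's d equivalent
#' `d = 2 r / sqrt(1 - r^2)`.
#'
#' @param x,y numeric samples (>= 3 each).
#' @return list: U, Z, p, r, d, n1, n2.
#' @examples
#' rankTests(1:10, 11:20)$p  # exact: 2 / choose(20, 10)
#' @export
rankTests <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 3 || n2 < 3) stop("need >= 3 values per sample")
  N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_tab <- table(c(x, y))
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  s2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  Z <- if (s2 > 0) (U - mu) / sqrt(s2) else 0
  has_ties <- any(tie_tab > 1)
  p <- if (!has_ties && n1 <= 50 && n2 <= 50)
    stats::wilcox.test(x, y, exact = TRUE)$p.value
  else min(1, 2 * stats::pnorm(-abs(Z)))
  if (s2 == 0) p <- 1
  r_es <- Z / sqrt(N)
  d <- if (abs(r_es) < 1) 2 * r_es / sqrt(1 - r_es^2) else Inf * sign(r_es)
  list(U = U, Z = Z, p = p, r = r_es, d = d, n1 = n1, n2 = n2)
}

#' t statistics from printed summary statistics
#'
#' Re-derives t tests from means, SDs and sample sizes: a pooled-variance
#' two-sample t or a one-sample t against `mu0`.
#'
#' @param mode `"two_sample_pooled"` or `"one_sample"`.
#' @param m1,sd1,n1 first (or only) sample summary.
#' @param m2,sd2,n2 second sample summary (two-sample mode).
#' @param mu0 null value for the one-sample test (default 0).
#' @return list: t, df, p (two-sided).
#' @examples
#' summaryT("two_sample_pooled", 51.4, 9.5, 26, 40.1, 9.6, 27)$t  # ~4.3
#' @export
summaryT <- function(mode = c("two_sample_pooled", "one_sample"),
                     m1, sd1, n1, m2 = NULL, sd2 = NULL, n2 = NULL,
                     mu0 = 0) {
  mode <- match.arg(mode)
  if (mode == "two_sample_pooled") {
    stopifnot(sd1 > 0 || sd2 > 0, n1 >= 2, n2 >= 2)
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    stopifnot(sd1 > 0, n1 >= 2)
    t <- (m1 - mu0) / (sd1 / sqrt(n1))
    df <- n1 - 1
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Power of a two-sample t test
#'
#' Noncentral-t power with noncentrality
#' `d * sqrt(n1 * n2 / (n1 + n2))` and `n1 + n2 - 2` degrees of freedom.
#'
#' @param d Cohen's d effect size (>= 0).
#' @param n1,n2 group sizes.
#' @param alpha significance level.
#' @param sided `"one"` or `"two"`.
#' @return power (probability of rejection).
#' @examples
#' powerTwoSampleT(0.74, 26, 27, sided = "one")  # ~0.84
#' @export
powerTwoSampleT <- function(d, n1, n2, alpha = 0.05,
                            sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(d >= 0, n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (sided == "one") {
    1 - stats::pt(stats::qt(1 - alpha, df), df, ncp)
  } else {
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  }
}

#' Minimal detectable partial eta squared of an F test
#'
#' Solves for the noncentrality parameter lambda at which the
#' `F(df1, df2)` test attains the target power, converts it to an effect
#' size via `f^2 = lambda / N` and returns
#' `eta_p^2 = f^2 / (1 + f^2)`.
#'
#' @param df1,df2 numerator/denominator degrees of freedom.
#' @param N total sample size.
#' @param alpha significance level.
#' @param power target power.
#' @return minimal detectable partial eta squared.
#' @examples
#' minDetectableEtaP2(1, 50, 53)  # ~0.13
#' @export
minDetectableEtaP2 <- function(df1, df2, N, alpha = 0.05, power = 0.80) {
  stopifnot(df1 >= 1, df2 >= 1)
  fc <- stats::qf(1 - alpha, df1, df2)
  g <- function(l) 1 - stats::pf(fc, df1, df2, ncp = l) - power
  if (g(1e4) < 0) stop("no solution for lambda in (0, 1e4)")
  lam <- stats::uniroot(g, c(1e-8, 1e4), tol = 1e-10)$root
  f2 <- lam / N
  f2 / (1 + f2)
}

#' Spearman rank correlation with t-approximation p value
#'
#' Average ranks handle ties; the p value uses the t approximation
#' `t = R * sqrt((n - 2) / (1 - R^2))` on `n - 2` degrees of freedom.
#' Constant input is flagged and returns missing values.
#'
#' @param x,y paired numeric vectors (>= 4 complete pairs).
#' @return list: R, p, n, flag.
#' @export
spearmanCorr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(R = NA_real_, p = NA_real_, n = n, flag = "constant_input"))
  R <- stats::cor(rank(x), rank(y))
  p <- if (abs(R) >= 1) 0
  else 2 * stats::pt(-abs(R) * sqrt((n - 2) / (1 - R^2)), n - 2)
  list(R = R, p = p, n = n, flag = character(0))
}

#' Compare trial number vs stimulus-specific repetition count as predictors
#'
#' Fits the repetition mixed model twice (maximum likelihood), once with the
#' overall trial number and once with the within-condition repetition count
#' (the rank of the trial among its condition's trials), and compares fit
#' criteria.  Negative `dAIC`/`dBIC` favour the trial-number model.
#'
#' @param table as in [fitRepetitionLMM()]; the repetition count is derived
#'   internally.
#' @param response response, as in [fitRepetitionLMM()].
#' @param window trialN window.
#' @return list: dAIC, dBIC, dLogLik (trialN minus repetition-count model),
#'   preferred (`"trialN"` or `"repN"`), fits.
#' @export
compareTrialPredictors <- function(table, response = "power",
                                   window = c(15, 137)) {
  d <- table
  d$repN <- stats::ave(d$trialN, d$subject_id, d$condition,
                       FUN = function(v) rank(v, ties.method = "first"))
  f_trial <- fitRepetitionLMM(d, response, window, REML = FALSE)
  d2 <- d
  # same window selection must apply before swapping the predictor, so the
  # two models see identical rows
  d2 <- d2[d2$trialN >= window[1] & d2$trialN <= window[2], , drop = FALSE]
  d2$trialN <- d2$repN
  f_rep <- fitRepetitionLMM(d2, response, window = range(d2$trialN),
                            REML = FALSE)
  dAIC <- f_trial$aic - f_rep$aic
  list(dAIC = dAIC, dBIC = f_trial$bic - f_rep$bic,
       dLogLik = f_trial$logLik - f_rep$logLik,
       preferred = if (dAIC < 0) "trialN" else "repN",
       fits = list(trialN = f_trial, repN = f_rep))
}
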