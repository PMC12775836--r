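test_that("repetition LMM recovers an exact linear trend", {
  set.seed(1)
  subj <- sprintf("s%02d", 1:10)
  tab <- expand.grid(subject_id = subj, trialN = seq(15, 137, 2),
                     condition = 1.2, stringsAsFactors = FALSE)
  tab$group <- ifelse(tab$subject_id <= "s05", "VSS", "control")
  # per-subject intercepts, identical slope 0.003/trial, no noise
  icept <- setNames(rnorm(10, 100, 5), subj)
  tab$st_power <- icept[tab$subject_id] + 0.3 * tab$trialN
  fit <- suppressWarnings(fitRepetitionLMM(tab, "power"))
  est <- fit$fixed$estimate_per_trial[fit$fixed$term == "tn"]
  # mixed-model optimisation stops at ~1e-3 relative accuracy on
  # zero-residual data
  expect_equal(est, 0.003, tolerance = 2e-3)
  # per-100-trial invariant
  expect_equal(fit$fixed$estimate_per100[fit$fixed$term == "tn"],
               100 * est, tolerance = 1e-12)
  expect_equal(unname(fit$slopes["VSS"]), unname(fit$slopes["control"]),
               tolerance = 5e-3)
})

test_that("LMM group coding makes VSS the reference level", {
  coh <- simulateCohort(generatorConfig(nVss = 5, nControl = 5,
                                        slopeVss = 0.8,
                                        slopeControl = 0.05,
                                        slopeSd = 0.05, seed = 3),
                        ecg = FALSE)
  st <- singleTrialTable(coh)
  fit <- suppressWarnings(fitRepetitionLMM(st, "power"))
  inter <- fit$fixed$estimate_per100[fit$fixed$term == "tn:grpcontrol"]
  expect_lt(inter, 0)                       # control shallower than VSS
  expect_gt(fit$slopes["VSS"], fit$slopes["control"])
})

test_that("mixed ANOVA: epsilon bounds, eta oracle and covariate support", {
  # two within levels: Greenhouse-Geisser epsilon is exactly 1
  set.seed(4)
  d2 <- expand.grid(subject_id = sprintf("s%d", 1:12), condition = 1:2)
  d2$group <- ifelse(as.numeric(sub("s", "", d2$subject_id)) <= 6,
                     "VSS", "control")
  d2$value <- rnorm(nrow(d2))
  a2 <- mixedAnovaGG(d2)
  expect_equal(a2$gg_epsilon[a2$effect == "condition"], 1, tolerance = 1e-9)

  # eta_p2 agrees with an explicit sums-of-squares oracle via aov()
  d4 <- expand.grid(subject_id = sprintf("s%d", 1:8), condition = 1:3)
  d4$group <- ifelse(as.numeric(sub("s", "", d4$subject_id)) <= 4,
                     "VSS", "control")
  set.seed(5)
  d4$value <- rnorm(nrow(d4)) +
    2 * (d4$condition == 2) + 1.5 * (d4$group == "VSS")
  res <- mixedAnovaGG(d4)
  av <- summary(aov(value ~ group * factor(condition) +
                      Error(factor(subject_id) / factor(condition)),
                    data = d4))
  ss_b <- av[["Error: factor(subject_id)"]][[1]]
  ss_w <- av[["Error: factor(subject_id):factor(condition)"]][[1]]
  eta_group <- ss_b["group", "Sum Sq"] /
    (ss_b["group", "Sum Sq"] + ss_b["Residuals", "Sum Sq"])
  eta_cond <- ss_w["factor(condition)", "Sum Sq"] /
    (ss_w["factor(condition)", "Sum Sq"] + ss_w["Residuals", "Sum Sq"])
  expect_equal(res$eta_p2[res$effect == "grp"], eta_group,
               tolerance = 1e-6)
  expect_equal(res$eta_p2[res$effect == "condition"], eta_cond,
               tolerance = 1e-6)

  # covariate accepted and reported
  d4$age <- rnorm(nrow(d4))
  resc <- mixedAnovaGG(d4, covariate = "age")
  expect_true("age" %in% resc$effect)
})

test_that("compound-symmetric data yield epsilon near 1", {
  # the epsilon estimate is biased low in small samples, so sphericity is
  # checked on a large simulated sample (100 subjects)
  set.seed(6)
  eps <- replicate(100, {
    subj_eff <- rnorm(100, 0, 2)
    d <- expand.grid(subject_id = 1:100, condition = 1:5)
    d$group <- ifelse(d$subject_id <= 50, "VSS", "control")
    d$value <- subj_eff[d$subject_id] + rnorm(nrow(d))
    a <- mixedAnovaGG(d)
    a$gg_epsilon[a$effect == "condition"]
  })
  expect_gte(median(eps), 0.95)
})

test_that("rank-sum test matches enumeration and the printed r identity", {
  # identical samples: no shift, ties everywhere
  r0 <- rankTests(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r0$Z, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$r, 0)
  # fully separated samples: exact enumeration p = 2 / choose(20, 10)
  r1 <- rankTests(1:10, 11:20)
  expect_equal(r1$U, 0)
  expect_equal(r1$p, 2 / choose(20, 10), tolerance = 1e-12)
  # effect-size identity reproducing the printed value
  expect_equal(round(2.14 / sqrt(26 + 27), 2), 0.29)
  # r follows Z/sqrt(N) for arbitrary data
  set.seed(7)
  r2 <- rankTests(rnorm(26), rnorm(27) + 0.5)
  expect_equal(r2$r, r2$Z / sqrt(53), tolerance = 1e-12)
  expect_error(rankTests(1:2, 1:5), ">= 3")
})

test_that("summary-statistic t tests reproduce printed group comparisons", {
  # anxiety-inventory group difference
  t1 <- summaryT("two_sample_pooled", 51.4, 9.5, 26, 40.1, 9.6, 27)
  expect_equal(round(t1$t, 1), 4.3)
  expect_equal(t1$df, 51)
  expect_lt(t1$p, 1e-4)
  # one-sample test of the VSS plasticity slopes
  t2 <- summaryT("one_sample", 0.246, 0.160, 26)
  expect_equal(round(t2$t, 2), 7.84)
  expect_equal(t2$df, 25)
  # equal means: t = 0, p = 1
  t3 <- summaryT("two_sample_pooled", 5, 1, 10, 5, 1, 10)
  expect_equal(t3$t, 0)
  expect_equal(t3$p, 1)
})

test_that("noncentral-t power calculator matches the design statement", {
  expect_lt(abs(100 * powerTwoSampleT(0.74, 26, 27, sided = "one") - 84),
            0.5)
  # null effect: power equals alpha
  expect_equal(powerTwoSampleT(0, 20, 20, alpha = 0.05, sided = "one"),
               0.05, tolerance = 1e-9)
  # power strictly increasing in d
  pw <- vapply(seq(0.1, 1.5, 0.1),
               function(d) powerTwoSampleT(d, 15, 15), numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("noncentral-t power agrees with Monte-Carlo simulation", {
  set.seed(8)
  n1 <- 26; n2 <- 27; d <- 0.74
  nrep <- 1e5
  x1 <- matrix(rnorm(n1 * nrep, d), n1)
  x2 <- matrix(rnorm(n2 * nrep, 0), n2)
  sp <- sqrt(((n1 - 1) * apply(x1, 2, var) +
              (n2 - 1) * apply(x2, 2, var)) / (n1 + n2 - 2))
  tt <- (colMeans(x1) - colMeans(x2)) / (sp * sqrt(1 / n1 + 1 / n2))
  mc <- mean(tt > qt(0.95, n1 + n2 - 2))
  expect_lt(abs(mc - powerTwoSampleT(d, n1, n2, sided = "one")), 0.01)
})

test_that("sensitivity solver reproduces the printed bound and its oracle", {
  e <- minDetectableEtaP2(1, 50, 53)
  expect_equal(round(e, 2), 0.13)
  # brute-force grid search over lambda as an independent oracle
  fc <- qf(0.95, 1, 50)
  grid <- seq(0.01, 20, by = 1e-4)
  pw <- 1 - pf(fc, 1, 50, ncp = grid)
  lam <- grid[which.min(abs(pw - 0.80))]
  e_oracle <- (lam / 53) / (1 + lam / 53)
  expect_equal(e, e_oracle, tolerance = 1e-4)
  # power -> alpha limit: vanishing detectable effect
  expect_lt(minDetectableEtaP2(1, 50, 53, power = 0.051), 0.001)
})

test_that("Spearman correlation handles ties, hands and nulls", {
  # hand computation (no ties): rho = 1 - 6 sum(d^2) / (n (n^2 - 1))
  x <- c(1, 2, 3, 4); y <- c(2, 1, 3, 4)
  expect_equal(spearmanCorr(x, y)$R, 1 - 6 * 2 / (4 * 15))
  expect_equal(spearmanCorr(1:10, (1:10)^3)$R, 1)
  expect_error(spearmanCorr(1:3, 3:1), ">= 4")
  expect_equal(spearmanCorr(c(1, 1, 1, 1), 1:4)$flag, "constant_input")
  # null uniformity: rejection rate at alpha = 0.05 within [0.03, 0.08]
  set.seed(9)
  rej <- mean(replicate(1000, spearmanCorr(rnorm(50), rnorm(50))$p < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.08)
})

test_that("predictor comparison distinguishes trial number from repetition count", {
  # single condition: the two predictors coincide, dAIC ~ 0
  set.seed(10)
  tab <- expand.grid(subject_id = sprintf("s%d", 1:8),
                     trialN = seq(15, 137, 3), stringsAsFactors = FALSE)
  tab$condition <- 1.2
  tab$group <- ifelse(as.numeric(sub("s", "", tab$subject_id)) <= 4,
                      "VSS", "control")
  tab$st_power <- 100 + 0.3 * tab$trialN + rnorm(nrow(tab), 0, 5)
  cp <- suppressWarnings(compareTrialPredictors(tab))
  expect_lt(abs(cp$dAIC), 1e-6)

  # repetition-count-driven data prefer the repetition-count model
  set.seed(11)
  tab2 <- expand.grid(subject_id = sprintf("s%d", 1:10),
                      trialN = 15:137, stringsAsFactors = FALSE)
  tab2$group <- ifelse(as.numeric(sub("s", "", tab2$subject_id)) <= 5,
                       "VSS", "control")
  # five conditions interleaved differently per subject
  tab2$condition <- ave(tab2$trialN, tab2$subject_id,
                        FUN = function(v) sample(rep(1:5, length.out =
                                                       length(v))))
  repn <- ave(tab2$trialN, tab2$subject_id, tab2$condition,
              FUN = function(v) rank(v))
  tab2$st_power <- 100 + 8 * repn + rnorm(nrow(tab2), 0, 4)
  cp2 <- suppressWarnings(compareTrialPredictors(tab2))
  expect_equal(cp2$preferred, "repN")

  # trial-number-driven data prefer the trial-number model
  tab3 <- tab2
  tab3$st_power <- 100 + 2 * tab3$trialN + rnorm(nrow(tab3), 0, 4)
  cp3 <- suppressWarnings(compareTrialPredictors(tab3))
  expect_equal(cp3$preferred, "trialN")
  expect_lt(cp3$dAIC, -2)
})
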