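#' @include AllClasses.R
NULL

.write_tsv <- function(x, path, seed) {
  con <- file(path, "w")
  writeLines(paste0("# gammarep v", as.character(
    utils::packageVersion("gammarep")), " seed=", seed), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the full analysis pipeline on a (simulated) cohort
#'
#' Orchestrates generate -> spectral reduction -> single-trial dynamics ->
#' HRV -> group statistics, writing every stage's table as TSV (with the
#' seed in a header comment) plus a JSON manifest.  Re-running with the
#' same configuration and seed reproduces identical tables.
#'
#' @param config a [GeneratorConfig-class] (or NULL to use defaults).
#' @param outDir output directory (created if needed).
#' @param seed integer seed; overrides `config@seed` when given.
#' @param hrv logical; run the HRV/autonomic-coupling stage.
#' @param window trialN window for the repetition models, default
#'   `c(15, 137)`.
#' @param nBoot bootstrap replicates for the dynamics-model CIs.
#' @param cohort optionally, an existing [GammaCohort-class] to analyse
#'   instead of simulating one.
#' @return (invisibly) the manifest list: `paths`, `seed`, `headline`
#'   (tau, inflection, per-group LMM slopes, slope-vs-HFnu correlation),
#'   `stages`, and in-memory `tables`.
#' @export
runPipeline <- function(config = NULL, outDir = tempfile("gammarep_run_"),
                        seed = NULL, hrv = TRUE, window = c(15, 137),
                        nBoot = 200, cohort = NULL) {
  if (is.null(config)) config <- generatorConfig()
  if (!is.null(seed)) config@seed <- seed
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sd <- config@seed
  manifest <- list(seed = sd, paths = list(), stages = list(),
                   headline = list())
  tables <- list()

  if (is.null(cohort)) cohort <- simulateCohort(config, ecg = hrv)
  manifest$stages$simulate <- sprintf("%d subjects, %d trials each",
    length(cohort@subjects), nrow(.subject_spectra(
      cohort, names(cohort@subjects)[1])@info))
  manifest$paths$truth <- .write_tsv(truthTable(cohort),
                                     file.path(outDir, "truth.tsv"), sd)

  gr <- grTable(cohort)
  tables$gr <- gr
  manifest$paths$gr <- .write_tsv(gr, file.path(outDir, "gr_table.tsv"), sd)
  manifest$stages$spectral <- sprintf("%d subject x condition rows", nrow(gr))

  st <- singleTrialTable(cohort)
  tables$singleTrial <- st
  manifest$paths$singleTrial <- .write_tsv(
    st, file.path(outDir, "single_trial.tsv"), sd)
  manifest$stages$dynamics <- sprintf(
    "%d trials, %d excluded by the IQR rule", nrow(st), sum(!st$kept))

  course <- grandAverageCourse(st)
  dp <- fitDualProcess(course$trialN, course$z, nBoot = nBoot, seed = sd)
  bl <- fitBrokenLine(course$trialN, course$z, nBoot = nBoot, seed = sd)
  slopes <- subjectSlope(st, window = window)
  tables$subjectSlopes <- slopes
  fits <- data.frame(
    model = c("dual_process", "broken_line"),
    params = c(sprintf("A=%.4g tau=%.4g B=%.4g C=%.4g", dp@A, dp@tau,
                       dp@B, dp@C),
               sprintf("psi=%.4g slope_pre=%.4g slope_post=%.4g", bl@psi,
                       bl@slopePre, bl@slopePost)),
    ci95 = c(sprintf("tau:[%.3g,%.3g]", dp@tauCi[1], dp@tauCi[2]),
             sprintf("psi:[%.3g,%.3g]", bl@psiCi[1], bl@psiCi[2])),
    r2_adj = c(dp@r2Adj, NA))
  manifest$paths$fits <- .write_tsv(fits, file.path(outDir, "fits.tsv"), sd)
  manifest$paths$slopes <- .write_tsv(
    slopes, file.path(outDir, "subject_slopes.tsv"), sd)
  manifest$headline$tau <- dp@tau
  manifest$headline$inflection <- bl@psi
  tables$dualProcess <- dp
  tables$brokenLine <- bl

  lmm <- tryCatch(suppressWarnings(
    fitRepetitionLMM(st, "power", window = window)),
    error = function(e) NULL)
  if (!is.null(lmm)) {
    manifest$headline$slope_vss_per100 <- unname(lmm$slopes["VSS"])
    manifest$headline$slope_control_per100 <- unname(lmm$slopes["control"])
    tables$lmm <- lmm
  }

  statlines <- c(
    sprintf("dual-process: tau=%.2f (R2adj=%.2f)", dp@tau, dp@r2Adj),
    sprintf("broken-line: inflection=%.2f", bl@psi))
  grp_test <- tryCatch(
    rankTests(slopes$coef[slopes$group == "VSS"],
              slopes$coef[slopes$group == "control"]),
    error = function(e) NULL)
  if (!is.null(grp_test))
    statlines <- c(statlines, sprintf(
      "group difference in slopes: U=%.1f Z=%.2f p=%.3g r=%.2f",
      grp_test$U, grp_test$Z, grp_test$p, grp_test$r))
  if (!is.null(lmm))
    statlines <- c(statlines, sprintf(
      "LMM slopes per 100 trials: VSS=%.3f control=%.3f",
      lmm$slopes["VSS"], lmm$slopes["control"]))

  if (hrv) {
    ht <- hrvTable(cohort)
    tables$hrv <- ht
    manifest$paths$hrv <- .write_tsv(ht, file.path(outDir, "hrv.tsv"), sd)
    m <- merge(slopes, ht[, c("subject_id", "hfnu")], by = "subject_id")
    sc <- spearmanCorr(m$coef, m$hfnu)
    manifest$headline$slope_hfnu_R <- sc$R
    statlines <- c(statlines, sprintf(
      "plasticity slope vs HFnu: Spearman R=%.2f p=%.3g (N=%d)",
      sc$R, sc$p, sc$n))
  } else {
    statlines <- c(statlines,
      "HRV stage disabled: autonomic-coupling correlation not computed")
  }
  stats_path <- file.path(outDir, "stats_report.txt")
  writeLines(c(paste0("# gammarep statistics report, seed=", sd),
               statlines), stats_path)
  manifest$paths$stats <- stats_path
  manifest$stages$stats <- sprintf("%d headline statistics",
                                   length(manifest$headline))
  manifest$tables <- tables
  jsonlite::write_json(
    manifest[c("seed", "paths", "stages", "headline")],
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest$paths$manifest <- file.path(outDir, "manifest.json")
  invisible(manifest)
}

#' Validate a pipeline run against the acceptance surfaces
#'
#' Evaluates the closed-form summary-statistic targets (always) and, when a
#' completed run manifest is supplied, the stochastic recovery targets
#' (dual-process time constant, broken-line inflection, group slopes)
#' against their reference intervals.  Missing inputs yield status
#' `"skipped"`, never a silent pass.
#'
#' @param manifest a [runPipeline()] result, or NULL for
#'   summary-statistics-only mode.
#' @return data.frame: target, value, reference, status.
#' @export
validateAcceptance <- function(manifest = NULL) {
  res <- list()
  add <- function(target, value, reference, pass)
    res[[length(res) + 1L]] <<- data.frame(
      target = target, value = value, reference = reference,
      status = if (is.na(pass)) "skipped" else if (pass) "pass" else "fail",
      stringsAsFactors = FALSE)

  p <- 100 * powerTwoSampleT(0.74, 26, 27, sided = "one")
  add("power_d074", p, "84 +/- 0.5", abs(p - 84) <= 0.5)
  e <- minDetectableEtaP2(1, 50, 53)
  add("min_eta_p2", e, "0.13 (2 dp)", round(e, 2) == 0.13)
  t1 <- summaryT("two_sample_pooled", 51.4, 9.5, 26, 40.1, 9.6, 27)
  add("stai_t", t1$t, "4.3 (1 dp), df 51",
      round(t1$t, 1) == 4.3 && t1$df == 51)
  t2 <- summaryT("one_sample", 0.246, 0.160, 26)
  add("vss_slope_t", t2$t, "7.84 (2 dp)", round(t2$t, 2) == 7.84)
  r <- 2.14 / sqrt(53)
  add("rank_r_identity", r, "0.29 (2 dp)", round(r, 2) == 0.29)

  hl <- if (!is.null(manifest)) manifest$headline else list()
  add("tau_in_ci", hl$tau %||% NA_real_, "[6.0, 9.6]",
      if (is.null(hl$tau)) NA else hl$tau >= 6.0 && hl$tau <= 9.6)
  add("inflection_in_ci", hl$inflection %||% NA_real_, "[12.6, 16.6]",
      if (is.null(hl$inflection)) NA
      else hl$inflection >= 12.6 && hl$inflection <= 16.6)
  add("slope_vss_in_ci", hl$slope_vss_per100 %||% NA_real_, "[0.28, 0.60]",
      if (is.null(hl$slope_vss_per100)) NA
      else hl$slope_vss_per100 >= 0.28 && hl$slope_vss_per100 <= 0.60)
  add("slope_control_in_ci", hl$slope_control_per100 %||% NA_real_,
      "[0.05, 0.34]",
      if (is.null(hl$slope_control_per100)) NA
      else hl$slope_control_per100 >= 0.05 &&
           hl$slope_control_per100 <= 0.34)
  do.call(rbind, res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
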