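#' @include AllClasses.R
NULL

#' Accessors for gammarep objects
#'
#' Small accessor family: `relPower()` returns the relative-power matrix of a
#' [RelativeSpectrum-class] or [TrialSpectra-class]; `freqs()` the frequency
#' grid; `trialInfo()` the per-trial metadata; `truthTable()` and
#' `cohortConfig()` the ground truth and configuration of a
#' [GammaCohort-class]; `intervals()` the R-R intervals of an
#' [RRSeries-class]; `grPower()`/`grFreq()` the summary metrics of a
#' [GRMetrics-class].
#'
#' @param object a gammarep S4 object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("relPower", function(object) standardGeneric("relPower"))
#' @rdname accessors
#' @export
setGeneric("freqs", function(object) standardGeneric("freqs"))
#' @rdname accessors
#' @export
setGeneric("trialInfo", function(object) standardGeneric("trialInfo"))
#' @rdname accessors
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setGeneric("cohortConfig", function(object) standardGeneric("cohortConfig"))
#' @rdname accessors
#' @export
setGeneric("intervals", function(object) standardGeneric("intervals"))
#' @rdname accessors
#' @export
setGeneric("grPower", function(object) standardGeneric("grPower"))
#' @rdname accessors
#' @export
setGeneric("grFreq", function(object) standardGeneric("grFreq"))

#' @rdname accessors
setMethod("relPower", "RelativeSpectrum", function(object) object@relPower)
#' @rdname accessors
setMethod("relPower", "TrialSpectra", function(object) object@relPower)
#' @rdname accessors
setMethod("freqs", "RelativeSpectrum", function(object) object@freqs)
#' @rdname accessors
setMethod("freqs", "TrialSpectra", function(object) object@freqs)
#' @rdname accessors
setMethod("freqs", "TFR", function(object) object@freqs)
#' @rdname accessors
setMethod("trialInfo", "TrialSpectra", function(object) object@info)
#' @rdname accessors
setMethod("truthTable", "GammaCohort", function(object) object@truth)
#' @rdname accessors
setMethod("cohortConfig", "GammaCohort", function(object) object@config)
#' @rdname accessors
setMethod("intervals", "RRSeries", function(object) object@intervals)
#' @rdname accessors
setMethod("grPower", "GRMetrics", function(object) object@grPower)
#' @rdname accessors
setMethod("grFreq", "GRMetrics", function(object) object@grFreq)

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:", object@nVss, "VSS +", object@nControl,
      "control subjects\n")
  cat("  conditions (deg/s):", paste(object@conditions, collapse = ", "),
      " x", object@nTrialsPerCondition, "trials\n")
  cat("  dynamics: tau =", object@tauDecay, "trials, A =", object@ampEarly,
      ", slopes (VSS/control) =", object@slopeVss, "/",
      object@slopeControl, "per 100 trials\n")
  cat("  level:", object@level, " seed:", object@seed, "\n")
})

setMethod("show", "TrialEpoch", function(object) {
  cat(sprintf(
    "TrialEpoch %s [%s] trial %d, %.1f deg/s: %d sensors x %d samples @ %g Hz\n",
    object@subjectId, object@group, object@trialN, object@condition,
    nrow(object@data), ncol(object@data), object@fs))
})

setMethod("show", "TFR", function(object) {
  d <- dim(object@values)
  cat(sprintf("TFR (%s): %d sensors x %d freqs (%g-%g Hz) x %d times\n",
              object@units, d[1], d[2], min(object@freqs), max(object@freqs),
              d[3]))
})

setMethod("show", "RelativeSpectrum", function(object) {
  cat(sprintf("RelativeSpectrum: %d sensor(s) x %d bins (%g-%g Hz)\n",
              nrow(object@relPower), length(object@freqs),
              min(object@freqs), max(object@freqs)))
})

setMethod("show", "TrialSpectra", function(object) {
  cat(sprintf("TrialSpectra %s [%s]: %d trials x %d bins (%g-%g Hz)\n",
              object@subjectId, object@group, nrow(object@relPower),
              length(object@freqs), min(object@freqs), max(object@freqs)))
})

setMethod("show", "GRMetrics", function(object) {
  if (object@ok)
    cat(sprintf(
      "GRMetrics: power %.2f%%, freq %.2f Hz (peak %.1f Hz, %d bins, %s)\n",
      object@grPower, object@grFreq, object@peakFreq, object@nBinsUsed,
      paste(object@sensorsUsed, collapse = ",")))
  else cat("GRMetrics: no response (peak <= 0)\n")
})

setMethod("show", "DualProcessFit", function(object) {
  cat(sprintf(
    "DualProcessFit: y ~ %.4g * exp(-n/%.3g) + %.4g * n + %.4g (R2adj %.3f)\n",
    object@A, object@tau, object@B, object@C, object@r2Adj))
  if (!anyNA(object@tauCi))
    cat(sprintf("  tau 95%% CI: [%.2f, %.2f]\n", object@tauCi[1],
                object@tauCi[2]))
  if (length(object@flags)) cat("  flags:", paste(object@flags,
                                                  collapse = ", "), "\n")
})

setMethod("show", "BrokenLineFit", function(object) {
  cat(sprintf(
    "BrokenLineFit: inflection at %.2f trials (slopes %.4g -> %.4g)\n",
    object@psi, object@slopePre, object@slopePost))
  if (!anyNA(object@psiCi))
    cat(sprintf("  psi 95%% CI: [%.2f, %.2f]\n", object@psiCi[1],
                object@psiCi[2]))
  if (length(object@flags)) cat("  flags:", paste(object@flags,
                                                  collapse = ", "), "\n")
})

setMethod("show", "EcgTrace", function(object) {
  cat(sprintf("EcgTrace: %.1f s @ %g Hz, %d true R peaks\n",
              length(object@samples) / object@fs, object@fs,
              length(object@trueRTimes)))
})

setMethod("show", "RRSeries", function(object) {
  cat(sprintf("RRSeries: %d intervals, mean %.1f ms (%d corrected)\n",
              length(object@intervals), mean(object@intervals),
              sum(object@corrected)))
})

setMethod("show", "HRVMetrics", function(object) {
  cat(sprintf("HRVMetrics: %.1f bpm, SDNN %.1f ms, RMSSD %.1f ms",
              object@bpm, object@sdnn, object@rmssd))
  if (!is.na(object@hfnu)) cat(sprintf(", HFnu %.1f%%", object@hfnu))
  cat("\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags,
                                                  collapse = ", "), "\n")
})

setMethod("show", "GammaCohort", function(object) {
  tb <- table(object@truth$group)
  cat(sprintf("GammaCohort: %d subjects (%s)\n", length(object@subjects),
              paste(names(tb), tb, sep = "=", collapse = ", ")))
})
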