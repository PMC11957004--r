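#' @include mixture_fit.R
NULL

#' Run the QC analysis on a detected event table
#'
#' The per-measurement analysis core: fit a Gaussian mixture to the blockage
#' amplitudes (order chosen by BIC), label the components, convert soft
#' counts to frequencies over the effective duration, and evaluate the two
#' QC metrics — marker-ratio target concentration and percent-target.
#'
#' @param table an [EventTable-class].
#' @param cMarker nominal internal-marker concentration, pM.
#' @param markerAmplitudeHint expected marker amplitude, pA; used when the
#'   BIC-selected order is below 3 (e.g. plasma samples with no gDNA).
#' @param KMax,nInit,seed mixture-fit controls (see [selectComponents()]).
#' @param fixK optional fixed component count, bypassing BIC selection.
#' @param targetLength,dilutionFactor,elutionVolume,plasmaVolume,massPerBp
#'   passed to [qcReport()] for the plasma back-calculation.
#' @return A [QCReport-class].
#' @export
analyzeEvents <- function(table, cMarker = 100, markerAmplitudeHint = NULL,
                          KMax = 4L, nInit = 10L, seed = 1L, fixK = NULL,
                          targetLength = 150, dilutionFactor = NA_real_,
                          elutionVolume = NA_real_, plasmaVolume = NA_real_,
                          massPerBp = 650) {
  amps <- table@events$amplitude
  fit <- if (is.null(fixK)) {
    selectComponents(amps, KMax = KMax, seed = seed, nInit = nInit)
  } else {
    fitMixture(amps, K = fixK, seed = seed, nInit = nInit)
  }
  diag <- character()
  fit <- withCallingHandlers(
    labelComponents(fit, markerAmplitudeHint = markerAmplitudeHint),
    warning = function(w) {
      diag <<- c(diag, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  freqs <- speciesFrequencies(fit, table)
  rep <- qcReport(freqs, cMarker = cMarker, targetLength = targetLength,
                  dilutionFactor = dilutionFactor,
                  elutionVolume = elutionVolume, plasmaVolume = plasmaVolume,
                  massPerBp = massPerBp, diagnostics = diag)
  attr(rep, "fit") <- fit
  rep
}

#' End-to-end QC from a current trace
#'
#' Full pipeline on a single recording: baseline estimation, hysteresis
#' event detection with clog exclusion, mixture fitting, and QC metrics.
#'
#' @param trace an [IonTrace-class].
#' @param kSigma,minDwell,maxBlockDuration,window detection parameters
#'   (see [detectEvents()] and [estimateBaseline()]).
#' @inheritParams analyzeEvents
#' @return A [QCReport-class]; the detected [EventTable-class] is attached
#'   as attribute `"events"` and the mixture fit as `"fit"`.
#' @export
runQC <- function(trace, cMarker = 100, kSigma = 5, minDwell = 1e-4,
                  maxBlockDuration = 1, window = 501L,
                  markerAmplitudeHint = NULL, KMax = 4L, nInit = 10L,
                  seed = 1L, fixK = NULL, targetLength = 150,
                  dilutionFactor = NA_real_, elutionVolume = NA_real_,
                  plasmaVolume = NA_real_, massPerBp = 650) {
  bl <- estimateBaseline(trace, window = window)
  tab <- detectEvents(trace, bl, kSigma = kSigma, minDwell = minDwell,
                      maxBlockDuration = maxBlockDuration)
  rep <- analyzeEvents(tab, cMarker = cMarker,
                       markerAmplitudeHint = markerAmplitudeHint,
                       KMax = KMax, nInit = nInit, seed = seed, fixK = fixK,
                       targetLength = targetLength,
                       dilutionFactor = dilutionFactor,
                       elutionVolume = elutionVolume,
                       plasmaVolume = plasmaVolume, massPerBp = massPerBp)
  attr(rep, "events") <- tab
  rep
}
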