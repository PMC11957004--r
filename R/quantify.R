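#' @include event_detect.R
NULL

#' Per-species event frequencies
#'
#' Event frequencies (events/s over the effective duration) for the three
#' roles in the QC assay: the cfDNA-like target, the 1 kbp internal marker,
#' and the high-molecular-weight gDNA contaminant.
#'
#' @slot fTarget,fMarker,fGdna events/s; all non-negative.
#' @export
setClass("FrequencySet",
  representation(fTarget = "numeric", fMarker = "numeric", fGdna = "numeric"))

setValidity("FrequencySet", function(object) {
  v <- c(object@fTarget, object@fMarker, object@fGdna)
  if (any(!is.finite(v)) || any(v < 0)) return("frequencies must be finite and >= 0")
  TRUE
})

#' @rdname FrequencySet-class
#' @param fTarget,fMarker,fGdna events/s.
#' @export
frequencySet <- function(fTarget, fMarker, fGdna = 0) {
  new("FrequencySet", fTarget = fTarget, fMarker = fMarker, fGdna = fGdna)
}

#' @export
setMethod("show", "FrequencySet", function(object) {
  cat(sprintf("FrequencySet: target %.4g /s, marker %.4g /s, gDNA %.4g /s\n",
              object@fTarget, object@fMarker, object@fGdna))
  invisible(NULL)
})

#' Target concentration from the internal-marker frequency ratio
#'
#' The quantification metric of the assay. In diffusion-limited transport the
#' capture rate of each species is proportional to its concentration and
#' independent of fragment length, so with a marker spiked at known
#' concentration `cMarker` the target concentration is
#' `C_T = C_M * f_T / f_M`. Being a frequency ratio, the estimate is
#' invariant to any global rescaling of event rates (pore size, clogging,
#' partial data loss).
#'
#' @param freqs a [FrequencySet-class].
#' @param cMarker marker concentration, pM.
#' @return Estimated target concentration, pM.
#' @export
estimateConcentration <- function(freqs, cMarker) {
  stopifnot(is(freqs, "FrequencySet"), cMarker > 0)
  if (freqs@fMarker <= 0) {
    stop("marker not detected (f_marker = 0): cannot form the concentration ratio; ",
         "check the mixture labelling or supply a marker amplitude hint")
  }
  cMarker * freqs@fTarget / freqs@fMarker
}

#' Percent-target qualification metric
#'
#' `%cfDNA = 100 * f_T / (f_T + f_gDNA)`: the fraction of target among
#' target-plus-genomic-DNA events. 100% means no detectable HMW gDNA
#' contamination; the marker frequency does not enter.
#'
#' @param freqs a [FrequencySet-class].
#' @return Percentage in `[0, 100]`.
#' @export
estimatePercentTarget <- function(freqs) {
  stopifnot(is(freqs, "FrequencySet"))
  denom <- freqs@fTarget + freqs@fGdna
  if (denom <= 0) {
    stop("undefined percentage: neither target nor gDNA events detected")
  }
  100 * freqs@fTarget / denom
}

#' Convert molar to mass concentration for dsDNA
#'
#' `ng/mL = c[pM] * length[bp] * massPerBp[g/mol/bp] * 1e-6`
#' (1 pM = 1e-12 mol/L; 1 ng/mL = 1e-6 g/L).
#'
#' @param c molar concentration, pM.
#' @param length fragment length, bp.
#' @param massPerBp average base-pair molar mass, g/mol/bp (default 650).
#' @return Mass concentration, ng/mL.
#' @export
molarToMassConcentration <- function(c, length, massPerBp = 650) {
  stopifnot(c >= 0, length > 0, massPerBp > 0)
  c * length * massPerBp * 1e-6
}

#' Inverse of [molarToMassConcentration()].
#' @inheritParams molarToMassConcentration
#' @param m mass concentration, ng/mL.
#' @export
massToMolarConcentration <- function(m, length, massPerBp = 650) {
  stopifnot(m >= 0, length > 0, massPerBp > 0)
  m / (length * massPerBp * 1e-6)
}

#' Back-calculate the plasma-equivalent cfDNA concentration
#'
#' Undoes the sample-preparation chain: the measured molar concentration in
#' the measurement buffer is converted to mass concentration, multiplied by
#' the dilution factor applied before measurement, and rescaled from the
#' elution volume to the original plasma volume (assuming full recovery of
#' cfDNA during extraction; `recovery` is exposed for sensitivity checks).
#'
#' @param cMeasured measured concentration in the measurement buffer, pM.
#' @param length assumed fragment length, bp.
#' @param dilutionFactor dilution applied to the eluate before measurement
#'   (e.g. 40).
#' @param elutionVolume extraction elution volume, uL (e.g. 55).
#' @param plasmaVolume plasma input volume, mL (e.g. 1).
#' @param massPerBp g/mol/bp.
#' @param recovery assumed extraction recovery fraction (default 1).
#' @return Plasma-equivalent concentration, ng/mL.
#' @export
backCalculatePlasma <- function(cMeasured, length, dilutionFactor,
                                elutionVolume, plasmaVolume,
                                massPerBp = 650, recovery = 1) {
  stopifnot(cMeasured >= 0, length > 0, dilutionFactor > 0,
            elutionVolume > 0, plasmaVolume > 0, recovery > 0)
  molarToMassConcentration(cMeasured, length, massPerBp) * dilutionFactor *
    (elutionVolume / (plasmaVolume * 1000)) / recovery
}

#' QC report for one measurement
#'
#' @slot cTarget estimated target concentration, pM.
#' @slot percentTarget percent-target qualification metric, %.
#' @slot cMarkerNominal nominal marker concentration, pM.
#' @slot plasmaEquivalent plasma-equivalent concentration, ng/mL (NA when
#'   no dilution/elution parameters were supplied).
#' @slot fragmentLengthAssumed bp used for molar-to-mass conversion.
#' @slot dilutionFactor,elutionVolume,plasmaVolume sample-prep parameters.
#' @slot frequencies the underlying [FrequencySet-class].
#' @slot diagnostics free-text notes (e.g. unassigned mixture components).
#' @export
setClass("QCReport",
  representation(
    cTarget = "numeric", percentTarget = "numeric",
    cMarkerNominal = "numeric", plasmaEquivalent = "numeric",
    fragmentLengthAssumed = "numeric", dilutionFactor = "numeric",
    elutionVolume = "numeric", plasmaVolume = "numeric",
    frequencies = "FrequencySet", diagnostics = "character"
  )
)

setValidity("QCReport", function(object) {
  if (object@cTarget < 0) return("cTarget must be >= 0")
  if (object@percentTarget < 0 || object@percentTarget > 100) {
    return("percentTarget must lie in [0, 100]")
  }
  TRUE
})

#' @rdname QCReport-class
#' @param freqs a [FrequencySet-class].
#' @param cMarker nominal marker concentration, pM.
#' @param targetLength assumed target fragment length, bp.
#' @param dilutionFactor,elutionVolume,plasmaVolume optional sample-prep
#'   parameters enabling the plasma back-calculation.
#' @param massPerBp g/mol/bp.
#' @param diagnostics character notes.
#' @export
qcReport <- function(freqs, cMarker, targetLength = 150,
                     dilutionFactor = NA_real_, elutionVolume = NA_real_,
                     plasmaVolume = NA_real_, massPerBp = 650,
                     diagnostics = character()) {
  # configs parsed from YAML may carry logical NA for unset fields
  dilutionFactor <- as.numeric(dilutionFactor %||% NA_real_)
  elutionVolume <- as.numeric(elutionVolume %||% NA_real_)
  plasmaVolume <- as.numeric(plasmaVolume %||% NA_real_)
  ct <- estimateConcentration(freqs, cMarker)
  pt <- estimatePercentTarget(freqs)
  pe <- if (all(is.finite(c(dilutionFactor, elutionVolume, plasmaVolume)))) {
    backCalculatePlasma(ct, targetLength, dilutionFactor, elutionVolume,
                        plasmaVolume, massPerBp)
  } else NA_real_
  new("QCReport", cTarget = ct, percentTarget = pt, cMarkerNominal = cMarker,
      plasmaEquivalent = pe, fragmentLengthAssumed = targetLength,
      dilutionFactor = dilutionFactor, elutionVolume = elutionVolume,
      plasmaVolume = plasmaVolume, frequencies = freqs,
      diagnostics = diagnostics)
}

#' @export
setMethod("show", "QCReport", function(object) {
  cat("Nanopore cfDNA QC report\n")
  cat(sprintf("  target concentration : %.3g pM (marker nominal %.3g pM)\n",
              object@cTarget, object@cMarkerNominal))
  cat(sprintf("  percent target       : %.1f %%\n", object@percentTarget))
  if (is.finite(object@plasmaEquivalent)) {
    cat(sprintf("  plasma equivalent    : %.3g ng/mL (len %g bp, %gx dilution, %g uL from %g mL)\n",
                object@plasmaEquivalent, object@fragmentLengthAssumed,
                object@dilutionFactor, object@elutionVolume, object@plasmaVolume))
  }
  if (length(object@diagnostics)) {
    cat("  diagnostics:", paste(object@diagnostics, collapse = "; "), "\n")
  }
  invisible(NULL)
})

#' @rdname QCReport-class
#' @param x a `QCReport`.
#' @export
cTarget <- function(x) x@cTarget

#' @rdname QCReport-class
#' @export
percentTarget <- function(x) x@percentTarget
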