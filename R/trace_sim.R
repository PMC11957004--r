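#' @include pore_geometry.R
NULL

#' Describe one DNA species in a simulated sample
#'
#' Returns a one-row data.frame describing a co-translocating DNA species:
#' its fragment length, molar concentration, blockage-amplitude distribution
#' (Normal, truncated at zero) quoted at the simulator's reference pore
#' diameter, and its dwell-time distribution (log-normal).
#'
#' @param name species label, e.g. `"target"`, `"marker"`, `"gDNA"`.
#' @param length fragment length, bp.
#' @param concentration molar concentration, pM.
#' @param amplitudeMean mean blockage amplitude at the reference pore, pA.
#' @param amplitudeSd amplitude standard deviation at the reference pore, pA.
#' @param dwellLogMean mean of log dwell time (log-seconds).
#' @param dwellLogSd standard deviation of log dwell time.
#' @export
speciesSpec <- function(name, length, concentration,
                        amplitudeMean, amplitudeSd,
                        dwellLogMean, dwellLogSd) {
  stopifnot(concentration >= 0, amplitudeMean > 0, amplitudeSd > 0, length > 0,
            dwellLogSd >= 0)
  data.frame(name = as.character(name), length_bp = length,
             concentration_pM = concentration,
             amplitude_mean_pA = amplitudeMean, amplitude_sd_pA = amplitudeSd,
             dwell_log_mean = dwellLogMean, dwell_log_sd = dwellLogSd,
             stringsAsFactors = FALSE)
}

#' Default three-species mock panel
#'
#' The standard mock sample: a 150 bp cfDNA-like target, the 1 kbp internal
#' marker at 100 pM, and a 10 kbp high-molecular-weight genomic-DNA
#' contaminant. Amplitude and dwell parameters are synthetic fixture values
#' chosen for clear histogram separability at the 10 nm reference pore; no
#' measured amplitudes or dwell statistics are claimed.
#'
#' @param targetConcentration target (150 bp) concentration, pM.
#' @param markerConcentration marker (1 kbp) concentration, pM.
#' @param gdnaConcentration HMW gDNA (10 kbp) concentration, pM.
#' @return A three-row species data.frame (see [speciesSpec()]).
#' @export
defaultSpeciesPanel <- function(targetConcentration = 120,
                                markerConcentration = 100,
                                gdnaConcentration = 100) {
  rbind(
    speciesSpec("target", 150, targetConcentration,
                amplitudeMean = 60, amplitudeSd = 6,
                dwellLogMean = log(1e-4), dwellLogSd = 0.35),
    speciesSpec("marker", 1000, markerConcentration,
                amplitudeMean = 160, amplitudeSd = 14,
                dwellLogMean = log(4e-4), dwellLogSd = 0.35),
    speciesSpec("gDNA", 10000, gdnaConcentration,
                amplitudeMean = 380, amplitudeSd = 32,
                dwellLogMean = log(2e-3), dwellLogSd = 0.4)
  )
}

#' Simulation specification for an ionic-current recording
#'
#' Bundles everything needed to generate a synthetic nanopore recording:
#' the species panel, the pore geometry (whose tip diameter rescales the
#' quoted amplitudes via [amplitudeScale()]), acquisition settings matching
#' the patch-clamp regime (100 kHz sampling, 5 kHz low-pass by default), the
#' diffusion-limited capture-rate constant, and optional clogged intervals
#' during which no events are captured.
#'
#' @slot species species data.frame (see [speciesSpec()]).
#' @slot pore a [PoreGeometry-class].
#' @slot referenceDiameter nm; diameter at which species amplitudes are quoted.
#' @slot openPoreCurrent pA.
#' @slot noiseSd pA, i.i.d. Gaussian noise on the rendered trace.
#' @slot samplingRate Hz.
#' @slot filterCutoff Hz, low-pass cutoff.
#' @slot duration s.
#' @slot captureRateConstant events/s/pM; per-species event rate is
#'   `captureRateConstant * concentration`, independent of fragment length
#'   (diffusion-limited capture).
#' @slot clogIntervals two-column matrix of (start, end) seconds.
#' @slot seed integer RNG seed; same seed, same events and trace.
#' @export
setClass("SimSpec",
  representation(
    species = "data.frame",
    pore = "PoreGeometry",
    referenceDiameter = "numeric",
    openPoreCurrent = "numeric",
    noiseSd = "numeric",
    samplingRate = "numeric",
    filterCutoff = "numeric",
    duration = "numeric",
    captureRateConstant = "numeric",
    clogIntervals = "matrix",
    seed = "numeric"
  )
)

setValidity("SimSpec", function(object) {
  msg <- character()
  need <- c("name", "length_bp", "concentration_pM", "amplitude_mean_pA",
            "amplitude_sd_pA", "dwell_log_mean", "dwell_log_sd")
  if (!all(need %in% names(object@species))) {
    msg <- c(msg, "species must have the speciesSpec() columns")
  } else if (any(object@species$concentration_pM < 0)) {
    msg <- c(msg, "species concentrations must be >= 0")
  }
  if (object@samplingRate <= 2 * object@filterCutoff) {
    msg <- c(msg, "samplingRate must exceed 2 * filterCutoff")
  }
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (object@captureRateConstant <= 0) {
    msg <- c(msg, "captureRateConstant must be positive")
  }
  ci <- object@clogIntervals
  if (NROW(ci)) {
    if (any(ci < 0) || any(ci > object@duration) || any(ci[, 2] <= ci[, 1])) {
      msg <- c(msg, "clog intervals must be within [0, duration] with start < end")
    }
    o <- order(ci[, 1])
    if (NROW(ci) > 1 && any(ci[o, 1][-1] < ci[o, 2][-NROW(ci)])) {
      msg <- c(msg, "clog intervals must not overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SimSpec-class
#' @param species,pore,referenceDiameter,openPoreCurrent,noiseSd,samplingRate,filterCutoff,duration,captureRateConstant,clogIntervals,seed see slots.
#' @export
simSpec <- function(species = defaultSpeciesPanel(),
                    pore = poreGeometry(10, bufferConductivity = 20,
                                        halfConeAngle = 5),
                    referenceDiameter = 10,
                    openPoreCurrent = 5000, noiseSd = 6,
                    samplingRate = 1e5, filterCutoff = 5e3,
                    duration = 1800, captureRateConstant = 0.02,
                    clogIntervals = .empty_intervals(), seed = 1L) {
  if (is.null(dim(clogIntervals))) {
    clogIntervals <- matrix(clogIntervals, ncol = 2)
  }
  new("SimSpec", species = species, pore = pore,
      referenceDiameter = referenceDiameter,
      openPoreCurrent = openPoreCurrent, noiseSd = noiseSd,
      samplingRate = samplingRate, filterCutoff = filterCutoff,
      duration = duration, captureRateConstant = captureRateConstant,
      clogIntervals = clogIntervals, seed = as.numeric(seed))
}

#' A uniformly sampled ionic current recording
#'
#' @slot samples current samples, pA.
#' @slot samplingRate Hz.
#' @slot biasVoltage mV.
#' @slot poreId pore label.
#' @slot truth for simulated traces, the injected event table
#'   (time/species/amplitude/dwell) with the clog intervals as the
#'   `"clogIntervals"` attribute; NULL for real recordings.
#' @export
setClass("IonTrace",
  representation(
    samples = "numeric",
    samplingRate = "numeric",
    biasVoltage = "numeric",
    poreId = "character",
    truth = "ANY"
  )
)

setValidity("IonTrace", function(object) {
  if (!all(is.finite(object@samples))) return("samples must all be finite")
  if (object@samplingRate <= 0) return("samplingRate must be positive")
  TRUE
})

#' @rdname IonTrace-class
#' @param samples,samplingRate,biasVoltage,poreId,truth see slots.
#' @export
ionTrace <- function(samples, samplingRate, biasVoltage = 400,
                     poreId = "pore1", truth = NULL) {
  new("IonTrace", samples = as.numeric(samples),
      samplingRate = samplingRate, biasVoltage = biasVoltage,
      poreId = poreId, truth = truth)
}

#' @export
setMethod("show", "IonTrace", function(object) {
  cat(sprintf("IonTrace '%s': %d samples @ %g kHz (%.2f s), %g mV bias\n",
              object@poreId, length(object@samples),
              object@samplingRate / 1e3,
              length(object@samples) / object@samplingRate,
              object@biasVoltage))
  invisible(NULL)
})

#' @rdname IonTrace-class
#' @param x an `IonTrace`.
#' @export
traceSamples <- function(x) x@samples

#' @rdname IonTrace-class
#' @export
samplingRate <- function(x) x@samplingRate

#' Simulate translocation events
#'
#' Each species arrives as an independent homogeneous Poisson process with
#' rate `captureRateConstant * concentration` (events/s) — concentration
#' dependent, fragment-length independent, the diffusion-limited capture
#' regime that underwrites the frequency-ratio concentration estimator.
#' Events falling inside clog intervals are thinned away. Blockage
#' amplitudes are Normal, truncated at zero, with mean and sd rescaled from
#' the reference pore by [amplitudeScale()]; dwell times are log-normal.
#' Output is deterministic given `spec@seed`.
#'
#' @param spec a [SimSpec-class].
#' @return data.frame with columns `time` (s), `species`, `amplitude` (pA),
#'   `dwell` (s), sorted by time.
#' @export
simulateEvents <- function(spec) {
  validObject(spec)
  scale <- amplitudeScale(spec@pore@tipDiameter, spec@referenceDiameter)
  with_seed(spec@seed, {
    out <- lapply(seq_len(nrow(spec@species)), function(i) {
      sp <- spec@species[i, ]
      lambda <- spec@captureRateConstant * sp$concentration_pM
      n <- rpois(1L, lambda * spec@duration)
      if (n == 0L) return(NULL)
      amp <- rnorm(n, sp$amplitude_mean_pA * scale, sp$amplitude_sd_pA * scale)
      while (any(amp <= 0)) {  # truncate at zero by resampling
        bad <- amp <= 0
        amp[bad] <- rnorm(sum(bad), sp$amplitude_mean_pA * scale,
                          sp$amplitude_sd_pA * scale)
      }
      data.frame(time = runif(n, 0, spec@duration),
                 species = sp$name,
                 amplitude = amp,
                 dwell = rlnorm(n, sp$dwell_log_mean, sp$dwell_log_sd),
                 stringsAsFactors = FALSE)
    })
    ev <- do.call(rbind, out)
    if (is.null(ev)) {
      ev <- data.frame(time = numeric(0), species = character(0),
                       amplitude = numeric(0), dwell = numeric(0))
    }
    ev <- ev[!.in_intervals(ev$time, spec@clogIntervals), , drop = FALSE]
    ev <- ev[order(ev$time), , drop = FALSE]
    rownames(ev) <- NULL
    ev
  })
}

## Low-pass approximation of the amplifier's Bessel response: a Gaussian FIR
## kernel with its -3 dB point at `cutoff` (sigma_t = sqrt(ln 2) / (2 pi fc)).
## Like a Bessel filter the step response is monotone (no overshoot), so long
## pulses settle to their full depth. Applied to the deviation from the
## open-pore level; edges are zero-padded.
.lowpass_kernel <- function(samplingRate, cutoff) {
  sigma <- sqrt(log(2)) / (2 * pi * cutoff) * samplingRate  # in samples
  half <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k / sum(k)
}

.lowpass <- function(dev, samplingRate, cutoff) {
  k <- .lowpass_kernel(samplingRate, cutoff)
  half <- (length(k) - 1L) %/% 2L
  padded <- c(numeric(half), dev, numeric(half))
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(half + 1L):(half + length(dev))])
}

#' Render a continuous current trace from an event list
#'
#' The trace is the open-pore current minus a rectangular pulse per event
#' (depth = amplitude, width = dwell; co-captured overlapping events sum),
#' low-pass filtered with a Gaussian kernel whose -3 dB point sits at
#' `filterCutoff` (a monotone-step approximation of the amplifier's Bessel
#' response), plus i.i.d.
#' Gaussian noise. Clog intervals are rendered as a deep depressed-current
#' plateau (80% blockade of the open-pore current) and flagged in the truth
#' metadata.
#'
#' @param spec a [SimSpec-class].
#' @param events event data.frame as from [simulateEvents()]; all event
#'   times must lie in `[0, duration]`.
#' @param poreId label stored on the trace.
#' @return An [IonTrace-class] with the events (and clog intervals) attached
#'   as truth metadata.
#' @export
renderTrace <- function(spec, events, poreId = "pore1") {
  validObject(spec)
  if (nrow(events) && (any(events$time < 0) || any(events$time > spec@duration))) {
    stop("event times must lie within [0, duration]")
  }
  n <- round(spec@duration * spec@samplingRate)
  dev <- numeric(n)  # deviation from the open-pore level, pA
  if (nrow(events)) {
    i0 <- pmax(1L, floor(events$time * spec@samplingRate) + 1L)
    i1 <- pmin(n, ceiling((events$time + events$dwell) * spec@samplingRate))
    for (k in seq_len(nrow(events))) {
      idx <- i0[k]:i1[k]
      dev[idx] <- dev[idx] - events$amplitude[k]
    }
  }
  ci <- spec@clogIntervals
  if (NROW(ci)) {
    for (k in seq_len(NROW(ci))) {
      j0 <- pmax(1L, floor(ci[k, 1] * spec@samplingRate) + 1L)
      j1 <- pmin(n, ceiling(ci[k, 2] * spec@samplingRate))
      dev[j0:j1] <- -0.8 * spec@openPoreCurrent
    }
  }
  dev <- .lowpass(dev, spec@samplingRate, spec@filterCutoff)
  noise <- if (spec@noiseSd > 0) {
    with_seed(spec@seed + 1e6, rnorm(n, 0, spec@noiseSd))
  } else 0
  truth <- events
  attr(truth, "clogIntervals") <- ci
  ionTrace(spec@openPoreCurrent + dev + noise, spec@samplingRate,
           biasVoltage = spec@pore@biasVoltage, poreId = poreId,
           truth = truth)
}
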