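#' @include trace_sim.R
NULL

#' Running baseline and noise model for a current trace
#'
#' @slot baseline per-sample running baseline estimate, pA.
#' @slot noiseSd scalar noise standard deviation estimate, pA.
#' @slot window running-median window, samples (odd).
#' @slot degenerate TRUE when the trace was constant and the noise estimate
#'   was floored at machine epsilon.
#' @export
setClass("BaselineModel",
  representation(
    baseline = "numeric",
    noiseSd = "numeric",
    window = "integer",
    degenerate = "logical"
  )
)

setValidity("BaselineModel", function(object) {
  if (object@window < 3L) return("window must be >= 3 samples")
  if (!is.finite(object@noiseSd) || object@noiseSd <= 0) {
    return("noiseSd must be positive after warm-up")
  }
  TRUE
})

#' Estimate the open-pore baseline and noise level
#'
#' Two-pass robust estimator. Sub-baseline runs at least one window long are
#' masked first (judged against a first-difference noise scale, which a
#' plateau cannot inflate), so that clogged plateaus longer than the window
#' cannot drag the running median down. Pass one then takes a running median
#' of the masked-and-interpolated trace and flags samples more than
#' 3 MAD-sigma below it as candidate event samples; pass two recomputes the
#' running median with those samples replaced by linear interpolation, so
#' brief blockades do not drag the baseline down either. The
#' noise is `1.4826 x` the median absolute deviation of the event-free
#' residuals. A perfectly constant trace gets a noise floor of machine
#' epsilon and is flagged degenerate.
#'
#' @param trace an [IonTrace-class].
#' @param window running-median window in samples (forced odd); must not
#'   exceed the trace length.
#' @return A [BaselineModel-class].
#' @export
estimateBaseline <- function(trace, window = 501L) {
  x <- trace@samples
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (length(x) < window) stop("trace shorter than the baseline window")
  # a running median tracks any depressed plateau longer than half the
  # window (a long clog), so first mask sub-baseline runs at least one
  # window long; the scale comes from first differences, which plateaus
  # cannot inflate, and short excursions are left to the two-pass logic
  gm <- median(x)
  s_hf <- mad(diff(x)) / sqrt(2)
  if (s_hf <= 0) s_hf <- 1.2533 * mean(abs(diff(x))) / sqrt(2)
  pre <- rep(FALSE, length(x))
  if (s_hf > 0) {
    cand <- x < gm - 3 * s_hf
    r <- rle(cand)
    long <- r$values & r$lengths >= window
    if (any(long)) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (i in which(long)) pre[starts[i]:ends[i]] <- TRUE
    }
  }
  if (all(pre)) pre <- rep(FALSE, length(x))
  interp <- function(mask) {
    if (!any(mask)) return(x)
    x2 <- x
    keep <- which(!mask)
    x2[mask] <- approx(keep, x[keep], xout = which(mask), rule = 2)$y
    x2
  }
  b1 <- runmed(interp(pre), window, endrule = "median")
  r1 <- x - b1
  s1 <- mad(r1[!pre])
  degenerate <- FALSE
  if (s1 <= 0) {
    # fall back on the mean absolute residual before declaring degeneracy
    s1 <- 1.2533 * mean(abs(r1[!pre]))
    if (s1 <= 0) {
      return(new("BaselineModel", baseline = b1,
                 noiseSd = .Machine$double.eps, window = window,
                 degenerate = TRUE))
    }
  }
  inevent <- pre | r1 < -3 * s1
  b2 <- if (any(inevent)) runmed(interp(inevent), window, endrule = "median") else b1
  s2 <- mad((x - b2)[!inevent])
  if (s2 <= 0) {
    s2 <- .Machine$double.eps
    degenerate <- TRUE
  }
  new("BaselineModel", baseline = b2, noiseSd = s2, window = window,
      degenerate = degenerate)
}

#' Detected translocation events with effective duration
#'
#' The central event container: one row per detected (or simulated)
#' translocation, plus the effective recording duration after subtracting
#' excluded (clogged) intervals. Frequencies computed over the effective
#' duration — rather than raw counts over wall-clock time — compensate for
#' data loss when a pore clogs.
#'
#' @slot events data.frame with columns `pore_id`, `chunk_id`,
#'   `start_time` (s), `dwell` (s), `amplitude` (pA) and, for simulated
#'   tables, `species`.
#' @slot recordedDuration total recording length, s.
#' @slot excludedIntervals two-column matrix of excluded (start, end) s.
#' @slot effectiveDuration `recordedDuration - sum(excluded lengths)`, s.
#' @export
setClass("EventTable",
  representation(
    events = "data.frame",
    recordedDuration = "numeric",
    excludedIntervals = "matrix",
    effectiveDuration = "numeric"
  )
)

setValidity("EventTable", function(object) {
  msg <- character()
  ev <- object@events
  need <- c("pore_id", "chunk_id", "start_time", "dwell", "amplitude")
  if (!all(need %in% names(ev))) {
    msg <- c(msg, paste("events must have columns", paste(need, collapse = ", ")))
  } else if (nrow(ev)) {
    if (any(ev$dwell <= 0)) msg <- c(msg, "event dwells must be positive")
    if (any(ev$amplitude <= 0)) msg <- c(msg, "event amplitudes must be positive")
  }
  expected <- object@recordedDuration - .interval_total(object@excludedIntervals)
  if (abs(object@effectiveDuration - expected) > 1e-9 * max(1, expected)) {
    msg <- c(msg, "effectiveDuration must equal recordedDuration minus excluded time")
  }
  if (object@effectiveDuration < 0) msg <- c(msg, "effectiveDuration must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname EventTable-class
#' @param events,recordedDuration,excludedIntervals see slots.
#' @export
eventTable <- function(events, recordedDuration,
                       excludedIntervals = .empty_intervals()) {
  if (!"pore_id" %in% names(events)) events$pore_id <- "pore1"
  if (!"chunk_id" %in% names(events)) events$chunk_id <- NA_character_
  if (is.null(dim(excludedIntervals))) {
    excludedIntervals <- matrix(excludedIntervals, ncol = 2)
  }
  new("EventTable", events = events, recordedDuration = recordedDuration,
      excludedIntervals = excludedIntervals,
      effectiveDuration = recordedDuration - .interval_total(excludedIntervals))
}

#' @rdname EventTable-class
#' @param object an `EventTable`.
#' @export
setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable: %d events over %.1f s effective (%.1f s recorded, %d excluded interval(s))\n",
              nrow(object@events), object@effectiveDuration,
              object@recordedDuration, NROW(object@excludedIntervals)))
  invisible(NULL)
})

#' @rdname EventTable-class
#' @param x an `EventTable`.
#' @export
events <- function(x) x@events

#' @rdname EventTable-class
#' @export
effectiveDuration <- function(x) x@effectiveDuration

#' @rdname EventTable-class
#' @export
excludedIntervals <- function(x) x@excludedIntervals

#' Event table straight from a simulated event stream
#'
#' Event-level shortcut past trace rendering and detection: wraps the
#' injected events of [simulateEvents()] as an [EventTable-class], with the
#' simulator's clog intervals as excluded intervals.
#'
#' @param evdf data.frame from [simulateEvents()].
#' @param spec the [SimSpec-class] that generated it.
#' @param poreId pore label.
#' @export
asEventTable <- function(evdf, spec, poreId = "pore1") {
  ev <- data.frame(pore_id = rep(poreId, nrow(evdf)),
                   chunk_id = NA_character_,
                   start_time = evdf$time, dwell = evdf$dwell,
                   amplitude = evdf$amplitude,
                   species = evdf$species,
                   stringsAsFactors = FALSE)
  eventTable(ev, recordedDuration = spec@duration,
             excludedIntervals = spec@clogIntervals)
}

## Sub-baseline excursions with hysteresis: a region is the maximal run of
## samples below (baseline - close_k * noiseSd) that contains at least one
## sample below (baseline - open_k * noiseSd). Returns start/end sample
## indices (the event opens at the first open-threshold crossing).
.find_excursions <- function(x, baseline, noiseSd, open_k, close_k = 1) {
  below_close <- x < baseline - close_k * noiseSd
  r <- rle(below_close)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  open_thr <- baseline - open_k * noiseSd
  out_start <- integer(0); out_end <- integer(0)
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    deep <- idx[x[idx] < open_thr[idx]]
    if (length(deep)) {
      out_start <- c(out_start, deep[1L])
      out_end <- c(out_end, ends[i])
    }
  }
  cbind(start = out_start, end = out_end)
}

#' Detect translocation events in a current trace
#'
#' Hysteresis threshold detector: an event opens when the current drops
#' below `baseline - kSigma * noiseSd` and closes when it returns above
#' `baseline - noiseSd`. The amplitude is baseline minus the minimum current
#' inside the event (robust for short, filter-attenuated pulses). Excursions
#' longer than `maxBlockDuration` are reclassified as clogs: they become
#' excluded intervals subtracted from the effective duration rather than
#' events. Events shorter than `minDwell` are discarded.
#'
#' @param trace an [IonTrace-class].
#' @param baseline a [BaselineModel-class] fitted on this trace.
#' @param kSigma opening threshold in noise sigmas (default 5).
#' @param minDwell minimum dwell, s; default 1e-4 s, about two filter-limited
#'   rise times at a 5 kHz cutoff.
#' @param maxBlockDuration excursions longer than this (s) are clogs.
#' @return An [EventTable-class], sorted by start time.
#' @export
detectEvents <- function(trace, baseline, kSigma = 5, minDwell = 1e-4,
                         maxBlockDuration = 1) {
  x <- trace@samples
  fs <- trace@samplingRate
  b <- baseline@baseline
  s <- baseline@noiseSd
  exc <- .find_excursions(x, b, s, kSigma)
  starts_t <- (exc[, 1] - 1L) / fs
  dwells <- (exc[, 2] - exc[, 1] + 1L) / fs
  is_clog <- dwells > maxBlockDuration
  excl <- if (any(is_clog)) {
    cbind(start = starts_t[is_clog], end = starts_t[is_clog] + dwells[is_clog])
  } else .empty_intervals()
  keep <- !is_clog & dwells >= minDwell
  amp <- numeric(sum(keep))
  ki <- which(keep)
  for (j in seq_along(ki)) {
    idx <- exc[ki[j], 1]:exc[ki[j], 2]
    imin <- idx[which.min(x[idx])]
    amp[j] <- b[imin] - x[imin]
  }
  ev <- data.frame(pore_id = rep(trace@poreId, sum(keep)),
                   chunk_id = rep(NA_character_, sum(keep)),
                   start_time = starts_t[keep], dwell = dwells[keep],
                   amplitude = amp, stringsAsFactors = FALSE)
  inside <- .in_intervals(ev$start_time, excl)
  ev <- ev[!inside, , drop = FALSE]
  ev <- ev[order(ev$start_time), , drop = FALSE]
  rownames(ev) <- NULL
  eventTable(ev, recordedDuration = length(x) / fs,
             excludedIntervals = excl)
}

#' Flag clogged intervals in a trace
#'
#' Any continuous sub-baseline excursion longer than `maxBlockDuration` is
#' treated as a pore clog rather than a translocation and returned as an
#' excluded interval; its length is later subtracted from the effective
#' recording duration so event frequencies stay unbiased.
#'
#' @inheritParams detectEvents
#' @return Two-column matrix of (start, end) excluded intervals, seconds.
#' @export
flagClogs <- function(trace, baseline, maxBlockDuration = 1) {
  x <- trace@samples
  fs <- trace@samplingRate
  exc <- .find_excursions(x, baseline@baseline, baseline@noiseSd, open_k = 5)
  dwells <- (exc[, 2] - exc[, 1] + 1L) / fs
  long <- dwells > maxBlockDuration
  if (!any(long)) return(.empty_intervals())
  st <- (exc[long, 1] - 1L) / fs
  cbind(start = st, end = st + dwells[long])
}

#' Event frequency over the effective duration
#'
#' `count / effectiveDuration`: using frequencies over the unclogged
#' (effective) duration instead of raw counts compensates for data lost to
#' timed pore clogging.
#'
#' @param table an [EventTable-class].
#' @param subset optional logical vector (length = number of events) or a
#'   species label selecting the events to count; all events by default.
#' @return Events per second.
#' @export
eventFrequency <- function(table, subset = NULL) {
  if (table@effectiveDuration <= 0) {
    stop("undefined frequency: effective duration is zero")
  }
  n <- if (is.null(subset)) {
    nrow(table@events)
  } else if (is.character(subset)) {
    sum(table@events$species == subset)
  } else {
    sum(subset)
  }
  n / table@effectiveDuration
}
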