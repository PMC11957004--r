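#' @include pipeline.R
NULL

#' Measurement-uncertainty grid over pores and acquisition time
#'
#' Holds the coefficient-of-variation matrices of the two QC metrics over a
#' grid of (number of pooled pores) x (acquisition duration) combinations —
#' the uncertainty-tuning experiment: pooling more pores or recording longer
#' accumulates events and shrinks the CV.
#'
#' @slot poreCounts integer vector of pooled-pore counts.
#' @slot durations numeric vector of acquisition durations, minutes.
#' @slot cvConcentration matrix (%), pores x durations, CV of the recovered
#'   target concentration; NA where a cell failed.
#' @slot cvPercent matrix (%), CV of percent-target.
#' @slot nReplicates replicates per cell.
#' @export
setClass("PoolingGrid",
  representation(
    poreCounts = "integer",
    durations = "numeric",
    cvConcentration = "matrix",
    cvPercent = "matrix",
    nReplicates = "integer"
  )
)

setValidity("PoolingGrid", function(object) {
  dm <- c(length(object@poreCounts), length(object@durations))
  if (!identical(dim(object@cvConcentration), dm) ||
      !identical(dim(object@cvPercent), dm)) {
    return("CV matrix dimensions must match poreCounts x durations")
  }
  vals <- c(object@cvConcentration, object@cvPercent)
  if (any(vals[is.finite(vals)] < 0)) return("CV values must be >= 0")
  TRUE
})

#' @export
setMethod("show", "PoolingGrid", function(object) {
  cat(sprintf("PoolingGrid: %d pore counts x %d durations (n = %d replicates)\n",
              length(object@poreCounts), length(object@durations),
              object@nReplicates))
  cat("CV of target concentration (%):\n")
  print(round(object@cvConcentration, 2))
  cat("CV of percent-target (%):\n")
  print(round(object@cvPercent, 2))
  invisible(NULL)
})

#' @rdname PoolingGrid-class
#' @param x a `PoolingGrid`.
#' @export
cvConcentration <- function(x) x@cvConcentration

#' @rdname PoolingGrid-class
#' @export
cvPercent <- function(x) x@cvPercent

#' Partition per-pore recordings into fixed-length chunks
#'
#' Splits each pore's event table into consecutive `chunkLength`-minute
#' chunks by start time (half-open intervals: an event exactly on a
#' boundary goes to the later chunk). Each chunk carries its own effective
#' duration (chunk length minus any excluded time overlapping it).
#'
#' @param tables list of per-pore [EventTable-class] objects (named by pore
#'   or in pore order).
#' @param chunkLength chunk length, minutes.
#' @return A chunked store: a list with `chunkLength` (min) and `pores`, a
#'   list (one entry per pore) of lists of per-chunk [EventTable-class]
#'   objects.
#' @export
chunkEvents <- function(tables, chunkLength = 5) {
  chunk_s <- chunkLength * 60
  pores <- lapply(seq_along(tables), function(p) {
    tab <- tables[[p]]
    if (tab@recordedDuration < chunk_s) {
      stop("chunk length (", chunkLength, " min) exceeds the recording of pore ", p)
    }
    nchunk <- floor(tab@recordedDuration / chunk_s)
    ev <- tab@events
    idx <- floor(ev$start_time / chunk_s) + 1L  # half-open: boundary -> later chunk
    lapply(seq_len(nchunk), function(ci) {
      evc <- ev[idx == ci, , drop = FALSE]
      lo <- (ci - 1L) * chunk_s
      evc$start_time <- evc$start_time - lo
      evc$chunk_id <- rep(sprintf("p%d_c%d", p, ci), nrow(evc))
      excl <- tab@excludedIntervals
      if (NROW(excl)) {
        s <- pmax(excl[, 1], lo) - lo
        e <- pmin(excl[, 2], lo + chunk_s) - lo
        keep <- e > s
        excl <- cbind(start = s[keep], end = e[keep])
      }
      rownames(evc) <- NULL
      eventTable(evc, recordedDuration = chunk_s, excludedIntervals = excl)
    })
  })
  names(pores) <- if (!is.null(names(tables))) names(tables) else
    paste0("pore", seq_along(tables))
  list(chunkLength = chunkLength, pores = pores)
}

#' Assemble pooled replicate measurements from a chunked store
#'
#' Builds `nReplicates` disjoint pooled event tables for one (pores,
#' duration) combination: replicate r takes the r-th block of
#' `duration / chunkLength` consecutive unused chunks from each of the
#' first `nPores` pores (mirroring n independent physical measurements);
#' with `shuffle = TRUE` the chunk order is first permuted per pore under
#' `seed`. Pooled effective duration is the sum over all contributing
#' chunks.
#'
#' @param store chunked store from [chunkEvents()].
#' @param nPores number of pores to pool.
#' @param duration acquisition duration per pore, minutes (a multiple of the
#'   chunk length).
#' @param nReplicates number of disjoint replicates.
#' @param seed seed for the optional shuffle.
#' @param shuffle permute chunk order before blocking (sensitivity mode).
#' @return List of pooled [EventTable-class] objects, length `nReplicates`.
#' @export
assembleReplicates <- function(store, nPores, duration, nReplicates = 3L,
                               seed = 1L, shuffle = FALSE) {
  if (nPores > length(store$pores)) {
    stop("requested ", nPores, " pores but the store holds ", length(store$pores))
  }
  m <- duration / store$chunkLength
  if (abs(m - round(m)) > 1e-9) {
    stop("duration must be a multiple of the chunk length")
  }
  m <- as.integer(round(m))
  navail <- min(vapply(store$pores[seq_len(nPores)], length, integer(1)))
  if (nReplicates * m > navail) {
    stop("insufficient chunks for ", nReplicates, " replicates of (",
         nPores, " pores, ", duration, " min): need ", nReplicates * m,
         " chunks/pore, have ", navail)
  }
  orders <- lapply(seq_len(nPores), function(p) {
    if (shuffle) with_seed(seed + p, sample.int(navail)) else seq_len(navail)
  })
  lapply(seq_len(nReplicates), function(r) {
    take <- ((r - 1L) * m + 1L):(r * m)
    chunks <- unlist(lapply(seq_len(nPores), function(p) {
      store$pores[[p]][orders[[p]][take]]
    }), recursive = FALSE)
    ev <- do.call(rbind, lapply(chunks, function(ch) ch@events))
    eff <- sum(vapply(chunks, function(ch) ch@effectiveDuration, numeric(1)))
    rownames(ev) <- NULL
    eventTable(ev, recordedDuration = eff)  # pooled time axis: no exclusions left
  })
}

#' Coefficient-of-variation grid over pore/duration combinations
#'
#' For every combination of pooled-pore count and acquisition duration,
#' assembles replicate pooled measurements, runs the mixture-fit and
#' quantification pipeline on each, and reports `CV = 100 * sd / mean` over
#' replicates for both QC metrics. A cell whose replicates cannot be
#' analysed (fit failure, chunk shortage) is marked NA rather than aborting
#' the grid.
#'
#' @param store chunked store from [chunkEvents()].
#' @param poreCounts integer vector, e.g. `1:4`.
#' @param durations numeric vector of minutes, e.g. `seq(5, 30, 5)`.
#' @param nReplicates replicates per cell (default 3).
#' @param cMarker marker concentration, pM.
#' @param markerAmplitudeHint,KMax,nInit,seed,fixK analysis controls
#'   (see [analyzeEvents()]).
#' @param shuffle passed to [assembleReplicates()].
#' @return A [PoolingGrid-class].
#' @export
cvGrid <- function(store, poreCounts = 1:4, durations = seq(5, 30, by = 5),
                   nReplicates = 3L, cMarker = 100,
                   markerAmplitudeHint = NULL, KMax = 4L, nInit = 10L,
                   seed = 1L, fixK = NULL, shuffle = FALSE) {
  cvc <- matrix(NA_real_, length(poreCounts), length(durations),
                dimnames = list(paste0(poreCounts, "p"), paste0(durations, "min")))
  cvp <- cvc
  for (i in seq_along(poreCounts)) {
    for (j in seq_along(durations)) {
      res <- tryCatch({
        reps <- assembleReplicates(store, poreCounts[i], durations[j],
                                   nReplicates = nReplicates, seed = seed,
                                   shuffle = shuffle)
        vals <- vapply(reps, function(tab) {
          qc <- analyzeEvents(tab, cMarker = cMarker,
                              markerAmplitudeHint = markerAmplitudeHint,
                              KMax = KMax, nInit = nInit, seed = seed,
                              fixK = fixK)
          c(qc@cTarget, qc@percentTarget)
        }, numeric(2))
        c(100 * sd(vals[1, ]) / mean(vals[1, ]),
          100 * sd(vals[2, ]) / mean(vals[2, ]))
      }, error = function(e) c(NA_real_, NA_real_))
      cvc[i, j] <- res[1]
      cvp[i, j] <- res[2]
    }
  }
  new("PoolingGrid", poreCounts = as.integer(poreCounts),
      durations = as.numeric(durations), cvConcentration = cvc,
      cvPercent = cvp, nReplicates = as.integer(nReplicates))
}

#' Long-format view of a pooling grid
#'
#' @param grid a [PoolingGrid-class].
#' @return data.frame with columns `pores`, `minutes`, `metric`,
#'   `cv_percent`.
#' @export
gridAsLong <- function(grid) {
  g <- expand.grid(pores = grid@poreCounts, minutes = grid@durations)
  rbind(
    data.frame(g, metric = "concentration",
               cv_percent = as.vector(grid@cvConcentration)),
    data.frame(g, metric = "percent_target",
               cv_percent = as.vector(grid@cvPercent))
  )
}
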