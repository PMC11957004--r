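#' @include quantify.R
NULL

#' Gaussian mixture fit over blockage amplitudes
#'
#' Result of the multi-Gaussian decomposition of a blockage-amplitude
#' sample. Each component carries a *soft count* — the sum of its posterior
#' membership probabilities (responsibilities) over all events, i.e. the
#' area of that Gaussian in event units. Soft counts divided by the
#' effective recording duration give the per-species event frequencies that
#' feed the QC metrics.
#'
#' @slot components data.frame with columns `label`, `weight`, `mean` (pA),
#'   `sd` (pA), `soft_count`; rows ordered by mean.
#' @slot nComponents integer K.
#' @slot logLik,bic fit quality; `BIC = -2 logLik + (3K - 1) log n`.
#' @slot converged logical.
#' @slot responsibilities n x K posterior membership matrix.
#' @slot n number of events fitted.
#' @export
setClass("MixtureFit",
  representation(
    components = "data.frame",
    nComponents = "integer",
    logLik = "numeric",
    bic = "numeric",
    converged = "logical",
    responsibilities = "matrix",
    n = "integer"
  )
)

setValidity("MixtureFit", function(object) {
  msg <- character()
  comp <- object@components
  if (abs(sum(comp$weight) - 1) > 1e-9) msg <- c(msg, "weights must sum to 1")
  if (any(comp$sd <= 0)) msg <- c(msg, "component sds must be positive")
  if (any(comp$soft_count < 0)) msg <- c(msg, "soft counts must be >= 0")
  if (abs(sum(comp$soft_count) - object@n) > 1e-6) {
    msg <- c(msg, "soft counts must sum to the number of events")
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit: K = %d, n = %d, logLik = %.2f, BIC = %.2f%s\n",
              object@nComponents, object@n, object@logLik, object@bic,
              if (object@converged) "" else " (not converged)"))
  print(object@components, digits = 4)
  invisible(NULL)
})

#' @rdname MixtureFit-class
#' @param x a `MixtureFit`.
#' @export
components <- function(x) x@components

#' @rdname MixtureFit-class
#' @export
softCounts <- function(x) setNames(x@components$soft_count, x@components$label)

## log-density matrix and per-point log-mixture density via log-sum-exp
.log_dens <- function(x, w, mu, sdv) {
  K <- length(w)
  ld <- matrix(0, length(x), K)
  for (k in seq_len(K)) {
    ld[, k] <- log(w[k]) + dnorm(x, mu[k], sdv[k], log = TRUE)
  }
  m <- ld[, 1L]
  if (K > 1L) for (k in 2:K) m <- pmax(m, ld[, k])
  list(ld = ld, lmix = m + log(rowSums(exp(ld - m))))
}

## k-means++-style seeding of K centres on a 1-D sample
.kmeanspp_centres <- function(x, K) {
  centres <- x[sample.int(length(x), 1L)]
  d2 <- (x - centres[1L])^2
  while (length(centres) < K) {
    nxt <- if (sum(d2) <= 0) {
      x[sample.int(length(x), 1L)]
    } else {
      x[sample.int(length(x), 1L, prob = d2)]
    }
    centres <- c(centres, nxt)
    d2 <- pmin(d2, (x - nxt)^2)
  }
  sort(centres)
}

.em_once <- function(x, K, tol = 1e-6, maxIter = 150L, sdFloor = 1e-3) {
  n <- length(x)
  mu <- .kmeanspp_centres(x, K)
  # nearest sorted centre via interval lookup on the midpoints
  assign0 <- if (K > 1L) findInterval(x, (mu[-1L] + mu[-K]) / 2) + 1L else
    rep(1L, n)
  sdv <- vapply(seq_len(K), function(k) {
    xs <- x[assign0 == k]
    s <- if (length(xs) > 1) sd(xs) else sd(x) / K
    max(s, sdFloor, sd(x) / (10 * K))
  }, numeric(1))
  w <- tabulate(assign0, K) / n
  w[w == 0] <- 1 / n
  w <- w / sum(w)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    e <- .log_dens(x, w, mu, sdv)
    ll <- sum(e$lmix)
    resp <- exp(e$ld - e$lmix)
    nk <- colSums(resp)
    if (any(nk <= 0)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sdv <- sqrt(colSums(resp * outer(x, mu, "-")^2) / nk)
    if (any(sdv < sdFloor)) return(NULL)  # degenerate: caller restarts
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  e <- .log_dens(x, w, mu, sdv)
  ll <- sum(e$lmix)
  resp <- exp(e$ld - e$lmix)
  list(w = w, mu = mu, sd = sdv, logLik = ll, resp = resp,
       converged = converged)
}

#' Fit a K-component Gaussian mixture to blockage amplitudes
#'
#' Expectation-maximisation on the raw (unbinned) 1-D amplitude sample with
#' `nInit` random restarts seeded k-means++-style; the restart with the
#' highest log-likelihood wins. Convergence when the log-likelihood gain
#' drops below `tol`. Restarts whose components collapse below the sd floor
#' (1e-3 pA) are discarded; if every restart collapses the fit fails.
#' Deterministic given `(amplitudes, K, seed)`.
#'
#' @param amplitudes numeric vector of blockage amplitudes, pA; needs at
#'   least `10 * K` events.
#' @param K number of Gaussian components.
#' @param seed RNG seed for the restarts.
#' @param nInit number of restarts (>= 10 by default).
#' @param tol log-likelihood convergence tolerance.
#' @return A [MixtureFit-class] with components ordered by mean and labels
#'   `"unassigned"` (see [labelComponents()]).
#' @export
fitMixture <- function(amplitudes, K, seed = 1L, nInit = 10L, tol = 1e-6) {
  x <- as.numeric(amplitudes)
  n <- length(x)
  if (n < 10L * K) stop("need at least 10*K events to fit K = ", K, " components")
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(nInit)) {
      fit <- .em_once(x, K, tol = tol)
      if (!is.null(fit) && (is.null(best) || fit$logLik > best$logLik)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) {
    stop("mixture fit failed: all ", nInit, " restarts collapsed to degenerate components")
  }
  o <- order(best$mu)
  resp <- best$resp[, o, drop = FALSE]
  comp <- data.frame(label = rep("unassigned", K),
                     weight = best$w[o], mean = best$mu[o], sd = best$sd[o],
                     soft_count = colSums(resp), stringsAsFactors = FALSE)
  p <- 3 * K - 1
  new("MixtureFit", components = comp, nComponents = as.integer(K),
      logLik = best$logLik, bic = -2 * best$logLik + p * log(n),
      converged = best$converged, responsibilities = resp, n = as.integer(n))
}

#' Choose the number of mixture components by BIC
#'
#' Fits `K = 1..KMax` and returns the fit with the smallest BIC (ties go to
#' the smaller K). A data-driven K matters because real cfDNA samples may
#' lack the gDNA population entirely, leaving only two amplitude
#' populations.
#'
#' @inheritParams fitMixture
#' @param KMax largest K to consider (default 4).
#' @return The BIC-optimal [MixtureFit-class].
#' @export
selectComponents <- function(amplitudes, KMax = 4L, seed = 1L, nInit = 10L) {
  fits <- list()
  errs <- character()
  for (K in seq_len(KMax)) {
    if (length(amplitudes) < 10L * K) break
    f <- tryCatch(fitMixture(amplitudes, K, seed = seed, nInit = nInit),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) errs <- c(errs, f) else fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) {
    stop("no mixture order could be fitted: ", paste(errs, collapse = "; "))
  }
  bics <- vapply(fits, function(f) f@bic, numeric(1))
  fits[[which.min(bics)]]  # which.min takes the first (smallest K) on ties
}

#' Assign species labels to mixture components
#'
#' Components are ordered by mean amplitude. With K = 3 the assignment is
#' positional: smallest mean is the target (shortest fragments block least),
#' then the 1 kbp marker, then HMW gDNA. With K < 3 the component nearest
#' `markerAmplitudeHint` becomes the marker, the remaining component is the
#' target if its mean is below the marker's (else gDNA), and absent roles
#' get soft count 0. With K > 3 the three components with the largest soft
#' counts take the three roles by mean order and the rest are labelled
#' `"unassigned"` with a warning.
#'
#' @param fit a converged [MixtureFit-class].
#' @param markerAmplitudeHint expected marker blockage amplitude, pA;
#'   required when K < 3.
#' @return The fit with `label` filled in.
#' @export
labelComponents <- function(fit, markerAmplitudeHint = NULL) {
  stopifnot(is(fit, "MixtureFit"))
  comp <- fit@components  # already ordered by mean
  K <- fit@nComponents
  lab <- rep("unassigned", K)
  if (K == 3L) {
    lab <- c("target", "marker", "gDNA")
  } else if (K < 3L) {
    if (is.null(markerAmplitudeHint)) {
      stop("K = ", K, " components: a markerAmplitudeHint (pA) is required ",
           "to identify the internal marker")
    }
    im <- which.min(abs(comp$mean - markerAmplitudeHint))
    lab[im] <- "marker"
    if (K == 2L) {
      io <- setdiff(1:2, im)
      lab[io] <- if (comp$mean[io] < comp$mean[im]) "target" else "gDNA"
    }
  } else {
    main <- sort(order(comp$soft_count, decreasing = TRUE)[1:3])
    lab[main] <- c("target", "marker", "gDNA")
    warning(K - 3L, " surplus mixture component(s) left unassigned")
  }
  comp$label <- lab
  fit@components <- comp
  fit
}

#' Per-species frequencies from a labelled mixture fit
#'
#' `f_s = softCount(s) / effectiveDuration` for each of target, marker and
#' gDNA; a role with no component contributes frequency 0. When K <= 3 and
#' nothing is unassigned, the frequencies conserve the event total:
#' `sum(f_s) * effectiveDuration = n`.
#'
#' @param fit a labelled [MixtureFit-class] (see [labelComponents()]).
#' @param table the [EventTable-class] the amplitudes came from.
#' @return A [FrequencySet-class].
#' @export
speciesFrequencies <- function(fit, table) {
  stopifnot(is(fit, "MixtureFit"), is(table, "EventTable"))
  if (all(fit@components$label == "unassigned")) {
    stop("mixture fit is unlabelled: call labelComponents() first")
  }
  if (table@effectiveDuration <= 0) {
    stop("undefined frequencies: effective duration is zero")
  }
  sc <- function(role) {
    sum(fit@components$soft_count[fit@components$label == role])
  }
  frequencySet(fTarget = sc("target") / table@effectiveDuration,
               fMarker = sc("marker") / table@effectiveDuration,
               fGdna = sc("gDNA") / table@effectiveDuration)
}
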