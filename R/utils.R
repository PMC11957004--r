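#' @import methods
#' @importFrom stats dnorm rnorm runif rpois rlnorm kmeans mad median runmed
#'   approx sd uniroot cor setNames quantile var
#' @importFrom utils head read.delim write.table tail
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards so seeded simulation calls do not
## perturb the global stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

## Half-open interval membership: is t in [start, end) for any row of
## `intervals` (2-column matrix)? Vectorised over t.
.in_intervals <- function(t, intervals) {
  if (is.null(intervals) || NROW(intervals) == 0L) {
    return(rep(FALSE, length(t)))
  }
  hit <- rep(FALSE, length(t))
  for (i in seq_len(NROW(intervals))) {
    hit <- hit | (t >= intervals[i, 1] & t < intervals[i, 2])
  }
  hit
}

.interval_total <- function(intervals) {
  if (is.null(intervals) || NROW(intervals) == 0L) return(0)
  sum(intervals[, 2] - intervals[, 1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.empty_intervals <- function() {
  matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}
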