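# Shared fixtures: everything is generated in code at test time.

# Small reference geometry: 10 nm tip, 5 degree half-cone, sigma = 20 S/m
# (a plausible high-salt value; tests never depend on its physical truth).
fix_geom <- function(d = 10, sigma = 20) {
  poreGeometry(tipDiameter = d, bufferConductivity = sigma, halfConeAngle = 5)
}

# Standard 120/100/100 pM mock at desk scale.
fix_mock_spec <- function(duration = 1800, seed = 1L, d_tip = 10,
                          clogs = .nanoporeQC_empty()) {
  simSpec(species = defaultSpeciesPanel(120, 100, 100),
          pore = fix_geom(d_tip), referenceDiameter = 10,
          duration = duration, seed = seed, clogIntervals = clogs)
}

.nanoporeQC_empty <- function() matrix(numeric(0), ncol = 2)

# Draw a labelled 3-component Gaussian sample with known truth.
fix_three_comp <- function(n = 9000, seed = 1,
                           means = c(60, 160, 380), sds = c(6, 14, 32),
                           weights = c(0.48, 0.26, 0.26)) {
  set.seed(seed)
  k <- sample.int(3, n, replace = TRUE, prob = weights)
  list(x = rnorm(n, means[k], sds[k]), k = k,
       means = means, sds = sds, weights = weights)
}

# Noiseless rectangular-pulse trace with known events; returns the trace and
# the injected truth (start index, width in samples, depth).
fix_rect_trace <- function(n_events = 50, fs = 1e4, open = 5000,
                           depth = 100, width = 20L, gap = 150L,
                           widths = NULL) {
  if (is.null(widths)) widths <- rep(width, n_events)
  n <- gap * (n_events + 2L)
  x <- rep(open, n)
  starts <- gap * seq_len(n_events)
  depths <- depth + seq_len(n_events)  # distinct depths aid amplitude checks
  for (i in seq_len(n_events)) {
    x[starts[i]:(starts[i] + widths[i] - 1L)] <- open - depths[i]
  }
  list(trace = ionTrace(x, fs), starts = starts, widths = widths,
       depths = depths, fs = fs)
}
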