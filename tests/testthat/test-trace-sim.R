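test_that("simulation is deterministic given the seed", {
  s1 <- fix_mock_spec(duration = 60, seed = 11)
  s2 <- fix_mock_spec(duration = 60, seed = 11)
  e1 <- simulateEvents(s1); e2 <- simulateEvents(s2)
  expect_identical(e1, e2)
  t1 <- renderTrace(s1, e1); t2 <- renderTrace(s2, e2)
  expect_identical(traceSamples(t1), traceSamples(t2))
  e3 <- simulateEvents(fix_mock_spec(duration = 60, seed = 12))
  expect_false(identical(e1, e3))
})

test_that("zero concentrations give an empty event list", {
  sp <- defaultSpeciesPanel(0, 0, 0)
  ev <- simulateEvents(simSpec(species = sp, duration = 100, seed = 1))
  expect_equal(nrow(ev), 0L)
})

test_that("per-species event counts follow the concentration-proportional Poisson rates", {
  # lambda_i = 0.02 * c_i: expected 4320 / 3600 / 3600 over 1800 s
  ev <- simulateEvents(fix_mock_spec(duration = 1800, seed = 3))
  counts <- table(ev$species)
  expected <- c(gDNA = 3600, marker = 3600, target = 4320)
  for (nm in names(expected)) {
    expect_lt(abs(counts[[nm]] - expected[[nm]]), 4 * sqrt(expected[[nm]]))
  }
})

test_that("equal concentrations give near-equal capture rates (length independence)", {
  ev <- simulateEvents(fix_mock_spec(duration = 5000, seed = 5))
  # marker (1 kbp) and gDNA (10 kbp) share 100 pM: lambda*T = 1e4 each
  r <- sum(ev$species == "marker") / sum(ev$species == "gDNA")
  expect_lt(abs(r - 1), 0.06)
})

test_that("events are thinned inside clog intervals", {
  clogs <- rbind(c(100, 160), c(400, 430))
  ev <- simulateEvents(fix_mock_spec(duration = 600, seed = 9, clogs = clogs))
  inside <- (ev$time >= 100 & ev$time < 160) | (ev$time >= 400 & ev$time < 430)
  expect_equal(sum(inside), 0L)
})

test_that("a zero-event zero-noise trace is constant at the open-pore current", {
  spec <- simSpec(species = defaultSpeciesPanel(0, 0, 0), duration = 0.5,
                  samplingRate = 2e4, noiseSd = 0, seed = 1)
  tr <- renderTrace(spec, simulateEvents(spec))
  expect_equal(range(traceSamples(tr)), c(5000, 5000), tolerance = 1e-9)
})

test_that("a long pulse passes the filter at full depth; a short pulse is attenuated", {
  base <- simSpec(species = defaultSpeciesPanel(0, 0, 0), duration = 0.2,
                  samplingRate = 1e5, filterCutoff = 5e3, noiseSd = 0, seed = 1)
  long_ev <- data.frame(time = 0.05, species = "target",
                        amplitude = 200, dwell = 0.02)  # 20 ms >> rise time
  tr <- renderTrace(base, long_ev)
  expect_lt(abs((5000 - min(traceSamples(tr))) - 200) / 200, 0.01)
  short_ev <- data.frame(time = 0.05, species = "target",
                         amplitude = 200, dwell = 2e-5)  # 20 us << rise time
  tr2 <- renderTrace(base, short_ev)
  depth <- 5000 - min(traceSamples(tr2))
  expect_lt(depth, 200)
  expect_gt(depth, 0)
})

test_that("the rendered trace matches a brute-force discrete convolution oracle", {
  spec <- simSpec(species = defaultSpeciesPanel(0, 0, 0), duration = 0.05,
                  samplingRate = 5e4, filterCutoff = 5e3, noiseSd = 0, seed = 1)
  ev <- data.frame(time = 0.01, species = "target", amplitude = 150,
                   dwell = 3e-4)
  tr <- renderTrace(spec, ev)
  # oracle: rebuild the pulse train and convolve with a unit-area Gaussian
  # kernel (-3 dB at the cutoff) by an explicit double loop
  fs <- 5e4; fc <- 5e3
  n <- round(0.05 * fs)
  dev <- numeric(n)
  i0 <- floor(0.01 * fs) + 1L
  i1 <- ceiling((0.01 + 3e-4) * fs)
  dev[i0:i1] <- -150
  sigma <- sqrt(log(2)) / (2 * pi * fc) * fs
  half <- ceiling(4 * sigma)
  kern <- exp(-((-half:half)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  y <- numeric(n)
  for (t in seq_len(n)) {
    for (j in -half:half) {
      src <- t + j
      if (src >= 1 && src <= n) y[t] <- y[t] + kern[j + half + 1] * dev[src]
    }
  }
  expect_equal(traceSamples(tr), 5000 + y, tolerance = 1e-10)
})

test_that("empirical rates converge to the Poisson intensities over seeds", {
  # lambda*T = 3600 for the marker; average over 10 seeds, relative error < 2%
  counts <- vapply(1:10, function(s) {
    ev <- simulateEvents(fix_mock_spec(duration = 1800, seed = s))
    sum(ev$species == "marker")
  }, numeric(1))
  expect_lt(abs(mean(counts) - 3600) / 3600, 0.02)
})

test_that("event-level and trace-level paths agree on frequency for long dwells", {
  sp <- speciesSpec("marker", 1000, 400, amplitudeMean = 200, amplitudeSd = 10,
                    dwellLogMean = log(2e-3), dwellLogSd = 0.1)
  spec <- simSpec(species = sp, duration = 30, samplingRate = 2e4,
                  filterCutoff = 4e3, noiseSd = 5, seed = 21)
  ev <- simulateEvents(spec)
  f_event <- nrow(ev) / spec@duration
  tr <- renderTrace(spec, ev)
  tab <- detectEvents(tr, estimateBaseline(tr, 801), kSigma = 5)
  f_trace <- eventFrequency(tab)
  expect_lt(abs(f_trace - f_event) / f_event, 0.05)
})
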