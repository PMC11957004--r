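test_that("a single-Normal sample is recovered within 3 standard errors", {
  set.seed(1)
  x <- rnorm(2000, 150, 12)
  fit <- fitMixture(x, 1, seed = 1)
  comp <- components(fit)
  expect_lt(abs(comp$mean - 150), 3 * 12 / sqrt(2000))
  expect_lt(abs(comp$sd - 12), 3 * 12 / sqrt(2 * 2000))
  expect_equal(comp$weight, 1)
})

test_that("well-separated components recover their soft counts within 5%", {
  fx <- fix_three_comp(n = 9000, seed = 2)
  fit <- fitMixture(fx$x, 3, seed = 1)
  sc <- components(fit)$soft_count
  truth <- as.numeric(table(fx$k))
  expect_true(all(abs(sc - truth) / truth < 0.05))
})

test_that("fitting is bit-for-bit deterministic given data, K and seed", {
  fx <- fix_three_comp(n = 3000, seed = 3)
  f1 <- fitMixture(fx$x, 3, seed = 99)
  f2 <- fitMixture(fx$x, 3, seed = 99)
  expect_identical(components(f1), components(f2))
  expect_identical(f1@logLik, f2@logLik)
})

test_that("soft counts are conserved and weights sum to one", {
  fx <- fix_three_comp(n = 4000, seed = 4)
  for (K in 1:4) {
    fit <- fitMixture(fx$x, K, seed = 5)
    expect_lt(abs(sum(components(fit)$soft_count) - 4000), 1e-6)
    expect_lt(abs(sum(components(fit)$weight) - 1), 1e-9)
    p <- 3 * K - 1
    expect_equal(fit@bic, -2 * fit@logLik + p * log(4000), tolerance = 1e-12)
  }
})

test_that("BIC order selection finds the true number of populations", {
  set.seed(6)
  one <- rnorm(1500, 100, 10)
  expect_equal(selectComponents(one, KMax = 4, seed = 1)@nComponents, 1L)
  fx <- fix_three_comp(n = 6000, seed = 7)
  expect_equal(selectComponents(fx$x, KMax = 4, seed = 1)@nComponents, 3L)
  # plasma-like: target + marker only, no gDNA
  set.seed(8)
  two <- c(rnorm(2000, 60, 6), rnorm(1500, 160, 14))
  fit2 <- selectComponents(two, KMax = 4, seed = 1)
  expect_equal(fit2@nComponents, 2L)
})

test_that("component labelling follows amplitude order and marker hints", {
  fx <- fix_three_comp(n = 3000, seed = 9, means = c(40, 120, 300),
                       sds = c(5, 10, 25))
  fit <- labelComponents(fitMixture(fx$x, 3, seed = 1))
  expect_equal(components(fit)$label, c("target", "marker", "gDNA"))

  set.seed(10)
  two <- c(rnorm(1500, 40, 5), rnorm(1200, 118, 10))
  f2 <- labelComponents(fitMixture(two, 2, seed = 1), markerAmplitudeHint = 120)
  expect_equal(components(f2)$label, c("target", "marker"))

  one <- fitMixture(rnorm(500, 100, 8), 1, seed = 1)
  expect_error(labelComponents(one), "[Hh]int")
  f1 <- labelComponents(one, markerAmplitudeHint = 100)
  expect_equal(components(f1)$label, "marker")

  f4 <- fitMixture(fx$x, 4, seed = 1)
  expect_warning(l4 <- labelComponents(f4), "unassigned")
  expect_equal(sum(components(l4)$label == "unassigned"), 1L)
})

test_that("species frequencies divide soft counts by the effective duration", {
  fx <- fix_three_comp(n = 9000, seed = 11)
  tab <- eventTable(data.frame(pore_id = "p", chunk_id = NA_character_,
                               start_time = seq_len(9000) * 0.1,
                               dwell = 1e-3, amplitude = fx$x),
                    recordedDuration = 1800)
  fit <- labelComponents(fitMixture(fx$x, 3, seed = 1))
  fr <- speciesFrequencies(fit, tab)
  sc <- softCounts(fit)
  expect_equal(fr@fTarget, sc[["target"]] / 1800)
  expect_equal(fr@fMarker, sc[["marker"]] / 1800)
  # conservation of the event total
  expect_lt(abs((fr@fTarget + fr@fMarker + fr@fGdna) * 1800 - 9000), 1e-6)
  # unlabelled fit is refused
  expect_error(speciesFrequencies(fitMixture(fx$x, 3, seed = 1), tab),
               "unlabelled")
  # two-component plasma-like fit: gDNA frequency is zero
  set.seed(12)
  two <- c(rnorm(2000, 60, 6), rnorm(1500, 160, 14))
  f2 <- labelComponents(fitMixture(two, 2, seed = 1), markerAmplitudeHint = 160)
  tab2 <- eventTable(data.frame(pore_id = "p", chunk_id = NA_character_,
                                start_time = seq_len(3500) * 0.1,
                                dwell = 1e-3, amplitude = two),
                     recordedDuration = 1800)
  fr2 <- speciesFrequencies(f2, tab2)
  expect_equal(fr2@fGdna, 0)
})

test_that("means and weights are recovered across seeds on separable mixtures", {
  # separation >= 4 sd, n = 3000; errors averaged over 20 seeds
  mean_err <- matrix(NA_real_, 20, 3)
  weight_err <- matrix(NA_real_, 20, 3)
  for (s in 1:20) {
    fx <- fix_three_comp(n = 3000, seed = 100 + s)
    comp <- components(fitMixture(fx$x, 3, seed = s))
    mean_err[s, ] <- abs(comp$mean - fx$means) / fx$means
    weight_err[s, ] <- abs(comp$weight - fx$weights)
  }
  expect_true(all(colMeans(mean_err) < 0.02))
  expect_true(all(colMeans(weight_err) < 0.03))
})

test_that("BIC picks the true order in at least 95% of seeds on the separable fixture", {
  hits <- vapply(1:20, function(s) {
    fx <- fix_three_comp(n = 3000, seed = 200 + s)
    selectComponents(fx$x, KMax = 4, seed = s)@nComponents == 3L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  fx <- fix_three_comp(n = 5000, seed = 13)
  ours <- components(fitMixture(fx$x, 3, seed = 1))
  mc <- Mclust(fx$x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(ours$mean, as.numeric(mc$parameters$mean), tolerance = 0.01)
  expect_equal(ours$weight, as.numeric(mc$parameters$pro), tolerance = 0.02)
})

test_that("degenerate and undersized fits fail loudly", {
  expect_error(fitMixture(rnorm(15), 2, seed = 1), "at least 10")
  expect_error(fitMixture(rep(100, 200), 2, seed = 1), "degenerate")
})
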