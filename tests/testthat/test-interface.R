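test_that("run configurations round-trip losslessly through YAML", {
  cfg <- runConfig(marker_concentration_pM = 100,
                   buffer_conductivity_S_m = 20,
                   detection = list(k_sigma = 6),
                   plasma = list(dilution_factor = 40, elution_volume_uL = 55,
                                 plasma_volume_mL = 1))
  path <- withr::local_tempfile(fileext = ".yaml")
  writeRunConfig(cfg, path)
  back <- readRunConfig(path)
  expect_equal(unclass(back), unclass(cfg))
  expect_equal(back$detection$k_sigma, 6)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(runConfig(marker_concentration_pM = -1),
               "marker_concentration_pM")
  expect_error(runConfig(detection = list(k_sigma = 0)), "k_sigma")
  expect_error(runConfig(simulator = list(duration_s = 0)), "duration_s")
})

test_that("traces round-trip through the delimited-text container", {
  tr <- ionTrace(5000 + sin(seq(0, 10, length.out = 500)), 2e4,
                 biasVoltage = 300, poreId = "npA")
  path <- withr::local_tempfile(fileext = ".txt")
  writeIonTrace(tr, path)
  back <- readIonTrace(path)
  expect_equal(traceSamples(back), traceSamples(tr), tolerance = 1e-5)
  expect_equal(samplingRate(back), 2e4)
  expect_equal(back@poreId, "npA")
  expect_equal(back@biasVoltage, 300)
})

test_that("event tables round-trip including excluded intervals", {
  spec <- fix_mock_spec(duration = 120, seed = 4,
                        clogs = rbind(c(10, 25)))
  tab <- asEventTable(simulateEvents(spec), spec, poreId = "npB")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEventTable(tab, path)
  back <- readEventTable(path)
  expect_equal(nrow(events(back)), nrow(events(tab)))
  expect_equal(events(back)$amplitude, events(tab)$amplitude, tolerance = 1e-6)
  expect_equal(effectiveDuration(back), 105)
  expect_equal(as.numeric(excludedIntervals(back)), c(10, 25))
})

test_that("the end-to-end trace pipeline recovers the mock composition", {
  spec <- fix_mock_spec(duration = 90, seed = 8)
  spec@samplingRate <- 2e4
  ev <- simulateEvents(spec)
  tr <- renderTrace(spec, ev)
  rep <- runQC(tr, cMarker = 100, fixK = 3, window = 501)
  expect_s4_class(rep, "QCReport")
  # ~580 events: loose statistical bounds on the 120 pM / 54.5% truth
  expect_gt(cTarget(rep), 70)
  expect_lt(cTarget(rep), 180)
  expect_gt(percentTarget(rep), 38)
  expect_lt(percentTarget(rep), 72)
  tab <- attr(rep, "events")
  expect_s4_class(tab, "EventTable")
  expect_gt(nrow(events(tab)), 0.8 * nrow(ev))
})

test_that("reports and fit summaries are written to disk", {
  spec <- fix_mock_spec(duration = 600, seed = 15)
  tab <- asEventTable(simulateEvents(spec), spec)
  rep <- analyzeEvents(tab, cMarker = 100, fixK = 3)
  y <- withr::local_tempfile(fileext = ".yaml")
  writeQCReport(rep, y, config = runConfig())
  out <- yaml::read_yaml(y)
  expect_equal(out$c_target_pM, cTarget(rep), tolerance = 1e-9)
  expect_equal(out$provenance$package, "nanoporeQC")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeMixtureSummary(attr(rep, "fit"), effectiveDuration(tab), tsv)
  comp <- read.delim(tsv)
  expect_equal(nrow(comp), 3L)
  expect_true(all(c("label", "soft_count", "frequency_per_s") %in% names(comp)))
})

test_that("the command-line wrapper simulates and analyses end to end", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "nanoporeqc.R", package = "nanoporeQC")
  dir <- withr::local_tempdir()
  cfgp <- file.path(dir, "cfg.yaml")
  writeRunConfig(runConfig(buffer_conductivity_S_m = 20,
                           simulator = list(duration_s = 120,
                                            sampling_rate_Hz = 5e3,
                                            filter_cutoff_Hz = 2e3)), cfgp)
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  out1 <- system2("Rscript", c(cli, "simulate", "--config", cfgp,
                               "--out-prefix", file.path(dir, "run"),
                               "--seed", "3"),
                  env = env, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "run_truth.tsv")))
  out2 <- system2("Rscript", c(cli, "qc", "--config", cfgp,
                               "--events", file.path(dir, "run_truth.tsv"),
                               "--out", file.path(dir, "report.yaml")),
                  env = env, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "report.yaml")))
  rep <- yaml::read_yaml(file.path(dir, "report.yaml"))
  expect_gt(rep$c_target_pM, 70)
  expect_lt(rep$c_target_pM, 180)
})
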