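#' @include uncertainty.R
NULL

#' Build a run configuration
#'
#' A validated named list of every knob the assay uses: marker and species
#' bookkeeping, detection parameters, mixture-fit controls, pore geometry
#' and buffer conductivity, optional simulator settings and the
#' dilution/elution parameters for the plasma back-calculation. The
#' configuration round-trips losslessly through YAML
#' ([writeRunConfig()] / [readRunConfig()]).
#'
#' @param ... overrides of the defaults listed below.
#' @return A list of class `"nanoporeQC_config"`.
#' @examples
#' cfg <- runConfig(marker_concentration_pM = 100, buffer_conductivity_S_m = 20)
#' cfg$detection$k_sigma
#' @export
runConfig <- function(...) {
  cfg <- list(
    marker_concentration_pM = 100,
    marker_length_bp = 1000,
    target_length_bp = 150,
    gdna_length_bp = 10000,
    mass_per_bp_g_mol = 650,
    detection = list(k_sigma = 5, min_dwell_s = 1e-4, window_samples = 501,
                     max_block_duration_s = 1),
    mixture = list(K_max = 4, n_init = 10, seed = 1,
                   marker_amplitude_hint_pA = NA),
    geometry = list(tip_diameter_nm = 10, half_cone_angle_deg = 5,
                    reference_diameter_nm = 10, bias_voltage_mV = 400),
    buffer_conductivity_S_m = NA,
    simulator = list(open_pore_current_pA = 5000, noise_sd_pA = 12,
                     sampling_rate_Hz = 1e5, filter_cutoff_Hz = 5e3,
                     duration_s = 1800, capture_rate_constant = 0.02),
    plasma = list(dilution_factor = NA, elution_volume_uL = NA,
                  plasma_volume_mL = NA)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  validateRunConfig(cfg)
  class(cfg) <- "nanoporeQC_config"
  cfg
}

#' @rdname runConfig
#' @param cfg a configuration list.
#' @export
validateRunConfig <- function(cfg) {
  pos <- c(marker_concentration_pM = cfg$marker_concentration_pM,
           marker_length_bp = cfg$marker_length_bp,
           target_length_bp = cfg$target_length_bp,
           gdna_length_bp = cfg$gdna_length_bp,
           mass_per_bp_g_mol = cfg$mass_per_bp_g_mol,
           k_sigma = cfg$detection$k_sigma,
           min_dwell_s = cfg$detection$min_dwell_s,
           window_samples = cfg$detection$window_samples,
           max_block_duration_s = cfg$detection$max_block_duration_s,
           K_max = cfg$mixture$K_max, n_init = cfg$mixture$n_init,
           tip_diameter_nm = cfg$geometry$tip_diameter_nm,
           duration_s = cfg$simulator$duration_s,
           sampling_rate_Hz = cfg$simulator$sampling_rate_Hz,
           capture_rate_constant = cfg$simulator$capture_rate_constant)
  bad <- names(pos)[!vapply(pos, function(v) is.numeric(v) && is.finite(v) && v > 0,
                            logical(1))]
  if (length(bad)) {
    stop("configuration error: field(s) must be positive numbers: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' @rdname runConfig
#' @param path file path.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
  class(cfg) <- "nanoporeQC_config"
  cfg
}

#' Build a SimSpec from a run configuration
#'
#' @param cfg a [runConfig()] list.
#' @param species species panel (default [defaultSpeciesPanel()]).
#' @param seed RNG seed.
#' @export
simSpecFromConfig <- function(cfg, species = defaultSpeciesPanel(), seed = 1L) {
  sigma <- cfg$buffer_conductivity_S_m
  if (!is.numeric(sigma) || !is.finite(sigma)) {
    sigma <- 20  # only used for conductance reporting, not amplitudes
  }
  simSpec(species = species,
          pore = poreGeometry(cfg$geometry$tip_diameter_nm,
                              bufferConductivity = sigma,
                              halfConeAngle = cfg$geometry$half_cone_angle_deg,
                              biasVoltage = cfg$geometry$bias_voltage_mV),
          referenceDiameter = cfg$geometry$reference_diameter_nm,
          openPoreCurrent = cfg$simulator$open_pore_current_pA,
          noiseSd = cfg$simulator$noise_sd_pA,
          samplingRate = cfg$simulator$sampling_rate_Hz,
          filterCutoff = cfg$simulator$filter_cutoff_Hz,
          duration = cfg$simulator$duration_s,
          captureRateConstant = cfg$simulator$capture_rate_constant,
          seed = seed)
}

#' Read and write current traces as delimited text
#'
#' Plain-text trace container: `#`-prefixed header lines carrying
#' `sampling_rate_hz`, `bias_voltage_mv` and `pore_id`, followed by one
#' current sample (pA) per line.
#'
#' @param trace an [IonTrace-class].
#' @param path file path.
#' @export
writeIonTrace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_hz: %.10g", trace@samplingRate),
               sprintf("# bias_voltage_mv: %.10g", trace@biasVoltage),
               sprintf("# pore_id: %s", trace@poreId)), con)
  writeLines(sprintf("%.6f", trace@samples), con)
  invisible(path)
}

#' @rdname writeIonTrace
#' @export
readIonTrace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) stop("trace file missing header field: ", key)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  ionTrace(as.numeric(lines[!grepl("^#", lines)]),
           samplingRate = as.numeric(getv("sampling_rate_hz")),
           biasVoltage = as.numeric(getv("bias_voltage_mv")),
           poreId = getv("pore_id"))
}

#' Read and write event tables as delimited text
#'
#' Tab-separated event table with `#`-prefixed header lines carrying the
#' recorded duration and any excluded (clogged) intervals, then columns
#' `pore_id`, `chunk_id`, `start_time_s`, `dwell_s`, `amplitude_pA` (and
#' `species` for simulated truth tables).
#'
#' @param table an [EventTable-class].
#' @param path file path.
#' @export
writeEventTable <- function(table, path) {
  con <- file(path, "w")
  excl <- table@excludedIntervals
  exstr <- if (NROW(excl)) {
    paste(sprintf("%.9g:%.9g", excl[, 1], excl[, 2]), collapse = ";")
  } else ""
  writeLines(c(sprintf("# recorded_duration_s: %.10g", table@recordedDuration),
               sprintf("# excluded_intervals: %s", exstr)), con)
  ev <- table@events
  names(ev)[names(ev) == "start_time"] <- "start_time_s"
  names(ev)[names(ev) == "dwell"] <- "dwell_s"
  names(ev)[names(ev) == "amplitude"] <- "amplitude_pA"
  suppressWarnings(write.table(ev, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  lines <- readLines(path, n = 10L)
  dur <- as.numeric(sub("^# recorded_duration_s:", "",
                        grep("^# recorded_duration_s:", lines, value = TRUE)[1]))
  exline <- trimws(sub("^# excluded_intervals:", "",
                       grep("^# excluded_intervals:", lines, value = TRUE)[1]))
  excl <- if (nzchar(exline)) {
    pairs <- strsplit(strsplit(exline, ";")[[1]], ":")
    do.call(rbind, lapply(pairs, function(p) as.numeric(p)))
  } else .empty_intervals()
  ev <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(ev)[names(ev) == "start_time_s"] <- "start_time"
  names(ev)[names(ev) == "dwell_s"] <- "dwell"
  names(ev)[names(ev) == "amplitude_pA"] <- "amplitude"
  ev$chunk_id <- as.character(ev$chunk_id)
  eventTable(ev, recordedDuration = dur, excludedIntervals = excl)
}

#' Serialise a QC report
#'
#' Writes the report as YAML (machine-readable) including a provenance
#' block echoing the analysis inputs.
#'
#' @param report a [QCReport-class].
#' @param path file path.
#' @param config optional [runConfig()] echoed into the provenance block.
#' @export
writeQCReport <- function(report, path, config = NULL) {
  out <- list(
    c_target_pM = report@cTarget,
    percent_target = report@percentTarget,
    c_marker_nominal_pM = report@cMarkerNominal,
    plasma_equivalent_ng_mL = if (is.finite(report@plasmaEquivalent))
      report@plasmaEquivalent else NULL,
    frequencies_per_s = list(target = report@frequencies@fTarget,
                             marker = report@frequencies@fMarker,
                             gDNA = report@frequencies@fGdna),
    diagnostics = as.list(report@diagnostics),
    provenance = list(package = "nanoporeQC",
                      version = as.character(utils::packageVersion("nanoporeQC")),
                      config = if (!is.null(config)) unclass(config) else NULL)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Serialise a mixture-fit component table
#'
#' Tab-separated summary: label, weight, mean_pA, sd_pA, soft_count and
#' frequency_per_s (soft count over the effective duration).
#'
#' @param fit a [MixtureFit-class].
#' @param effectiveDuration seconds; used for the frequency column.
#' @param path file path.
#' @export
writeMixtureSummary <- function(fit, effectiveDuration, path) {
  comp <- fit@components
  out <- data.frame(label = comp$label, weight = comp$weight,
                    mean_pA = comp$mean, sd_pA = comp$sd,
                    soft_count = comp$soft_count,
                    frequency_per_s = comp$soft_count / effectiveDuration)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise a pooling grid
#'
#' Writes the CV matrices as a delimited wide matrix per metric plus a
#' long-format table (pores, minutes, metric, cv_percent).
#'
#' @param grid a [PoolingGrid-class].
#' @param prefix output path prefix; files `<prefix>_cv_concentration.tsv`,
#'   `<prefix>_cv_percent.tsv`, `<prefix>_long.tsv` are written.
#' @export
writePoolingGrid <- function(grid, prefix) {
  write.table(grid@cvConcentration, paste0(prefix, "_cv_concentration.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  write.table(grid@cvPercent, paste0(prefix, "_cv_percent.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  write.table(gridAsLong(grid), paste0(prefix, "_long.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
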