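#' Describe one analyte's chromatographic peak
#'
#' An analyte peak model holds everything the simulator needs to place one
#' analyte in a chromatogram: where it elutes, its peak shape, and how
#' strongly the detector responds to it at each monitored wavelength.
#'
#' The peak shape is an exponentially-modified Gaussian (EMG), the standard
#' empirical model for tailed chromatographic peaks; `tau = 0` gives a pure
#' Gaussian. `retention_time` is the apex (mode) of the peak, not the EMG
#' location parameter -- the simulator shifts the EMG so the mode lands at
#' the configured time.
#'
#' @param name Analyte name (unique within a configuration).
#' @param retention_time Apex time in minutes; must be positive.
#' @param sigma Gaussian width in minutes; must be positive.
#' @param tau Exponential tail constant in minutes; `0` means pure Gaussian.
#' @param response_factor Named numeric vector of detector response factors,
#'   one per wavelength (names are wavelengths in nm). Units: peak area
#'   (response x minutes) per (ug/mL of analyte x uL injected). Wavelengths
#'   not listed get zero response.
#' @return An object of class `analyte_peak_model`.
#' @examples
#' analyte_peak_model("rutin", retention_time = 27.4, sigma = 0.12,
#'                    tau = 0.04, response_factor = c("256" = 2.12))
#' @export
analyte_peak_model <- function(name, retention_time, sigma, tau = 0,
                               response_factor) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(retention_time) || length(retention_time) != 1L ||
      retention_time <= 0)
    stop("retention_time must be a single positive number (minutes)")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number (minutes)")
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("tau must be a single non-negative number (minutes)")
  if (!is.numeric(response_factor) || is.null(names(response_factor)) ||
      any(!nzchar(names(response_factor))))
    stop("response_factor must be a named numeric vector (names = nm)")
  if (any(response_factor < 0))
    stop("response_factor values must be >= 0")
  structure(list(name = name, retention_time = retention_time,
                 sigma = sigma, tau = tau,
                 response_factor = response_factor),
            class = "analyte_peak_model")
}

#' Configure a synthetic multi-wavelength HPLC-DAD acquisition
#'
#' Bundles the analyte models with run-level acquisition settings. The
#' generated signal at a channel is
#' `baseline_drift * t + N(0, noise_sd) + sum of analyte peaks`, where each
#' peak's true integrated area equals
#' `concentration x injection_volume x response_factor` (response x minutes).
#'
#' @param analytes List of [analyte_peak_model()] objects with unique names.
#' @param concentrations Named numeric vector, ug/mL per analyte name; all
#'   must be non-negative and every analyte needs an entry.
#' @param injection_volume Injected volume in uL.
#' @param channels Wavelengths monitored, nm.
#' @param run_length Run length in minutes; must contain every peak with a
#'   5 x (sigma + tau) margin.
#' @param sampling_rate Detector sampling rate in points per second.
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise added to each
#'   sample, response units.
#' @param baseline_drift Linear baseline drift, response units per minute.
#' @param retention_jitter_sd Run-to-run retention-time jitter s.d., minutes.
#' @param seed Integer seed; each (seed, channel) pair has its own stream.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(analytes, concentrations,
                              injection_volume = 5,
                              channels = c(210, 225, 256, 320),
                              run_length = 53, sampling_rate = 5,
                              noise_sd = 0.2, baseline_drift = 0,
                              retention_jitter_sd = 0, seed = 1L) {
  stopifnot(is.list(analytes), length(analytes) >= 1L)
  ok <- vapply(analytes, inherits, logical(1), "analyte_peak_model")
  if (!all(ok)) stop("analytes must all be analyte_peak_model objects")
  nms <- vapply(analytes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("analyte names must be unique")
  names(analytes) <- nms
  if (is.null(names(concentrations)) ||
      !all(nms %in% names(concentrations)))
    stop("concentrations must be named and cover every analyte")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (injection_volume <= 0) stop("injection_volume must be > 0")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (retention_jitter_sd < 0) stop("retention_jitter_sd must be >= 0")
  need <- max(vapply(analytes, function(a)
    a$retention_time + 5 * (a$sigma + a$tau), numeric(1)))
  if (run_length < need)
    stop(sprintf(
      "run_length %.2f min too short to contain all peaks (need >= %.2f)",
      run_length, need))
  structure(list(analytes = analytes,
                 concentrations = concentrations[nms],
                 injection_volume = injection_volume,
                 channels = channels, run_length = run_length,
                 sampling_rate = sampling_rate, noise_sd = noise_sd,
                 baseline_drift = baseline_drift,
                 retention_jitter_sd = retention_jitter_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Unit-area EMG evaluated on a time grid, centred so that t = 0 has unit
# area under the density with location parameter mu = 0. Log-space form
# keeps the erfc factor stable for small tau.
emg_density <- function(t, mu, sigma, tau) {
  if (tau < sigma * 1e-6) return(stats::dnorm(t, mean = mu, sd = sigma))
  z <- (sigma / tau - (t - mu) / sigma) / sqrt(2)
  logh <- -log(tau) - log(2) + sigma^2 / (2 * tau^2) - (t - mu) / tau +
    log(2) + stats::pnorm(-sqrt(2) * z, log.p = TRUE)
  exp(logh)
}

# Offset of the EMG mode relative to its Gaussian location parameter mu,
# found numerically (zero for a pure Gaussian).
emg_mode_offset <- function(sigma, tau) {
  if (tau < sigma * 1e-6) return(0)
  stats::optimize(function(d) emg_density(d, 0, sigma, tau),
                  interval = c(0, sigma + 5 * tau),
                  maximum = TRUE, tol = 1e-9)$maximum
}

# One reproducible stream per (seed, channel): channels can be simulated
# independently and in any order.
channel_seed <- function(seed, channel) {
  as.integer((as.numeric(seed) * 1009L + as.numeric(channel)) %% 2147483647)
}

#' Simulate one detector channel of an HPLC-DAD run
#'
#' Generates the sampled signal for one wavelength: linear baseline drift
#' plus i.i.d. Gaussian noise plus one EMG peak per analyte with non-zero
#' concentration and response at that wavelength. Each peak's true area
#' (trapezoidal integral over minutes) is
#' `concentration x injection_volume x response_factor`.
#'
#' Output is deterministic for a given `(config$seed, channel)` pair.
#'
#' @param config A [simulation_config()].
#' @param channel Wavelength in nm; must be one of `config$channels`.
#' @return A [chromatogram()] object.
#' @export
simulate_chromatogram <- function(config, channel) {
  stopifnot(inherits(config, "simulation_config"))
  if (!channel %in% config$channels)
    stop(sprintf("channel %s nm is not configured (channels: %s)",
                 format(channel), paste(config$channels, collapse = ", ")))
  dt <- 1 / (config$sampling_rate * 60)             # minutes per sample
  times <- seq(0, config$run_length, by = dt)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(channel_seed(config$seed, channel))
  signal <- config$baseline_drift * times
  if (config$noise_sd > 0)
    signal <- signal + stats::rnorm(length(times), sd = config$noise_sd)
  truth <- list()
  for (a in config$analytes) {
    rf <- a$response_factor[as.character(channel)]
    conc <- config$concentrations[[a$name]]
    jitter <- if (config$retention_jitter_sd > 0)
      stats::rnorm(1, sd = config$retention_jitter_sd) else 0
    if (is.na(rf) || rf == 0 || conc == 0) next
    area <- conc * config$injection_volume * unname(rf)
    apex <- a$retention_time + jitter
    mu <- apex - emg_mode_offset(a$sigma, a$tau)
    signal <- signal + area * emg_density(times, mu, a$sigma, a$tau)
    truth[[a$name]] <- list(apex_time = apex, area = area)
  }
  chromatogram(times = times, signal = signal, wavelength = channel,
               injection_volume = config$injection_volume,
               sample_id = sprintf("sim-seed%d-%gnm", config$seed, channel),
               truth = truth)
}

#' Simulate a negative-control run lacking selected analytes
#'
#' Identical to [simulate_chromatogram()] but with the named analytes'
#' concentrations forced to zero, emulating control preparations that omit
#' a herb and hence its constituents. Omitting nothing reproduces the full
#' simulation exactly (same random stream).
#'
#' @param config A [simulation_config()].
#' @param omit Character vector of analyte names to blank out.
#' @param channel Wavelength in nm.
#' @return A [chromatogram()] object.
#' @export
simulate_negative_control <- function(config, omit, channel) {
  stopifnot(inherits(config, "simulation_config"))
  unknown <- setdiff(omit, names(config$analytes))
  if (length(unknown))
    stop("unknown analyte name(s) in omit: ", paste(unknown, collapse = ", "))
  config$concentrations[omit] <- 0
  simulate_chromatogram(config, channel)
}

# Save/restore the global RNG state so simulation calls do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write / read a chromatogram as CSV with a JSON sidecar
#'
#' The CSV holds `time_min,signal`; acquisition metadata (wavelength,
#' injection volume, sample id) goes to `<path>.json`.
#'
#' @param chrom A [chromatogram()].
#' @param path CSV file path.
#' @return `path`, invisibly (`write_chromatogram`); a [chromatogram()]
#'   (`read_chromatogram`).
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  utils::write.csv(data.frame(time_min = chrom$times, signal = chrom$signal),
                   path, row.names = FALSE)
  meta <- list(wavelength = chrom$wavelength,
               injection_volume = chrom$injection_volume,
               sample_id = chrom$sample_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_chromatogram <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_min", "signal") %in% names(d)))
    stop("chromatogram CSV must have columns time_min,signal")
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  chromatogram(times = d$time_min, signal = d$signal,
               wavelength = meta$wavelength %||% NA_real_,
               injection_volume = meta$injection_volume %||% NA_real_,
               sample_id = meta$sample_id %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a simulation configuration as YAML or JSON
#'
#' Serialises a [simulation_config()] to YAML (default) or JSON, chosen by
#' file extension. Reading re-validates everything through the
#' constructors, so a hand-edited file that violates an invariant (negative
#' widths, missing concentrations, too-short run...) fails on load with
#' the constructor's error message.
#'
#' @param config A [simulation_config()].
#' @param path File path ending in `.yml`, `.yaml` or `.json`.
#' @return `path`, invisibly (`write_simulation_config`); a validated
#'   [simulation_config()] (`read_simulation_config`).
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  x <- list(
    analytes = lapply(unname(config$analytes), function(a)
      list(name = a$name, retention_time = a$retention_time,
           sigma = a$sigma, tau = a$tau,
           response_factor = as.list(a$response_factor))),
    concentrations = as.list(config$concentrations),
    injection_volume = config$injection_volume,
    channels = config$channels, run_length = config$run_length,
    sampling_rate = config$sampling_rate, noise_sd = config$noise_sd,
    baseline_drift = config$baseline_drift,
    retention_jitter_sd = config$retention_jitter_sd,
    seed = config$seed)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  need <- c("analytes", "concentrations", "injection_volume", "channels",
            "run_length", "sampling_rate", "noise_sd", "baseline_drift",
            "retention_jitter_sd", "seed")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("config file lacks field(s): ", paste(missing, collapse = ", "))
  analytes <- lapply(x$analytes, function(a)
    analyte_peak_model(a$name, a$retention_time, a$sigma, a$tau %||% 0,
                       unlist(a$response_factor)))
  simulation_config(analytes = analytes,
                    concentrations = unlist(x$concentrations),
                    injection_volume = x$injection_volume,
                    channels = unlist(x$channels),
                    run_length = x$run_length,
                    sampling_rate = x$sampling_rate,
                    noise_sd = x$noise_sd,
                    baseline_drift = x$baseline_drift,
                    retention_jitter_sd = x$retention_jitter_sd,
                    seed = x$seed)
}
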