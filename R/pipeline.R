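#' Default analyte panel for the six-component assay
#'
#' The marker panel of Danggui-Kushen pills (DKP), a classical
#' *Angelica sinensis* / *Sophora flavescens* preparation: six compounds
#' monitored at four DAD wavelengths -- matrine,
#' oxymatrine and catechin at 210 nm, gallic acid (the internal reference)
#' at 225 nm, rutin at 256 nm and ferulic acid at 320 nm. Retention times
#' are configuration inputs (the gradient program is not modelled); the
#' defaults give well-separated peaks in elution order matching the channel
#' assignments. Response factors are expressed per uL injected so that a
#' 5 uL injection reproduces realistic calibration slopes.
#'
#' @return Named list of [analyte_peak_model()] objects.
#' @export
dkp_analytes <- function() {
  mk <- analyte_peak_model
  list(
    matrine = mk("matrine", retention_time = 6.8, sigma = 0.08,
                 tau = 0.02, response_factor = c("210" = 6.9958 / 5)),
    oxymatrine = mk("oxymatrine", retention_time = 9.6, sigma = 0.09,
                    tau = 0.02, response_factor = c("210" = 8.6405 / 5)),
    gallic_acid = mk("gallic_acid", retention_time = 12.1, sigma = 0.09,
                     tau = 0.02, response_factor = c("225" = 27.728 / 5)),
    catechin = mk("catechin", retention_time = 15.2, sigma = 0.10,
                  tau = 0.03, response_factor = c("210" = 37.684 / 5)),
    rutin = mk("rutin", retention_time = 27.4, sigma = 0.12,
               tau = 0.04, response_factor = c("256" = 10.578 / 5)),
    ferulic_acid = mk("ferulic_acid", retention_time = 33.8, sigma = 0.12,
                      tau = 0.03, response_factor = c("320" = 10.658 / 5)))
}

# stock standard concentrations, ug/mL; the mixed standard is a 0.5/5
# dilution of each stock
dkp_stocks <- function() {
  c(matrine = 1191.8, gallic_acid = 11552.6, oxymatrine = 5.7,
    catechin = 44.4, ferulic_acid = 17.3, rutin = 848.2)
}

# analyte -> assigned detection wavelength (nm)
dkp_channels <- function() {
  c(matrine = 210, oxymatrine = 210, catechin = 210,
    gallic_acid = 225, rutin = 256, ferulic_acid = 320)
}

#' Study configuration for the full single-marker workflow
#'
#' Collects everything [run_pipeline()] needs: the analyte panel, which
#' analyte anchors the single-marker calculations, the serial-dilution
#' scheme, the multi-volume injection series used for the relative
#' correction factors, per-batch ground-truth contents for the synthetic
#' samples, sample-preparation geometry, validation replicate counts and
#' thresholds, and the master seed.
#'
#' @param analytes Named list of [analyte_peak_model()] (default
#'   [dkp_analytes()]).
#' @param internal_reference Name of the single marker whose standard
#'   anchors all QAMS calculations; exactly one analyte.
#' @param stocks Named stock concentrations, ug/mL.
#' @param standard_aliquot Aliquot of each stock making the mixed standard,
#'   mL.
#' @param calibration_aliquots Aliquot volumes of the dilution series, mL.
#' @param flask_volume Volumetric-flask final volume, mL.
#' @param injection_volumes Injection volumes for the multipoint RCF, uL.
#' @param batches Character vector of batch ids.
#' @param batch_contents Matrix (batch x analyte) of true mass fractions in
#'   percent used as generator ground truth; defaults to the shipped
#'   reference table's external-standard contents.
#' @param sample_mass Weighed sample mass, g.
#' @param extract_volume Test-solution final volume, mL.
#' @param noise_sd,baseline_drift,retention_jitter_sd Simulator settings
#'   (see [simulation_config()]).
#' @param sampling_rate Detector sampling rate, points per second.
#' @param replicates Replicate count for precision / stability /
#'   repeatability / recovery stages.
#' @param thresholds Named list of pass thresholds (percent):
#'   `precision`, `stability`, `repeatability`, `recovery_low`,
#'   `recovery_high`, `rcf_robustness`.
#' @param rtr_tolerance Fractional tolerance for relative-retention peak
#'   matching.
#' @param condition_effect_sd Relative s.d. of per-condition detector
#'   response perturbations in the robustness grid.
#' @param stability_degradation_pct_per_h Linear degradation rate applied
#'   to the stability series, percent of content per hour.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(analytes = dkp_analytes(),
                         internal_reference = "gallic_acid",
                         stocks = dkp_stocks(),
                         standard_aliquot = 0.5,
                         calibration_aliquots = c(0.1, 0.25, 0.5, 1, 2, 3),
                         flask_volume = 5,
                         injection_volumes = c(3, 5, 10, 15, 20),
                         batches = paste0("2017120", 1:5),
                         batch_contents = NULL,
                         sample_mass = 5, extract_volume = 10,
                         noise_sd = 0.2, baseline_drift = 0.02,
                         retention_jitter_sd = 0.01,
                         sampling_rate = 5,
                         replicates = 6,
                         thresholds = list(precision = 2.0,
                                           stability = 2.0,
                                           repeatability = 2.0,
                                           recovery_low = 95,
                                           recovery_high = 105,
                                           rcf_robustness = 2.27),
                         rtr_tolerance = 0.05,
                         condition_effect_sd = 0.01,
                         stability_degradation_pct_per_h = 0,
                         seed = 1L) {
  nms <- names(analytes)
  if (!internal_reference %in% nms)
    stop("internal_reference must be one of the configured analytes")
  if (anyDuplicated(nms)) stop("analyte names must be unique")
  if (!all(nms %in% names(stocks)))
    stop("stocks must cover every analyte")
  if (is.null(batch_contents)) {
    ref <- load_reference_tables()
    es <- ref$table4[ref$table4$method == "ES",
                     c("batch", nms)]
    batch_contents <- as.matrix(es[match(batches, es$batch), nms])
    rownames(batch_contents) <- batches
    if (anyNA(batch_contents))
      stop("no default contents for these batch ids; supply batch_contents")
  }
  structure(list(analytes = analytes,
                 internal_reference = internal_reference,
                 stocks = stocks[nms],
                 standard_aliquot = standard_aliquot,
                 calibration_aliquots = calibration_aliquots,
                 flask_volume = flask_volume,
                 injection_volumes = injection_volumes,
                 batches = batches, batch_contents = batch_contents,
                 sample_mass = sample_mass,
                 extract_volume = extract_volume,
                 noise_sd = noise_sd, baseline_drift = baseline_drift,
                 retention_jitter_sd = retention_jitter_sd,
                 sampling_rate = sampling_rate,
                 replicates = replicates, thresholds = thresholds,
                 rtr_tolerance = rtr_tolerance,
                 condition_effect_sd = condition_effect_sd,
                 stability_degradation_pct_per_h =
                   stability_degradation_pct_per_h,
                 seed = as.integer(seed)),
            class = "study_config")
}

# simulation_config for one injection of given per-analyte concentrations
sim_config_for <- function(study, concentrations, injection_volume = 5,
                           seed, analytes = study$analytes) {
  simulation_config(analytes = unname(analytes),
                    concentrations = concentrations,
                    injection_volume = injection_volume,
                    sampling_rate = study$sampling_rate,
                    noise_sd = study$noise_sd,
                    baseline_drift = study$baseline_drift,
                    retention_jitter_sd = study$retention_jitter_sd,
                    seed = seed)
}

# derived sub-seed per pipeline stage, kept within 32-bit integer range
stage_seed <- function(seed, stage, k = 0L) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729 + k * 131) %%
               2147483629)
}

#' Measure each analyte's peak in one injection
#'
#' Simulates (or accepts) the per-channel chromatograms of one injection,
#' detects peaks, and assigns each analyte the detected peak nearest its
#' expected retention time at its assigned wavelength.
#'
#' @param study A [study_config()].
#' @param concentrations Named per-analyte concentrations, ug/mL.
#' @param injection_volume uL.
#' @param seed Seed for this injection.
#' @param window Maximum |apex - expected| mismatch, minutes.
#' @param analytes Optional perturbed analyte models (robustness grid).
#' @return data.frame: `analyte`, `wavelength`, `apex_time`, `area`,
#'   `height`, `width_half`, `snr` (`NA` rows when a peak is absent).
measure_injection <- function(study, concentrations, injection_volume,
                              seed, window = 0.5,
                              analytes = study$analytes) {
  channels <- dkp_channels()[names(study$analytes)]
  cfg <- sim_config_for(study, concentrations, injection_volume, seed,
                        analytes = analytes)
  peaks_by_channel <- lapply(unique(channels), function(ch)
    detect_peaks(simulate_chromatogram(cfg, ch)))
  names(peaks_by_channel) <- as.character(unique(channels))
  rows <- lapply(names(study$analytes), function(an) {
    ch <- as.character(channels[[an]])
    pk <- peaks_by_channel[[ch]]
    pk <- pk[pk$area > 0, , drop = FALSE]
    exp_rt <- analytes[[an]]$retention_time
    out <- data.frame(analyte = an, wavelength = as.numeric(ch),
                      apex_time = NA_real_, area = NA_real_,
                      height = NA_real_, width_half = NA_real_,
                      snr = NA_real_)
    if (nrow(pk)) {
      i <- which.min(abs(pk$apex_time - exp_rt))
      if (abs(pk$apex_time[i] - exp_rt) <= window)
        out[1, 3:7] <- pk[i, c("apex_time", "area", "height",
                               "width_half", "snr")]
    }
    out
  })
  do.call(rbind, rows)
}

mixed_standard_conc <- function(study) {
  study$stocks * study$standard_aliquot / study$flask_volume
}

batch_conc <- function(study, batch) {
  mf <- study$batch_contents[batch, names(study$analytes)]
  # invert mass_fraction(): conc = mf/100 * mass * 1e6 / volume
  mf / 100 * study$sample_mass * 1e6 / study$extract_volume
}

#' Run the full single-marker quantification workflow
#'
#' Executes the complete study on synthetic data: calibration of every
#' analyte from its serial-dilution series (with LOD/LOQ), multipoint
#' relative correction factors from the multi-volume standard injections,
#' relative-retention peak localization, per-batch quantification by both
#' the external-standard and the single-marker route with their relative
#' errors, and the validation battery (precision, stability,
#' repeatability, recovery, RCF robustness, localization-method
#' comparison). When `out_dir` is given, writes the calibration / RCF /
#' content tables and validation report as CSV plus a JSON run log; reruns
#' with the same seed produce byte-identical files.
#'
#' @param study A [study_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return A list bundle: `calibration` (curves + report data.frame),
#'   `rcf` (`rcf_estimate` objects + table), `rtr` (expected relative
#'   retentions), `contents` (per-batch ES/QAMS/RE table), `validation`
#'   (stacked statistic rows), `robustness`, `localization`, `log`.
#' @export
run_pipeline <- function(study, out_dir = NULL) {
  stopifnot(inherits(study, "study_config"))
  nms <- names(study$analytes)
  ref <- study$internal_reference
  channels <- dkp_channels()[nms]

  ## --- calibration -----------------------------------------------------
  conc_levels <- lapply(study$calibration_aliquots, function(a)
    study$stocks * a / study$flask_volume)
  cal_meas <- lapply(seq_along(conc_levels), function(i)
    measure_injection(study, conc_levels[[i]], injection_volume = 5,
                      seed = stage_seed(study$seed, 1L, i)))
  curves <- lapply(nms, function(an) {
    areas <- vapply(cal_meas, function(m) m$area[m$analyte == an],
                    numeric(1))
    ok <- !is.na(areas)
    ser <- standard_series(an, study$stocks[[an]],
                           study$calibration_aliquots[ok],
                           study$flask_volume, areas[ok])
    cv <- fit_calibration(ser)
    low <- which.min(ser$concentrations)
    hpc <- vapply(cal_meas, function(m) m$height[m$analyte == an],
                  numeric(1))[ok][low] / ser$concentrations[low]
    ll <- estimate_lod_loq(study$noise_sd, hpc)
    cv$lod <- ll$lod; cv$loq <- ll$loq
    cv
  })
  names(curves) <- nms
  cal_table <- do.call(rbind, lapply(curves, function(cv)
    data.frame(analyte = cv$analyte_name, slope = cv$slope,
               intercept = cv$intercept, r = cv$r,
               range_low = cv$linear_range[1],
               range_high = cv$linear_range[2],
               lod = cv$lod, loq = cv$loq)))
  rownames(cal_table) <- NULL

  ## --- multipoint RCF + expected relative retentions -------------------
  std_conc <- mixed_standard_conc(study)
  std_meas <- lapply(seq_along(study$injection_volumes), function(i)
    measure_injection(study, std_conc, study$injection_volumes[i],
                      seed = stage_seed(study$seed, 2L, i)))
  others <- setdiff(nms, ref)
  rcf_estimates <- lapply(others, function(an) {
    pairs <- t(vapply(std_meas, function(m)
      c(m$area[m$analyte == ref], m$area[m$analyte == an]), numeric(2)))
    multipoint_rcf(pairs, ref_conc = std_conc[[ref]],
                   k_conc = std_conc[[an]], analyte_name = an,
                   internal_reference = ref,
                   wavelength = channels[[an]])
  })
  names(rcf_estimates) <- others
  rcf_table <- data.frame(
    injection_volume = c(as.character(study$injection_volumes),
                         "Mean", "RSD%"))
  for (an in others)
    rcf_table[[an]] <- c(rcf_estimates[[an]]$per_injection_values,
                         rcf_estimates[[an]]$mean_rcf,
                         rcf_estimates[[an]]$rsd_percent)
  rtr_expected <- vapply(nms, function(an) {
    rt_k <- mean(vapply(std_meas, function(m)
      m$apex_time[m$analyte == an], numeric(1)), na.rm = TRUE)
    rt_s <- mean(vapply(std_meas, function(m)
      m$apex_time[m$analyte == ref], numeric(1)), na.rm = TRUE)
    relative_retention(rt_k, rt_s)
  }, numeric(1))

  ## --- per-batch quantification: ES vs QAMS ----------------------------
  content_rows <- list()
  errors <- character(0)
  for (b in seq_along(study$batches)) {
    batch <- study$batches[b]
    meas <- measure_injection(study, batch_conc(study, batch),
                              injection_volume = 5,
                              seed = stage_seed(study$seed, 3L, b))
    a_ref <- meas$area[meas$analyte == ref]
    if (is.na(a_ref)) {
      errors <- c(errors, sprintf(
        "batch %s: internal reference peak not found; batch skipped",
        batch))
      next
    }
    ref_conc_sample <- suppressWarnings(es_content(curves[[ref]], a_ref))
    es_mf <- qams_mf <- stats::setNames(rep(NA_real_, length(nms)), nms)
    for (an in nms) {
      a_k <- meas$area[meas$analyte == an]
      if (is.na(a_k)) next
      es_conc <- suppressWarnings(es_content(curves[[an]], a_k))
      es_mf[an] <- mass_fraction(es_conc, study$extract_volume,
                                 study$sample_mass)
      if (an == ref) {
        qams_mf[an] <- es_mf[an]   # reference is quantified by ES only
      } else {
        qc <- qams_content(rcf_estimates[[an]]$mean_rcf, a_k, a_ref,
                           as.numeric(ref_conc_sample))
        qams_mf[an] <- mass_fraction(qc, study$extract_volume,
                                     study$sample_mass)
      }
    }
    re <- relative_error(es_mf, qams_mf)
    re[ref] <- NA_real_
    content_rows[[batch]] <- rbind(
      data.frame(batch = batch, method = "ES", analyte = nms,
                 value = unname(es_mf)),
      data.frame(batch = batch, method = "QAMS", analyte = nms,
                 value = unname(qams_mf)),
      data.frame(batch = batch, method = "RE", analyte = nms,
                 value = unname(re)))
  }
  contents <- do.call(rbind, content_rows)
  rownames(contents) <- NULL

  ## --- validation battery ----------------------------------------------
  reps <- study$replicates
  rep_areas <- function(conc, stage, vol = 5) {
    ms <- lapply(seq_len(reps), function(i)
      measure_injection(study, conc, vol,
                        seed = stage_seed(study$seed, stage, i)))
    stats::setNames(lapply(nms, function(an)
      stats::na.omit(vapply(ms, function(m) m$area[m$analyte == an],
                            numeric(1)))), nms)
  }
  prec_std <- run_precision_suite(rep_areas(std_conc, 4L),
                                  study$thresholds$precision,
                                  label = "precision_standard")
  prec_test <- run_precision_suite(
    rep_areas(batch_conc(study, study$batches[1]), 5L),
    study$thresholds$precision, label = "precision_test")

  # stability: same solution re-injected over 24 h, optional linear loss
  stab_hours <- c(0, 2, 4, 8, 12, 24)
  stab_series <- stats::setNames(vector("list", length(nms)), nms)
  for (i in seq_along(stab_hours)) {
    fac <- max(0, 1 - study$stability_degradation_pct_per_h / 100 *
                 stab_hours[i])
    m <- measure_injection(study, batch_conc(study, study$batches[1]) *
                             fac, 5, seed = stage_seed(study$seed, 6L, i))
    for (an in nms)
      stab_series[[an]] <- c(stab_series[[an]],
                             m$area[m$analyte == an])
  }
  stab_series <- lapply(stab_series, function(v) v[!is.na(v)])
  stability <- run_precision_suite(stab_series,
                                   study$thresholds$stability,
                                   label = "stability")

  # repeatability: independent parallel preparations, quantified by ES
  repeat_series <- stats::setNames(vector("list", length(nms)), nms)
  for (i in seq_len(reps)) {
    m <- measure_injection(study, batch_conc(study, study$batches[1]), 5,
                           seed = stage_seed(study$seed, 7L, i))
    for (an in nms) {
      a_k <- m$area[m$analyte == an]
      if (is.na(a_k)) next
      mf <- mass_fraction(
        as.numeric(suppressWarnings(es_content(curves[[an]], a_k))),
        study$extract_volume, study$sample_mass)
      repeat_series[[an]] <- c(repeat_series[[an]], mf)
    }
  }
  repeatability <- run_precision_suite(repeat_series,
                                       study$thresholds$repeatability,
                                       label = "repeatability")

  # recovery: spike each analyte at ~100% of the original content
  orig_conc <- batch_conc(study, study$batches[1])
  rec_rows <- list()
  for (i in seq_len(reps)) {
    m <- measure_injection(study, 2 * orig_conc, 5,
                           seed = stage_seed(study$seed, 8L, i))
    for (an in nms) {
      a_k <- m$area[m$analyte == an]
      if (is.na(a_k)) next
      found_ug <- as.numeric(suppressWarnings(
        es_content(curves[[an]], a_k))) * study$extract_volume
      orig_ug <- orig_conc[[an]] * study$extract_volume
      rec_rows[[length(rec_rows) + 1L]] <- data.frame(
        analyte = an, replicate = i,
        recovery = recovery_rate(orig_ug, orig_ug, found_ug))
    }
  }
  rec_raw <- do.call(rbind, rec_rows)
  recovery <- do.call(rbind, lapply(nms, function(an) {
    v <- rec_raw$recovery[rec_raw$analyte == an]
    data.frame(test = "recovery", analyte = an, n = length(v),
               rsd_percent = if (length(v) >= 2) rsd(v) else NA_real_,
               threshold = study$thresholds$recovery_high,
               pass = mean(v) >= study$thresholds$recovery_low &&
                 mean(v) <= study$thresholds$recovery_high)
  }))

  ## --- robustness grid + localization comparison -----------------------
  rob <- simulate_robustness_grid(study)
  robustness <- rcf_robustness(rob$rcf_grid,
                               study$thresholds$rcf_robustness)
  localization <- compare_localization_methods(rob$rt_grid, ref)

  validation <- rbind(prec_std, prec_test, stability, repeatability,
                      recovery)
  rownames(validation) <- NULL

  bundle <- list(calibration = list(curves = curves, table = cal_table),
                 rcf = list(estimates = rcf_estimates, table = rcf_table),
                 rtr = rtr_expected, contents = contents,
                 validation = validation, robustness = robustness,
                 localization = localization,
                 log = list(seed = study$seed,
                            version = as.character(
                              utils::packageVersion("qamskit")),
                            config_hash = config_hash(study),
                            errors = errors))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# per-condition robustness grid. A condition change (instrument, column,
# flow, temperature) mostly rescales ALL peak areas jointly (injection /
# flow / detector effects, s.d. condition_effect_sd) with a four-times
# smaller analyte-specific selectivity residual; the joint part cancels in
# the RCF ratio, which is exactly why the RCF is robust. The time axis
# drifts by a per-condition scale (flow/instrument) and offset (column).
simulate_robustness_grid <- function(study) {
  conditions <- rbind(
    data.frame(axis = "instrument", condition = c("instrument_A",
                                                  "instrument_B"),
               scale = c(1.000, 1.012), offset = c(0, 0.03)),
    data.frame(axis = "column", condition = paste0("column_", 1:3),
               scale = c(1.000, 1.008, 0.994), offset = c(0, 0.05, -0.04)),
    data.frame(axis = "flow_rate", condition = c("flow_0.8", "flow_1.0",
                                                 "flow_1.2"),
               scale = 1.0 / c(0.8, 1.0, 1.2), offset = 0),
    data.frame(axis = "temperature", condition = c("temp_25", "temp_30",
                                                   "temp_35"),
               scale = c(1.010, 1.000, 0.991), offset = 0))
  nms <- names(study$analytes)
  ref <- study$internal_reference
  std_conc <- mixed_standard_conc(study)
  rcf_grid <- rt_grid <- NULL
  for (i in seq_len(nrow(conditions))) {
    sd_i <- stage_seed(study$seed, 9L, i)
    old <- .Random.seed_save()
    set.seed(sd_i)
    common <- stats::rnorm(1, mean = 1, sd = study$condition_effect_sd)
    resp_fac <- common * stats::rnorm(length(nms), mean = 1,
                                      sd = study$condition_effect_sd / 4)
    .Random.seed_restore(old)
    models <- study$analytes
    for (j in seq_along(nms)) {
      a <- models[[j]]
      a$response_factor <- a$response_factor * abs(resp_fac[j])
      a$retention_time <- a$retention_time * conditions$scale[i] +
        conditions$offset[i]
      models[[j]] <- a
    }
    m <- measure_injection(study, std_conc, 5, seed = sd_i,
                           analytes = models)
    a_ref <- m$area[m$analyte == ref]
    for (an in setdiff(nms, ref)) {
      a_k <- m$area[m$analyte == an]
      if (is.na(a_k) || is.na(a_ref) || a_k <= 0 || a_ref <= 0) next
      rcf_grid <- rbind(rcf_grid, data.frame(
        axis = conditions$axis[i], condition = conditions$condition[i],
        analyte = an,
        rcf = compute_rcf(std_conc[[ref]], a_ref, std_conc[[an]], a_k)))
    }
    rt_grid <- rbind(rt_grid, data.frame(
      condition = conditions$condition[i], analyte = m$analyte,
      retention_time = m$apex_time))
  }
  list(rcf_grid = rcf_grid, rt_grid = rt_grid[!is.na(rt_grid$retention_time), ])
}

config_hash <- function(study) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(study, f)
  unname(tools::md5sum(f))
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$calibration$table,
                   file.path(out_dir, "calibration.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$rcf$table, file.path(out_dir, "rcf.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$contents, file.path(out_dir, "contents.csv"),
                   row.names = FALSE)
  write_validation_report(bundle$validation,
                          file.path(out_dir, "validation.csv"))
  utils::write.csv(bundle$localization,
                   file.path(out_dir, "localization.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Load the shipped reference tables
#'
#' Returns the package's bundled reference tables -- calibration lines with
#' ranges and LOD/LOQ, the multipoint relative correction factors by
#' injection volume, and the per-batch ES/QAMS/RE contents -- as data
#' frames. Each file's MD5 is verified against the shipped checksum sidecar
#' before parsing; a mismatch is an error.
#'
#' @param dir Directory holding the fixture files; defaults to the
#'   package's `extdata`.
#' @return list with elements `table2` (calibration), `table3` (RCF by
#'   injection volume; rows `3,5,10,15,20,Mean,RSD%`), `table4` (contents:
#'   one row per batch x method).
#' @export
load_reference_tables <- function(dir = system.file("extdata",
                                                    package = "qamskit")) {
  sums <- utils::read.table(file.path(dir, "checksums.txt"),
                            col.names = c("md5", "file"),
                            stringsAsFactors = FALSE)
  files <- c(table2 = "table2_calibration.csv",
             table3 = "table3_rcf.csv",
             table4 = "table4_contents.csv")
  for (f in files) {
    want <- sums$md5[sums$file == f]
    got <- unname(tools::md5sum(file.path(dir, f)))
    if (!length(want) || want != got)
      stop("checksum mismatch for fixture ", f)
  }
  out <- lapply(files, function(f)
    utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                    check.names = FALSE))
  names(out) <- names(files)
  out
}
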