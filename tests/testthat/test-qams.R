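test_that("the relative correction factor follows its defining ratio", {
  expect_equal(compute_rcf(3, 120, 3, 120), 1)          # self
  expect_equal(compute_rcf(2, 100, 1, 25), 2)
  for (s in 1:25) {
    set.seed(s)
    ws <- runif(1, 0.1, 1e3); as_ <- runif(1, 1, 1e5)
    wk <- runif(1, 0.1, 1e3); ak <- runif(1, 1, 1e5)
    lam <- runif(1, 0.1, 10)
    f <- compute_rcf(ws, as_, wk, ak)
    # joint area scaling (injection volume, detector gain) cancels
    expect_equal(compute_rcf(ws, lam * as_, wk, lam * ak), f)
    expect_equal(compute_rcf(ws, as_, ws, as_), 1)
  }
  expect_error(compute_rcf(0, 1, 1, 1), "ref_conc")
  expect_error(compute_rcf(1, 1, 1, -2), "k_area")
})

test_that("multipoint RCF summaries reproduce the reference per-injection columns", {
  ref <- load_reference_tables()$table3
  vols <- ref[1:5, ]
  printed_mean <- as.numeric(ref[ref$injection_volume == "Mean", -1])
  printed_rsd <- as.numeric(ref[ref$injection_volume == "RSD%", -1])
  for (j in seq_along(printed_mean)) {
    est <- multipoint_rcf(values = as.numeric(vols[[j + 1]]),
                          analyte_name = names(vols)[j + 1])
    expect_equal(round(est$mean_rcf, 2), printed_mean[j])
    expect_equal(round(est$rsd_percent, 2), printed_rsd[j])
  }
  const <- multipoint_rcf(values = rep(2.5, 5))
  expect_equal(const$rsd_percent, 0)
  expect_error(multipoint_rcf(values = 3.8), "undefined")
})

test_that("per-injection RCFs derive from (ref_area, k_area) pairs", {
  inj <- cbind(ref_area = c(100, 210, 390), k_area = c(50, 103, 201))
  est <- multipoint_rcf(inj, ref_conc = 2, k_conc = 1)
  expect_equal(est$per_injection_values,
               (1 * inj[, 1]) / (2 * inj[, 2]))
  expect_equal(est$mean_rcf, mean(est$per_injection_values))
})

test_that("relative retention is a clock-invariant ratio", {
  expect_equal(relative_retention(8, 8), 1)
  expect_equal(relative_retention(20, 8), 2.5)
  expect_equal(relative_retention(20 * 1.3, 8 * 1.3),
               relative_retention(20, 8))
  expect_error(relative_retention(-1, 8))
})

test_that("relative retention localizes all analytes in a full synthetic run", {
  st <- study_config(seed = 8, retention_jitter_sd = 0)
  conc <- st$stocks * st$standard_aliquot / st$flask_volume
  cfg <- simulation_config(unname(st$analytes), conc,
                           retention_jitter_sd = 0, noise_sd = 0.2,
                           seed = 8)
  peaks <- do.call(rbind, lapply(c(210, 225, 256, 320), function(chan)
    detect_peaks(simulate_chromatogram(cfg, chan))))
  ref_rt <- st$analytes$gallic_acid$retention_time
  ref_peak <- peaks[which.min(abs(peaks$apex_time - ref_rt)), ]
  targets <- data.frame(
    analyte = names(st$analytes),
    expected_rtr = vapply(st$analytes, function(a)
      a$retention_time / ref_rt, numeric(1)))
  hits <- locate_peaks_by_rtr(peaks, ref_peak, targets)
  expect_true(all(!is.na(hits$peak_row)))
  for (i in seq_len(nrow(hits)))
    expect_equal(hits$apex_time[i],
                 st$analytes[[hits$analyte[i]]]$retention_time,
                 tolerance = 0.01)

  # negative control lacking matrine: matrine absent, the rest matched
  peaks_nc <- do.call(rbind, lapply(c(210, 225, 256, 320), function(chan)
    detect_peaks(simulate_negative_control(cfg, "matrine", chan))))
  ref_peak_nc <- peaks_nc[which.min(abs(peaks_nc$apex_time - ref_rt)), ]
  hits_nc <- locate_peaks_by_rtr(peaks_nc, ref_peak_nc, targets)
  expect_true(is.na(hits_nc$peak_row[hits_nc$analyte == "matrine"]))
  expect_true(all(!is.na(hits_nc$peak_row[hits_nc$analyte != "matrine"])))
})

test_that("equidistant candidates break ties to the earlier-eluting peak", {
  peaks <- data.frame(apex_time = c(9, 11), area = c(1, 1),
                      height = c(1, 1))
  ref_peak <- list(apex_time = 10)
  hit <- locate_peaks_by_rtr(peaks, ref_peak,
                             data.frame(analyte = "x", expected_rtr = 1),
                             tolerance = 0.2)
  expect_equal(hit$apex_time, 9)
  expect_error(locate_peaks_by_rtr(peaks, list(apex_time = NA_real_),
                                   data.frame(analyte = "x",
                                              expected_rtr = 1)),
               "reference peak missing")
})

test_that("single-marker content inverts the correction-factor algebra", {
  expect_equal(qams_content(1, 50, 50, 7.5), 7.5)
  for (s in 1:25) {
    set.seed(s)
    ws <- runif(1, 1, 100); wk <- runif(1, 1, 100)
    as_ <- runif(1, 10, 1e4); ak <- runif(1, 10, 1e4)
    f <- compute_rcf(ws, as_, wk, ak)
    # closed loop on the same run returns the analyte's own concentration
    expect_equal(qams_content(f, ak, as_, ws), wk)
  }
  expect_error(qams_content(1, 0, 1, 1), "k_area")
})

test_that("mass fraction is plain unit bookkeeping", {
  expect_equal(mass_fraction(1000, 10, 1), 1.0)
  expect_equal(mass_fraction(1000, 10, 0.5), 2.0)
  conc <- runif(5, 1, 1e4)
  expect_equal(mass_fraction(conc, 10, 5), conc * 2e-4)
  expect_error(mass_fraction(-1, 10, 5))
})

test_that("relative error reproduces the printed comparison convention", {
  expect_equal(round(relative_error(0.1190, 0.1170), 2), 1.68)
  expect_equal(round(relative_error(1.3427, 1.3138), 2), 2.15)
  expect_equal(relative_error(0.5, 0.5), 0)
  expect_true(is.na(relative_error(0, 1)))   # internal reference marker
  expect_error(relative_error(-1, 1))
})
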