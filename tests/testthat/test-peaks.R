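test_that("baseline-only traces yield an empty peak table", {
  cfg <- tiny_config(concentrations = c(alpha = 0, ref = 0, beta = 0),
                     noise_sd = 0.2, baseline_drift = 0.05, seed = 2)
  pk <- detect_peaks(simulate_chromatogram(cfg, 210))
  expect_s3_class(pk, "peak_table")
  expect_equal(nrow(pk), 0)
})

test_that("the 210 nm channel of the default panel shows exactly three peaks", {
  st <- study_config(seed = 4)
  conc <- st$stocks * st$standard_aliquot / st$flask_volume
  cfg <- simulation_config(unname(st$analytes), conc,
                           noise_sd = 0.2, seed = 4)
  pk <- detect_peaks(simulate_chromatogram(cfg, 210))
  expect_equal(nrow(pk), 3)   # matrine, oxymatrine, catechin
  expect_equal(nrow(detect_peaks(simulate_chromatogram(cfg, 225))), 1)
})

test_that("two Gaussians ten sigma apart are resolved with sample-accurate apexes", {
  twins <- list(
    analyte_peak_model("p1", 5.0, sigma = 0.1,
                       response_factor = c("210" = 1)),
    analyte_peak_model("p2", 6.0, sigma = 0.1,
                       response_factor = c("210" = 1)))
  cfg <- simulation_config(twins, c(p1 = 50, p2 = 50), channels = 210,
                           run_length = 10, noise_sd = 0, seed = 1)
  ch <- simulate_chromatogram(cfg, 210)
  pk <- detect_peaks(ch)
  expect_equal(nrow(pk), 2)
  dt <- 1 / (cfg$sampling_rate * 60)
  expect_lte(abs(pk$apex_time[1] - 5.0), dt + 1e-12)
  expect_lte(abs(pk$apex_time[2] - 6.0), dt + 1e-12)
})

test_that("integration matches the closed-form Gaussian area within 0.1%", {
  cfg <- tiny_config(concentrations = c(alpha = 10, ref = 0, beta = 0))
  ch <- simulate_chromatogram(cfg, 210)
  area <- integrate_peak(ch, c(2.2, 3.8))
  expect_equal(area, 10 * 5 * 2 * 60, tolerance = 1e-3)
})

test_that("integration returns 0 on empty regions and removes constant offsets", {
  cfg <- tiny_config(concentrations = c(alpha = 10, ref = 0, beta = 0))
  ch <- simulate_chromatogram(cfg, 210)
  expect_equal(integrate_peak(ch, c(9, 11)), 0)
  flat <- chromatogram(ch$times, ch$signal + 50)   # constant offset
  expect_equal(integrate_peak(flat, c(9, 11)), 0, tolerance = 1e-9)
  expect_equal(integrate_peak(flat, c(2.2, 3.8)), 10 * 5 * 2 * 60,
               tolerance = 1e-3)
  expect_error(integrate_peak(ch, c(3.8, 2.2)), "inverted")
  expect_error(integrate_peak(ch, c(-1, 3)), "range")
})

test_that("integration is additive over adjacent intervals on a corrected trace", {
  cfg <- tiny_config()
  ch <- simulate_chromatogram(cfg, 210)
  # split point in the flat valley between alpha (3 min) and beta (8 min)
  whole <- integrate_peak(ch, c(2.0, 9.2))
  parts <- integrate_peak(ch, c(2.0, 5.5)) + integrate_peak(ch, c(5.5, 9.2))
  expect_equal(whole, parts, tolerance = 1e-6)
})

test_that("signal-to-noise follows its definition and scales with noise", {
  set.seed(7)
  t <- seq(0, 2, by = 1 / 300)
  noise <- rnorm(length(t), sd = 10)
  ch <- chromatogram(t, noise)
  s <- stats::sd(noise[t <= 0.5])
  pk <- list(height = 30)
  expect_equal(signal_to_noise(ch, pk), 30 / s)
  ch2 <- chromatogram(t, noise / 2)
  expect_equal(signal_to_noise(ch2, pk), 2 * (30 / s))
  expect_error(signal_to_noise(chromatogram(t, rep(1, length(t))), pk),
               "zero")
})

test_that("measured S/N tracks amplitude over noise across seeds", {
  # Monte-Carlo: simulated apex S/N ~ height / noise_sd within 15%
  ratios <- vapply(1:40, function(s) {
    cfg <- tiny_config(concentrations = c(alpha = 0, ref = 20, beta = 0),
                       noise_sd = 2, seed = s)
    ch <- simulate_chromatogram(cfg, 225)
    pk <- detect_peaks(ch, min_snr = 5)
    true_height <- 20 * 5 * 4 / (0.08 * sqrt(2 * pi))
    pk$snr[1] / (true_height / 2)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("theoretical plates follow the half-height formula", {
  expect_equal(theoretical_plates(list(apex_time = 10, width_half = 0.43)),
               2996.2, tolerance = 1e-4)
  expect_equal(theoretical_plates(list(apex_time = 4, width_half = 4)),
               5.54)
  n1 <- theoretical_plates(list(apex_time = 10, width_half = 0.2))
  n2 <- theoretical_plates(list(apex_time = 10, width_half = 0.1))
  expect_equal(n2 / n1, 4)
  expect_error(theoretical_plates(list(apex_time = 1, width_half = 0)))
})

test_that("resolution matches its definition and the Gaussian 6-sigma identity", {
  co <- list(apex_time = 5, width_half = 0.2)
  expect_equal(resolution(co, co), 0)
  p1 <- list(apex_time = 10, width_half = 1 / 1.699)
  p2 <- list(apex_time = 12, width_half = 1 / 1.699)
  expect_equal(resolution(p1, p2), 2.0)
  expect_error(resolution(p2, p1), "before")
  # peaks 6 sigma apart resolve at Rs ~ 1.5
  twins <- list(
    analyte_peak_model("a", 5.0, sigma = 0.1,
                       response_factor = c("210" = 1)),
    analyte_peak_model("b", 5.6, sigma = 0.1,
                       response_factor = c("210" = 1)))
  cfg <- simulation_config(twins, c(a = 50, b = 50), channels = 210,
                           run_length = 10, noise_sd = 0,
                           sampling_rate = 20, seed = 1)
  pk <- detect_peaks(simulate_chromatogram(cfg, 210))
  expect_equal(nrow(pk), 2)
  expect_equal(resolution(pk[1, ], pk[2, ]), 1.5, tolerance = 0.05)
})

test_that("detect then integrate recovers every configured true area within 1%", {
  st <- study_config(seed = 6, noise_sd = 0, baseline_drift = 0,
                     retention_jitter_sd = 0)
  conc <- st$stocks * st$standard_aliquot / st$flask_volume
  cfg <- simulation_config(unname(st$analytes), conc, noise_sd = 0,
                           seed = 6)
  for (chan in c(210, 225, 256, 320)) {
    ch <- simulate_chromatogram(cfg, chan)
    pk <- detect_peaks(ch)
    for (nm in names(ch$truth)) {
      tr <- ch$truth[[nm]]
      i <- which.min(abs(pk$apex_time - tr$apex_time))
      expect_equal(pk$area[i], tr$area * 60, tolerance = 0.01,
                   label = sprintf("area of %s at %d nm", nm, chan))
    }
  }
})
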