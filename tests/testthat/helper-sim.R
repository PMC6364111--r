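# shared builders for fast synthetic fixtures

# independent trapezoid quadrature used as the integration oracle
trapz <- function(t, y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)

# three-analyte panel on a short run: reference plus two targets
tiny_panel <- function() {
  list(
    alpha = analyte_peak_model("alpha", retention_time = 3, sigma = 0.08,
                               response_factor = c("210" = 2)),
    ref = analyte_peak_model("ref", retention_time = 5, sigma = 0.08,
                             response_factor = c("225" = 4)),
    beta = analyte_peak_model("beta", retention_time = 8, sigma = 0.10,
                              tau = 0.03, response_factor = c("210" = 3)))
}

tiny_config <- function(concentrations = c(alpha = 10, ref = 20, beta = 5),
                        noise_sd = 0, baseline_drift = 0,
                        retention_jitter_sd = 0, injection_volume = 5,
                        run_length = 12, seed = 1L, ...) {
  simulation_config(tiny_panel(), concentrations = concentrations,
                    injection_volume = injection_volume,
                    channels = c(210, 225), run_length = run_length,
                    noise_sd = noise_sd, baseline_drift = baseline_drift,
                    retention_jitter_sd = retention_jitter_sd,
                    seed = seed, ...)
}

# full default study run, cached so several tests can share one pipeline
.pipeline_cache <- new.env(parent = emptyenv())
cached_pipeline <- function(seed = 101L) {
  key <- as.character(seed)
  if (is.null(.pipeline_cache[[key]])) {
    study <- study_config(seed = seed)
    t0 <- Sys.time()
    bundle <- run_pipeline(study)
    .pipeline_cache[[key]] <- list(
      study = study, bundle = bundle,
      elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
  }
  .pipeline_cache[[key]]
}
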