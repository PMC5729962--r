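# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

# modest-statistics lookup table for module-level tests (grid chosen to
# cover the physiological mua/musp excursions of the failure trajectories)
small_test_lut <- function() {
  if (is.null(.fixtures$small_lut)) {
    .fixtures$small_lut <- build_lut(
      mua_grid = c(0.01, 1.5, 3, 5, 8),
      musp_grid = c(5, 10, 15, 20, 25, 30),
      n_photons = 2e4, seed = 5)
  }
  .fixtures$small_lut
}

# production-statistics reduced table for the acceptance checks
acceptance_lut <- function() {
  if (is.null(.fixtures$acc_lut)) {
    .fixtures$acc_lut <- build_lut(
      mua_grid = c(0.01, 1.5, 3, 5, 8),
      musp_grid = c(5, 10, 15, 20, 25, 30),
      n_photons = 1e5, seed = 7)
  }
  .fixtures$acc_lut
}

test_extinction <- function() {
  if (is.null(.fixtures$eps)) {
    .fixtures$eps <- synthetic_hemoglobin_extinction()
  }
  .fixtures$eps
}

# noiseless Siegert-type curve 1 + beta * exp(-2 tau / tauc) on a log grid
# (15 points/decade spanning tauc/1000 .. ~300 tauc)
siegert_curve <- function(tauc, beta = 1, points_per_decade = 15) {
  lags <- tauc * 10^seq(-3, 2.5, by = 1 / points_per_decade)
  g2_curve(lags, 1 + beta * exp(-2 * lags / tauc))
}

# random short Poisson trace for correlator property tests
random_trace <- function(n_bins, mean_counts = 3, bin_seconds = 1e-6) {
  intensity_trace(rpois(n_bins, mean_counts), bin_seconds)
}

# full DCS reduction: stream -> trace -> linear FFT g2 -> log filter -> tau1/2
pipeline_tau_half <- function(stream, bin_seconds = 2e-6, max_lag_s = NULL) {
  trace <- bin_timetags(stream, bin_seconds)
  mls <- if (is.null(max_lag_s)) stream_duration(stream) / 4 else max_lag_s
  curve <- g2_fft(trace, "linear",
                  max_lag_bins = floor(mls / trace$bin_seconds))
  estimate_tau_half(log_downsample(curve, 15))
}
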