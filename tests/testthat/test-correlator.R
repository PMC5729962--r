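test_that("constant intensity gives g2 = 1 at every lag for all estimators", {
  tr <- intensity_trace(rep(5, 1024), 1e-6)
  expect_equal(g2_fft(tr, "circular")$g2, rep(1, 1023), tolerance = 1e-12)
  expect_equal(g2_fft(tr, "linear")$g2, rep(1, 1023), tolerance = 1e-12)
  expect_equal(g2_multitau(tr, m = 16)$g2,
               rep(1, nrow(g2_multitau(tr, m = 16))), tolerance = 1e-12)
})

test_that("alternating trace has circular g2 of 2 at even lags, 0 at odd", {
  tr <- intensity_trace(rep(c(1, 0), 512), 1e-6)
  g <- g2_fft(tr, "circular")$g2
  expect_equal(g[seq(2, 1022, by = 2)], rep(2, 511), tolerance = 1e-10)
  expect_equal(g[seq(1, 1023, by = 2)], rep(0, 512), tolerance = 1e-10)
  # brute-force direct correlator agrees on the same trace (linear variant)
  d <- g2_direct(tr, 1:50)
  f <- g2_fft(tr, "linear", max_lag_bins = 50)
  expect_lt(max(abs(d$g2 - f$g2)), 1e-10)
})

test_that("linear FFT estimator equals the direct oracle on random traces", {
  set.seed(123)
  for (i in 1:25) {
    tr <- random_trace(sample(64:2048, 1), mean_counts = runif(1, 0.5, 10))
    lags <- seq_len(min(tr$n_bins - 1, 200))
    expect_lt(max(abs(g2_fft(tr, "linear", max(lags))$g2 -
                        g2_direct(tr, lags)$g2)), 1e-10)
  }
})

test_that("circular g2 is invariant under cyclic shifts of the trace", {
  set.seed(5)
  counts <- rpois(256, 4)
  g1 <- g2_fft(intensity_trace(counts, 1e-6), "circular")$g2
  for (shift in c(1, 17, 100)) {
    shifted <- c(counts[-seq_len(shift)], counts[seq_len(shift)])
    expect_equal(g2_fft(intensity_trace(shifted, 1e-6), "circular")$g2, g1,
                 tolerance = 1e-10)
  }
})

test_that("g2 is invariant under intensity scaling", {
  set.seed(6)
  counts <- rpois(512, 3)
  for (fn in list(function(tr) g2_fft(tr, "linear", 100)$g2,
                  function(tr) g2_multitau(tr)$g2)) {
    expect_equal(fn(intensity_trace(counts * 7, 1e-6)),
                 fn(intensity_trace(counts, 1e-6)), tolerance = 1e-10)
  }
})

test_that("a single photon produces zero correlation at all lags", {
  counts <- c(rep(0, 100), 1, rep(0, 100))
  d <- g2_direct(intensity_trace(counts, 1e-6), 1:50)
  expect_equal(d$g2, rep(0, 50))
})

test_that("a Poisson-only stream is shot-noise flat: g2 near 1", {
  set.seed(9)
  rate <- 5e4
  ticks <- sort(floor(runif(rpois(1, rate * 2), 0, 2 / 80e-9)))
  ps <- photon_stream(ticks, 80e-9, duration_ticks = 2 / 80e-9)
  tr <- bin_timetags(ps, 1e-5)
  g <- g2_fft(tr, "linear", max_lag_bins = 500)$g2
  se <- sd(g)
  # no more outliers beyond 3 SE than chance allows, and bias below 1%
  expect_lt(mean(abs(g - 1) > 3 * se), 0.02)
  expect_lt(abs(mean(g) - 1), 0.01)
})

test_that("degenerate traces raise classed errors", {
  expect_error(g2_fft(intensity_trace(rep(0, 16), 1e-6)),
               class = "perfopt_zero_trace")
  expect_error(g2_fft(intensity_trace(5, 1e-6)), class = "perfopt_invalid")
  expect_error(g2_direct(intensity_trace(rpois(32, 2), 1e-6), lags_bins = 40),
               class = "perfopt_invalid")
})

test_that("multitau lag grid follows the m + (levels-1) m/2 arithmetic", {
  tr <- intensity_trace(rpois(5000, 3), 1e-6)
  cv <- g2_multitau(tr, m = 16, levels = 8)
  expect_equal(nrow(cv), 16 + 7 * 8)
  expect_true(all(diff(cv$lag_s) > 0))
  expect_warning(g2_multitau(intensity_trace(rpois(64, 3), 1e-6),
                             m = 16, levels = 10),
                 "truncating")
})

test_that("multitau and FFT agree on a decaying-intensity stream", {
  sp <- stream_spec(5e4, 2, 1e-3, beta = 1, seed = 31)
  tr <- bin_timetags(simulate_photon_stream(sp), 1e-5)
  mt <- g2_multitau(tr, m = 16)
  ff <- log_downsample(g2_fft(tr, "linear", max_lag_bins = 20000), 20)
  # compare on overlapping lags via interpolation of the fft curve
  keep <- mt$lag_s > 2e-5 & mt$lag_s < 5e-3
  fi <- approx(ff$lag_s, ff$g2, mt$lag_s[keep])$y
  expect_lt(max(abs(mt$g2[keep] - fi) / fi), 0.05)
})

test_that("an exponential-g2 stream matches its analytic decay constant", {
  sp <- stream_spec(5e4, 4, 1e-3, beta = 1, seed = 77)
  tr <- bin_timetags(simulate_photon_stream(sp), 1e-5)
  cv <- log_downsample(g2_fft(tr, "linear", max_lag_bins = 20000), 15)
  # fit log(g2 - 1) ~ tau on lags where the decay dominates noise
  keep <- cv$lag_s < 1.5e-3 & cv$g2 > 1.05
  fit <- lm(log(cv$g2[keep] - 1) ~ cv$lag_s[keep])
  tauc_hat <- -2 / coef(fit)[2]
  expect_lt(abs(tauc_hat - 1e-3) / 1e-3, 0.1)
})

test_that("logarithmic downsampling averages within log-spaced bins", {
  # already-sparse curve passes through unchanged
  cv <- g2_curve(10^seq(-6, -3, by = 0.5), seq(2, 1, length.out = 7))
  out <- log_downsample(cv, points_per_decade = 2)
  expect_equal(out$lag_s, cv$lag_s)
  expect_equal(out$g2, cv$g2)

  # bin-count bound: 1000 linear lags over 3 decades at 10/decade
  lin <- g2_curve(seq(1e-6, 1e-3, length.out = 1000), rep(1, 1000))
  expect_lte(nrow(log_downsample(lin, 10)), 31)
  expect_true(all(diff(log_downsample(lin, 10)$lag_s) > 0))

  # variance reduction on noisy replicates
  set.seed(21)
  lags <- seq(1e-6, 1e-3, length.out = 600)
  raw_var <- c(); ds_var <- c()
  for (r in 1:100) {
    g <- 1 + exp(-2 * lags / 1e-4) + rnorm(600, sd = 0.05)
    cv <- g2_curve(lags, g)
    ds <- log_downsample(cv, 10)
    mid <- function(curve) curve$g2[curve$lag_s > 3e-4] # flat region
    raw_var <- c(raw_var, var(mid(cv)))
    ds_var <- c(ds_var, var(mid(ds)))
  }
  expect_lt(mean(ds_var), mean(raw_var))
})

test_that("g2 curves round-trip through TSV", {
  cv <- g2_curve(10^seq(-6, -2, by = 0.25), runif(17, 1, 2), method = "fft",
                 n_photons = 123, duration_seconds = 1.5)
  path <- withr::local_tempfile()
  write_g2_curve(cv, path)
  back <- read_g2_curve(path)
  expect_equal(back$lag_s, cv$lag_s)
  expect_equal(back$g2, cv$g2)
  expect_equal(attr(back, "method"), "fft")
})
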