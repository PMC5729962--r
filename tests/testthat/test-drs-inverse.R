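wl_grid <- seq(480, 680, by = 2)

test_that("dark/reference correction implements the calibration formula", {
  dark <- reflectance_spectrum(wl_grid, rep(100, length(wl_grid)))
  ref <- reflectance_spectrum(wl_grid, rep(1100, length(wl_grid)))
  # raw == reference -> R = standard albedo everywhere
  out <- correct_spectrum(ref, dark, ref, 0.5)
  expect_equal(out$value, rep(0.5, length(wl_grid)))
  # raw == dark -> zero
  expect_equal(correct_spectrum(dark, dark, ref)$value, rep(0, length(wl_grid)))
  # 30% of the dynamic range -> 0.15 with a 50% standard
  raw <- reflectance_spectrum(wl_grid, dark$value + 0.3 * (ref$value - dark$value))
  expect_equal(correct_spectrum(raw, dark, ref, 0.5)$value,
               rep(0.15, length(wl_grid)))
  expect_equal(attr(correct_spectrum(raw, dark, ref), "stage"),
               "reference_corrected")
  # grid mismatch and bad calibration are rejected
  expect_error(correct_spectrum(raw, dark,
                                reflectance_spectrum(wl_grid + 1, ref$value)),
               class = "perfopt_invalid")
  expect_error(correct_spectrum(raw, ref, dark), class = "perfopt_calibration")
})

test_that("moving-average smoothing preserves constants and reduces variance", {
  spec <- reflectance_spectrum(wl_grid, rep(2, length(wl_grid)))
  expect_equal(smooth_spectrum(spec, 1)$value, spec$value)
  expect_equal(smooth_spectrum(spec, 11)$value, spec$value)
  expect_error(smooth_spectrum(spec, 4), class = "perfopt_invalid")

  set.seed(2)
  ratios <- replicate(100, {
    noisy <- reflectance_spectrum(wl_grid, rnorm(length(wl_grid)))
    sm <- smooth_spectrum(noisy, 11)
    interior <- 6:(length(wl_grid) - 5)
    var(sm$value[interior]) / var(noisy$value[interior])
  })
  expect_equal(mean(ratios), 1 / 11, tolerance = 0.25)
})

test_that("smoothing commutes with interior wavelength subsetting", {
  set.seed(4)
  spec <- reflectance_spectrum(wl_grid, runif(length(wl_grid), 1, 2))
  sm <- smooth_spectrum(spec, 5)
  sub <- reflectance_spectrum(spec$wavelength_nm[11:60], spec$value[11:60])
  sm_sub <- smooth_spectrum(sub, 5)
  # away from the subset's own edges the two routes agree
  expect_equal(sm_sub$value[3:48], sm$value[13:58])
})

test_that("the absorption model evaluates the hemoglobin mixture exactly", {
  eps <- tibble::tibble(wavelength_nm = c(500, 600), eps_hbo2 = c(2000, 1000),
                        eps_hb = c(1500, 1000))
  # 20 uM fully deoxygenated at eps_hb = 1500
  p <- tissue_model_params(20, 0, 10, 1)
  expect_equal(model_mua(p, eps, 500), log(10) * 2e-5 * 1500)
  # printed worked example: eps_hb = 1000 -> 0.0461 cm^-1
  expect_equal(round(model_mua(p, eps, 600), 4), 0.0461)
  # isosbestic wavelength: independent of saturation
  vals <- vapply(c(0, 0.4, 1), function(s) {
    model_mua(tissue_model_params(20, s, 10, 1), eps, 600)
  }, numeric(1))
  expect_equal(max(vals) - min(vals), 0)
  # no hemoglobin, no absorption
  expect_equal(model_mua(tissue_model_params(0, 0.5, 10, 1), eps, c(500, 600)),
               c(0, 0))
  expect_error(model_mua(p, eps, 700), class = "perfopt_range")
})

test_that("mua is affine in saturation and linear in concentration", {
  eps <- test_extinction()
  wl <- seq(500, 650, by = 25)
  f <- function(hbt, s) model_mua(tissue_model_params(hbt, s, 10, 1), eps, wl)
  mid <- f(20, 0.5)
  expect_equal(mid, (f(20, 0.2) + f(20, 0.8)) / 2, tolerance = 1e-12)
  expect_equal(f(40, 0.3), 2 * f(20, 0.3), tolerance = 1e-12)
})

test_that("the scattering power law anchors at the reference wavelength", {
  p <- tissue_model_params(10, 0.5, 20, 1, lambda0_nm = 600)
  expect_identical(model_musp(p, 600), 20)
  expect_equal(model_musp(tissue_model_params(10, 0.5, 20, 0), seq(450, 700, 50)),
               rep(20, 6))
  expect_equal(model_musp(p, 650), 20 * (650 / 600)^-1, tolerance = 1e-12)
})

test_that("the forward spectrum responds to scale and absorption", {
  lut <- small_test_lut()
  eps <- test_extinction()
  wl <- seq(500, 650, by = 10)
  p <- tissue_model_params(19, 0.68, 20, 1.2)
  expect_equal(model_spectrum(p, lut, eps, wl, scale = 0)$value,
               rep(0, length(wl)))
  lo <- model_spectrum(tissue_model_params(10, 0.68, 20, 1.2), lut, eps, wl)
  hi <- model_spectrum(tissue_model_params(40, 0.68, 20, 1.2), lut, eps, wl)
  expect_true(all(hi$value < lo$value))
})

test_that("scale calibration is the least-squares ratio", {
  lut <- small_test_lut()
  wl <- seq(500, 650, by = 10)
  model <- model_phantom_spectrum(lut, wl, volume_fraction = 0.005)
  expect_equal(calibrate_scale(model, model), 1, tolerance = 1e-12)
  twice <- reflectance_spectrum(wl, 2 * model$value)
  expect_equal(calibrate_scale(twice, model), 2, tolerance = 1e-12)
  set.seed(6)
  noisy <- reflectance_spectrum(wl, 3 * model$value *
                                  (1 + rnorm(length(wl), sd = 0.01)))
  expect_equal(calibrate_scale(noisy, model), 3, tolerance = 0.01)
})

test_that("noise-free inverse crime recovers the generator parameters", {
  lut <- small_test_lut()
  eps <- test_extinction()
  wl <- seq(500, 650, by = 10)
  truth <- tissue_model_params(19, 0.68, 20, 1.2)
  spec <- model_spectrum(truth, lut, eps, wl)
  fit <- fit_spectrum(spec, lut, eps, n_starts = 5, seed = 3)
  expect_lt(abs(fit$params$hbt_uM - 19) / 19, 0.05)
  expect_lt(abs(fit$params$sto2 - 0.68), 0.02)
  expect_lt(fit$objective, 0.5)
  expect_true(fit$converged)
  # objective at the truth is not beaten by nearby perturbed parameter sets
  meas <- spec
  obj_at <- function(hbt, s) {
    m <- model_spectrum(tissue_model_params(hbt, s, 20, 1.2), lut, eps, wl)
    mean(abs(m$value - meas$value) / meas$value) * 100
  }
  base <- obj_at(19, 0.68)
  for (d in list(c(2, 0), c(-2, 0), c(0, 0.08), c(0, -0.08))) {
    expect_gt(obj_at(19 + d[1], 0.68 + d[2]), base)
  }
})

test_that("a generator at the saturation bound is recovered on the bound", {
  lut <- small_test_lut()
  eps <- test_extinction()
  wl <- seq(500, 650, by = 10)
  spec <- model_spectrum(tissue_model_params(22, 1, 18, 1), lut, eps, wl)
  fit <- fit_spectrum(spec, lut, eps, n_starts = 5, seed = 9)
  expect_gte(fit$params$sto2, 0.97)
  expect_lte(fit$params$sto2, 1)
})

test_that("recovery error grows monotonically with spectral noise", {
  lut <- small_test_lut()
  eps <- test_extinction()
  wl <- seq(500, 650, by = 10)
  truth <- tissue_model_params(19, 0.68, 20, 1.2)
  clean <- model_spectrum(truth, lut, eps, wl)
  set.seed(12)
  med_err <- vapply(c(0, 0.005, 0.02), function(sig) {
    errs <- replicate(12, {
      noisy <- reflectance_spectrum(
        wl, pmax(clean$value * (1 + rnorm(length(wl), sd = sig)), 1e-12),
        stage = "calibrated")
      f <- fit_spectrum(noisy, lut, eps, n_starts = 4,
                        seed = sample.int(1e6, 1),
                        init = c(19, 0.68, 20, 1.2))
      abs(f$params$sto2 - 0.68)
    })
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) >= -0.005))
  expect_lt(med_err[1], 1e-4)
})

test_that("spectra round-trip through TSV with their stage", {
  spec <- reflectance_spectrum(wl_grid, runif(length(wl_grid)), "smoothed")
  path <- withr::local_tempfile()
  write_spectrum(spec, path)
  back <- read_spectrum(path)
  expect_equal(back$value, spec$value)
  expect_equal(attr(back, "stage"), "smoothed")
})

test_that("the synthetic extinction library has the canonical features", {
  eps <- synthetic_hemoglobin_extinction()
  at <- function(wl, col) eps[[col]][eps$wavelength_nm == wl]
  # deoxy excess throughout the red window
  red <- eps$wavelength_nm >= 600
  expect_true(all(eps$eps_hb[red] > eps$eps_hbo2[red]))
  # oxy doublet flanking the 560 nm dip
  expect_gt(at(540, "eps_hbo2"), at(560, "eps_hbo2"))
  expect_gt(at(578, "eps_hbo2"), at(560, "eps_hbo2"))
  # deoxy single peak near 555
  expect_gt(at(555, "eps_hb"), at(520, "eps_hb"))
  expect_gt(at(555, "eps_hb"), at(590, "eps_hb"))
  expect_true(all(eps$eps_hb > 0) && all(eps$eps_hbo2 > 0))
})
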