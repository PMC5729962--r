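test_that("Henyey-Greenstein sampling has mean cosine g", {
  s <- perfopt:::cpp_hg_sample(2e5, 0.9, 123)
  expect_equal(mean(s), 0.9, tolerance = 0.003)
  expect_true(all(s >= -1 & s <= 1))
  # isotropic limit
  s0 <- perfopt:::cpp_hg_sample(2e5, 0, 321)
  expect_lt(abs(mean(s0)), 0.005)
})

test_that("strong absorption kills the collected signal", {
  r <- mc_reflectance(optical_properties_from_musp(1000, 10),
                      probe_geometry(), 1e4, seed = 1)
  expect_lt(r$reflectance, 1e-4)
})

test_that("terminal photon weights account for the launched energy", {
  r <- mc_reflectance(optical_properties_from_musp(1, 10), probe_geometry(),
                      5e4, seed = 2)
  total <- with(r$tallies, specular + absorbed + escaped + killed + lost)
  expect_equal(total / 5e4, 1, tolerance = 0.005)
  expect_gte(r$reflectance, 0)
  expect_lte(r$reflectance, 1)
})

test_that("Monte Carlo runs are deterministic per seed", {
  props <- optical_properties_from_musp(0.5, 12)
  a <- mc_reflectance(props, probe_geometry(), 1e4, seed = 99)
  b <- mc_reflectance(props, probe_geometry(), 1e4, seed = 99)
  expect_identical(a$reflectance, b$reflectance)
  expect_identical(a$tallies, b$tallies)
  c <- mc_reflectance(props, probe_geometry(), 1e4, seed = 100)
  expect_false(identical(a$reflectance, c$reflectance))
})

test_that("swapping equal source and detector fibers preserves collection", {
  # with equal radii and a shared NA the two roles are optically symmetric,
  # so the collected fraction must agree between the two labelings within
  # Monte Carlo noise (independent seeds)
  props <- optical_properties_from_musp(0.5, 15)
  g1 <- probe_geometry(source_radius_mm = 0.1, detector_radius_mm = 0.1)
  a <- mc_reflectance(props, g1, 1e5, seed = 4)
  b <- mc_reflectance(props, g1, 1e5, seed = 5)
  expect_lt(abs(a$reflectance - b$reflectance),
            4 * sqrt(a$standard_error^2 + b$standard_error^2))
})

test_that("build_lut composes per-cell runs deterministically", {
  geom <- probe_geometry()
  lut <- build_lut(mua_grid = c(0.5, 2), musp_grid = c(8, 16), geom = geom,
                   n_photons = 5e3, seed = 11)
  expect_equal(dim(lut$reflectance), c(2, 2))
  # cells match standalone runs with the same derived sub-seed
  sub_seed <- (11 * 1000003 + 1 * 7919) %% 2^48
  cell <- mc_reflectance(optical_properties_from_musp(0.5, 8, lut$g, lut$n_tissue),
                         geom, 5e3, seed = sub_seed)
  expect_identical(lut$reflectance[1, 1], cell$reflectance)
  # identical seed -> bit-identical table
  lut2 <- build_lut(mua_grid = c(0.5, 2), musp_grid = c(8, 16), geom = geom,
                    n_photons = 5e3, seed = 11)
  expect_identical(lut$reflectance, lut2$reflectance)
  # musp = 0 column is defined as zero
  lut0 <- build_lut(mua_grid = c(0.5, 2), musp_grid = c(0, 16), geom = geom,
                    n_photons = 5e3, seed = 11)
  expect_equal(lut0$reflectance[, 1], c(0, 0))
})

test_that("the production grids enumerate 252 cells", {
  defaults <- formals(build_lut)
  mua_grid <- eval(defaults$mua_grid)
  musp_grid <- eval(defaults$musp_grid)
  expect_equal(length(mua_grid), 12)
  expect_equal(length(musp_grid), 21)
  expect_equal(length(mua_grid) * length(musp_grid), 252)
})

test_that("bilinear lookup reproduces nodes and cell centers", {
  lut <- small_test_lut()
  expect_identical(lut_lookup(lut, lut$mua_grid[2], lut$musp_grid[3]),
                   lut$reflectance[2, 3])
  center <- lut_lookup(lut, mean(lut$mua_grid[2:3]), mean(lut$musp_grid[3:4]))
  expect_equal(center, mean(lut$reflectance[2:3, 3:4]), tolerance = 1e-12)
  expect_error(lut_lookup(lut, 50, 10), class = "perfopt_lut_range")
  expect_error(lut_lookup(lut, 50, 10), "mua")
  expect_error(lut_lookup(lut, 1, 100), "musp")
})

test_that("lookup-table reflectance decreases with absorption", {
  lut <- small_test_lut()
  # node-level check with Monte Carlo allowance
  for (j in seq_along(lut$musp_grid)) {
    r <- lut$reflectance[, j]
    se <- lut$standard_error[, j]
    viol <- diff(r) > 3 * sqrt(se[-1]^2 + se[-length(se)]^2)
    expect_false(any(viol))
  }
  # dense interpolated queries along a fixed musp row
  q <- lut_lookup(lut, seq(0.01, 8, length.out = 200), 15)
  expect_true(all(diff(q) <= 1e-12))
})

test_that("diffusion oracle behaves physically", {
  p <- optical_properties(0.1, 100, 0.9, 1.4)
  expect_gt(diffusion_reflectance(p, 5),
            diffusion_reflectance(optical_properties(0.2, 100, 0.9, 1.4), 5))
  rr <- vapply(c(2, 5, 10, 20), function(r) diffusion_reflectance(p, r),
               numeric(1))
  expect_true(all(diff(rr) < 0))
  expect_warning(diffusion_reflectance(optical_properties(5, 10, 0.9, 1.4), 5),
                 "dubious")
})

test_that("Monte Carlo matches the diffusion oracle in its regime", {
  p <- optical_properties(0.1, 100, 0.9, 1.0) # matched boundary
  mc <- mc_radial_reflectance(p, c(4.5, 5.5), n_photons = 6e4, seed = 13)
  ratio <- mc$reflectance_per_cm2 / diffusion_reflectance(p, 5)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("Mie code reproduces an independent reference to 4 significant figures", {
  # 1-um polystyrene (n = 1.59) in water (n = 1.33); reference values from an
  # independently coded Lorenz-Mie implementation (scipy Bessel route)
  e600 <- mie_efficiencies(pi * 1.0 * 1.33 / 0.600, 1.59 / 1.33)
  expect_equal(e600$Qsca, 2.774974, tolerance = 1e-4)
  expect_equal(e600$g, 0.9205548, tolerance = 1e-4)
  e500 <- mie_efficiencies(pi * 1.0 * 1.33 / 0.500, 1.59 / 1.33)
  expect_equal(e500$Qsca, 3.339307, tolerance = 1e-4)
  expect_equal(e500$g, 0.9282200, tolerance = 1e-4)
})

test_that("Mie suspension properties follow Rayleigh and dilution limits", {
  # size parameter -> 0: asymmetry vanishes, Qsca follows x^4 scaling
  e1 <- mie_efficiencies(0.05, 1.2)
  e2 <- mie_efficiencies(0.025, 1.2)
  expect_lt(abs(e1$g), 1e-3)
  expect_equal(e1$Qsca / e2$Qsca, 16, tolerance = 0.05)
  # mus scales linearly with volume fraction
  p1 <- mie_properties(1, 1.59, 1.33, 600, 0.01)
  p2 <- mie_properties(1, 1.59, 1.33, 600, 0.02)
  expect_equal(p2$mus / p1$mus, 2, tolerance = 1e-9)
  expect_equal(p1$mua, 0)
})

test_that("lookup tables round-trip through the text format", {
  lut <- build_lut(mua_grid = c(0.5, 2), musp_grid = c(8, 16),
                   n_photons = 5e3, seed = 11)
  path <- withr::local_tempfile()
  write_lut(lut, path)
  back <- read_lut(path)
  expect_identical(back$reflectance, lut$reflectance)
  expect_equal(back$mua_grid, lut$mua_grid)
  expect_equal(back$geometry, lut$geometry)
  expect_identical(back$geometry_hash, lut$geometry_hash)
})
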