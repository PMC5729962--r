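#' Optical properties of a homogeneous medium
#'
#' @param mua Absorption coefficient (cm^-1), >= 0.
#' @param mus Scattering coefficient (cm^-1), >= 0.
#' @param g Scattering anisotropy (mean cosine of deflection), |g| < 1.
#'   Default 0.9, typical of soft tissue.
#' @param n Refractive index, >= 1. Default 1.4.
#' @return An `optical_properties` list; the reduced scattering coefficient
#'   `musp = mus * (1 - g)` is always derived, never stored independently.
#' @export
optical_properties <- function(mua, mus, g = 0.9, n = 1.4) {
  if (mua < 0 || mus < 0) stop_perfopt("perfopt_invalid", "mua and mus must be >= 0")
  if (abs(g) >= 1) stop_perfopt("perfopt_invalid", "|g| must be < 1")
  if (n < 1) stop_perfopt("perfopt_invalid", "n must be >= 1")
  structure(list(mua = mua, mus = mus, g = g, n = n), class = "optical_properties")
}

#' Reduced scattering coefficient of an `optical_properties` object
#' @param props An [optical_properties()].
#' @return `mus * (1 - g)` in cm^-1.
#' @export
musp <- function(props) props$mus * (1 - props$g)

#' Optical properties from a reduced scattering target
#'
#' Convenience constructor: given the reduced scattering coefficient, the
#' full scattering coefficient is `musp / (1 - g)`.
#'
#' @param mua Absorption coefficient (cm^-1).
#' @param musp Reduced scattering coefficient (cm^-1).
#' @inheritParams optical_properties
#' @return An [optical_properties()].
#' @export
optical_properties_from_musp <- function(mua, musp, g = 0.9, n = 1.4) {
  optical_properties(mua, musp / (1 - g), g, n)
}

#' Source-detector fiber probe geometry
#'
#' Defaults follow the reflectance probe modeled throughout the package:
#' 1.1-mm source-detector separation, 100-um source and 200-um detection
#' fiber cores, NA 0.22 silica fibers in contact with the tissue.
#'
#' @param separation_mm Center-to-center source-detector distance (mm).
#' @param source_radius_mm,detector_radius_mm Fiber core radii (mm).
#' @param numerical_aperture Fiber NA (defined in air), in (0, 1).
#' @param n_above Refractive index of the coupling medium above the tissue
#'   (fiber face, fused silica by default).
#' @return A `probe_geometry` list.
#' @export
probe_geometry <- function(separation_mm = 1.1, source_radius_mm = 0.05,
                           detector_radius_mm = 0.1,
                           numerical_aperture = 0.22, n_above = 1.457) {
  if (separation_mm <= 0) stop_perfopt("perfopt_invalid", "separation must be > 0")
  if (source_radius_mm <= 0 || detector_radius_mm <= 0) {
    stop_perfopt("perfopt_invalid", "fiber radii must be > 0")
  }
  if (numerical_aperture <= 0 || numerical_aperture >= 1) {
    stop_perfopt("perfopt_invalid", "NA must be in (0, 1)")
  }
  structure(list(separation_mm = separation_mm,
                 source_radius_mm = source_radius_mm,
                 detector_radius_mm = detector_radius_mm,
                 numerical_aperture = numerical_aperture,
                 n_above = n_above),
            class = "probe_geometry")
}

geometry_hash <- function(geom) {
  paste(formatC(unlist(geom), format = "g", digits = 10), collapse = "|")
}

#' Monte Carlo reflectance for a fiber probe
#'
#' Transports `n_photons` photon packets through a semi-infinite homogeneous
#' medium and returns the fraction of launched light collected by the
#' detector fiber (within its footprint and NA acceptance cone). Detection
#' uses an azimuthal-symmetry ring estimator, which is exact in expectation
#' and far lower variance than literal disc-hit scoring for sub-millimeter
#' fibers.
#'
#' @param props An [optical_properties()].
#' @param geom A [probe_geometry()].
#' @param n_photons Photon packets (>= 1e3). Default 1e5, adequate for
#'   desk-scale work; increase for production tables.
#' @param seed Integer RNG seed; runs are bit-reproducible per seed.
#' @return A list with `reflectance`, `standard_error`, and the raw weight
#'   `tallies` (specular, absorbed, escaped, roulette-killed, lost).
#' @export
mc_reflectance <- function(props, geom, n_photons = 1e5, seed = 1) {
  stopifnot(inherits(props, "optical_properties"), inherits(geom, "probe_geometry"))
  if (n_photons < 1e3) stop_perfopt("perfopt_invalid", "n_photons must be >= 1e3")
  if (props$mus <= 0) {
    return(list(reflectance = 0, standard_error = 0,
                tallies = list(note = "no scattering: nothing is diffusely collected")))
  }
  res <- cpp_mc_probe(props$mua, props$mus, props$g, props$n, geom$n_above,
                      geom$source_radius_mm / 10, geom$detector_radius_mm / 10,
                      geom$separation_mm / 10, geom$numerical_aperture,
                      as.integer(n_photons), as.double(seed))
  refl <- res$collected / n_photons
  se <- sqrt(max(res$collected_sq / n_photons - refl^2, 0) / n_photons)
  list(reflectance = refl, standard_error = se,
       tallies = res[c("specular", "absorbed", "escaped", "killed", "lost")])
}

#' Build a reflectance lookup table over an optical-property grid
#'
#' One Monte Carlo run per `(mua, musp)` grid cell, each with a decorrelated
#' sub-seed so the table is deterministic given `seed`. The table is indexed
#' by the reduced scattering coefficient; each cell simulates with
#' `mus = musp / (1 - g)`. Cells with `musp = 0` are defined as zero
#' reflectance (no scattering means no diffuse collection) so interpolation
#' stays well-defined.
#'
#' @param mua_grid,musp_grid Strictly increasing grids (cm^-1). Defaults are
#'   the production grids: 12 absorption values 0.01, 0.5, then 1 to 19 in
#'   steps of 2, and 21 reduced-scattering values 0 to 40 in steps of 2
#'   (252 cells).
#' @param geom A [probe_geometry()].
#' @param g,n_tissue Anisotropy and tissue refractive index used in every
#'   cell.
#' @param n_photons Photons per cell.
#' @param seed Master seed.
#' @return A `reflectance_lut` with the reflectance matrix
#'   (rows = `mua_grid`, columns = `musp_grid`), standard errors, geometry
#'   and provenance fields. Has [tidy()] and [autoplot()] methods.
#' @export
build_lut <- function(mua_grid = c(0.01, 0.5, seq(1, 19, by = 2)),
                      musp_grid = seq(0, 40, by = 2),
                      geom = probe_geometry(), g = 0.9, n_tissue = 1.4,
                      n_photons = 1e5, seed = 1) {
  if (is.unsorted(mua_grid, strictly = TRUE) || is.unsorted(musp_grid, strictly = TRUE)) {
    stop_perfopt("perfopt_invalid", "grids must be strictly increasing")
  }
  R <- matrix(0, nrow = length(mua_grid), ncol = length(musp_grid))
  SE <- matrix(0, nrow = length(mua_grid), ncol = length(musp_grid))
  idx <- 0L
  for (j in seq_along(musp_grid)) {
    for (i in seq_along(mua_grid)) {
      idx <- idx + 1L
      if (musp_grid[j] <= 0) next
      sub_seed <- (as.double(seed) * 1000003 + idx * 7919) %% 2^48
      cell <- mc_reflectance(
        optical_properties_from_musp(mua_grid[i], musp_grid[j], g, n_tissue),
        geom, n_photons = n_photons, seed = sub_seed)
      R[i, j] <- cell$reflectance
      SE[i, j] <- cell$standard_error
    }
  }
  structure(list(mua_grid = mua_grid, musp_grid = musp_grid,
                 reflectance = R, standard_error = SE,
                 n_photons_per_cell = n_photons, geometry = geom,
                 g = g, n_tissue = n_tissue, seed = seed,
                 geometry_hash = geometry_hash(geom)),
            class = "reflectance_lut")
}

#' @export
print.reflectance_lut <- function(x, ...) {
  cat(sprintf(
    "<reflectance_lut> %d mua x %d musp cells (%d total), %.3g photons/cell, sep %.3g mm, NA %.2f\n",
    length(x$mua_grid), length(x$musp_grid),
    length(x$mua_grid) * length(x$musp_grid), x$n_photons_per_cell,
    x$geometry$separation_mm, x$geometry$numerical_aperture))
  invisible(x)
}

#' @method tidy reflectance_lut
#' @export
tidy.reflectance_lut <- function(x, ...) {
  tidyr::expand_grid(mua = x$mua_grid, musp = x$musp_grid) |>
    dplyr::mutate(reflectance = as.vector(t(x$reflectance)),
                  standard_error = as.vector(t(x$standard_error)))
}

#' @method autoplot reflectance_lut
#' @export
autoplot.reflectance_lut <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$musp, y = .data$mua,
                               fill = .data$reflectance)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = expression(mu[s] * minute ~ (cm^-1)),
                  y = expression(mu[a] ~ (cm^-1)),
                  fill = "R", title = "Forward reflectance lookup table")
}

#' Bilinear lookup in a reflectance table
#'
#' @param lut A [build_lut()] table.
#' @param mua,musp Query coordinates (cm^-1); vectors are recycled to common
#'   length. Queries must lie within the grid's convex hull.
#' @return Interpolated reflectance values.
#' @export
lut_lookup <- function(lut, mua, musp) {
  stopifnot(inherits(lut, "reflectance_lut"))
  n <- max(length(mua), length(musp))
  mua <- rep_len(mua, n)
  musp <- rep_len(musp, n)
  ga <- lut$mua_grid
  gs <- lut$musp_grid
  tol_a <- 1e-8 * (ga[length(ga)] - ga[1])
  tol_s <- 1e-8 * (gs[length(gs)] - gs[1])
  if (any(mua < ga[1] - tol_a) || any(mua > ga[length(ga)] + tol_a)) {
    bad <- range(mua[mua < ga[1] - tol_a | mua > ga[length(ga)] + tol_a])
    stop_perfopt("perfopt_lut_range", sprintf(
      "mua query outside table range [%g, %g] (offending values near %g)",
      ga[1], ga[length(ga)], bad[1]))
  }
  if (any(musp < gs[1] - tol_s) || any(musp > gs[length(gs)] + tol_s)) {
    bad <- range(musp[musp < gs[1] - tol_s | musp > gs[length(gs)] + tol_s])
    stop_perfopt("perfopt_lut_range", sprintf(
      "musp query outside table range [%g, %g] (offending values near %g)",
      gs[1], gs[length(gs)], bad[1]))
  }
  mua <- pmin(pmax(mua, ga[1]), ga[length(ga)])
  musp <- pmin(pmax(musp, gs[1]), gs[length(gs)])
  ia <- pmin(pmax(findInterval(mua, ga), 1), length(ga) - 1)
  is <- pmin(pmax(findInterval(musp, gs), 1), length(gs) - 1)
  fa <- (mua - ga[ia]) / (ga[ia + 1] - ga[ia])
  fs <- (musp - gs[is]) / (gs[is + 1] - gs[is])
  R <- lut$reflectance
  R[cbind(ia, is)] * (1 - fa) * (1 - fs) +
    R[cbind(ia + 1, is)] * fa * (1 - fs) +
    R[cbind(ia, is + 1)] * (1 - fa) * fs +
    R[cbind(ia + 1, is + 1)] * fa * fs
}

#' Persist a lookup table as text
#'
#' Plain-text serialization: a JSON metadata header (grids, geometry, seed,
#' photons per cell) in `#`-prefixed lines followed by the reflectance and
#' standard-error matrices as TSV. Round-trips exactly at full double
#' precision.
#'
#' @param lut A [build_lut()] table.
#' @param path File path.
#' @return `read_lut` returns a `reflectance_lut`; `write_lut` returns `path`
#'   invisibly.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "reflectance_lut"))
  meta <- list(mua_grid = lut$mua_grid, musp_grid = lut$musp_grid,
               n_photons_per_cell = lut$n_photons_per_cell,
               geometry = unclass(lut$geometry), g = lut$g,
               n_tissue = lut$n_tissue, seed = lut$seed,
               geometry_hash = lut$geometry_hash)
  hdr <- paste0("#meta=", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  fmt_rows <- function(M) apply(M, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(hdr, "#matrix=reflectance", fmt_rows(lut$reflectance),
               "#matrix=standard_error", fmt_rows(lut$standard_error)), path)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  lines <- readLines(path)
  meta_line <- grep("^#meta=", lines, value = TRUE)
  if (!length(meta_line)) stop_perfopt("perfopt_format", "missing #meta= header")
  meta <- jsonlite::fromJSON(sub("^#meta=", "", meta_line[1]))
  starts <- grep("^#matrix=", lines)
  parse_block <- function(from, to) {
    block <- lines[(from + 1):to]
    do.call(rbind, lapply(strsplit(block, "\t", fixed = TRUE), as.numeric))
  }
  ends <- c(starts[-1] - 1, length(lines))
  mats <- Map(parse_block, starts, ends)
  names(mats) <- sub("^#matrix=", "", lines[starts])
  geom <- do.call(probe_geometry, as.list(meta$geometry))
  structure(list(mua_grid = meta$mua_grid, musp_grid = meta$musp_grid,
                 reflectance = mats$reflectance,
                 standard_error = mats$standard_error,
                 n_photons_per_cell = meta$n_photons_per_cell,
                 geometry = geom, g = meta$g, n_tissue = meta$n_tissue,
                 seed = meta$seed, geometry_hash = geometry_hash(geom)),
            class = "reflectance_lut")
}

#' Diffusion-approximation reflectance oracle
#'
#' Closed-form steady-state diffuse reflectance R(r) (cm^-2) of a
#' semi-infinite medium at radial distance r from a normally incident pencil
#' beam, using the extrapolated-boundary dipole solution. Valid in the
#' diffusive regime (`musp >> mua`, r of a few transport lengths); used as an
#' independent physics cross-check of the Monte Carlo code, not as the
#' forward model.
#'
#' @param props An [optical_properties()] (the refractive-index mismatch sets
#'   the extrapolation length; `A = 1` when matched).
#' @param separation_mm Source-detector distance (mm).
#' @param n_outside Refractive index of the upper half space. Default 1.
#' @return Diffuse reflectance per unit area (cm^-2).
#' @export
diffusion_reflectance <- function(props, separation_mm, n_outside = 1) {
  stopifnot(inherits(props, "optical_properties"))
  mua <- props$mua
  msp <- musp(props)
  if (msp < 10 * mua) {
    warn("diffusion approximation is dubious here: musp is not >> mua")
  }
  r <- separation_mm / 10
  mutr <- mua + msp
  D <- 1 / (3 * mutr)
  mueff <- sqrt(mua / D)
  z0 <- 1 / mutr
  # internal-reflection parameter (Groenhuis approximation); A = 1 if matched
  nrel <- props$n / n_outside
  A <- if (abs(nrel - 1) < 1e-9) 1 else {
    rd <- -1.440 / nrel^2 + 0.710 / nrel + 0.668 + 0.0636 * nrel
    (1 + rd) / (1 - rd)
  }
  zb <- 2 * A * D
  r1 <- sqrt(r^2 + z0^2)
  r2 <- sqrt(r^2 + (z0 + 2 * zb)^2)
  (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
      (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
}

#' Radially resolved Monte Carlo reflectance
#'
#' Pencil-beam companion to [diffusion_reflectance()]: tallies the weight
#' escaping the surface into annuli and converts to reflectance per unit
#' area (cm^-2).
#'
#' @param props An [optical_properties()].
#' @param r_edges_mm Annulus edges (mm), strictly increasing.
#' @param n_photons Photon packets.
#' @param seed RNG seed.
#' @param n_outside Refractive index above the surface. Default 1 (matched
#'   boundary when `props$n` is also 1).
#' @return A tibble with annulus centers (mm), reflectance per cm^2 and its
#'   standard error estimate.
#' @export
mc_radial_reflectance <- function(props, r_edges_mm, n_photons = 1e5, seed = 1,
                                  n_outside = 1) {
  stopifnot(inherits(props, "optical_properties"))
  edges_cm <- r_edges_mm / 10
  res <- cpp_mc_radial(props$mua, props$mus, props$g, props$n, n_outside,
                       as.integer(n_photons), as.double(seed), edges_cm)
  area <- pi * diff(edges_cm^2)
  w <- res$ring_weight
  tibble(
    r_mm = (r_edges_mm[-1] + r_edges_mm[-length(r_edges_mm)]) / 2,
    reflectance_per_cm2 = w / n_photons / area,
    standard_error = sqrt(pmax(w, 1e-300)) / n_photons / area
  )
}

# ---- Mie theory -------------------------------------------------------------

#' Mie efficiencies of a homogeneous sphere
#'
#' Lorenz-Mie scattering/extinction efficiencies and the asymmetry parameter,
#' computed with the standard downward-recurrence logarithmic-derivative
#' scheme (Bohren-Huffman), truncated at the conventional
#' `x + 4 x^(1/3) + 2` term count.
#'
#' @param x Size parameter `pi * d * n_medium / lambda`.
#' @param m Relative refractive index `n_sphere / n_medium` (may be complex).
#' @return A list with `Qext`, `Qsca`, `g`.
#' @export
mie_efficiencies <- function(x, m) {
  if (x <= 0) stop_perfopt("perfopt_invalid", "size parameter must be > 0")
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  mx <- m * x
  # logarithmic derivative D_n(mx) by downward recurrence
  nstart <- ceiling(max(nmax, Mod(mx)) + 16)
  D <- complex(nstart + 1)
  for (n in nstart:1) {
    # D_{n} from D_{n+1}: D_{k-1} = k/mx - 1/(D_k + k/mx) with k = n + 1
    D[n] <- (n + 1) / mx - 1 / (D[n + 1] + (n + 1) / mx)
  }
  # Riccati-Bessel psi, chi by upward recurrence
  n_seq <- seq_len(nmax)
  psi <- numeric(nmax); chi <- numeric(nmax)
  psi_m1 <- cos(x); psi_0 <- sin(x)
  chi_m1 <- -sin(x); chi_0 <- cos(x)
  a <- complex(nmax); b <- complex(nmax)
  for (n in n_seq) {
    psi[n] <- (2 * n - 1) / x * psi_0 - psi_m1
    chi[n] <- (2 * n - 1) / x * chi_0 - chi_m1
    psi_m1 <- psi_0; psi_0 <- psi[n]
    chi_m1 <- chi_0; chi_0 <- chi[n]
  }
  psi_prev <- c(sin(x), psi[-nmax])
  chi_prev <- c(cos(x), chi[-nmax])
  xi <- complex(real = psi, imaginary = -chi)
  xi_prev <- complex(real = psi_prev, imaginary = -chi_prev)
  Dn <- D[n_seq]
  ta <- Dn / m + n_seq / x
  tb <- Dn * m + n_seq / x
  a <- (ta * psi - psi_prev) / (ta * xi - xi_prev)
  b <- (tb * psi - psi_prev) / (tb * xi - xi_prev)
  if (any(!is.finite(Mod(a))) || any(!is.finite(Mod(b)))) {
    stop_perfopt("perfopt_numeric", "Mie series failed to converge")
  }
  n <- n_seq
  Qext <- 2 / x^2 * sum((2 * n + 1) * Re(a + b))
  Qsca <- 2 / x^2 * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  gsum <- sum(n[-nmax] * (n[-nmax] + 2) / (n[-nmax] + 1) *
                Re(a[-nmax] * Conj(a[-1]) + b[-nmax] * Conj(b[-1]))) +
    sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  g <- 4 / (x^2 * Qsca) * gsum
  list(Qext = Qext, Qsca = Qsca, g = g)
}

#' Optical properties of a microsphere suspension via Mie theory
#'
#' Independent-scatterer model for a dilute suspension of monodisperse
#' spheres (e.g. the 1-um polystyrene calibration phantom): the scattering
#' coefficient is number density times geometric cross-section times the Mie
#' scattering efficiency, the anisotropy is the Mie asymmetry parameter, and
#' absorption is zero.
#'
#' @param diameter_um Sphere diameter (um).
#' @param n_sphere,n_medium Refractive indices of sphere and medium.
#' @param wavelength_nm Vacuum wavelength (nm).
#' @param volume_fraction Sphere volume fraction, in (0, 0.1) so independent
#'   scattering holds.
#' @return An [optical_properties()] with `mua = 0` and the suspension's
#'   `mus`, `g`, and medium index.
#' @export
mie_properties <- function(diameter_um, n_sphere, n_medium, wavelength_nm,
                           volume_fraction) {
  if (diameter_um <= 0 || wavelength_nm <= 0) {
    stop_perfopt("perfopt_invalid", "diameter and wavelength must be > 0")
  }
  if (volume_fraction <= 0 || volume_fraction >= 0.1) {
    stop_perfopt("perfopt_invalid",
                 "volume_fraction must be in (0, 0.1) for independent scattering")
  }
  d_cm <- diameter_um * 1e-4
  lambda_cm <- wavelength_nm * 1e-7
  x <- pi * d_cm * n_medium / lambda_cm
  eff <- mie_efficiencies(x, n_sphere / n_medium)
  number_density <- volume_fraction / (pi / 6 * d_cm^3) # spheres per cm^3
  sigma_g <- pi * (d_cm / 2)^2
  optical_properties(mua = 0, mus = number_density * sigma_g * eff$Qsca,
                     g = eff$g, n = n_medium)
}
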