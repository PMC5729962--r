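#' Specification of a synthetic photon stream
#'
#' Target statistics of a simulated DCS measurement: a photon stream whose
#' intensity process yields an analytic intensity autocorrelation
#' `g2(tau) = 1 + beta * exp(-2 tau / tauc)`, the Siegert form for a
#' single-exponential field decorrelation.
#'
#' @param mean_rate_hz Mean detected photon rate (Hz).
#' @param duration_s Record length (s).
#' @param tauc_s Field decorrelation time (s).
#' @param beta Intercept contrast in (0, 1]; 1 for a fully coherent speckle,
#'   lower when uncorrelated background mixes in.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A `stream_spec` list.
#' @export
stream_spec <- function(mean_rate_hz, duration_s, tauc_s, beta = 1, seed = 1) {
  if (mean_rate_hz <= 0 || duration_s <= 0 || tauc_s <= 0) {
    stop_perfopt("perfopt_invalid", "rate, duration and tauc must be positive")
  }
  if (beta <= 0 || beta > 1) {
    stop_perfopt("perfopt_invalid", "beta must be in (0, 1]")
  }
  structure(list(mean_rate_hz = mean_rate_hz, duration_s = duration_s,
                 tauc_s = tauc_s, beta = beta, seed = seed),
            class = "stream_spec")
}

#' Simulate a photon time-tag stream with prescribed g2
#'
#' The intensity process is the squared magnitude of a complex
#' Ornstein-Uhlenbeck field with correlation time `tauc_s` (an AR(1)
#' recursion on a fine grid), mixed with a constant background so the
#' intercept equals `beta`: for mixing fraction `f = sqrt(beta)` the
#' normalized intensity is `f * |E|^2 / <|E|^2> + (1 - f)`, giving exactly
#' `g2(tau) = 1 + beta exp(-2 tau / tauc)`. Photon arrivals are then drawn as
#' an inhomogeneous Poisson process at the target mean rate and quantized to
#' tagger ticks.
#'
#' @param spec A [stream_spec()].
#' @param tick_seconds Tagger tick (s). Default 80e-9.
#' @param oversample Intensity-grid resolution as a fraction of `tauc`:
#'   `dt = tauc / oversample` (floored at one tick). Default 50.
#' @return A [photon_stream()].
#' @export
simulate_photon_stream <- function(spec, tick_seconds = 80e-9, oversample = 50) {
  stopifnot(inherits(spec, "stream_spec"))
  if (tick_seconds > spec$tauc_s / 10) {
    warn("tick_seconds is coarser than tauc/10: the decay will be unresolvable")
  }
  set.seed(spec$seed)
  dt <- max(spec$tauc_s / oversample, tick_seconds)
  n_cells <- ceiling(spec$duration_s / dt)
  rho <- exp(-dt / spec$tauc_s)
  sig <- sqrt((1 - rho^2) / 2) # stationary variance 1/2 per quadrature
  er <- as.numeric(stats::filter(rnorm(n_cells, sd = sig), rho,
                                 method = "recursive",
                                 init = rnorm(1, sd = sqrt(0.5))))
  ei <- as.numeric(stats::filter(rnorm(n_cells, sd = sig), rho,
                                 method = "recursive",
                                 init = rnorm(1, sd = sqrt(0.5))))
  intensity <- er^2 + ei^2
  f <- sqrt(spec$beta)
  intensity <- f * intensity / mean(intensity) + (1 - f)
  lam <- spec$mean_rate_hz * intensity * dt
  counts <- rpois(n_cells, lam)
  cell_idx <- rep.int(seq_len(n_cells), counts)
  times <- (cell_idx - 1 + runif(length(cell_idx))) * dt
  duration_ticks <- ceiling(spec$duration_s / tick_seconds)
  ticks <- floor(times / tick_seconds)
  ticks <- sort(ticks[ticks < duration_ticks])
  photon_stream(ticks, tick_seconds, duration_ticks, channel = "sim")
}

#' Simulate a flow series of photon streams
#'
#' One stream per pump dial speed, with the decorrelation time inversely
#' proportional to flow speed (`tauc = k / speed`), plus a no-flow stream
#' with a much longer decorrelation time. This is the synthetic analog of a
#' flow-phantom dial sweep; the -1 log-log slope of half-decay lag versus
#' speed is its testable consequence.
#'
#' @param dial_speeds Positive flow speeds (arbitrary units).
#' @param k Calibration constant (s * speed-unit): `tauc = k / speed`.
#' @param base_spec A [stream_spec()] supplying rate, duration, beta; its
#'   `tauc_s` is overridden per speed and its seed offsets the per-stream
#'   seeds.
#' @param tauc_noflow_s Decorrelation time for the no-flow stream; must be
#'   much longer than any flow `tauc`. Default 100x the slowest flow.
#' @return A tibble with columns `speed`, `tauc_s`, and a list-column
#'   `stream`; the first row (`speed = 0`) is the no-flow stream.
#' @export
simulate_flow_series <- function(dial_speeds, k, base_spec,
                                 tauc_noflow_s = NULL) {
  if (any(dial_speeds <= 0)) {
    stop_perfopt("perfopt_invalid", "dial speeds must be positive")
  }
  taucs <- k / dial_speeds
  if (is.null(tauc_noflow_s)) tauc_noflow_s <- 100 * max(taucs)
  all_taucs <- c(tauc_noflow_s, taucs)
  speeds <- c(0, dial_speeds)
  streams <- purrr::imap(all_taucs, function(tc, i) {
    simulate_photon_stream(stream_spec(base_spec$mean_rate_hz,
                                       base_spec$duration_s, tc,
                                       base_spec$beta,
                                       seed = base_spec$seed + 1000 * i))
  })
  tibble(speed = speeds, tauc_s = all_taucs, stream = streams)
}

#' Stepped clamp occlusion protocol
#'
#' Minute-by-minute opening gap of a screw clamp placed over the supplying
#' artery: held wide open (3.2 mm) for the first two minutes, tightened by
#' 0.4 mm per minute to full occlusion (0.4 mm) reached at minute 8, held
#' occluded, then reopened with the same step pattern and held open so the
#' protocol spans about 20 minutes.
#'
#' @param variant `"pigs234_hold2"` (full occlusion held 2 min, default) or
#'   `"pig1_hold4"` (held 4 min).
#' @return An `occlusion_protocol` tibble with columns `time_min`, `gap_mm`
#'   (piecewise constant per minute).
#' @export
make_occlusion_protocol <- function(variant = c("pigs234_hold2", "pig1_hold4")) {
  variant <- match.arg(variant)
  hold <- if (variant == "pig1_hold4") 4L else 2L
  closing <- seq(3.2 - 0.4, 0.4, by = -0.4)           # minutes 2..8
  reopening <- seq(0.4 + 0.4, 3.2, by = 0.4)          # same step pattern back
  gaps <- c(3.2, 3.2, closing, rep(0.4, hold - 1), reopening)
  gaps <- c(gaps, rep(3.2, max(0, 20 - length(gaps))))
  gaps <- round(gaps, 6) # the +/-0.4 arithmetic must yield exact levels
  out <- tibble(time_min = seq_along(gaps) - 1, gap_mm = gaps)
  class(out) <- c("occlusion_protocol", class(out))
  attr(out, "variant") <- variant
  out
}

#' @method autoplot occlusion_protocol
#' @export
autoplot.occlusion_protocol <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min, y = .data$gap_mm)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (min)", y = "clamp gap (mm)",
                  title = "Arterial clamp occlusion protocol")
}

#' Simulate a hemodynamic trajectory for a flap scenario
#'
#' Time courses of relative flow, total hemoglobin and oxygen saturation
#' under three scenarios. `normal`: stationary around the healthy levels
#' (19 uM, StO2 0.68) with small fluctuations. `arterial_failure`: inflow is
#' cut, so flow collapses within about a minute and both [HbT] and StO2 fall
#' to low plateaus. `venous_failure`: outflow is blocked, so flow declines
#' with a slower (8 min) time constant while blood pools — [HbT] rises toward
#' an elevated plateau and StO2 falls. The [HbT] direction is therefore the
#' discriminating signature between the two failure modes. Failure onset is
#' at 2 min, after a clean baseline.
#'
#' @param scenario `"normal"`, `"arterial_failure"`, or `"venous_failure"`.
#' @param duration_min Trajectory length (min).
#' @param seed RNG seed for the fluctuations.
#' @param cadence_s Sample spacing (s). Default 7 (the acquisition cycle).
#' @param noise_sd Relative amplitude of multiplicative fluctuations.
#'   Default 0.02.
#' @return A `hemodynamic_trajectory` tibble with columns `time_min`,
#'   `flow_factor`, `hbt_uM`, `sto2`.
#' @export
simulate_failure_trajectory <- function(scenario = c("normal", "arterial_failure",
                                                     "venous_failure"),
                                        duration_min = 20, seed = 1,
                                        cadence_s = 7, noise_sd = 0.02) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  t_min <- seq(0, duration_min, by = cadence_s / 60)
  base <- list(flow = 1, hbt = 19, sto2 = 0.68)
  onset <- 2
  relax <- function(target, tau_min) {
    ifelse(t_min < onset, 1,
           target + (1 - target) * exp(-(t_min - onset) / tau_min))
  }
  traj <- switch(scenario,
    normal = list(flow = rep(1, length(t_min)),
                  hbt = rep(1, length(t_min)),
                  sto2 = rep(1, length(t_min))),
    arterial_failure = list(flow = relax(0.02, 1),
                            hbt = relax(0.537, 1),   # -46% plateau
                            sto2 = relax(0.24, 1)),  # -76% plateau
    venous_failure = list(flow = relax(0.15, 8),
                          hbt = relax(2.633, 8),     # +163% plateau
                          sto2 = relax(0.037, 8))    # -96% plateau
  )
  jitter <- function(n) 1 + rnorm(n, sd = noise_sd)
  n <- length(t_min)
  out <- tibble(
    time_min = t_min,
    flow_factor = pmin(pmax(base$flow * traj$flow * jitter(n), 0), 1),
    hbt_uM = pmax(base$hbt * traj$hbt * jitter(n), 0),
    sto2 = pmin(pmax(base$sto2 * traj$sto2 * jitter(n), 0), 1)
  )
  class(out) <- c("hemodynamic_trajectory", class(out))
  attr(out, "scenario") <- scenario
  out
}

#' @method autoplot hemodynamic_trajectory
#' @export
autoplot.hemodynamic_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"time_min",
                            names_to = "parameter")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = sprintf("Hemodynamic trajectory (%s)",
                                  attr(object, "scenario")))
}

#' Render a trajectory into synthetic measurements
#'
#' Turns a hemodynamic trajectory into the raw data the analysis pipeline
#' consumes: per time point, a photon time-tag stream whose decorrelation
#' time scales as `tauc_base / flow_factor` (flow floored at `flow_floor` so
#' the decay stays resolvable) and a reflectance spectrum from the forward
#' model at the trajectory's ([HbT], StO2) with multiplicative Gaussian
#' noise. Deterministic per `seed`.
#'
#' @param trajectory A [simulate_failure_trajectory()] tibble.
#' @param lut A [build_lut()] table.
#' @param eps Extinction table.
#' @param base_spec A [stream_spec()] giving the baseline (flow factor 1)
#'   stream statistics; per-point seeds derive from `seed`.
#' @param wavelengths_nm Spectral grid for the rendered spectra.
#' @param A,B,scale Scattering amplitude/power and instrument scale used in
#'   the forward model.
#' @param noise Multiplicative Gaussian noise SD on spectra. Default 0.01.
#' @param flow_floor Lower bound applied to `flow_factor` when scaling
#'   `tauc`. Default 0.05.
#' @param seed Master seed.
#' @param tick_seconds Tagger tick (s).
#' @return A `synthetic_experiment` list: the trajectory, a tibble `data`
#'   with list-columns `stream` and `spectrum`, and the generator truth.
#' @export
render_experiment <- function(trajectory, lut, eps, base_spec,
                              wavelengths_nm = seq(500, 650, by = 10),
                              A = 20, B = 1.2, scale = 1, noise = 0.01,
                              flow_floor = 0.05, seed = 1,
                              tick_seconds = 80e-9) {
  stopifnot(inherits(trajectory, "hemodynamic_trajectory"))
  set.seed(seed)
  spec_seeds <- sample.int(2^30, nrow(trajectory))
  rows <- purrr::pmap(
    list(trajectory$time_min, trajectory$flow_factor, trajectory$hbt_uM,
         trajectory$sto2, spec_seeds),
    function(tm, ff, hbt, sto2, s) {
      tauc <- base_spec$tauc_s / max(ff, flow_floor)
      stream <- simulate_photon_stream(
        stream_spec(base_spec$mean_rate_hz, base_spec$duration_s, tauc,
                    base_spec$beta, seed = s),
        tick_seconds = tick_seconds)
      params <- tissue_model_params(hbt, sto2, A, B)
      clean <- model_spectrum(params, lut, eps, wavelengths_nm, scale)
      set.seed(s + 1)
      noisy <- clean$value * (1 + rnorm(length(wavelengths_nm), sd = noise))
      spectrum <- reflectance_spectrum(wavelengths_nm, pmax(noisy, 1e-12),
                                       stage = "calibrated")
      list(stream = stream, spectrum = spectrum)
    })
  structure(list(
    trajectory = trajectory,
    data = tibble(time_min = trajectory$time_min,
                  stream = purrr::map(rows, "stream"),
                  spectrum = purrr::map(rows, "spectrum")),
    truth = list(scenario = attr(trajectory, "scenario"), A = A, B = B,
                 scale = scale, noise = noise, flow_floor = flow_floor,
                 base_spec = unclass(base_spec), seed = seed,
                 wavelengths_nm = wavelengths_nm)
  ), class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("<synthetic_experiment> scenario '%s', %d time points over %.3g min\n",
              x$truth$scenario, nrow(x$data), max(x$data$time_min)))
  invisible(x)
}

#' Write / read a synthetic experiment as a directory of plain files
#'
#' Layout: `timetags/scan_<i>.csv`, `spectra/scan_<i>.tsv`,
#' `trajectory.tsv`, `truth.json`.
#'
#' @param experiment A [render_experiment()] result.
#' @param dir Directory path (created if missing).
#' @return `read_experiment` returns a `synthetic_experiment`;
#'   `write_experiment` returns `dir` invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(file.path(dir, "timetags"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(experiment$data))) {
    write_timetags(experiment$data$stream[[i]],
                   file.path(dir, "timetags", sprintf("scan_%04d.csv", i)))
    write_spectrum(experiment$data$spectrum[[i]],
                   file.path(dir, "spectra", sprintf("scan_%04d.tsv", i)))
  }
  utils::write.table(as_tibble(experiment$trajectory),
                     file.path(dir, "trajectory.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- experiment$truth
  truth$scenario_attr <- attr(experiment$trajectory, "scenario")
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  traj <- utils::read.table(file.path(dir, "trajectory.tsv"), header = TRUE,
                            sep = "\t")
  traj <- as_tibble(traj)
  class(traj) <- c("hemodynamic_trajectory", class(traj))
  attr(traj, "scenario") <- truth$scenario
  tag_files <- sort(list.files(file.path(dir, "timetags"), full.names = TRUE))
  spec_files <- sort(list.files(file.path(dir, "spectra"), full.names = TRUE))
  structure(list(
    trajectory = traj,
    data = tibble(time_min = traj$time_min,
                  stream = purrr::map(tag_files, read_timetags),
                  spectrum = purrr::map(spec_files, read_spectrum)),
    truth = truth
  ), class = "synthetic_experiment")
}
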