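#' Baseline-referenced percent change with propagated uncertainty
#'
#' `P = 100 * (mean(response) - mean(baseline)) / mean(baseline)`, with the
#' uncertainty from first-order propagation of error treating the two means
#' as independent with standard deviations `sd_x` (baseline) and `sd_y`
#' (response): `sigma_P = 100 * sqrt((sd_y / xbar)^2 + (ybar * sd_x /
#' xbar^2)^2)`. Standard deviations (not standard errors) of the scan sets
#' are used.
#'
#' @param baseline,response Non-empty numeric vectors of per-scan values.
#' @return A one-row `response_measure` tibble: `percent_change`,
#'   `uncertainty`, the group means/SDs and counts.
#' @export
percent_change <- function(baseline, response) {
  baseline <- baseline[is.finite(baseline)]
  response <- response[is.finite(response)]
  if (!length(baseline) || !length(response)) {
    stop_perfopt("perfopt_invalid", "baseline and response must be non-empty")
  }
  xbar <- mean(baseline)
  ybar <- mean(response)
  if (xbar == 0) {
    stop_perfopt("perfopt_undefined_response", "baseline mean is zero")
  }
  sx <- if (length(baseline) > 1) sd(baseline) else 0
  sy <- if (length(response) > 1) sd(response) else 0
  out <- tibble(
    percent_change = 100 * (ybar - xbar) / xbar,
    uncertainty = 100 * sqrt((sy / xbar)^2 + (ybar * sx / xbar^2)^2),
    baseline_mean = xbar, baseline_sd = sx,
    response_mean = ybar, response_sd = sy,
    n_baseline = length(baseline), n_response = length(response)
  )
  class(out) <- c("response_measure", class(out))
  out
}

#' Select baseline scans from a timestamped series
#'
#' Two conventions: `edges_2min` takes the scans in the first and last two
#' minutes of the record (the clamp is wide open at both ends of a stepped
#' occlusion protocol); `first_three` takes the first three scans (the
#' pre-ligation baseline of a failure simulation).
#'
#' @param series A tibble with a `time_min` column.
#' @param mode `"edges_2min"` or `"first_three"`.
#' @return The baseline subset of `series`.
#' @export
select_baseline <- function(series, mode = c("edges_2min", "first_three")) {
  mode <- match.arg(mode)
  if (!"time_min" %in% names(series)) {
    stop_perfopt("perfopt_invalid", "series must have a time_min column")
  }
  if (mode == "first_three") {
    if (nrow(series) < 3) {
      stop_perfopt("perfopt_invalid", "need at least 3 points for first_three")
    }
    return(series[1:3, ])
  }
  t_end <- max(series$time_min)
  if (t_end < 4) {
    stop_perfopt("perfopt_invalid",
                 "series shorter than 4 min: the 2-min edge windows overlap")
  }
  series[series$time_min < 2 | series$time_min > t_end - 2, ]
}

#' Classify vascular compromise from per-parameter responses
#'
#' Operationalizes the direction-of-change signature: both failure modes
#' slow the flow (half-decay lag up) and deoxygenate the flap (StO2 down),
#' and only the total-hemoglobin direction separates them — venous
#' congestion pools blood ([HbT] up), arterial failure drains it
#' ([HbT] down).
#'
#' @param responses Named list of `response_measure` rows (or percent-change
#'   numbers) for `tau_half`, `sto2`, `hbt`.
#' @param thresholds Named list of positive percent thresholds: `flow`
#'   (minimum tau-half increase), `sto2` (minimum StO2 drop), `hbt` (minimum
#'   [HbT] excursion in either direction). Defaults 50, 20, 20 — well inside
#'   the reported failure effect sizes while rejecting normal fluctuation.
#' @return A `compromise_call` list: `label` in `none`, `arterial`,
#'   `venous`, `indeterminate`, plus the signed evidence.
#' @export
classify_compromise <- function(responses,
                                thresholds = list(flow = 50, sto2 = 20, hbt = 20)) {
  need <- c("tau_half", "sto2", "hbt")
  if (!all(need %in% names(responses))) {
    stop_perfopt("perfopt_invalid", sprintf(
      "responses must include %s", paste(need, collapse = ", ")))
  }
  val <- function(x) if (is.data.frame(x)) x$percent_change[1] else as.numeric(x)
  ev <- purrr::map_dbl(responses[need], val)
  if (anyNA(ev)) {
    stop_perfopt("perfopt_invalid", "missing percent change for a parameter")
  }
  flow_up <- ev[["tau_half"]] > thresholds$flow
  sto2_down <- ev[["sto2"]] < -thresholds$sto2
  label <- if (flow_up && sto2_down) {
    if (ev[["hbt"]] > thresholds$hbt) "venous"
    else if (ev[["hbt"]] < -thresholds$hbt) "arterial"
    else "indeterminate"
  } else if (!flow_up && !sto2_down && abs(ev[["hbt"]]) <= thresholds$hbt) {
    "none"
  } else {
    "indeterminate"
  }
  structure(list(label = label, evidence = ev, thresholds = thresholds),
            class = "compromise_call")
}

#' @export
print.compromise_call <- function(x, ...) {
  cat(sprintf(
    "<compromise_call> %s (tau_half %+0.1f%%, StO2 %+0.1f%%, HbT %+0.1f%%)\n",
    x$label, x$evidence[["tau_half"]], x$evidence[["sto2"]], x$evidence[["hbt"]]))
  invisible(x)
}

#' Analyze one synthetic (or matching on-disk) experiment end to end
#'
#' Per time point: the photon stream is binned, autocorrelated (linear FFT
#' estimator), logarithmically downsampled and reduced to the half-decay lag;
#' the spectrum is inverted against the lookup table for [HbT] and StO2.
#' Scans whose half-decay estimation fails (flat curve) are recorded as
#' missing, excluded from the means, and counted. Baseline-referenced
#' percent changes with propagated uncertainty are computed for the three
#' parameters and the compromise classification applied.
#'
#' @param experiment A [render_experiment()] result, or a directory written
#'   by [write_experiment()].
#' @param lut A [build_lut()] table (the same geometry as the generator for
#'   synthetic data).
#' @param eps Extinction table.
#' @param scale Instrument scaling ratio used in the inversion.
#' @param baseline_mode Passed to [select_baseline()]. Default
#'   `"first_three"`.
#' @param bin_seconds Intensity binning for the correlator. Default 10 us.
#' @param max_lag_s Longest correlation lag analyzed. Default a quarter of
#'   the record.
#' @param points_per_decade Logarithmic filter density. Default 15.
#' @param plateau_cfg A [plateau_config()].
#' @param thresholds Classification thresholds, see [classify_compromise()].
#' @param n_starts Optimization starts per spectral fit. Default 3.
#' @return An `occlusion_report` list: `series` (per-scan tibble),
#'   `responses` (per-parameter `response_measure`s), `call` (the
#'   [classify_compromise()] result), and counts of failed scans. Has
#'   [tidy()] and [glance()] methods.
#' @export
run_occlusion_analysis <- function(experiment, lut, eps, scale = 1,
                                   baseline_mode = "first_three",
                                   bin_seconds = 1e-5, max_lag_s = NULL,
                                   points_per_decade = 15,
                                   plateau_cfg = plateau_config(),
                                   thresholds = list(flow = 50, sto2 = 20, hbt = 20),
                                   n_starts = 3) {
  if (is.character(experiment)) experiment <- read_experiment(experiment)
  stopifnot(inherits(experiment, "synthetic_experiment"))
  n_scan <- nrow(experiment$data)
  rows <- vector("list", n_scan)
  prev_par <- NULL # warm start: tissue composition drifts slowly scan-to-scan
  for (i in seq_len(n_scan)) {
    stream <- experiment$data$stream[[i]]
    spectrum <- experiment$data$spectrum[[i]]
    tau <- tryCatch({
      trace <- bin_timetags(stream, bin_seconds)
      mls <- max_lag_s %||% (stream_duration(stream) / 4)
      curve <- g2_fft(trace, mode = "linear",
                      max_lag_bins = floor(mls / trace$bin_seconds))
      est <- estimate_tau_half(log_downsample(curve, points_per_decade),
                               plateau_cfg)
      c(est$tau_half, est$spread)
    }, perfopt_error = function(e) c(NA_real_, NA_real_))
    fit <- tryCatch(
      fit_spectrum(spectrum, lut, eps, scale = scale,
                   n_starts = if (is.null(prev_par)) n_starts + 3 else n_starts,
                   seed = 1000 + i, init = prev_par),
      perfopt_error = function(e) NULL)
    if (!is.null(fit)) {
      prev_par <- c(fit$params$hbt_uM, fit$params$sto2, fit$params$A,
                    fit$params$B)
    }
    rows[[i]] <- tibble(
      time_min = experiment$data$time_min[i],
      tau_half_s = tau[1], tau_half_spread_s = tau[2],
      hbt_uM = if (is.null(fit)) NA_real_ else fit$params$hbt_uM,
      sto2 = if (is.null(fit)) NA_real_ else fit$params$sto2,
      fit_objective = if (is.null(fit)) NA_real_ else fit$objective)
  }
  series <- dplyr::bind_rows(rows)

  base <- select_baseline(series, baseline_mode)
  nonbase <- series[!series$time_min %in% base$time_min, ]
  if (baseline_mode == "edges_2min") {
    # maximum occlusion sits at mid-protocol for the symmetric clamp series
    mid <- max(series$time_min) / 2
    resp <- nonbase[nonbase$time_min >= mid - 2 & nonbase$time_min <= mid, ]
  } else {
    # failure plateaus: take the final quarter of the record
    resp <- nonbase[nonbase$time_min >= max(series$time_min) * 0.75, ]
  }
  if (nrow(resp) < 1) resp <- nonbase
  responses <- list(
    tau_half = percent_change(base$tau_half_s, resp$tau_half_s),
    hbt = percent_change(base$hbt_uM, resp$hbt_uM),
    sto2 = percent_change(base$sto2, resp$sto2)
  )
  call <- classify_compromise(responses, thresholds)
  structure(list(series = series, responses = responses, call = call,
                 n_failed_tau = sum(is.na(series$tau_half_s)),
                 n_failed_fit = sum(is.na(series$hbt_uM)),
                 truth = experiment$truth),
            class = "occlusion_report")
}

#' @export
print.occlusion_report <- function(x, ...) {
  cat(sprintf("<occlusion_report> %d scans (%d tau-half failures, %d fit failures)\n",
              nrow(x$series), x$n_failed_tau, x$n_failed_fit))
  print(x$call)
  invisible(x)
}

#' @method tidy occlusion_report
#' @export
tidy.occlusion_report <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$responses, function(r, nm) {
    dplyr::mutate(as_tibble(r), parameter = nm, .before = 1)
  }))
}

#' @method glance occlusion_report
#' @export
glance.occlusion_report <- function(x, ...) {
  tibble(label = x$call$label, n_scans = nrow(x$series),
         n_failed_tau = x$n_failed_tau, n_failed_fit = x$n_failed_fit)
}

#' @method autoplot occlusion_report
#' @export
autoplot.occlusion_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$series,
                            c("tau_half_s", "hbt_uM", "sto2"),
                            names_to = "parameter")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = sprintf("Occlusion analysis (call: %s)",
                                  object$call$label))
}

#' Write an analysis report to disk
#'
#' Time series as TSV; responses and the classification as JSON.
#'
#' @param report An `occlusion_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "occlusion_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$series, file.path(dir, "series.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(responses = purrr::map(report$responses, ~as.list(.x[1, ])),
         call = list(label = report$call$label,
                     evidence = as.list(report$call$evidence),
                     thresholds = report$call$thresholds),
         n_failed_tau = report$n_failed_tau,
         n_failed_fit = report$n_failed_fit),
    file.path(dir, "responses.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
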