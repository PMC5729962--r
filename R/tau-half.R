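#' Plateau enumeration configuration for the tau-half statistic
#'
#' The half-decay lag of a g2 curve is defined relative to its top and bottom
#' plateaus. Measured curves are noisy and plateaus may be poorly defined, so
#' instead of a single plateau choice the estimator enumerates many candidate
#' plateau ranges and averages the resulting half-decay lags. This object
#' fixes the enumeration: window lengths, the leading/trailing regions the
#' windows may occupy, and a minimum top-bottom contrast guard that rejects
#' flat (no-decay) curves.
#'
#' @param top_window_lengths,bottom_window_lengths Integer window lengths
#'   (each >= 2) for candidate top/bottom plateau ranges. Default `c(3, 4, 5)`.
#' @param top_region_points,bottom_region_points How many leading (trailing)
#'   curve points are eligible for top (bottom) windows. Default 10.
#' @param min_contrast Required `mean_top - mean_bottom` for a pair to be
#'   retained. `NULL` (default) uses a data-driven guard of 3 standard
#'   deviations of the bottom region (floored at a tiny positive value for
#'   noiseless curves).
#' @return A `plateau_config` list.
#' @export
plateau_config <- function(top_window_lengths = c(3L, 4L, 5L),
                           bottom_window_lengths = c(3L, 4L, 5L),
                           top_region_points = 10L,
                           bottom_region_points = 10L,
                           min_contrast = NULL) {
  top_window_lengths <- as.integer(top_window_lengths)
  bottom_window_lengths <- as.integer(bottom_window_lengths)
  if (any(c(top_window_lengths, bottom_window_lengths) < 2)) {
    stop_perfopt("perfopt_invalid", "window lengths must be >= 2")
  }
  if (top_region_points < max(top_window_lengths) ||
      bottom_region_points < max(bottom_window_lengths)) {
    stop_perfopt("perfopt_invalid",
                 "region sizes must be >= the largest window length")
  }
  if (!is.null(min_contrast) && min_contrast <= 0) {
    stop_perfopt("perfopt_invalid", "min_contrast must be positive")
  }
  structure(list(top_window_lengths = top_window_lengths,
                 bottom_window_lengths = bottom_window_lengths,
                 top_region_points = as.integer(top_region_points),
                 bottom_region_points = as.integer(bottom_region_points),
                 min_contrast = min_contrast),
            class = "plateau_config")
}

window_means <- function(values, lengths) {
  n <- length(values)
  out <- numeric(0)
  for (L in lengths) {
    if (L > n) next
    for (s in seq_len(n - L + 1)) {
      out <- c(out, mean(values[s:(s + L - 1)]))
    }
  }
  out
}

#' Enumerate candidate plateau pairs of a g2 curve
#'
#' Top windows are all contiguous runs of the configured lengths within the
#' first `top_region_points` lags; bottom windows likewise within the last
#' `bottom_region_points` lags. Every (top, bottom) combination whose mean
#' contrast reaches `min_contrast` is retained.
#'
#' @param curve A [g2_curve()], typically after [log_downsample()].
#' @param cfg A [plateau_config()].
#' @return A tibble with columns `top_mean`, `bottom_mean`.
#' @export
enumerate_plateau_pairs <- function(curve, cfg = plateau_config()) {
  stopifnot(inherits(curve, "g2_curve"), inherits(cfg, "plateau_config"))
  n <- nrow(curve)
  if (n < cfg$top_region_points + cfg$bottom_region_points) {
    stop_perfopt("perfopt_invalid", sprintf(
      "curve has %d points; need at least %d for the configured plateau regions",
      n, cfg$top_region_points + cfg$bottom_region_points))
  }
  top_vals <- curve$g2[seq_len(cfg$top_region_points)]
  bot_vals <- curve$g2[(n - cfg$bottom_region_points + 1):n]
  tops <- window_means(top_vals, cfg$top_window_lengths)
  bots <- window_means(bot_vals, cfg$bottom_window_lengths)
  min_contrast <- cfg$min_contrast
  if (is.null(min_contrast)) {
    min_contrast <- max(3 * sd(bot_vals), sqrt(.Machine$double.eps))
  }
  pairs <- tidyr::expand_grid(top_mean = tops, bottom_mean = bots)
  pairs <- dplyr::filter(pairs, .data$top_mean - .data$bottom_mean >= min_contrast)
  if (!nrow(pairs)) {
    stop_perfopt("perfopt_flat_curve",
                 "no plateau pair reaches the contrast guard: flat / no-decay curve")
  }
  pairs
}

#' Half-decay lag for one plateau pair
#'
#' Returns the lag at which the curve first crosses downward through the
#' midpoint `(top_mean + bottom_mean) / 2`, interpolated linearly in g2
#' versus log(lag) between the bracketing samples. The first crossing is
#' used because noisy curves can re-cross.
#'
#' @param curve A [g2_curve()].
#' @param top_mean,bottom_mean Plateau means with `top_mean > bottom_mean`.
#' @return The half-decay lag in seconds.
#' @export
tau_half_sub <- function(curve, top_mean, bottom_mean) {
  stopifnot(inherits(curve, "g2_curve"))
  if (top_mean <= bottom_mean) {
    stop_perfopt("perfopt_invalid", "top_mean must exceed bottom_mean")
  }
  target <- (top_mean + bottom_mean) / 2
  g <- curve$g2
  below <- which(g < target)
  j <- below[below > 1 & g[below - 1] >= target][1]
  if (is.na(j)) {
    stop_perfopt("perfopt_no_crossing",
                 "curve never crosses the half-decay target from above")
  }
  lt0 <- log(curve$lag_s[j - 1])
  lt1 <- log(curve$lag_s[j])
  frac <- (target - g[j - 1]) / (g[j] - g[j - 1])
  exp(lt0 + frac * (lt1 - lt0))
}

#' Robust half-decay statistic of a g2 curve
#'
#' For every retained plateau pair the half-decay lag is computed with
#' [tau_half_sub()]; pairs whose crossing search fails are dropped (and
#' counted), never imputed. The representative tau-half is the plain mean of
#' the per-pair values and the spread their standard deviation — the
#' model-free blood-flow surrogate used throughout the package.
#'
#' @param curve A [g2_curve()].
#' @param cfg A [plateau_config()].
#' @return A `tau_half_estimate` with fields `tau_half`, `spread`,
#'   `sub_values`, `n_pairs`, `n_failed`. Has [tidy()] and [glance()]
#'   methods.
#' @export
estimate_tau_half <- function(curve, cfg = plateau_config()) {
  pairs <- enumerate_plateau_pairs(curve, cfg)
  subs <- purrr::pmap_dbl(pairs, function(top_mean, bottom_mean) {
    tryCatch(tau_half_sub(curve, top_mean, bottom_mean),
             perfopt_no_crossing = function(e) NA_real_)
  })
  ok <- !is.na(subs)
  if (!any(ok)) {
    stop_perfopt("perfopt_no_decay",
                 "every plateau pair failed the half-decay crossing search")
  }
  sub_values <- subs[ok]
  structure(list(
    tau_half = mean(sub_values),
    spread = if (length(sub_values) > 1) sd(sub_values) else 0,
    sub_values = sub_values,
    n_pairs = length(sub_values),
    n_failed = sum(!ok)
  ), class = "tau_half_estimate")
}

#' @export
print.tau_half_estimate <- function(x, ...) {
  cat(sprintf("<tau_half_estimate> tau_half = %.4g s (spread %.2g s, %d pairs, %d failed)\n",
              x$tau_half, x$spread, x$n_pairs, x$n_failed))
  invisible(x)
}

#' @method tidy tau_half_estimate
#' @export
tidy.tau_half_estimate <- function(x, ...) {
  tibble(sub_value_s = x$sub_values)
}

#' @method glance tau_half_estimate
#' @export
glance.tau_half_estimate <- function(x, ...) {
  tibble(tau_half_s = x$tau_half, spread_s = x$spread,
         n_pairs = x$n_pairs, n_failed = x$n_failed)
}
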