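#' Intensity autocorrelation curves
#'
#' All correlator estimators return a `g2_curve`: a tibble with columns
#' `lag_s` (strictly increasing positive lags, seconds) and `g2`, carrying the
#' estimator name and record metadata as attributes. Lag zero (the shot-noise
#' self term) is excluded everywhere, following standard photon-correlation
#' practice. The normalization convention is fixed so a constant intensity
#' gives g2 = 1 exactly at every lag.
#'
#' @param lag_s,g2 Numeric vectors of equal length.
#' @param method Estimator label (`"fft"`, `"multitau"`, `"direct"`, ...).
#' @param n_photons,duration_seconds Record metadata (optional).
#' @param meta Named list of estimator settings.
#' @return A tibble of class `g2_curve`.
#' @export
g2_curve <- function(lag_s, g2, method = "unknown", n_photons = NA_real_,
                     duration_seconds = NA_real_, meta = list()) {
  if (length(lag_s) != length(g2)) {
    stop_perfopt("perfopt_invalid", "lag_s and g2 must have equal length")
  }
  if (length(lag_s) && (any(lag_s <= 0) || is.unsorted(lag_s, strictly = TRUE))) {
    stop_perfopt("perfopt_invalid", "lags must be positive and strictly increasing")
  }
  if (anyNA(g2) || any(!is.finite(g2))) {
    stop_perfopt("perfopt_invalid", "g2 values must be finite")
  }
  out <- tibble(lag_s = as.numeric(lag_s), g2 = as.numeric(g2))
  class(out) <- c("g2_curve", class(out))
  attr(out, "method") <- method
  attr(out, "n_photons") <- n_photons
  attr(out, "duration_seconds") <- duration_seconds
  attr(out, "meta") <- meta
  out
}

check_trace_for_g2 <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (trace$n_bins < 2) {
    stop_perfopt("perfopt_invalid", "trace must have at least 2 bins")
  }
  if (sum(trace$counts) == 0) {
    stop_perfopt("perfopt_zero_trace",
                 "all-zero trace: g2 normalization by <I>^2 is undefined")
  }
  invisible(trace)
}

#' FFT intensity autocorrelation estimator
#'
#' Computes g2(tau) from an intensity trace via the Wiener–Khinchin route:
#' the inverse FFT of the power spectrum of I(t), normalized by the squared
#' mean intensity. `mode = "circular"` is the literal periodic estimator,
#' g2(k) = (1/N) sum_j I_j I_(j+k mod N) / <I>^2. `mode = "linear"` (default)
#' zero-pads to at least 2N so no wrap-around occurs and normalizes lag k by
#' its N-k overlapping terms, matching the brute-force estimator
#' [g2_direct()] to rounding error.
#'
#' @param trace An `intensity_trace` (see [bin_timetags()]).
#' @param mode `"linear"` (zero-padded, default) or `"circular"`.
#' @param max_lag_bins Largest lag to return, in bins. Defaults to `N - 1`.
#' @return A [g2_curve()].
#' @export
g2_fft <- function(trace, mode = c("linear", "circular"), max_lag_bins = NULL) {
  mode <- match.arg(mode)
  check_trace_for_g2(trace)
  I <- trace$counts
  N <- length(I)
  Ibar <- mean(I)
  if (is.null(max_lag_bins)) max_lag_bins <- N - 1
  max_lag_bins <- min(max_lag_bins, N - 1)
  k <- seq_len(max_lag_bins)
  if (mode == "circular") {
    ac <- Re(fft(Mod(fft(I))^2, inverse = TRUE)) / N
    g2 <- ac[k + 1] / (N * Ibar^2)
  } else {
    M <- 2^ceiling(log2(2 * N))
    Ip <- c(I, numeric(M - N))
    ac <- Re(fft(Mod(fft(Ip))^2, inverse = TRUE)) / M
    g2 <- ac[k + 1] / ((N - k) * Ibar^2)
  }
  g2_curve(k * trace$bin_seconds, g2, method = "fft",
           n_photons = sum(I), duration_seconds = N * trace$bin_seconds,
           meta = list(mode = mode, bin_seconds = trace$bin_seconds))
}

#' Brute-force direct correlator (oracle)
#'
#' Literal time-domain estimator with the same normalization conventions as
#' `g2_fft(mode = "linear")`: g2(k) = mean over the N-k overlapping products
#' I_j I_(j+k), divided by <I>^2 (mean over the full trace). Slow on long
#' traces; its role is ground truth for the FFT path.
#'
#' @param trace An `intensity_trace`.
#' @param lags_bins Integer lag offsets (>= 1, < N).
#' @return A [g2_curve()].
#' @export
g2_direct <- function(trace, lags_bins = seq_len(min(trace$n_bins - 1, 256))) {
  check_trace_for_g2(trace)
  I <- trace$counts
  N <- length(I)
  lags_bins <- as.integer(lags_bins)
  if (any(lags_bins < 1) || any(lags_bins >= N)) {
    stop_perfopt("perfopt_invalid", "lag offsets must be >= 1 and < N")
  }
  Ibar <- mean(I)
  g2 <- vapply(lags_bins, function(k) {
    sum(I[seq_len(N - k)] * I[(k + 1):N]) / ((N - k) * Ibar^2)
  }, numeric(1))
  g2_curve(lags_bins * trace$bin_seconds, g2, method = "direct",
           n_photons = sum(I), duration_seconds = N * trace$bin_seconds,
           meta = list(bin_seconds = trace$bin_seconds))
}

#' Multitau intensity autocorrelation estimator
#'
#' Standard multitau scheme with quasi-logarithmic lag spacing: `m` linear
#' lags at the base bin width, then successive pairwise bin-doubling with
#' `m/2` new lags per level. Normalization is symmetric: each lag is divided
#' by the product of the means of the two overlapping monitor windows, so a
#' constant trace gives exactly 1 and count scaling cancels.
#'
#' @param trace An `intensity_trace`.
#' @param m Lags in the base level; even, >= 8. Default 16.
#' @param levels Number of levels. Default: as many as the trace supports.
#' @return A [g2_curve()]; lag count is `m + (levels - 1) * m/2`.
#' @export
g2_multitau <- function(trace, m = 16, levels = NULL) {
  check_trace_for_g2(trace)
  m <- as.integer(m)
  if (m < 8 || m %% 2 != 0) {
    stop_perfopt("perfopt_invalid", "m must be even and >= 8")
  }
  I <- trace$counts
  max_levels <- 1L
  n <- length(I)
  while (n %/% 2 >= m + 1) { # next level needs lags up to m at halved length
    max_levels <- max_levels + 1L
    n <- n %/% 2
  }
  if (is.null(levels)) levels <- max_levels
  levels <- as.integer(levels)
  if (levels < 1) stop_perfopt("perfopt_invalid", "levels must be >= 1")
  if (levels > max_levels) {
    warn(sprintf("trace too short for %d levels; truncating to %d", levels, max_levels))
    levels <- max_levels
  }

  sym_g2 <- function(x, k) {
    n <- length(x)
    left <- x[seq_len(n - k)]
    right <- x[(k + 1):n]
    mean(left * right) / (mean(left) * mean(right))
  }

  lag_s <- numeric(0)
  g2 <- numeric(0)
  x <- I
  bin <- trace$bin_seconds
  for (lev in seq_len(levels)) {
    ks <- if (lev == 1) seq_len(m) else (m %/% 2 + 1):m
    lag_s <- c(lag_s, ks * bin)
    g2 <- c(g2, vapply(ks, function(k) sym_g2(x, k), numeric(1)))
    if (lev < levels) {
      nn <- (length(x) %/% 2) * 2
      x <- x[seq(1, nn, by = 2)] + x[seq(2, nn, by = 2)]
      bin <- bin * 2
    }
  }
  g2_curve(lag_s, g2, method = "multitau",
           n_photons = sum(I), duration_seconds = length(I) * trace$bin_seconds,
           meta = list(m = m, levels = levels, bin_seconds = trace$bin_seconds))
}

#' Logarithmic downsampling of an autocorrelation curve
#'
#' Smooths a raw g2 curve by averaging within logarithmically spaced lag
#' bins: the output lag is the geometric mean of the member lags and the
#' output g2 their arithmetic mean. Empty bins are dropped; a curve already
#' at or below the target density passes through unchanged.
#'
#' @param curve A [g2_curve()].
#' @param points_per_decade Target density; >= 1. Default 15.
#' @return A [g2_curve()] with strictly increasing lags.
#' @export
log_downsample <- function(curve, points_per_decade = 15) {
  stopifnot(inherits(curve, "g2_curve"))
  if (points_per_decade < 1) {
    stop_perfopt("perfopt_invalid", "points_per_decade must be >= 1")
  }
  if (nrow(curve) <= 1) return(curve)
  lo <- floor(log10(min(curve$lag_s)) * points_per_decade) / points_per_decade
  hi <- ceiling(log10(max(curve$lag_s)) * points_per_decade) / points_per_decade
  # the last break must lie strictly above the largest lag so that a point
  # sitting exactly on a break edge keeps its own bin
  breaks <- 10^seq(lo, hi + 1.5 / points_per_decade, by = 1 / points_per_decade)
  bin <- findInterval(curve$lag_s, breaks)
  lag_out <- vapply(split(curve$lag_s, bin), function(v) exp(mean(log(v))), numeric(1))
  g2_out <- vapply(split(curve$g2, bin), mean, numeric(1))
  ord <- order(lag_out)
  g2_curve(lag_out[ord], g2_out[ord], method = attr(curve, "method"),
           n_photons = attr(curve, "n_photons"),
           duration_seconds = attr(curve, "duration_seconds"),
           meta = c(attr(curve, "meta"),
                    list(points_per_decade = points_per_decade)))
}

#' Read and write autocorrelation curves as TSV
#'
#' Format: `#` metadata header lines then `lag_s<TAB>g2` rows.
#'
#' @param curve A [g2_curve()].
#' @param path File path.
#' @return `read_g2_curve` returns a [g2_curve()]; `write_g2_curve` returns
#'   `path` invisibly.
#' @export
write_g2_curve <- function(curve, path) {
  stopifnot(inherits(curve, "g2_curve"))
  hdr <- c(sprintf("#method=%s", attr(curve, "method")),
           sprintf("#n_photons=%.17g", attr(curve, "n_photons")),
           sprintf("#duration_seconds=%.17g", attr(curve, "duration_seconds")),
           "lag_s\tg2")
  rows <- sprintf("%.17g\t%.17g", curve$lag_s, curve$g2)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_g2_curve
#' @export
read_g2_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NA_character_) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(m)) return(default)
    sub(paste0("^#", key, "="), "", m[1])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) && grepl("^lag_s", body[1])) body <- body[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  lag <- as.numeric(vapply(parts, `[`, character(1), 1))
  g2 <- as.numeric(vapply(parts, `[`, character(1), 2))
  g2_curve(lag, g2, method = get("method", "unknown"),
           n_photons = as.numeric(get("n_photons", "NA")),
           duration_seconds = as.numeric(get("duration_seconds", "NA")))
}

#' Plot an autocorrelation curve
#'
#' @param object A [g2_curve()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot g2_curve
#' @export
autoplot.g2_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_s, y = .data$g2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(g[2](tau)),
                  title = sprintf("Intensity autocorrelation (%s)", attr(object, "method")))
}
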