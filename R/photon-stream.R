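#' Photon time-tag streams
#'
#' A `photon_stream` holds the arrival times of individually detected photons
#' as integer ticks of the time-tagger clock (default 80 ns per tick), the
#' measurement primitive of diffuse correlation spectroscopy (DCS). Ticks are
#' stored as doubles so records longer than 2^31 ticks are representable
#' exactly (ticks stay below 2^53).
#'
#' @param ticks Non-decreasing vector of non-negative integer arrival times,
#'   in tagger ticks.
#' @param tick_seconds Seconds per tagger tick. Default `80e-9`.
#' @param duration_ticks Total record length in ticks. Defaults to
#'   `max(ticks) + 1` (or 1 for an empty stream).
#' @param channel Detection channel identifier.
#' @return An object of class `photon_stream`.
#' @examples
#' ps <- photon_stream(c(0, 5, 12), duration_ticks = 100)
#' ps
#' @export
photon_stream <- function(ticks, tick_seconds = 80e-9, duration_ticks = NULL,
                          channel = "ch1") {
  ticks <- as.double(ticks)
  if (anyNA(ticks)) stop_perfopt("perfopt_invalid", "ticks must not contain NA")
  if (length(ticks) && any(ticks < 0)) {
    stop_perfopt("perfopt_invalid", "ticks must be non-negative")
  }
  if (length(ticks) && any(ticks != floor(ticks))) {
    stop_perfopt("perfopt_invalid", "ticks must be integers (whole numbers)")
  }
  if (is.unsorted(ticks)) {
    stop_perfopt("perfopt_invalid", "ticks must be non-decreasing (sorted arrival order)")
  }
  if (is.null(duration_ticks)) {
    duration_ticks <- if (length(ticks)) max(ticks) + 1 else 1
  }
  duration_ticks <- as.double(duration_ticks)
  if (!is.finite(duration_ticks) || duration_ticks <= 0) {
    stop_perfopt("perfopt_invalid", "duration_ticks must be a positive number")
  }
  if (length(ticks) && max(ticks) >= duration_ticks) {
    stop_perfopt("perfopt_invalid", "every tick must be < duration_ticks")
  }
  if (!is.finite(tick_seconds) || tick_seconds <= 0) {
    stop_perfopt("perfopt_invalid", "tick_seconds must be positive")
  }
  structure(
    list(ticks = ticks, tick_seconds = tick_seconds,
         duration_ticks = duration_ticks, channel = as.character(channel)),
    class = "photon_stream"
  )
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf(
    "<photon_stream> %s photons, %.4g s record (%g ns/tick), channel '%s', mean rate %.4g Hz\n",
    format(length(x$ticks), big.mark = ","),
    x$duration_ticks * x$tick_seconds, x$tick_seconds * 1e9, x$channel,
    length(x$ticks) / (x$duration_ticks * x$tick_seconds)))
  invisible(x)
}

#' @export
length.photon_stream <- function(x) length(x$ticks)

#' Duration of a photon stream in seconds
#' @param stream A [photon_stream()].
#' @return Record length in seconds.
#' @export
stream_duration <- function(stream) stream$duration_ticks * stream$tick_seconds

#' Bin photon time tags into an intensity trace
#'
#' Counts photons in contiguous half-open intervals `[j*bin, (j+1)*bin)` of
#' equal width, producing the indexed intensity vector that the correlators
#' consume. The bin width must be an exact integer multiple of the tick clock
#' so the lag grid cannot drift against the tagger; a trailing partial bin is
#' discarded, never padded.
#'
#' @param stream A [photon_stream()].
#' @param bin_seconds Bin width in seconds; must be a positive integer
#'   multiple of `tick_seconds`. Default 13 ticks (about 1.04 us at the 80-ns
#'   clock).
#' @return An `intensity_trace`: integer counts per bin plus timing metadata.
#' @examples
#' ps <- photon_stream(c(0, 1, 2, 3), duration_ticks = 4)
#' bin_timetags(ps, bin_seconds = 2 * ps$tick_seconds)$counts
#' @export
bin_timetags <- function(stream, bin_seconds = stream$tick_seconds * 13) {
  stopifnot(inherits(stream, "photon_stream"))
  bin_ticks <- bin_seconds / stream$tick_seconds
  if (bin_seconds < stream$tick_seconds * (1 - 1e-9)) {
    stop_perfopt("perfopt_invalid", "bin_seconds must be >= tick_seconds")
  }
  if (abs(bin_ticks - round(bin_ticks)) > 1e-6 * bin_ticks) {
    stop_perfopt("perfopt_invalid",
                 "bin_seconds must be an integer multiple of tick_seconds")
  }
  bin_ticks <- round(bin_ticks)
  n_bins <- floor(stream$duration_ticks / bin_ticks)
  if (n_bins < 1) {
    stop_perfopt("perfopt_invalid", "record shorter than one bin")
  }
  idx <- floor(stream$ticks / bin_ticks) + 1
  kept <- idx <= n_bins
  counts <- tabulate(idx[kept], nbins = n_bins)
  new_intensity_trace(counts,
                      bin_seconds = bin_ticks * stream$tick_seconds,
                      tick_seconds = stream$tick_seconds,
                      n_discarded = sum(!kept))
}

new_intensity_trace <- function(counts, bin_seconds, tick_seconds = NA_real_,
                                n_discarded = 0L) {
  structure(
    list(counts = as.numeric(counts), bin_seconds = bin_seconds,
         n_bins = length(counts),
         mean_rate = sum(counts) / (length(counts) * bin_seconds),
         tick_seconds = tick_seconds, n_discarded = n_discarded),
    class = "intensity_trace"
  )
}

#' Construct an intensity trace directly from counts
#'
#' Mostly useful in tests and examples; [bin_timetags()] is the normal route.
#'
#' @param counts Non-negative photon counts per bin.
#' @param bin_seconds Bin width in seconds.
#' @return An `intensity_trace`.
#' @export
intensity_trace <- function(counts, bin_seconds) {
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0)) {
    stop_perfopt("perfopt_invalid", "counts must be non-negative")
  }
  if (!is.finite(bin_seconds) || bin_seconds <= 0) {
    stop_perfopt("perfopt_invalid", "bin_seconds must be positive")
  }
  new_intensity_trace(counts, bin_seconds)
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf(
    "<intensity_trace> %s bins of %.3g s (%.4g s total), mean rate %.4g Hz\n",
    format(x$n_bins, big.mark = ","), x$bin_seconds,
    x$n_bins * x$bin_seconds, x$mean_rate))
  invisible(x)
}

#' Rebin an intensity trace to a coarser resolution
#'
#' @param trace An `intensity_trace`.
#' @param factor Integer >= 1; new bin width is `factor` old bins. A trailing
#'   remainder of fewer than `factor` bins is discarded.
#' @return An `intensity_trace`.
#' @export
rebin_trace <- function(trace, factor) {
  stopifnot(inherits(trace, "intensity_trace"))
  factor <- as.integer(factor)
  if (factor < 1) stop_perfopt("perfopt_invalid", "factor must be >= 1")
  if (factor == 1) return(trace)
  n <- (trace$n_bins %/% factor) * factor
  counts <- colSums(matrix(trace$counts[seq_len(n)], nrow = factor))
  new_intensity_trace(counts, trace$bin_seconds * factor, trace$tick_seconds,
                      trace$n_discarded)
}

# ---- I/O --------------------------------------------------------------------

TIMETAG_MAGIC <- "PHTTAG01"

#' Read and write photon time-tag files
#'
#' Two on-disk formats round-trip bit exactly:
#' \describe{
#'   \item{csv}{Text: header lines `#tick_seconds=...`, `#duration_ticks=...`,
#'     `#channel=...`, then one integer tick per line.}
#'   \item{binary}{Packed little-endian: 8-byte magic `PHTTAG01`, two 64-bit
#'     header fields (tick_seconds as IEEE double, duration_ticks as unsigned
#'     64-bit), then the 64-bit tick array.}
#' }
#'
#' @param path File path.
#' @param format `"csv"` or `"binary"`.
#' @param stream A [photon_stream()].
#' @return `read_timetags` returns a [photon_stream()]; `write_timetags`
#'   returns `path` invisibly.
#' @export
read_timetags <- function(path, format = c("csv", "binary")) {
  format <- match.arg(format)
  if (format == "csv") {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    get <- function(key) {
      m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
      if (!length(m)) stop_perfopt("perfopt_format", sprintf("missing header '#%s='", key))
      sub(paste0("^#", key, "="), "", m[1])
    }
    tick_seconds <- as.numeric(get("tick_seconds"))
    duration_ticks <- as.numeric(get("duration_ticks"))
    ch <- tryCatch(get("channel"), error = function(e) "ch1")
    body <- lines[!grepl("^#", lines)]
    body <- body[nzchar(body)]
    ticks <- as.numeric(body)
    if (anyNA(ticks)) stop_perfopt("perfopt_format", "non-numeric tick line in CSV")
    if (is.unsorted(ticks)) {
      stop_perfopt("perfopt_format", "ticks in file are not sorted (non-decreasing)")
    }
    photon_stream(ticks, tick_seconds, duration_ticks, ch)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- rawToChar(readBin(con, "raw", 8))
    if (!identical(magic, TIMETAG_MAGIC)) {
      stop_perfopt("perfopt_format",
                   sprintf("unknown magic bytes '%s' (expected '%s')", magic, TIMETAG_MAGIC))
    }
    tick_seconds <- readBin(con, "double", 1, size = 8, endian = "little")
    duration_ticks <- read_u64(con, 1)
    n <- read_u64(con, 1)
    ticks <- read_u64(con, n)
    if (is.unsorted(ticks)) {
      stop_perfopt("perfopt_format", "ticks in file are not sorted (non-decreasing)")
    }
    photon_stream(ticks, tick_seconds, duration_ticks, "ch1")
  }
}

#' @rdname read_timetags
#' @export
write_timetags <- function(stream, path, format = c("csv", "binary")) {
  stopifnot(inherits(stream, "photon_stream"))
  format <- match.arg(format)
  if (format == "csv") {
    hdr <- c(
      sprintf("#tick_seconds=%.17g", stream$tick_seconds),
      sprintf("#duration_ticks=%.17g", stream$duration_ticks),
      sprintf("#channel=%s", stream$channel)
    )
    writeLines(c(hdr, format(stream$ticks, scientific = FALSE, trim = TRUE)), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(TIMETAG_MAGIC), con)
    writeBin(stream$tick_seconds, con, size = 8, endian = "little")
    write_u64(con, stream$duration_ticks)
    write_u64(con, length(stream$ticks))
    write_u64(con, stream$ticks)
  }
  invisible(path)
}

# 64-bit unsigned integers via two 32-bit words (values < 2^53 exact)
read_u64 <- function(con, n) {
  if (n == 0) return(numeric(0))
  words <- readBin(con, "integer", 2 * n, size = 4, endian = "little")
  lo <- words[seq(1, 2 * n, by = 2)]
  hi <- words[seq(2, 2 * n, by = 2)]
  lo <- ifelse(lo < 0, lo + 2^32, lo)
  hi <- ifelse(hi < 0, hi + 2^32, hi)
  hi * 2^32 + lo
}

write_u64 <- function(con, x) {
  x <- as.double(x)
  hi <- floor(x / 2^32)
  lo <- x - hi * 2^32
  as_i32 <- function(v) as.integer(ifelse(v >= 2^31, v - 2^32, v))
  words <- integer(2 * length(x))
  words[seq(1, length(words), by = 2)] <- as_i32(lo)
  words[seq(2, length(words), by = 2)] <- as_i32(hi)
  writeBin(words, con, size = 4, endian = "little")
}
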