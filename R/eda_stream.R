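#' Construct a skin-conductance stream
#'
#' An `eda_stream` holds an evenly sampled electrodermal activity trace:
#' an absolute start time (POSIX seconds), a sampling rate, and a vector
#' of conductance samples in microsiemens. The default rate of 4 Hz
#' matches the wrist-worn device the package emulates.
#'
#' @param samples numeric vector of conductance values, microsiemens;
#'   must be nonnegative and of length >= 1.
#' @param sample_rate_hz samples per second; must be > 0. Default 4.
#' @param start_time absolute start time, seconds since the POSIX epoch
#'   (a `POSIXct` is accepted and converted). Default 0.
#' @return an object of class `eda_stream`.
#' @examples
#' s <- eda_stream(rep(1, 240))
#' stream_duration(s) # 60 seconds
#' @export
eda_stream <- function(samples, sample_rate_hz = 4, start_time = 0) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a numeric vector of length >= 1", call. = FALSE)
  if (anyNA(samples))
    stop("`samples` must not contain missing values", call. = FALSE)
  if (any(samples < 0))
    stop("EDA samples must be nonnegative (microsiemens)", call. = FALSE)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("`sample_rate_hz` must be a single positive number", call. = FALSE)
  if (inherits(start_time, "POSIXt")) start_time <- as.numeric(start_time)
  if (!is.numeric(start_time) || length(start_time) != 1L || !is.finite(start_time))
    stop("`start_time` must be a single finite number (POSIX seconds)", call. = FALSE)
  structure(
    list(start_time = as.numeric(start_time),
         sample_rate_hz = as.numeric(sample_rate_hz),
         samples = as.numeric(samples)),
    class = "eda_stream"
  )
}

#' Sample time offsets of a stream
#'
#' @param stream an `eda_stream`.
#' @return numeric vector of offsets in seconds from the stream start;
#'   the first sample is at offset 0.
#' @export
stream_times <- function(stream) {
  stopifnot(inherits(stream, "eda_stream"))
  (seq_along(stream$samples) - 1) / stream$sample_rate_hz
}

#' Duration of a stream in seconds
#'
#' @param stream an `eda_stream`.
#' @return `length(samples) / sample_rate_hz`, seconds.
#' @export
stream_duration <- function(stream) {
  stopifnot(inherits(stream, "eda_stream"))
  length(stream$samples) / stream$sample_rate_hz
}

#' @export
print.eda_stream <- function(x, ...) {
  cat(sprintf("<eda_stream> %d samples @ %g Hz (%.1f s), start %s\n",
              length(x$samples), x$sample_rate_hz,
              stream_duration(x),
              format(as.POSIXct(x$start_time, origin = "1970-01-01", tz = "UTC"),
                     "%Y-%m-%d %H:%M:%OS2 UTC")))
  cat(sprintf("  range [%.4f, %.4f] uS, mean %.4f uS\n",
              min(x$samples), max(x$samples), mean(x$samples)))
  invisible(x)
}
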