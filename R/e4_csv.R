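#' Write a stream in the export-style CSV dialect
#'
#' Plain-text dialect modelled on wristband vendor exports: line 1 is
#' the POSIX start time, line 2 the sampling rate in Hz, lines 3+ one
#' conductance sample per line, all printed with 6 decimal places.
#'
#' @param stream an [eda_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_e4_csv <- function(stream, path) {
  stopifnot(inherits(stream, "eda_stream"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("%.6f", stream$start_time),
               sprintf("%.6f", stream$sample_rate_hz),
               sprintf("%.6f", stream$samples)),
             con, sep = "\n")
  invisible(path)
}

#' Read a stream from the export-style CSV dialect
#'
#' Parse failures are reported with the 1-based line number of the
#' offending line: a malformed start time (line 1), a nonnumeric or
#' nonpositive rate (line 2), or a nonnumeric/negative sample row.
#'
#' @param path file written by [write_e4_csv()].
#' @return an [eda_stream()]; round-trips preserve start time, rate and
#'   every sample to within 1e-6.
#' @export
read_e4_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("file too short: need 2 header lines plus at least 1 sample",
         call. = FALSE)
  start_time <- suppressWarnings(as.numeric(lines[1L]))
  if (is.na(start_time))
    stop("line 1: start time is not numeric: '", lines[1L], "'", call. = FALSE)
  rate <- suppressWarnings(as.numeric(lines[2L]))
  if (is.na(rate))
    stop("line 2: sample rate is not numeric: '", lines[2L], "'", call. = FALSE)
  if (rate <= 0)
    stop("line 2: sample rate must be positive, got '", lines[2L], "'",
         call. = FALSE)
  samples <- suppressWarnings(as.numeric(lines[-(1:2)]))
  bad <- which(is.na(samples))
  if (length(bad))
    stop("line ", bad[1L] + 2L, ": sample is not numeric: '",
         lines[bad[1L] + 2L], "'", call. = FALSE)
  neg <- which(samples < 0)
  if (length(neg))
    stop("line ", neg[1L] + 2L, ": sample is negative", call. = FALSE)
  eda_stream(samples, rate, start_time)
}
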