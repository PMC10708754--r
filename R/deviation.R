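#' Deviation-trigger configuration
#'
#' Parameters of the event-based prompting engine. The operative
#' threshold is a 20% rise over the calibrated baseline (the 15%
#' literature benchmark remains reachable through
#' `threshold_fraction = 0.15`); deviation notifications are capped at
#' four per study day so participants are not overwhelmed. The
#' smoothing, sustain and refractory durations are implementation
#' parameters: the rise must be sustained for 30 s of smoothed signal,
#' long enough that phasic SCR activity — even a cluster of overlapping
#' SCRs, whose smoothed elevation decays within a few seconds — cannot
#' fire a trigger, while genuine tonic elevations (minutes) always can;
#' and triggers cannot pile up inside one survey response window
#' (15-min refractory).
#'
#' @param threshold_fraction fractional rise over baseline that counts
#'   as a deviation; in (0, 1), default 0.20.
#' @param smooth_window_s centred moving-average width, seconds;
#'   0 disables smoothing (raw comparison). Default 5.
#' @param sustain_s time the smoothed signal must stay at or above the
#'   threshold before a trigger fires, seconds. Default 30.
#' @param refractory_s dead time after a trigger, seconds. Default 900.
#' @param daily_cap maximum deviation notifications emitted per study
#'   day. Default 4.
#' @return a `deviation_config` list.
#' @export
deviation_config <- function(threshold_fraction = 0.20,
                             smooth_window_s = 5,
                             sustain_s = 30,
                             refractory_s = 900,
                             daily_cap = 4L) {
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1)
    stop("`threshold_fraction` must lie in (0, 1)", call. = FALSE)
  if (smooth_window_s < 0 || sustain_s < 0 || refractory_s < 0)
    stop("durations must be >= 0", call. = FALSE)
  if (daily_cap < 0) stop("`daily_cap` must be >= 0", call. = FALSE)
  structure(list(threshold_fraction = threshold_fraction,
                 smooth_window_s = smooth_window_s,
                 sustain_s = sustain_s,
                 refractory_s = refractory_s,
                 daily_cap = as.integer(daily_cap)),
            class = "deviation_config")
}

#' Compute the calibration baseline
#'
#' The baseline marker is the arithmetic mean of all samples in the
#' half-open window `[window_start_s, window_start_s + window_s)`,
#' by default the full 3-minute calibration recording (720 samples at
#' 4 Hz).
#'
#' @param stream an [eda_stream()] covering the window.
#' @param window_start_s window start, seconds from stream start.
#' @param window_s window length, seconds; must be >= 30 (shorter
#'   windows contain too few samples to be a meaningful resting mean)
#'   and must not extend past the stream end.
#' @param member_id optional identifier carried into trigger logs.
#' @return an `eda_baseline` with fields `mean_eda_us`, `window_s`,
#'   `n_samples`, `member_id`.
#' @export
compute_baseline <- function(stream, window_start_s = 0, window_s = 180,
                             member_id = NA_character_) {
  stopifnot(inherits(stream, "eda_stream"))
  if (window_s < 30)
    stop("`window_s` must be >= 30 s for a meaningful baseline", call. = FALSE)
  if (window_start_s < 0 ||
      window_start_s + window_s > stream_duration(stream) + 1e-9)
    stop("baseline window extends past the stream end", call. = FALSE)
  t <- stream_times(stream)
  idx <- which(t >= window_start_s & t < window_start_s + window_s)
  structure(list(mean_eda_us = mean(stream$samples[idx]),
                 window_s = window_s,
                 n_samples = length(idx),
                 member_id = member_id),
            class = "eda_baseline")
}

#' Centred moving-average smoother
#'
#' Averages, at each sample, all samples within `smooth_window_s / 2`
#' seconds on either side, truncating the window at the stream edges.
#' A zero-width window is the identity.
#'
#' @param stream an [eda_stream()].
#' @param smooth_window_s window width in seconds (>= 0).
#' @return a smoothed `eda_stream` of the same length.
#' @export
smooth_stream <- function(stream, smooth_window_s) {
  stopifnot(inherits(stream, "eda_stream"), smooth_window_s >= 0)
  if (smooth_window_s == 0) return(stream)
  n <- length(stream$samples)
  k <- floor(smooth_window_s / 2 * stream$sample_rate_hz + 1e-9)
  if (k == 0) return(stream)
  cs <- cumsum(c(0, stream$samples))
  i <- seq_len(n)
  lo <- pmax(i - k, 1L)
  hi <- pmin(i + k, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  eda_stream(sm, stream$sample_rate_hz, stream$start_time)
}

#' Detect EDA deviations in a single forward pass
#'
#' A trigger fires at the first instant at which the smoothed signal
#' has been at or above `baseline * (1 + threshold_fraction)`
#' continuously for `sustain_s` seconds, subject to a refractory
#' period since the previous trigger. The pass is streaming-compatible:
#' the decision at sample `t` uses only smoothed samples up to `t`
#' (the centred smoother itself introduces a fixed half-window
#' latency). The threshold comparison uses a 1e-9 relative tolerance
#' so that a step of exactly `(1 + threshold) * baseline` triggers
#' despite floating-point rounding in the moving average.
#'
#' @param stream the raw [eda_stream()].
#' @param baseline an [compute_baseline()] result with positive mean.
#' @param cfg a [deviation_config()].
#' @return data.frame of triggers: `time_s` (offset from stream
#'   start), `time` (POSIXct, UTC), `smoothed_eda_us`, `baseline_us`,
#'   `threshold_us`, `emitted` (NA until [gate_and_cap()]).
#' @export
detect_deviations <- function(stream, baseline, cfg = deviation_config()) {
  stopifnot(inherits(stream, "eda_stream"),
            inherits(baseline, "eda_baseline"),
            inherits(cfg, "deviation_config"))
  if (baseline$mean_eda_us <= 0)
    stop("baseline mean must be > 0: a relative threshold is undefined at 0",
         call. = FALSE)
  sm <- smooth_stream(stream, cfg$smooth_window_s)
  thr <- baseline$mean_eda_us * (1 + cfg$threshold_fraction)
  above <- sm$samples >= thr * (1 - 1e-9)
  rate <- stream$sample_rate_hz
  # consecutive run length ending at each sample
  r <- rle(above)
  run <- sequence(r$lengths)
  run[!above] <- 0L
  need <- round(cfg$sustain_s * rate) + 1L  # (need-1)/rate >= sustain_s
  cand <- which(run >= need)
  t <- stream_times(stream)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (t[i] >= last + cfg$refractory_s) {
      keep <- c(keep, i)
      last <- t[i]
    }
  }
  data.frame(
    time_s = t[keep],
    time = as.POSIXct(stream$start_time + t[keep],
                      origin = "1970-01-01", tz = "UTC"),
    smoothed_eda_us = sm$samples[keep],
    baseline_us = rep(baseline$mean_eda_us, length(keep)),
    threshold_us = rep(thr, length(keep)),
    emitted = rep(NA, length(keep))
  )
}

#' Gate triggers to study hours and apply the daily cap
#'
#' Only triggers inside a day's study window are eligible; of those,
#' the first `daily_cap` per study day are emitted as notifications.
#' The cap counter resets at each day's window start. The cap counts
#' notifications sent, not surveys completed.
#'
#' @param triggers data.frame from [detect_deviations()] (possibly
#'   spanning several days).
#' @param design a [study_design()].
#' @return the input with `emitted` filled in (TRUE for the emitted
#'   subset, FALSE otherwise).
#' @export
gate_and_cap <- function(triggers, design) {
  if (nrow(triggers) == 0L) {
    triggers$emitted <- logical(0)
    return(triggers)
  }
  days <- as.Date(triggers$time, tz = "UTC")
  emitted <- logical(nrow(triggers))
  for (d in unique(days)) {
    day <- as.Date(d, origin = "1970-01-01")
    win <- study_windows(design, day, n_days = 1L)
    sel <- which(days == day)
    sel <- sel[order(triggers$time[sel])]
    eligible <- sel[triggers$time[sel] >= win$window_start &
                    triggers$time[sel] < win$window_end]
    emitted[head(eligible, design$deviation_cfg$daily_cap)] <- TRUE
  }
  triggers$emitted <- emitted
  triggers
}

#' Write a trigger log CSV
#'
#' One row per trigger: member, day, ISO time, smoothed level,
#' baseline, emitted flag (0/1).
#'
#' @param triggers gated trigger table ([gate_and_cap()]).
#' @param member_id member identifier column value.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trigger_log <- function(triggers, member_id, path) {
  df <- data.frame(
    member_id = rep(member_id, nrow(triggers)),
    day = format(as.Date(triggers$time, tz = "UTC")),
    trigger_time_iso = format_iso(triggers$time),
    smoothed_eda_us = sprintf("%.6f", triggers$smoothed_eda_us),
    baseline_us = sprintf("%.6f", triggers$baseline_us),
    emitted = as.integer(triggers$emitted)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_iso <- function(time) {
  format(time, "%Y-%m-%dT%H:%M:%OS3+00:00", tz = "UTC")
}
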