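#' Member simulation profile
#'
#' Describes one family member's resting physiology and response
#' behavior. Tonic levels default to the low end of the resting range
#' (skin conductance in the absence of stimuli typically sits within
#' 0--2 microsiemens); response probabilities default to the observed
#' per-role completion rates of the pilot deployment the generator
#' emulates (random prompts: mothers .80, fathers .68, children .45;
#' deviation prompts: .74 / .65 / .77).
#'
#' The tonic drift scale defaults to 0.0125 uS. That value is chosen so
#' that slow drift (about +/- 3 sd) stays inside the detection margin
#' between a 25% arousal episode and the 20% deviation threshold:
#' ground-truth episodes are then recoverable against a fixed
#' calibration baseline, which is what makes the generator useful as a
#' detector test bed.
#'
#' @param role one of `"mother"`, `"father"`, `"child"`.
#' @param tonic_mean_us resting tonic skin-conductance level, uS (> 0).
#' @param tonic_drift_sd stationary standard deviation of the slow
#'   tonic drift, uS (>= 0).
#' @param scr_rate_per_min rate of spontaneous skin-conductance
#'   responses, events per minute (>= 0).
#' @param artifact_rate_per_hour rate of motion-artifact spikes, events
#'   per hour (>= 0).
#' @param response_prob_random,response_prob_deviation probability in
#'   `[0, 1]` that a prompt of that kind is answered completely.
#' @return a `member_profile` list.
#' @export
member_profile <- function(role = c("mother", "father", "child"),
                           tonic_mean_us = NULL,
                           tonic_drift_sd = 0.0125,
                           scr_rate_per_min = NULL,
                           artifact_rate_per_hour = NULL,
                           response_prob_random = NULL,
                           response_prob_deviation = NULL) {
  role <- match.arg(role)
  defaults <- list(
    mother = list(tonic = 1.0, scr = 1.5, art = 2, p_rand = 0.80, p_dev = 0.74),
    father = list(tonic = 0.9, scr = 1.5, art = 2, p_rand = 0.68, p_dev = 0.65),
    child  = list(tonic = 1.2, scr = 2.0, art = 3, p_rand = 0.45, p_dev = 0.77)
  )[[role]]
  if (is.null(tonic_mean_us)) tonic_mean_us <- defaults$tonic
  if (is.null(scr_rate_per_min)) scr_rate_per_min <- defaults$scr
  if (is.null(artifact_rate_per_hour)) artifact_rate_per_hour <- defaults$art
  if (is.null(response_prob_random)) response_prob_random <- defaults$p_rand
  if (is.null(response_prob_deviation)) response_prob_deviation <- defaults$p_dev

  if (!is.numeric(tonic_mean_us) || tonic_mean_us <= 0)
    stop("`tonic_mean_us` must be > 0", call. = FALSE)
  if (tonic_drift_sd < 0) stop("`tonic_drift_sd` must be >= 0", call. = FALSE)
  if (scr_rate_per_min < 0 || artifact_rate_per_hour < 0)
    stop("event rates must be >= 0", call. = FALSE)
  for (p in c(response_prob_random, response_prob_deviation))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("response probabilities must lie in [0, 1]", call. = FALSE)

  structure(list(role = role,
                 tonic_mean_us = tonic_mean_us,
                 tonic_drift_sd = tonic_drift_sd,
                 scr_rate_per_min = scr_rate_per_min,
                 artifact_rate_per_hour = artifact_rate_per_hour,
                 response_prob_random = response_prob_random,
                 response_prob_deviation = response_prob_deviation),
            class = "member_profile")
}

#' Simulate a resting (tonic) EDA trace
#'
#' The tonic level is the profile mean plus a slowly mean-reverting
#' AR(1) drift (correlation time about two minutes) with stationary
#' standard deviation `tonic_drift_sd`, clipped at 0 uS. With
#' `tonic_drift_sd = 0` the trace is exactly constant.
#'
#' @param profile a [member_profile()].
#' @param duration_s trace length in seconds (> 0).
#' @param seed integer seed; the same seed reproduces the trace exactly.
#' @param sample_rate_hz sampling rate, default 4 Hz.
#' @param start_time absolute POSIX start time of the trace.
#' @return an [eda_stream()].
#' @export
simulate_tonic <- function(profile, duration_s, seed,
                           sample_rate_hz = 4, start_time = 0) {
  stopifnot(inherits(profile, "member_profile"))
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("`duration_s` must be a single positive number of seconds", call. = FALSE)
  n <- round(duration_s * sample_rate_hz)
  if (n < 1) stop("`duration_s` too short for one sample", call. = FALSE)
  sdv <- profile$tonic_drift_sd
  if (sdv == 0) {
    x <- rep(profile$tonic_mean_us, n)
  } else {
    dt <- 1 / sample_rate_hz
    phi <- exp(-dt / 120)                     # ~2 min mean-reversion time
    innov_sd <- sdv * sqrt(1 - phi^2)
    x <- with_seed(seed, {
      d0 <- rnorm(1, 0, sdv)
      e <- rnorm(n, 0, innov_sd)
      e[1] <- phi * d0 + e[1]
      d <- as.numeric(stats::filter(e, phi, method = "recursive"))
      profile$tonic_mean_us + d
    })
  }
  eda_stream(pmax(x, 0), sample_rate_hz, start_time)
}

#' Phasic skin-conductance response events
#'
#' Validates and assembles a table of SCR events. Each event is a
#' biexponential bump `amplitude * (exp(-t/decay) - exp(-t/rise)) / norm`
#' added to the stream from its onset onward.
#'
#' @param onset_s onset in seconds from stream start.
#' @param amplitude_us peak phasic rise, uS (> 0).
#' @param rise_tau_s,decay_tau_s kernel time constants, seconds; must
#'   satisfy `decay_tau_s > rise_tau_s > 0`. Defaults 0.75 s and 2 s,
#'   a typical SCR morphology.
#' @return data.frame with one row per event.
#' @export
scr_events <- function(onset_s, amplitude_us,
                       rise_tau_s = 0.75, decay_tau_s = 2.0) {
  if (length(onset_s) == 0L)
    return(data.frame(onset_s = numeric(0), amplitude_us = numeric(0),
                      rise_tau_s = numeric(0), decay_tau_s = numeric(0)))
  ev <- data.frame(onset_s = onset_s, amplitude_us = amplitude_us,
                   rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s)
  if (any(ev$amplitude_us <= 0)) stop("SCR amplitudes must be > 0", call. = FALSE)
  if (any(ev$rise_tau_s <= 0) || any(ev$decay_tau_s <= ev$rise_tau_s))
    stop("SCR time constants must satisfy decay_tau_s > rise_tau_s > 0",
         call. = FALSE)
  ev
}

# Biexponential kernel sampled at offsets tt (>= 0 assumed elsewhere),
# scaled so its maximum over the sampled offsets equals 1. Normalising
# on the sampling grid (rather than at the continuous-time peak) makes
# the discrete peak of each event equal its amplitude exactly.
scr_kernel <- function(tt, rise_tau, decay_tau) {
  k <- exp(-tt / decay_tau) - exp(-tt / rise_tau)
  m <- max(k)
  if (m <= 0) return(rep(0, length(tt)))
  k / m
}

#' Superimpose phasic SCR events on a stream
#'
#' @param stream an [eda_stream()].
#' @param events a table from [scr_events()]; onsets must fall within
#'   the stream duration.
#' @return a new `eda_stream`; everywhere >= the input.
#' @export
superimpose_scrs <- function(stream, events) {
  stopifnot(inherits(stream, "eda_stream"))
  if (is.null(events) || nrow(events) == 0L) return(stream)
  events <- scr_events(events$onset_s, events$amplitude_us,
                       events$rise_tau_s, events$decay_tau_s)
  dur <- stream_duration(stream)
  if (any(events$onset_s < 0) || any(events$onset_s >= dur))
    stop("SCR onset beyond stream end", call. = FALSE)
  t <- stream_times(stream)
  x <- stream$samples
  rate <- stream$sample_rate_hz
  n <- length(x)
  for (j in seq_len(nrow(events))) {
    # kernel support: beyond ~32 decay constants the tail is < 1e-14
    first <- ceiling(events$onset_s[j] * rate) + 1L
    last <- min(n, first + ceiling(32 * events$decay_tau_s[j] * rate))
    idx <- first:last
    tt <- t[idx] - events$onset_s[j]
    x[idx] <- x[idx] +
      events$amplitude_us[j] * scr_kernel(tt, events$rise_tau_s[j],
                                          events$decay_tau_s[j])
  }
  eda_stream(x, stream$sample_rate_hz, stream$start_time)
}

#' Arousal episode table
#'
#' Ground-truth elevations of the tonic level: during an episode the
#' tonic trace is multiplied by `level_multiplier` (reached linearly
#' over a ramp). A multiplicative episode makes "a 20% increase over
#' baseline" well defined whatever the member's resting level.
#'
#' @param start_s,end_s episode bounds, seconds from stream start;
#'   `end_s > start_s`.
#' @param level_multiplier dimensionless factor >= 1.
#' @return data.frame sorted by onset.
#' @export
arousal_episodes <- function(start_s, end_s, level_multiplier) {
  if (length(start_s) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      level_multiplier = numeric(0)))
  ep <- data.frame(start_s = start_s, end_s = end_s,
                   level_multiplier = level_multiplier)
  if (any(ep$end_s <= ep$start_s))
    stop("episodes must have end_s > start_s", call. = FALSE)
  if (any(ep$level_multiplier < 1))
    stop("`level_multiplier` must be >= 1", call. = FALSE)
  ep <- ep[order(ep$start_s), , drop = FALSE]
  rownames(ep) <- NULL
  ep
}

#' Apply arousal episodes to a stream
#'
#' Inside each episode the tonic multiplier rises linearly from 1 to
#' `level_multiplier` over `ramp_s`, holds, and decays back linearly
#' over `ramp_s` after `end_s`. Outside episodes (and their ramps) the
#' stream is unchanged. Episodes must be non-overlapping.
#'
#' @param stream an [eda_stream()].
#' @param episodes a table from [arousal_episodes()].
#' @param ramp_s linear on/off ramp duration, seconds (>= 0).
#' @return a new `eda_stream`.
#' @export
apply_episodes <- function(stream, episodes, ramp_s = 15) {
  stopifnot(inherits(stream, "eda_stream"), ramp_s >= 0)
  if (is.null(episodes) || nrow(episodes) == 0L) return(stream)
  episodes <- arousal_episodes(episodes$start_s, episodes$end_s,
                               episodes$level_multiplier)
  if (nrow(episodes) > 1L &&
      any(episodes$start_s[-1] < episodes$end_s[-nrow(episodes)]))
    stop("episodes must not overlap", call. = FALSE)
  t <- stream_times(stream)
  m <- rep(1, length(t))
  for (j in seq_len(nrow(episodes))) {
    s <- episodes$start_s[j]; e <- episodes$end_s[j]
    L <- episodes$level_multiplier[j]
    if (ramp_s > 0) {
      up <- pmin(pmax((t - s) / ramp_s, 0), 1)
      dn <- ifelse(t <= e, 1, pmin(pmax(1 - (t - e) / ramp_s, 0), 1))
      shape <- pmin(up, dn)
    } else {
      shape <- as.numeric(t >= s & t <= e)
    }
    m <- m + (L - 1) * shape
  }
  eda_stream(stream$samples * m, stream$sample_rate_hz, stream$start_time)
}

#' Add motion-artifact spikes
#'
#' Inserts brief (0.25--2 s) half-sine spikes of random sign at
#' Poisson-distributed times, clipping the result at 0 uS, and returns
#' the ground-truth artifact onsets. A zero rate is the identity.
#'
#' @param stream an [eda_stream()].
#' @param rate_per_hour expected artifact count per hour (>= 0).
#' @param seed integer seed.
#' @return list with elements `stream` (the corrupted `eda_stream`) and
#'   `artifact_times` (sorted onset offsets, seconds).
#' @export
add_artifacts <- function(stream, rate_per_hour, seed) {
  stopifnot(inherits(stream, "eda_stream"))
  if (!is.numeric(rate_per_hour) || rate_per_hour < 0)
    stop("`rate_per_hour` must be >= 0", call. = FALSE)
  dur <- stream_duration(stream)
  if (rate_per_hour == 0)
    return(list(stream = stream, artifact_times = numeric(0)))
  t <- stream_times(stream)
  out <- with_seed(seed, {
    n <- rpois(1, rate_per_hour * dur / 3600)
    if (n == 0) return(list(x = stream$samples, times = numeric(0)))
    onsets <- sort(runif(n, 0, max(dur - 2, 0)))
    widths <- runif(n, 0.25, 2)
    amps <- runif(n, 0.5, 2.0) * sample(c(-1, 1), n, replace = TRUE)
    x <- stream$samples
    for (j in seq_len(n)) {
      idx <- which(t >= onsets[j] & t <= onsets[j] + widths[j])
      if (length(idx))
        x[idx] <- x[idx] + amps[j] * sin(pi * (t[idx] - onsets[j]) / widths[j])
    }
    list(x = x, times = onsets)
  })
  list(stream = eda_stream(pmax(out$x, 0), stream$sample_rate_hz,
                           stream$start_time),
       artifact_times = out$times)
}

#' Simulate a 3-minute calibration recording
#'
#' Mirrors the researcher-led orientation in which each member wears
#' the device at rest for three minutes; the mean of this recording is
#' the member's deviation baseline.
#'
#' @inheritParams simulate_tonic
#' @param window_s calibration length, default 180 s.
#' @return an [eda_stream()].
#' @export
simulate_calibration <- function(profile, seed, window_s = 180,
                                 sample_rate_hz = 4, start_time = 0) {
  simulate_tonic(profile, window_s, seed, sample_rate_hz, start_time)
}

# Draw non-overlapping episodes inside [0, dur]; consecutive episodes
# are separated by at least `min_gap_s` so each one is independently
# recoverable by a detector with a 15-min refractory period.
draw_episodes <- function(dur, rate_per_day, seed, min_gap_s = 1000) {
  with_seed(seed, {
    n <- rpois(1, rate_per_day)
    if (n == 0) return(arousal_episodes(numeric(0), numeric(0), numeric(0)))
    starts <- sort(runif(n, 0, dur))
    lens <- runif(n, 120, 480)
    mult <- runif(n, 1.15, 1.35)
    keep <- logical(n)
    last_end <- -Inf
    for (j in seq_len(n)) {
      if (starts[j] >= last_end + min_gap_s &&
          starts[j] + lens[j] <= dur) {
        keep[j] <- TRUE
        last_end <- starts[j] + lens[j]
      }
    }
    arousal_episodes(starts[keep], starts[keep] + lens[keep], mult[keep])
  })
}

#' Simulate one member-day recording session with ground truth
#'
#' Composes the four generators — tonic drift, arousal episodes,
#' spontaneous SCRs, motion artifacts — over the study window of the
#' given day, and returns the stream together with everything needed to
#' score a detector: the injected episodes, SCR events, and artifact
#' onsets. Deterministic under `seed`.
#'
#' @param profile a [member_profile()].
#' @param design a [study_design()].
#' @param day a `Date` (study window chosen by its weekday).
#' @param seed integer seed for the whole session.
#' @param episodes optional [arousal_episodes()] table to inject
#'   verbatim; `NULL` draws them at `episode_rate_per_day`.
#' @param episode_rate_per_day expected episode count per session when
#'   `episodes` is `NULL`. Default 3, which after the detector's daily
#'   cap yields roughly the two deviation prompts per day seen in
#'   deployments of this design.
#' @param ramp_s episode on/off ramp, seconds.
#' @return list with `stream` (an [eda_stream()] starting at the
#'   window start), and `ground_truth`: `episodes`, `scrs`,
#'   `artifact_times`.
#' @export
simulate_member_session <- function(profile, design, day, seed,
                                    episodes = NULL,
                                    episode_rate_per_day = 3,
                                    ramp_s = 20) {
  stopifnot(inherits(profile, "member_profile"))
  win <- study_windows(design, as.Date(day), n_days = 1L)
  dur <- as.numeric(win$window_end - win$window_start, units = "secs")
  rate <- 4
  tonic <- simulate_tonic(profile, dur, derive_seed(seed, 1),
                          sample_rate_hz = rate,
                          start_time = as.numeric(win$window_start))
  if (is.null(episodes))
    episodes <- draw_episodes(dur, episode_rate_per_day, derive_seed(seed, 2))
  else
    episodes <- arousal_episodes(episodes$start_s, episodes$end_s,
                                 episodes$level_multiplier)
  x <- apply_episodes(tonic, episodes, ramp_s = ramp_s)
  scrs <- with_seed(derive_seed(seed, 3), {
    n <- rpois(1, profile$scr_rate_per_min * dur / 60)
    if (n == 0) scr_events(numeric(0), numeric(0))
    else scr_events(sort(runif(n, 0, dur - 1 / rate)), runif(n, 0.05, 0.3))
  })
  x <- superimpose_scrs(x, scrs)
  art <- add_artifacts(x, profile$artifact_rate_per_hour, derive_seed(seed, 4))
  list(stream = art$stream,
       ground_truth = list(episodes = episodes, scrs = scrs,
                           artifact_times = art$artifact_times))
}
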