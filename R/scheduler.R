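#' Study design: windows, intervals, caps
#'
#' The configuration a deployment prints: study hours of 4--8 p.m. on
#' weekdays and 10 a.m.--6 p.m. on weekends (chosen to avoid school
#' hours), each day's window divided into four equal intervals with one
#' random prompt per interval, ten study days, one reminder per missed
#' random prompt, a 15-minute response window, and the deviation engine
#' configuration.
#'
#' Windows are interpreted as local clock times in a fixed time zone
#' (default UTC) with no daylight-saving adjustment mid-study; see the
#' methods vignette for this limitation.
#'
#' @param weekday_window,weekend_window length-2 character vectors of
#'   "HH:MM" clock times (start, end).
#' @param n_intervals equal intervals per window (>= 1); the window
#'   length must divide into whole seconds.
#' @param n_days study length in days.
#' @param random_reminder send one reminder per missed random prompt?
#' @param survey_window_min minutes allowed to complete a survey.
#' @param deviation_cfg a [deviation_config()].
#' @param min_gap_s minimum spacing enforced when merging prompt
#'   streams, seconds.
#' @param reminder_lag_min minutes after an unanswered prompt before
#'   its reminder becomes eligible; defaults to the response window.
#' @param tz time zone for clock-time arithmetic.
#' @return a `study_design` list.
#' @export
study_design <- function(weekday_window = c("16:00", "20:00"),
                         weekend_window = c("10:00", "18:00"),
                         n_intervals = 4L,
                         n_days = 10L,
                         random_reminder = TRUE,
                         survey_window_min = 15,
                         deviation_cfg = deviation_config(),
                         min_gap_s = 120,
                         reminder_lag_min = survey_window_min,
                         tz = "UTC") {
  parse_clock <- function(x) {
    m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
    if (length(m) != 3L) stop("bad clock time: '", x, "'", call. = FALSE)
    as.numeric(m[2]) * 3600 + as.numeric(m[3]) * 60
  }
  wd <- vapply(weekday_window, parse_clock, numeric(1), USE.NAMES = FALSE)
  we <- vapply(weekend_window, parse_clock, numeric(1), USE.NAMES = FALSE)
  if (wd[2] <= wd[1] || we[2] <= we[1])
    stop("study windows must be non-empty", call. = FALSE)
  if (n_intervals < 1) stop("`n_intervals` must be >= 1", call. = FALSE)
  for (len in c(diff(wd), diff(we)))
    if ((len / n_intervals) %% 1 != 0)
      stop("window length must divide into `n_intervals` whole-second parts",
           call. = FALSE)
  if (n_days < 1) stop("`n_days` must be >= 1", call. = FALSE)
  if (survey_window_min <= 0) stop("`survey_window_min` must be > 0", call. = FALSE)
  stopifnot(inherits(deviation_cfg, "deviation_config"))
  structure(list(weekday_window_s = wd, weekend_window_s = we,
                 weekday_window = weekday_window,
                 weekend_window = weekend_window,
                 n_intervals = as.integer(n_intervals),
                 n_days = as.integer(n_days),
                 random_reminder = isTRUE(random_reminder),
                 survey_window_min = survey_window_min,
                 deviation_cfg = deviation_cfg,
                 min_gap_s = min_gap_s,
                 reminder_lag_min = reminder_lag_min,
                 tz = tz),
            class = "study_design")
}

#' Study windows for consecutive calendar days
#'
#' One window per day, the weekday or weekend window chosen by the
#' day's local weekday.
#'
#' @param design a [study_design()].
#' @param start_date first study day (`Date` or coercible).
#' @param n_days number of days; defaults to the design's.
#' @return data.frame: `day` (Date), `is_weekend`, `window_start`,
#'   `window_end` (POSIXct in the design's time zone).
#' @export
study_windows <- function(design, start_date, n_days = design$n_days) {
  stopifnot(inherits(design, "study_design"))
  days <- as.Date(start_date) + seq_len(n_days) - 1L
  wd_num <- as.integer(format(days, "%u"))  # 1 = Mon ... 7 = Sun
  is_weekend <- wd_num >= 6L
  midnight <- as.POSIXct(paste(format(days), "00:00:00"), tz = design$tz)
  start_s <- ifelse(is_weekend, design$weekend_window_s[1],
                    design$weekday_window_s[1])
  end_s <- ifelse(is_weekend, design$weekend_window_s[2],
                  design$weekday_window_s[2])
  data.frame(day = days,
             is_weekend = is_weekend,
             window_start = midnight + start_s,
             window_end = midnight + end_s)
}

#' Partition a window into equal half-open intervals
#'
#' Contiguous `[a, b)` intervals of equal length that tile the window
#' exactly; every instant of the window belongs to exactly one
#' interval.
#'
#' @param window_start,window_end POSIXct bounds.
#' @param n_intervals number of parts; the window length must divide
#'   into whole seconds.
#' @return data.frame: `interval_index` (0-based), `start`, `end`.
#' @export
partition_intervals <- function(window_start, window_end, n_intervals) {
  len <- as.numeric(window_end, units = "secs") -
    as.numeric(window_start, units = "secs")
  if (len <= 0) stop("window must be non-empty", call. = FALSE)
  per <- len / n_intervals
  if (per %% 1 != 0)
    stop("window does not divide into whole-second intervals", call. = FALSE)
  idx <- seq_len(n_intervals) - 1L
  data.frame(interval_index = idx,
             start = window_start + idx * per,
             end = window_start + (idx + 1L) * per)
}

#' Draw the day's random prompts
#'
#' Exactly one prompt per interval, at a time uniform over that
#' interval; deterministic under `seed`.
#'
#' @param window one row of [study_windows()] (or any list with
#'   `day`, `window_start`, `window_end`).
#' @param n_intervals intervals per window.
#' @param seed integer seed.
#' @param member_id identifier carried on each prompt.
#' @return a prompt table: `member_id`, `day`, `kind` ("random"),
#'   `scheduled_time`, `interval_index`, `interval_start`,
#'   `interval_end`, `prompt_id`, `parent_prompt` (NA).
#' @export
draw_random_prompts <- function(window, n_intervals, seed,
                                member_id = NA_character_) {
  iv <- partition_intervals(window$window_start, window$window_end,
                            n_intervals)
  len <- as.numeric(iv$end) - as.numeric(iv$start)
  offs <- with_seed(seed, runif(n_intervals))
  times <- iv$start + offs * len          # in [start, end)
  data.frame(
    member_id = rep(member_id, n_intervals),
    day = rep(as.Date(window$day), n_intervals),
    kind = rep("random", n_intervals),
    scheduled_time = times,
    interval_index = iv$interval_index,
    interval_start = iv$start,
    interval_end = iv$end,
    prompt_id = sprintf("%s-%s-r%d", member_id, format(as.Date(window$day)),
                        iv$interval_index),
    parent_prompt = rep(NA_character_, n_intervals)
  )
}

#' Schedule a reminder for an unanswered random prompt
#'
#' At most one reminder per random prompt, drawn uniformly between the
#' moment the prompt's response window has lapsed unanswered and the
#' end of the prompt's interval; no reminder if the survey was
#' completed, or if no room remains inside the interval. Reminders
#' apply to the random schedule only — deviation prompts are rejected.
#'
#' @param prompt a single-row prompt table (kind "random").
#' @param answered was the prompt's survey completed?
#' @param now current time (POSIXct); reminder is never scheduled
#'   before `now`.
#' @param seed integer seed.
#' @param lag_min minutes after the prompt before a reminder is
#'   eligible (default: the 15-min response window).
#' @return a single-row prompt table of kind "reminder", or `NULL`.
#' @export
schedule_reminder <- function(prompt, answered, now = prompt$scheduled_time,
                              seed = 0L, lag_min = 15) {
  if (nrow(prompt) != 1L) stop("`prompt` must be a single row", call. = FALSE)
  if (prompt$kind != "random")
    stop("reminders apply to random prompts only", call. = FALSE)
  if (isTRUE(answered)) return(NULL)
  earliest <- max(as.numeric(prompt$scheduled_time) + lag_min * 60,
                  as.numeric(now))
  end <- as.numeric(prompt$interval_end)
  if (earliest >= end) return(NULL)  # interval over (or no room): no reminder
  at <- with_seed(seed, earliest + runif(1) * (end - earliest))
  out <- prompt
  out$kind <- "reminder"
  out$scheduled_time <- as.POSIXct(at, origin = "1970-01-01",
                                   tz = attr(prompt$scheduled_time, "tzone"))
  out$parent_prompt <- prompt$prompt_id
  out$prompt_id <- paste0(prompt$prompt_id, "-rem")
  out
}

# empty prompt table with deviation-prompt columns
deviation_prompts <- function(triggers, member_id, day, design) {
  em <- triggers[which(triggers$emitted), , drop = FALSE]
  n <- nrow(em)
  data.frame(
    member_id = rep(member_id, n),
    day = rep(as.Date(day), n),
    kind = rep("deviation", n),
    scheduled_time = em$time,
    interval_index = rep(NA_integer_, n),
    interval_start = as.POSIXct(rep(NA_real_, n), origin = "1970-01-01",
                                tz = design$tz),
    interval_end = as.POSIXct(rep(NA_real_, n), origin = "1970-01-01",
                              tz = design$tz),
    prompt_id = if (n) sprintf("%s-%s-d%d", member_id,
                               format(as.Date(day)), seq_len(n) - 1L)
                else character(0),
    parent_prompt = rep(NA_character_, n)
  )
}

#' Merge random and deviation prompt streams
#'
#' Time-ordered union of the two notification streams per member. If
#' two prompts fall within `min_gap_s` of each other the later one is
#' delayed to `min_gap_s` after its predecessor (applied left to
#' right, so all output gaps are >= `min_gap_s`). Participants see a
#' single undifferentiated stream; use [blind_schedule()] for an
#' export that hides prompt kind.
#'
#' @param random_prompts,deviation_prompts prompt tables with the
#'   columns of [draw_random_prompts()].
#' @param min_gap_s minimum spacing, seconds. Default 120.
#' @return the merged prompt table ordered by member and time.
#' @export
merge_prompt_streams <- function(random_prompts, deviation_prompts,
                                 min_gap_s = 120) {
  all <- rbind(random_prompts, deviation_prompts)
  if (nrow(all) == 0L) return(all)
  out <- NULL
  for (m in unique(all$member_id)) {
    g <- all[all$member_id == m, , drop = FALSE]
    g <- g[order(g$scheduled_time), , drop = FALSE]
    tt <- as.numeric(g$scheduled_time)
    if (nrow(g) > 1L)
      for (i in 2:nrow(g))
        if (tt[i] < tt[i - 1] + min_gap_s) tt[i] <- tt[i - 1] + min_gap_s
    g$scheduled_time <- as.POSIXct(tt, origin = "1970-01-01",
                                   tz = attr(all$scheduled_time, "tzone"))
    out <- rbind(out, g)
  }
  rownames(out) <- NULL
  out
}

#' Blinded view of a prompt schedule
#'
#' Drops every field from which the prompt kind could be recovered
#' (kind, interval bookkeeping, identifiers that encode kind), leaving
#' only member, day and time — what a participant's phone shows.
#'
#' @param prompts a prompt table.
#' @return data.frame: `member_id`, `day`, `scheduled_time_iso`.
#' @export
blind_schedule <- function(prompts) {
  ord <- order(prompts$member_id, prompts$scheduled_time)
  p <- prompts[ord, , drop = FALSE]
  data.frame(member_id = p$member_id,
             day = format(p$day),
             scheduled_time_iso = format_iso(p$scheduled_time))
}

#' Write a schedule CSV
#'
#' @param prompts prompt table.
#' @param path output path.
#' @param blinded write the blinded variant (no kind, no interval)?
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(prompts, path, blinded = FALSE) {
  if (blinded) {
    df <- blind_schedule(prompts)
  } else {
    df <- data.frame(member_id = prompts$member_id,
                     day = format(prompts$day),
                     kind = prompts$kind,
                     scheduled_time_iso = format_iso(prompts$scheduled_time),
                     interval_index = prompts$interval_index)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
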