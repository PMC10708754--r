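#' Default four-member family roster
#'
#' Two parents and two children, the family composition the study
#' design assumes.
#'
#' @param family_id family identifier.
#' @return data.frame: `member_id`, `role`, `family`.
#' @export
default_roster <- function(family_id = "fam1") {
  data.frame(member_id = c("mother1", "father1", "child1", "child2"),
             role = c("mother", "father", "child", "child"),
             family = family_id)
}

#' Full-study run configuration
#'
#' Bundles everything a reproducible run needs: the design, the family
#' roster, the master seed (all per-member and per-day seeds are
#' derived from it deterministically), the episode mode and the output
#' directory.
#'
#' @param design a [study_design()].
#' @param roster data.frame with `member_id`, `role` (and optional
#'   `family`); at least one member.
#' @param master_seed integer master seed.
#' @param start_date first study day. Default a Monday so the default
#'   10-day run covers 8 weekday and 2 weekend windows.
#' @param episode_mode `"random"` draws arousal episodes at the
#'   generator's default rate; `"elevated"` injects one full-window
#'   50% elevation per day (every day then hits the deviation cap);
#'   `"none"` injects no episodes.
#' @param out_dir output directory for [simulate_study()].
#' @param write_streams also write each member-day EDA stream as an
#'   export-style CSV under `streams/`? Off by default; streams are
#'   reproducible from the seeds in the manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(design = study_design(),
                       roster = default_roster(),
                       master_seed = 1L,
                       start_date = as.Date("2023-05-01"),
                       episode_mode = c("random", "elevated", "none"),
                       out_dir = NULL,
                       write_streams = FALSE) {
  stopifnot(inherits(design, "study_design"))
  episode_mode <- match.arg(episode_mode)
  if (!is.data.frame(roster) || nrow(roster) < 1L ||
      !all(c("member_id", "role") %in% names(roster)))
    stop("`roster` must be a data.frame with >= 1 member and columns member_id, role",
         call. = FALSE)
  if (anyDuplicated(roster$member_id))
    stop("member ids must be unique", call. = FALSE)
  if (!all(roster$role %in% c("mother", "father", "child")))
    stop("roles must be mother/father/child", call. = FALSE)
  structure(list(design = design, roster = roster,
                 master_seed = as.integer(master_seed),
                 start_date = as.Date(start_date),
                 episode_mode = episode_mode,
                 out_dir = out_dir,
                 write_streams = isTRUE(write_streams)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' Human-editable mirror of the [run_config()] fields; command-line
#' flags override file values.
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `path` invisibly / a `run_config`.
#' @export
write_run_config <- function(config, path) {
  d <- config$design
  yaml::write_yaml(list(
    design = list(weekday_window = d$weekday_window,
                  weekend_window = d$weekend_window,
                  n_intervals = d$n_intervals,
                  n_days = d$n_days,
                  random_reminder = d$random_reminder,
                  survey_window_min = d$survey_window_min,
                  min_gap_s = d$min_gap_s,
                  tz = d$tz,
                  threshold_fraction = d$deviation_cfg$threshold_fraction,
                  smooth_window_s = d$deviation_cfg$smooth_window_s,
                  sustain_s = d$deviation_cfg$sustain_s,
                  refractory_s = d$deviation_cfg$refractory_s,
                  daily_cap = d$deviation_cfg$daily_cap),
    roster = lapply(seq_len(nrow(config$roster)), function(i)
      list(member_id = config$roster$member_id[i],
           role = config$roster$role[i],
           family = if ("family" %in% names(config$roster))
             config$roster$family[i] else "fam1")),
    master_seed = config$master_seed,
    start_date = format(config$start_date),
    episode_mode = config$episode_mode,
    write_streams = config$write_streams
  ), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  d <- y$design
  design <- study_design(
    weekday_window = unlist(d$weekday_window),
    weekend_window = unlist(d$weekend_window),
    n_intervals = d$n_intervals %||% 4L,
    n_days = d$n_days %||% 10L,
    random_reminder = d$random_reminder %||% TRUE,
    survey_window_min = d$survey_window_min %||% 15,
    min_gap_s = d$min_gap_s %||% 120,
    tz = d$tz %||% "UTC",
    deviation_cfg = deviation_config(
      threshold_fraction = d$threshold_fraction %||% 0.20,
      smooth_window_s = d$smooth_window_s %||% 5,
      sustain_s = d$sustain_s %||% 5,
      refractory_s = d$refractory_s %||% 900,
      daily_cap = d$daily_cap %||% 4L))
  roster <- do.call(rbind, lapply(y$roster, function(r)
    data.frame(member_id = r$member_id, role = r$role,
               family = r$family %||% "fam1")))
  run_config(design = design, roster = roster,
             master_seed = y$master_seed %||% 1L,
             start_date = as.Date(y$start_date %||% "2023-05-01"),
             episode_mode = y$episode_mode %||% "random",
             write_streams = y$write_streams %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete study end to end
#'
#' For every roster member: a 3-minute calibration recording and its
#' baseline; then, per study day, a ground-truth EDA session, deviation
#' detection with study-hour gating and the daily cap, the day's
#' stratified random prompts, survey issue for every notification,
#' simulated responses, reminders for unanswered random prompts, and
#' finalization. Writes schedules (plain and blinded), trigger and
#' response logs, engagement and endorsement reports, a summary, and a
#' manifest of config hash and derived seeds. Re-running with the same
#' configuration reproduces every output file byte for byte.
#'
#' @param config a [run_config()] with `out_dir` set (or `out_dir`
#'   supplied here).
#' @param out_dir output directory; must not already contain files
#'   unless `overwrite = TRUE`.
#' @param overwrite wipe an existing output directory first?
#' @return invisibly, a list with the response log, trigger log,
#'   engagement table and output paths.
#' @export
simulate_study <- function(config, out_dir = config$out_dir,
                           overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) stop("an output directory is required", call. = FALSE)
  if (dir.exists(out_dir) && length(dir(out_dir, all.files = FALSE)) > 0L) {
    if (!overwrite)
      stop("output directory ", out_dir,
           " is not empty; pass overwrite = TRUE to replace it", call. = FALSE)
    unlink(out_dir, recursive = TRUE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- config$design
  roster <- config$roster
  windows <- study_windows(design, config$start_date)
  catalog <- survey_catalog()

  member_seeds <- vapply(seq_len(nrow(roster)),
                         function(i) derive_seed(config$master_seed, i),
                         integer(1))
  names(member_seeds) <- roster$member_id

  all_prompts <- NULL
  all_triggers <- NULL
  all_instances <- list()
  baselines <- NULL
  if (config$write_streams)
    dir.create(file.path(out_dir, "streams"), showWarnings = FALSE)

  for (i in seq_len(nrow(roster))) {
    mid <- roster$member_id[i]
    role <- roster$role[i]
    profile <- member_profile(role)
    mseed <- member_seeds[[i]]

    calib <- simulate_calibration(profile, derive_seed(mseed, 999))
    baseline <- compute_baseline(calib, member_id = mid)
    baselines <- rbind(baselines,
                       data.frame(member_id = mid, role = role,
                                  mean_eda_us = baseline$mean_eda_us,
                                  n_samples = baseline$n_samples))

    for (dix in seq_len(nrow(windows))) {
      w <- windows[dix, ]
      dseed <- derive_seed(mseed, dix)
      dur <- as.numeric(w$window_end - w$window_start, units = "secs")
      episodes <- switch(config$episode_mode,
        random = NULL,
        elevated = arousal_episodes(0.1, dur - 0.1, 1.5),
        none = arousal_episodes(numeric(0), numeric(0), numeric(0)))
      sess <- simulate_member_session(profile, design, w$day, dseed,
                                      episodes = episodes)
      if (config$write_streams)
        write_e4_csv(sess$stream,
                     file.path(out_dir, "streams",
                               sprintf("%s_%s.csv", mid, format(w$day))))
      trig <- detect_deviations(sess$stream, baseline, design$deviation_cfg)
      trig <- gate_and_cap(trig, design)
      if (nrow(trig)) {
        trig_rows <- cbind(member_id = mid, day = format(w$day), trig)
        all_triggers <- rbind(all_triggers, trig_rows)
      }
      dev_p <- deviation_prompts(trig, mid, w$day, design)
      rnd_p <- draw_random_prompts(w, design$n_intervals,
                                   derive_seed(dseed, 41), member_id = mid)
      merged <- merge_prompt_streams(rnd_p, dev_p, design$min_gap_s)
      inst <- lapply(seq_len(nrow(merged)), function(j)
        issue_survey(merged[j, ], role, catalog,
                     survey_window_min = design$survey_window_min))
      inst <- simulate_responses(inst, profile, catalog,
                                 seed = derive_seed(dseed, 42))
      # one reminder per unanswered random prompt, inside its interval
      reminders <- NULL
      if (design$random_reminder) {
        for (j in seq_len(nrow(merged))) {
          if (merged$kind[j] != "random") next
          done <- inst[[j]]$status == "complete"
          rem <- schedule_reminder(merged[j, ], answered = done,
                                   now = merged$scheduled_time[j] +
                                     design$reminder_lag_min * 60,
                                   seed = derive_seed(dseed, 500 + j),
                                   lag_min = design$reminder_lag_min)
          reminders <- rbind(reminders, rem)
        }
      }
      all_prompts <- rbind(all_prompts, merged, reminders)
      all_instances <- c(all_instances, inst)
    }
  }

  log <- responses_to_log(all_instances)
  eng <- engagement(log)

  # ---- reports ----------------------------------------------------------
  write_schedule_csv(all_prompts, file.path(out_dir, "schedule.csv"))
  write_schedule_csv(all_prompts, file.path(out_dir, "schedule_blinded.csv"),
                     blinded = TRUE)
  if (!is.null(all_triggers)) {
    df <- data.frame(member_id = all_triggers$member_id,
                     day = all_triggers$day,
                     trigger_time_iso = format_iso(all_triggers$time),
                     smoothed_eda_us = sprintf("%.6f", all_triggers$smoothed_eda_us),
                     baseline_us = sprintf("%.6f", all_triggers$baseline_us),
                     emitted = as.integer(all_triggers$emitted))
  } else {
    df <- data.frame(member_id = character(0), day = character(0),
                     trigger_time_iso = character(0),
                     smoothed_eda_us = character(0),
                     baseline_us = character(0), emitted = integer(0))
  }
  write.csv(df, file.path(out_dir, "triggers.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(log, file.path(out_dir, "responses.csv"), row.names = FALSE)
  eng_out <- eng
  eng_out$rate_pct <- ifelse(is.na(eng$rate_pct), "",
                             sprintf("%.4f", eng$rate_pct))
  write.csv(eng_out, file.path(out_dir, "engagement.csv"),
            row.names = FALSE, quote = FALSE)
  baselines$mean_eda_us <- sprintf("%.6f", baselines$mean_eda_us)
  write.csv(baselines, file.path(out_dir, "baselines.csv"),
            row.names = FALSE, quote = FALSE)
  for (q in c("emotion", "activity")) {
    tab <- tryCatch(endorsement_table(log, q), error = function(e) NULL)
    if (!is.null(tab)) {
      fm <- format_endorsement(tab,
                               aliases = if (q == "emotion") emotion_aliases())
      write.csv(as.data.frame(fm),
                file.path(out_dir, paste0("endorsement_", q, ".csv")))
    }
  }
  n_dev_emitted <- if (is.null(all_triggers)) 0L
                   else sum(all_triggers$emitted)
  summary <- list(
    engagement_overall_pooled_pct = pooled_engagement(log, "overall"),
    engagement_overall_member_mean_pct =
      pooled_engagement(log, "overall", "member_mean"),
    engagement_random_pct = pooled_engagement(log, "random"),
    engagement_deviation_pct = pooled_engagement(log, "deviation"),
    deviation_prompts_emitted = n_dev_emitted,
    deviation_prompts_per_member_day =
      n_dev_emitted / (nrow(roster) * design$n_days),
    n_members = nrow(roster), n_days = design$n_days
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    master_seed = config$master_seed,
    member_seeds = as.list(member_seeds),
    start_date = format(config$start_date),
    episode_mode = config$episode_mode
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(log = log, engagement = eng, prompts = all_prompts,
                 triggers = all_triggers, summary = summary,
                 out_dir = out_dir))
}
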