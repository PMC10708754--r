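#' Episode-recovery experiment
#'
#' Measures detector sensitivity under controlled ground truth: each
#' seeded session injects arousal episodes of a known multiplier at
#' fixed, well-separated onsets (spaced beyond the refractory period)
#' into a default-profile stream with zero motion artifacts; the
#' baseline comes from that member's simulated calibration. An episode
#' counts as detected if any trigger falls inside it.
#'
#' @param n_sessions number of seeded sessions. Default 20.
#' @param seed experiment seed; session seeds are derived from it.
#' @param multiplier episode level multiplier. Default 1.25, i.e. a
#'   25% rise against the 20% operative threshold.
#' @param episode_starts_s,episode_len_s episode onsets and common
#'   length within the session, seconds.
#' @param design a [study_design()]; sessions use its weekday window.
#' @param role profile role for the simulated member.
#' @return list: `sensitivity` (detected / injected), `n_episodes`,
#'   `n_detected`, `false_alarms` (triggers outside any episode).
#' @export
episode_recovery_experiment <- function(n_sessions = 20, seed = 1L,
                                        multiplier = 1.25,
                                        episode_starts_s = c(1800, 5400, 9000),
                                        episode_len_s = 300,
                                        design = study_design(),
                                        role = "mother") {
  profile <- member_profile(role, artifact_rate_per_hour = 0)
  episodes <- arousal_episodes(episode_starts_s,
                               episode_starts_s + episode_len_s,
                               rep(multiplier, length(episode_starts_s)))
  day <- as.Date("2023-05-01")  # a Monday: weekday window
  n_det <- 0L; n_tot <- 0L; fa <- 0L
  for (s in seq_len(n_sessions)) {
    sseed <- derive_seed(seed, s)
    calib <- simulate_calibration(profile, derive_seed(sseed, 999))
    baseline <- compute_baseline(calib)
    sess <- simulate_member_session(profile, design, day, sseed,
                                    episodes = episodes)
    trig <- detect_deviations(sess$stream, baseline, design$deviation_cfg)
    for (j in seq_len(nrow(episodes))) {
      n_tot <- n_tot + 1L
      hit <- any(trig$time_s >= episodes$start_s[j] &
                 trig$time_s <= episodes$end_s[j])
      if (hit) n_det <- n_det + 1L
    }
    in_any <- vapply(trig$time_s, function(tt)
      any(tt >= episodes$start_s & tt <= episodes$end_s), logical(1))
    fa <- fa + sum(!in_any)
  }
  list(sensitivity = n_det / n_tot, n_episodes = n_tot,
       n_detected = n_det, false_alarms = fa)
}

#' Engagement-recovery experiment
#'
#' Issues `n_prompts` surveys to a simulated respondent whose full-
#' response probability is known, simulates the responses, and
#' recovers the pooled engagement rate — a calibration check that the
#' response model and the rate computation agree.
#'
#' @param n_prompts number of prompts. Default 10000.
#' @param response_prob full-response probability. Default 0.8.
#' @param seed integer seed.
#' @param role respondent role.
#' @return list: `rate_pct` (recovered pooled engagement, percent),
#'   `n_prompts`.
#' @export
engagement_recovery_experiment <- function(n_prompts = 10000,
                                           response_prob = 0.8,
                                           seed = 1L, role = "mother") {
  profile <- member_profile(role, response_prob_random = response_prob,
                            response_prob_deviation = response_prob)
  catalog <- survey_catalog()
  t0 <- as.numeric(as.POSIXct("2023-05-01 16:00:00", tz = "UTC"))
  prompts <- data.frame(
    member_id = "m1",
    day = as.Date("2023-05-01"),
    kind = "random",
    scheduled_time = as.POSIXct(t0 + (seq_len(n_prompts) - 1) * 1200,
                                origin = "1970-01-01", tz = "UTC"),
    interval_index = NA_integer_,
    prompt_id = sprintf("m1-p%06d", seq_len(n_prompts)),
    parent_prompt = NA_character_
  )
  inst <- lapply(seq_len(n_prompts), function(j)
    issue_survey(prompts[j, ], role, catalog))
  inst <- simulate_responses(inst, profile, catalog, seed = seed,
                             partial_prob = 0)
  log <- responses_to_log(inst)
  list(rate_pct = pooled_engagement(log, "random"), n_prompts = n_prompts)
}

#' Sibling-agreement experiment
#'
#' Simulates per-family sibling response behavior with a shared
#' family-level propensity plus child-level noise, computes each
#' child's random-prompt completion rate over `n_prompts` binomial
#' prompts, and runs the agreement-and-aggregation pipeline: ICC(1),
#' the .51 aggregation gate, and a mother-vs-father paired comparison
#' on simulated parent rates. Default propensity distributions emulate
#' the family deployment this design comes from (child rates centred
#' near 45% with most variance between families; mothers near 80%,
#' fathers near 68%).
#'
#' @param n_families number of families. Default 11.
#' @param n_prompts random prompts per member. Default 40 (4 per day
#'   over 10 days).
#' @param seed integer seed.
#' @param child_base,child_between_sd,child_within_sd child propensity
#'   model: family mean ~ `child_base` +/- `child_between_sd`, child
#'   offset sd `child_within_sd`, clamped to `[0.02, 0.98]`.
#' @param mother_mean,mother_sd,father_mean,father_sd parent
#'   propensity distributions.
#' @return list: `icc_random` ([icc1()] result on sibling rate pairs),
#'   `aggregation` ([aggregate_children()] result),
#'   `mother_father` ([paired_comparison()] of parent rates),
#'   `rates` (per-member rate table).
#' @export
sibling_agreement_experiment <- function(n_families = 11, n_prompts = 40,
                                         seed = 1L,
                                         child_base = 0.446,
                                         child_between_sd = 0.25,
                                         child_within_sd = 0.07,
                                         mother_mean = 0.796, mother_sd = 0.092,
                                         father_mean = 0.679, father_sd = 0.157) {
  clamp <- function(p) pmin(pmax(p, 0.02), 0.98)
  sim <- with_seed(seed, {
    fam_mean <- clamp(rnorm(n_families, child_base, child_between_sd))
    child1_p <- clamp(fam_mean + rnorm(n_families, 0, child_within_sd))
    child2_p <- clamp(fam_mean + rnorm(n_families, 0, child_within_sd))
    mother_p <- clamp(rnorm(n_families, mother_mean, mother_sd))
    father_p <- clamp(rnorm(n_families, father_mean, father_sd))
    rate <- function(p) 100 * rbinom(n_families, n_prompts, p) / n_prompts
    list(child1 = rate(child1_p), child2 = rate(child2_p),
         mother = rate(mother_p), father = rate(father_p))
  })
  pairs <- cbind(sim$child1, sim$child2)
  agreement <- icc1(pairs)
  aggregation <- aggregate_children(pairs, agreement)
  list(icc_random = agreement,
       aggregation = aggregation,
       mother_father = paired_comparison(sim$mother, sim$father),
       rates = data.frame(family = seq_len(n_families),
                          mother = sim$mother, father = sim$father,
                          child1 = sim$child1, child2 = sim$child2))
}
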