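#' The survey instrument catalog
#'
#' The momentary survey asks four questions (five for parents): the
#' current emotion (13 options), its intensity (0--100 slider), the
#' current activity (12 options), present company (8 options for
#' children, 9 for parents), and — parents only — momentary parenting
#' stress (0--100 slider). Catalog sizes are enforced at construction.
#'
#' The canonical emotion list follows the instrument definition
#' ("relaxed", "scared"); report output can relabel these to the
#' "content" / "afraid-scared" wording some summaries use via
#' [emotion_aliases()].
#'
#' @param emotions 13 emotion labels.
#' @param activities 12 activity labels.
#' @param company_child 8 company options shown to children.
#' @param company_parent 9 company options shown to parents.
#' @return a `survey_catalog` list.
#' @export
survey_catalog <- function(
    emotions = c("happy", "nervous", "sad", "excited", "relaxed",
                 "frustrated", "scared", "angry", "surprised", "proud",
                 "ashamed", "guilty", "disgusted"),
    activities = c("homework", "cooking", "chores", "shopping", "eating",
                   "playing games", "work", "exercising", "watching TV",
                   "relaxing", "social media", "sports/outdoor activities"),
    company_child = c("alone", "mom", "dad", "brother", "sister",
                      "whole family", "friend", "group of friends"),
    company_parent = c("alone", "significant other", "younger son",
                       "older son", "younger daughter", "older daughter",
                       "whole family", "friend", "group of friends")) {
  if (length(emotions) != 13L) stop("exactly 13 emotions required", call. = FALSE)
  if (length(activities) != 12L) stop("exactly 12 activities required", call. = FALSE)
  if (length(company_child) != 8L) stop("exactly 8 child company options required", call. = FALSE)
  if (length(company_parent) != 9L) stop("exactly 9 parent company options required", call. = FALSE)
  if (anyDuplicated(emotions) || anyDuplicated(activities))
    stop("catalog labels must be unique", call. = FALSE)
  structure(list(emotions = emotions, activities = activities,
                 company_child = company_child,
                 company_parent = company_parent,
                 intensity_range = c(0L, 100L),
                 parenting_stress_range = c(0L, 100L)),
            class = "survey_catalog")
}

#' Report-layer emotion relabelling
#'
#' @return named character vector mapping canonical instrument labels
#'   to the relabelled report wording.
#' @export
emotion_aliases <- function() {
  c(relaxed = "content", scared = "afraid/scared")
}

required_fields <- function(role) {
  base <- c("emotion", "intensity", "activity", "company")
  if (role %in% c("mother", "father")) c(base, "parenting_stress") else base
}

#' Issue a survey for a prompt
#'
#' Creates a pending survey instance: 4 required questions for
#' children, 5 for parents, expiring 15 minutes (by default) after
#' issue.
#'
#' @param prompt a single-row prompt table.
#' @param role `"mother"`, `"father"` or `"child"`.
#' @param catalog a [survey_catalog()].
#' @param now issue time; defaults to the prompt's scheduled time.
#' @param survey_window_min minutes until expiry.
#' @return a `survey_instance`.
#' @export
issue_survey <- function(prompt, role, catalog = survey_catalog(),
                         now = prompt$scheduled_time,
                         survey_window_min = 15) {
  if (!role %in% c("mother", "father", "child"))
    stop("unknown role: '", role, "'", call. = FALSE)
  stopifnot(inherits(catalog, "survey_catalog"))
  issued <- as.numeric(now)
  structure(list(
    prompt_id = prompt$prompt_id,
    member_id = prompt$member_id,
    kind = prompt$kind,
    role = role,
    issued_at = issued,
    expires_at = issued + survey_window_min * 60,
    required = required_fields(role),
    answers = list(),
    answered_at = NA_real_,
    status = "pending"
  ), class = "survey_instance")
}

validate_answer <- function(instance, field, value, catalog) {
  ok_scale <- function(v) {
    is.numeric(v) && length(v) == 1L && !is.na(v) && v %% 1 == 0 &&
      v >= 0 && v <= 100
  }
  switch(field,
    emotion = {
      if (!value %in% catalog$emotions)
        stop("'", value, "' is not one of the 13 catalog emotions",
             call. = FALSE)
    },
    activity = {
      if (!value %in% catalog$activities)
        stop("'", value, "' is not one of the 12 catalog activities",
             call. = FALSE)
    },
    company = {
      opts <- if (instance$role == "child") catalog$company_child
              else catalog$company_parent
      if (!value %in% opts)
        stop("'", value, "' is not a company option for role ",
             instance$role, call. = FALSE)
    },
    intensity = ,
    parenting_stress = {
      if (!ok_scale(value))
        stop("`", field, "` must be an integer in 0..100", call. = FALSE)
    },
    stop("unknown survey field: '", field, "'", call. = FALSE)
  )
  invisible(TRUE)
}

#' Record one answer on a pending survey
#'
#' Answers are validated against the catalog (labels must be in the
#' respondent's option list; sliders are integers in 0--100) and
#' rejected at or after expiry — the 15-minute boundary is exclusive.
#' When the last required answer arrives the instance becomes
#' `complete`.
#'
#' @param instance a pending `survey_instance`.
#' @param field one of the instance's required fields.
#' @param value the answer.
#' @param now answer time (POSIXct or POSIX seconds).
#' @param catalog the [survey_catalog()] to validate against.
#' @return the updated `survey_instance`.
#' @export
record_answer <- function(instance, field, value, now,
                          catalog = survey_catalog()) {
  stopifnot(inherits(instance, "survey_instance"))
  if (instance$status != "pending")
    stop("survey is already ", instance$status, call. = FALSE)
  now <- as.numeric(now)
  if (now >= instance$expires_at)
    stop("answer rejected: survey expired at ",
         format_iso(as.POSIXct(instance$expires_at, origin = "1970-01-01",
                               tz = "UTC")), call. = FALSE)
  if (!field %in% instance$required)
    stop("field '", field, "' is not asked of role ", instance$role,
         call. = FALSE)
  validate_answer(instance, field, value, catalog)
  instance$answers[[field]] <- value
  if (all(instance$required %in% names(instance$answers))) {
    instance$status <- "complete"
    instance$answered_at <- now
  }
  instance
}

#' Finalize expired surveys
#'
#' Every pending instance past its expiry is classified: `incomplete`
#' if it was started (at least one answer) but not finished, `missed`
#' if no answer was given. Already-finalized instances are untouched,
#' so the operation is idempotent.
#'
#' @param instances list of `survey_instance` objects.
#' @param now classification time.
#' @return the updated list.
#' @export
finalize_expired <- function(instances, now) {
  now <- as.numeric(now)
  lapply(instances, function(inst) {
    if (inst$status == "pending" && now >= inst$expires_at) {
      inst$status <- if (length(inst$answers) >= 1L) "incomplete" else "missed"
    }
    inst
  })
}

#' Simulated respondent behavior
#'
#' Answers each pending instance fully with the profile's
#' kind-specific response probability, partially (a strict subset of
#' required answers) with `partial_prob`, and otherwise ignores it;
#' instances are then finalized at their expiry. Answer content is
#' drawn from categorical distributions over the catalog; the default
#' emotion weights put most mass on happy/relaxed with a tail of
#' negative emotions, and the default activity weights favour
#' relaxing, chores, work, TV and eating — the broad shape observed in
#' family deployments of this instrument. Deterministic under `seed`.
#'
#' @param instances list of `survey_instance` objects.
#' @param profile a [member_profile()] supplying response
#'   probabilities.
#' @param catalog a [survey_catalog()].
#' @param seed integer seed.
#' @param partial_prob probability of a started-but-unfinished
#'   response, in `[0, 1]`. Default 0.05.
#' @param emotion_weights,activity_weights optional nonnegative weight
#'   vectors over the catalog lists.
#' @return the updated (finalized) list.
#' @export
simulate_responses <- function(instances, profile, catalog = survey_catalog(),
                               seed = 0L, partial_prob = 0.05,
                               emotion_weights = NULL,
                               activity_weights = NULL) {
  stopifnot(inherits(profile, "member_profile"),
            inherits(catalog, "survey_catalog"))
  if (partial_prob < 0 || partial_prob > 1 ||
      profile$response_prob_random + partial_prob > 1 + 1e-12 ||
      profile$response_prob_deviation + partial_prob > 1 + 1e-12)
    stop("response probabilities must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  if (is.null(emotion_weights))
    emotion_weights <- c(happy = 35, nervous = 7, sad = 2, excited = 8,
                         relaxed = 32, frustrated = 11, scared = 1,
                         angry = 1, surprised = 1, proud = 1,
                         ashamed = 0.4, guilty = 0.4, disgusted = 0.2)
  if (is.null(activity_weights))
    activity_weights <- c(homework = 2, cooking = 4, chores = 13,
                          shopping = 4, eating = 10, `playing games` = 9,
                          work = 13, exercising = 3, `watching TV` = 12,
                          relaxing = 19, `social media` = 3,
                          `sports/outdoor activities` = 8)
  stopifnot(length(emotion_weights) == 13L, length(activity_weights) == 12L,
            all(emotion_weights >= 0), all(activity_weights >= 0))

  with_seed(seed, {
    out <- lapply(instances, function(inst) {
      if (inst$status != "pending") return(inst)
      p_full <- if (inst$kind == "deviation") profile$response_prob_deviation
                else profile$response_prob_random
      u <- runif(1)
      if (u >= p_full + partial_prob) return(inst)  # ignored
      fields <- inst$required
      if (u >= p_full) {            # partial: strict nonempty subset
        k <- sample(length(fields) - 1L, 1L)
        fields <- sample(fields, k)
      }
      at <- inst$issued_at + runif(1, 30, (inst$expires_at - inst$issued_at) - 30)
      comp <- if (inst$role == "child") catalog$company_child
              else catalog$company_parent
      for (f in fields) {
        value <- switch(f,
          emotion = sample(catalog$emotions, 1L, prob = emotion_weights),
          activity = sample(catalog$activities, 1L, prob = activity_weights),
          company = sample(comp, 1L),
          intensity = sample(0:100, 1L),
          parenting_stress = sample(0:100, 1L))
        inst <- record_answer(inst, f, value, at, catalog)
      }
      inst
    })
    finalize_expired(out, now = max(vapply(out, `[[`, 0, "expires_at")) + 1)
  })
}

#' Flatten survey instances into a response log
#'
#' @param instances list of finalized `survey_instance` objects.
#' @param blinded drop the prompt-kind column?
#' @return data.frame with one row per survey: member, role, kind,
#'   issue/answer ISO times, the five answers, status.
#' @export
responses_to_log <- function(instances, blinded = FALSE) {
  get <- function(inst, f) {
    v <- inst$answers[[f]]
    if (is.null(v)) NA else v
  }
  df <- do.call(rbind, lapply(instances, function(inst) {
    data.frame(
      member_id = inst$member_id,
      role = inst$role,
      kind = inst$kind,
      issued_iso = format_iso(as.POSIXct(inst$issued_at,
                                         origin = "1970-01-01", tz = "UTC")),
      answered_iso = if (is.na(inst$answered_at)) NA_character_ else
        format_iso(as.POSIXct(inst$answered_at, origin = "1970-01-01",
                              tz = "UTC")),
      emotion = as.character(get(inst, "emotion")),
      intensity = as.numeric(get(inst, "intensity")),
      activity = as.character(get(inst, "activity")),
      company = as.character(get(inst, "company")),
      parenting_stress = as.numeric(get(inst, "parenting_stress")),
      status = inst$status
    )
  }))
  if (blinded) df$kind <- NULL
  df
}
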