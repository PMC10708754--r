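# Independent brute-force oracles used to check the package's
# vectorised implementations. These deliberately use naive loops and
# textbook formulas, not the code paths under test.

# pointwise biexponential kernel sum, one sample at a time
oracle_kernel_sum <- function(stream, events) {
  t <- (seq_along(stream$samples) - 1) / stream$sample_rate_hz
  out <- stream$samples
  for (j in seq_len(nrow(events))) {
    tt <- t - events$onset_s[j]
    k <- ifelse(tt >= 0,
                exp(-tt / events$decay_tau_s[j]) -
                  exp(-tt / events$rise_tau_s[j]), 0)
    m <- max(k)
    for (i in seq_along(out))
      if (tt[i] >= 0) out[i] <- out[i] + events$amplitude_us[j] * k[i] / m
  }
  out
}

# windowed mean computed independently at every index
oracle_moving_avg <- function(x, rate, window_s) {
  n <- length(x)
  k <- floor(window_s / 2 * rate + 1e-9)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - k):min(n, i + k)
    mean(x[idx])
  }, numeric(1))
}

# exhaustive offline deviation scan: at every sample, re-check the full
# sustain window, then apply the refractory rule greedily
oracle_detect_times <- function(stream, baseline_mean, cfg) {
  rate <- stream$sample_rate_hz
  sm <- oracle_moving_avg(stream$samples, rate, cfg$smooth_window_s)
  thr <- baseline_mean * (1 + cfg$threshold_fraction)
  above <- sm >= thr * (1 - 1e-9)
  need <- round(cfg$sustain_s * rate) + 1
  t <- (seq_along(sm) - 1) / rate
  times <- numeric(0)
  last <- -Inf
  for (i in seq_along(sm)) {
    if (i < need) next
    if (!all(above[(i - need + 1):i])) next
    if (t[i] >= last + cfg$refractory_s) {
      times <- c(times, t[i])
      last <- t[i]
    }
  }
  times
}

# one-way random-effects ANOVA via stats::aov
oracle_icc1_aov <- function(m) {
  df <- data.frame(value = as.vector(t(m)),
                   family = factor(rep(seq_len(nrow(m)), each = 2)))
  tab <- summary(stats::aov(value ~ family, data = df))[[1]]
  msb <- tab["family", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  (msb - msw) / (msb + msw)
}

# quick builder for finalized response-log rows
make_log <- function(member_id, role, kind, status,
                     emotion = NA_character_, activity = NA_character_) {
  data.frame(member_id = member_id, role = role, kind = kind,
             issued_iso = NA_character_, answered_iso = NA_character_,
             emotion = emotion, intensity = NA_real_, activity = activity,
             company = NA_character_, parenting_stress = NA_real_,
             status = status)
}

# issue a standalone survey instance without a scheduler prompt
make_instance <- function(kind = "random", role = "child",
                          issued = as.POSIXct("2023-05-01 16:00:00",
                                              tz = "UTC")) {
  prompt <- data.frame(member_id = "m1", kind = kind, prompt_id = "p1",
                       scheduled_time = issued)
  issue_survey(prompt, role, survey_catalog())
}
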