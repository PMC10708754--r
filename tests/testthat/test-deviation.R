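test_that("baseline is the mean over the half-open calibration window", {
  s <- eda_stream(rep(1, 720))
  b <- compute_baseline(s)
  expect_equal(b$mean_eda_us, 1.0)
  expect_equal(b$n_samples, 720L)

  ramp <- eda_stream(seq(0, 2, length.out = 720))
  expect_equal(compute_baseline(ramp)$mean_eda_us, 1.0)

  set.seed(5)  # fixture only
  x <- runif(1200, 0.5, 1.5)
  noisy <- eda_stream(x)
  b <- compute_baseline(noisy, window_start_s = 30, window_s = 180)
  t <- stream_times(noisy)
  idx <- which(t >= 30 & t < 210)
  expect_equal(b$mean_eda_us, sum(x[idx]) / length(idx), tolerance = 1e-9)

  expect_error(compute_baseline(eda_stream(rep(1, 100))), "past the stream end")
  expect_error(compute_baseline(s, window_s = 20), ">= 30")
})

test_that("smoothing equals the brute-force windowed mean and has clean edge cases", {
  set.seed(6)  # fixture only
  s <- eda_stream(runif(400, 0, 2))
  expect_identical(smooth_stream(s, 0), s)

  const <- eda_stream(rep(1.3, 100))
  expect_equal(smooth_stream(const, 5)$samples, const$samples)

  sm <- smooth_stream(s, 5)
  expect_equal(sm$samples, oracle_moving_avg(s$samples, 4, 5),
               tolerance = 1e-12)
})

test_that("a sustained suprathreshold stream triggers once per refractory period", {
  cfg <- deviation_config()
  b <- compute_baseline(eda_stream(rep(1, 720)))
  hot <- eda_stream(rep(1.25, 4 * 2000))
  trig <- detect_deviations(hot, b, cfg)
  expect_gt(nrow(trig), 1)
  expect_equal(trig$time_s[1], cfg$sustain_s)
  expect_equal(diff(trig$time_s), rep(cfg$refractory_s, nrow(trig) - 1))

  warm <- eda_stream(rep(1.10, 4 * 2000))
  expect_equal(nrow(detect_deviations(warm, b, cfg)), 0L)

  zero <- structure(list(mean_eda_us = 0, window_s = 180, n_samples = 720,
                         member_id = NA), class = "eda_baseline")
  expect_error(detect_deviations(hot, zero, cfg), "> 0")
})

test_that("threshold boundary: an exact 1.20 x baseline step fires, minus epsilon does not", {
  cfg <- deviation_config()
  b <- compute_baseline(eda_stream(rep(1, 720)))
  step_exact <- eda_stream(c(rep(1, 200), rep(1.2, 4 * 120)))
  expect_gt(nrow(detect_deviations(step_exact, b, cfg)), 0)
  step_under <- eda_stream(c(rep(1, 200), rep(1.2 - 1e-6, 4 * 120)))
  expect_equal(nrow(detect_deviations(step_under, b, cfg)), 0L)
})

test_that("streaming detector matches the exhaustive offline scan", {
  cfg <- deviation_config(sustain_s = 5, refractory_s = 60)
  for (s in 1:25) {
    x <- withr::with_seed(s, {
      base <- 1 + 0.05 * cumsum(rnorm(1200)) / sqrt(1200)
      # occasional sustained elevations
      if (s %% 3 == 0) base[400:700] <- base[400:700] * 1.3
      pmax(base + rnorm(1200, 0, 0.05), 0)
    })
    stream <- eda_stream(x)
    got <- detect_deviations(stream, compute_baseline(eda_stream(rep(1, 720))),
                             cfg)
    expect_equal(got$time_s, oracle_detect_times(stream, 1, cfg))
  }
})

test_that("raising the threshold never increases the trigger count", {
  for (s in 1:10) {
    x <- withr::with_seed(s, pmax(1 + rnorm(2400, 0.1, 0.15), 0))
    stream <- eda_stream(x)
    b <- compute_baseline(eda_stream(rep(1, 720)))
    counts <- vapply(c(0.15, 0.20, 0.25), function(tf)
      nrow(detect_deviations(stream, b,
                             deviation_config(threshold_fraction = tf,
                                              sustain_s = 5,
                                              refractory_s = 60))),
      numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("gating keeps only in-window triggers and the cap limits emissions per day", {
  design <- study_design()
  mk <- function(times_utc) {
    tt <- as.POSIXct(times_utc, tz = "UTC")
    data.frame(time_s = as.numeric(tt), time = tt,
               smoothed_eda_us = 1.3, baseline_us = 1, threshold_us = 1.2,
               emitted = NA)
  }
  # 10 in-window triggers on a weekday (16:00-20:00), cap 4
  t10 <- mk(sprintf("2023-05-01 16:%02d:00", seq(5, 50, by = 5)))
  g <- gate_and_cap(t10, design)
  expect_equal(sum(g$emitted), 4L)
  expect_true(all(which(g$emitted) == 1:4))

  # all outside the window: none emitted
  out <- mk(c("2023-05-01 09:00:00", "2023-05-01 21:00:00"))
  expect_equal(sum(gate_and_cap(out, design)$emitted), 0L)

  # mixed in/out across two days equals filter-then-take-first-4 per day
  mixed <- mk(c("2023-05-01 15:00:00", "2023-05-01 16:10:00",
                "2023-05-01 17:00:00", "2023-05-01 17:30:00",
                "2023-05-01 18:00:00", "2023-05-01 18:30:00",
                "2023-05-01 19:00:00", "2023-05-06 09:00:00",
                "2023-05-06 10:30:00", "2023-05-06 17:59:00"))
  g <- gate_and_cap(mixed, design)
  brute <- logical(10)
  for (d in c("2023-05-01", "2023-05-06")) {
    win <- study_windows(design, as.Date(d), n_days = 1)
    idx <- which(as.Date(mixed$time, tz = "UTC") == as.Date(d) &
                 mixed$time >= win$window_start & mixed$time < win$window_end)
    brute[head(idx, 4)] <- TRUE
  }
  expect_equal(g$emitted, brute)

  empty <- gate_and_cap(t10[0, ], design)
  expect_equal(nrow(empty), 0L)
})

test_that("emitted triggers respect the refractory spacing", {
  design <- study_design()
  p <- member_profile("father", artifact_rate_per_hour = 0)
  calib <- simulate_calibration(p, seed = 21)
  b <- compute_baseline(calib)
  dur <- 4 * 3600
  sess <- simulate_member_session(p, design, as.Date("2023-05-03"), seed = 22,
                                  episodes = arousal_episodes(0.1, dur - 0.1,
                                                              1.5))
  trig <- gate_and_cap(detect_deviations(sess$stream, b,
                                         design$deviation_cfg), design)
  em <- trig$time_s[trig$emitted]
  expect_equal(sum(trig$emitted), design$deviation_cfg$daily_cap)
  if (length(em) > 1)
    expect_true(all(diff(em) >= design$deviation_cfg$refractory_s))
})
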