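test_that("study windows follow the weekday/weekend clock times", {
  design <- study_design()
  w <- study_windows(design, as.Date("2023-05-01"))  # a Monday
  expect_equal(nrow(w), 10L)
  expect_equal(sum(w$is_weekend), 2L)  # Sat 6th, Sun 7th
  lens <- as.numeric(w$window_end - w$window_start, units = "hours")
  expect_true(all(lens[!w$is_weekend] == 4))
  expect_true(all(lens[w$is_weekend] == 8))
  expect_equal(format(w$window_start[1], "%H:%M"), "16:00")
  expect_equal(format(w$window_start[w$is_weekend][1], "%H:%M"), "10:00")

  # any start date: window count equals n_days
  for (d in c("2023-05-04", "2023-07-15"))
    expect_equal(nrow(study_windows(design, as.Date(d))), 10L)
})

test_that("interval partition tiles the window exactly with half-open parts", {
  design <- study_design()
  w <- study_windows(design, as.Date("2023-05-01"), n_days = 7)
  wd <- w[!w$is_weekend, ][1, ]
  we <- w[w$is_weekend, ][1, ]
  iv_wd <- partition_intervals(wd$window_start, wd$window_end, 4)
  iv_we <- partition_intervals(we$window_start, we$window_end, 4)
  expect_true(all(as.numeric(iv_wd$end - iv_wd$start, units = "mins") == 60))
  expect_true(all(as.numeric(iv_we$end - iv_we$start, units = "mins") == 120))

  # exhaustive 1-s membership scan: every instant in exactly one interval
  instants <- seq(as.numeric(wd$window_start), as.numeric(wd$window_end) - 1,
                  by = 1)
  membership <- vapply(instants, function(x)
    sum(x >= as.numeric(iv_wd$start) & x < as.numeric(iv_wd$end)),
    numeric(1))
  expect_true(all(membership == 1))

  odd <- as.POSIXct("2023-05-01 16:00:01", tz = "UTC")
  expect_error(partition_intervals(wd$window_start, odd, 4), "whole-second")
})

test_that("each day draws exactly one prompt per interval, reproducibly", {
  design <- study_design()
  w <- study_windows(design, as.Date("2023-05-01"), n_days = 2)
  for (s in c(1, 99, 4242)) {
    p <- draw_random_prompts(w[1, ], 4, seed = s, member_id = "m")
    expect_equal(nrow(p), 4L)
    expect_equal(sort(p$interval_index), 0:3)
    expect_true(all(p$scheduled_time >= p$interval_start &
                    p$scheduled_time < p$interval_end))
  }
  a <- draw_random_prompts(w[1, ], 4, seed = 7, member_id = "m")
  b <- draw_random_prompts(w[1, ], 4, seed = 7, member_id = "m")
  expect_identical(a$scheduled_time, b$scheduled_time)
})

test_that("within-interval prompt offsets are uniform (Kolmogorov-Smirnov)", {
  design <- study_design()
  w <- study_windows(design, as.Date("2023-05-01"), n_days = 1)
  offs <- vapply(1:10000, function(s) {
    p <- draw_random_prompts(w[1, ], 4, seed = s, member_id = "m")
    as.numeric(p$scheduled_time[1]) - as.numeric(p$interval_start[1])
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(offs, "punif", 0, 3600))
  expect_gt(ks$p.value, 0.01)
})

test_that("reminders obey the within-interval rule", {
  design <- study_design()
  w <- study_windows(design, as.Date("2023-05-01"), n_days = 1)
  p <- draw_random_prompts(w[1, ], 4, seed = 3, member_id = "m")
  mid <- p[1, ]
  mid$scheduled_time <- mid$interval_start + 600  # 10 min into the interval

  expect_null(schedule_reminder(mid, answered = TRUE, seed = 1))

  rem <- schedule_reminder(mid, answered = FALSE, seed = 1)
  expect_equal(rem$kind, "reminder")
  expect_equal(rem$parent_prompt, mid$prompt_id)
  expect_gte(as.numeric(rem$scheduled_time),
             as.numeric(mid$scheduled_time) + 15 * 60)
  expect_lt(as.numeric(rem$scheduled_time), as.numeric(mid$interval_end))

  # prompt at interval end minus 1 s: no room for a reminder
  late <- p[1, ]
  late$scheduled_time <- late$interval_end - 1
  expect_null(schedule_reminder(late, answered = FALSE, seed = 1))

  dev <- p[1, ]
  dev$kind <- "deviation"
  expect_error(schedule_reminder(dev, answered = FALSE, seed = 1),
               "random prompts only")
})

test_that("merged prompt streams are ordered with the minimum gap enforced", {
  design <- study_design()
  w <- study_windows(design, as.Date("2023-05-01"), n_days = 1)
  rnd <- draw_random_prompts(w[1, ], 4, seed = 5, member_id = "m")

  # disjoint streams: sorted union, times untouched
  far <- rnd[2, ]
  far$kind <- "deviation"
  far$scheduled_time <- far$scheduled_time + 3600
  merged <- merge_prompt_streams(rnd[1, ], far, min_gap_s = 120)
  expect_equal(as.numeric(merged$scheduled_time),
               sort(as.numeric(c(rnd$scheduled_time[1],
                                 far$scheduled_time))))

  # 1 s apart: the later one is pushed to +120 s
  near <- rnd[1, ]
  near$kind <- "deviation"
  near$prompt_id <- "m-dev"
  near$scheduled_time <- rnd$scheduled_time[1] + 1
  merged <- merge_prompt_streams(rnd[1, ], near, min_gap_s = 120)
  expect_equal(diff(as.numeric(merged$scheduled_time)), 120)

  # collision stress: all output gaps >= min_gap_s
  for (s in 1:20) {
    dev <- rnd
    dev$kind <- "deviation"
    dev$prompt_id <- paste0(dev$prompt_id, "-d")
    dev$scheduled_time <- withr::with_seed(s,
      rnd$scheduled_time + runif(4, -300, 300))
    m <- merge_prompt_streams(rnd, dev, min_gap_s = 120)
    expect_true(all(diff(as.numeric(m$scheduled_time)) >= 120))
  }
})

test_that("the blinded export carries no field that reveals prompt kind", {
  design <- study_design()
  w <- study_windows(design, as.Date("2023-05-01"), n_days = 1)
  rnd <- draw_random_prompts(w[1, ], 4, seed = 5, member_id = "m")
  dev <- rnd[1, ]
  dev$kind <- "deviation"
  dev$prompt_id <- "m-d0"
  dev$interval_index <- NA_integer_
  dev$scheduled_time <- dev$scheduled_time + 1800
  blind <- blind_schedule(merge_prompt_streams(rnd, dev, 120))
  expect_setequal(names(blind), c("member_id", "day", "scheduled_time_iso"))
})

test_that("a full 4-member x 10-day random schedule generates in under a second", {
  design <- study_design()
  w <- study_windows(design, as.Date("2023-05-01"))
  elapsed <- system.time({
    prompts <- NULL
    for (m in 1:4) for (d in 1:10)
      prompts <- rbind(prompts,
                       draw_random_prompts(w[d, ], 4, seed = m * 100 + d,
                                           member_id = paste0("m", m)))
  })["elapsed"]
  expect_equal(nrow(prompts), 160L)
  expect_lt(elapsed, 1)
})
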