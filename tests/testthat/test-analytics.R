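test_that("engagement is completes over receives, per kind, with undefined flags", {
  log <- rbind(
    make_log(rep("a", 10), "mother", "random",
             c(rep("complete", 8), "incomplete", "missed")),
    make_log(rep("a", 2), "mother", "deviation", c("complete", "missed"))
  )
  e <- engagement(log)
  expect_equal(e$rate_pct[e$kind == "random"], 80)
  expect_equal(e$rate_pct[e$kind == "deviation"], 50)
  expect_equal(e$rate_pct[e$kind == "overall"], 100 * 9 / 12)

  only_random <- make_log(rep("b", 4), "child", "random", rep("complete", 4))
  e <- engagement(only_random)
  expect_true(e$undefined[e$kind == "deviation"])
  expect_true(is.na(e$rate_pct[e$kind == "deviation"]))

  pend <- make_log("c", "child", "random", "pending")
  expect_error(engagement(pend), "pending")
})

test_that("pooled engagement is invariant under duplicating members", {
  log <- rbind(
    make_log(rep("a", 10), "mother", "random",
             c(rep("complete", 7), rep("missed", 3))),
    make_log(rep("b", 5), "child", "random",
             c(rep("complete", 2), rep("missed", 3)))
  )
  dup <- log
  dup$member_id <- paste0(dup$member_id, "-copy")
  expect_equal(pooled_engagement(rbind(log, dup), "random"),
               pooled_engagement(log, "random"))
  expect_equal(pooled_engagement(log, "random"), 100 * 9 / 15)
})

test_that("ICC(1) reproduces its defining cases and the ANOVA oracle", {
  perfect <- icc1(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(perfect$icc1, 1)
  expect_equal(perfect$band, "very strong")
  expect_true(perfect$aggregate)

  disagree <- icc1(rbind(c(1, 2), c(2, 1), c(1, 2)))
  expect_lt(disagree$icc1, 0)
  expect_equal(disagree$band, "lack")
  expect_false(disagree$aggregate)

  for (s in 1:50) {
    m <- withr::with_seed(s, matrix(rnorm(2 * sample(3:30, 1), 50, 20),
                                    ncol = 2))
    expect_equal(icc1(m)$icc1, oracle_icc1_aov(m), tolerance = 1e-9)
  }

  flat <- icc1(matrix(5, nrow = 4, ncol = 2))
  expect_true(flat$undefined)
  expect_true(is.na(flat$icc1))

  expect_error(icc1(data.frame(family = c(1, 1, 1, 2, 2, 3, 3),
                               value = 1:7)), "exactly 2")
  expect_error(icc1(cbind(1:2, 1:2)), "at least 3")
})

test_that("agreement bands follow the .31/.51/.71/.91 cut points", {
  mk <- function(target) {
    # two-point construction with a known ICC: between/within mix
    within <- 1 - target
    between <- target
    withr::with_seed(42, {
      fam <- rnorm(200, 0, sqrt(between))
      matrix(rep(fam, 2) + rnorm(400, 0, sqrt(within)), ncol = 2)
    })
  }
  expect_equal(icc1(mk(0.2))$band, "lack", tolerance = 0)
  got <- icc1(mk(0.95))
  expect_equal(got$band, "very strong")
  bands <- icc_band(c(0.1, 0.35, 0.55, 0.8, 0.99))
  expect_equal(bands, c("lack", "weak", "moderate", "strong", "very strong"))
})

test_that("child aggregation fires iff ICC(1) >= .51", {
  high <- icc1(cbind(c(60, 40, 20), c(62, 41, 19)))
  expect_true(high$aggregate)
  agg <- aggregate_children(rbind(c(60, 70), c(40, 42), c(20, 18)), high)
  expect_true(agg$aggregated)
  expect_equal(agg$values$value, c(65, 41, 19))

  low <- icc1(rbind(c(1, 2), c(2, 1), c(1, 2)))
  keep <- aggregate_children(rbind(c(60, 70), c(40, 42), c(20, 18)), low)
  expect_false(keep$aggregated)
  expect_equal(nrow(keep$values), 6L)

  for (s in 1:100) {
    m <- withr::with_seed(s, matrix(runif(10, 0, 100), ncol = 2))
    agg <- aggregate_children(m, icc1(cbind(c(1, 2, 3), c(1, 2, 3))))
    expect_equal(agg$values$value, (m[, 1] + m[, 2]) / 2)
  }
})

test_that("paired comparisons match the textbook formulas and flag degeneracies", {
  same <- paired_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$cohens_d, 0)
  expect_equal(same$p_two_sided, 1)

  const <- paired_comparison(c(2, 3, 4), c(1, 2, 3))
  expect_true(const$zero_variance)
  expect_true(is.na(const$t_stat))

  for (s in 1:100) {
    n <- withr::with_seed(s, sample(5:40, 1))
    a <- withr::with_seed(s + 1000, rnorm(n, 60, 15))
    b <- withr::with_seed(s + 2000, rnorm(n, 55, 15))
    got <- paired_comparison(a, b)
    ref <- stats::t.test(a, b, paired = TRUE)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-9)
    expect_equal(got$cohens_d, mean(a - b) / stats::sd(a - b),
                 tolerance = 1e-12)
    expect_equal(got$df, n - 1)
  }

  big <- paired_comparison(c(10, 30, 20, 40), c(1, 2, 3, 4))
  expect_equal(big$interpretation, "large")
})

test_that("endorsement tables sum to 100 with dashes for zero counts", {
  one <- make_log("a", "mother", "random", "complete", emotion = "happy")
  tab <- endorsement_table(one, "emotion")
  expect_equal(tab["happy", "mother.random"], 100)
  expect_equal(sum(tab[, "mother.random"]), 100)
  fm <- format_endorsement(tab)
  expect_equal(fm["happy", "mother.random"], "100.00%")
  expect_true(all(fm[rownames(fm) != "happy", "mother.random"] == "-"))

  emos <- survey_catalog()$emotions
  log <- withr::with_seed(8, rbind(
    make_log(rep("a", 200), "mother", "random", "complete",
             emotion = sample(emos, 200, replace = TRUE)),
    make_log(rep("b", 150), "child", "deviation", "complete",
             emotion = sample(emos[1:5], 150, replace = TRUE))
  ))
  tab <- suppressWarnings(endorsement_table(log, "emotion"))
  expect_true(all(abs(colSums(tab) - 100) < 0.1))
  counts <- attr(tab, "counts")
  fm <- format_endorsement(tab)
  expect_true(all((fm == "-") == (counts == 0)))

  aliased <- format_endorsement(tab, aliases = emotion_aliases())
  expect_true("content" %in% rownames(aliased))
  expect_true("afraid/scared" %in% rownames(aliased))
  expect_false("relaxed" %in% rownames(aliased))

  w <- testthat::capture_warnings(endorsement_table(
    rbind(log, make_log("c", "father", "random", "missed")), "emotion"))
  expect_true(any(grepl("father.random", w)))
})

test_that("USE subscale scores exclude ease items 7-8", {
  all7 <- use_scores(rep(7, 11), rep(7, 4))
  expect_equal(all7$ease_of_use, 7)
  expect_equal(all7$satisfaction, 7)

  # items 7-8 never enter the mean, whatever they hold
  for (x in list(c(1, 1), c(7, 7), c(NA, NA))) {
    ease <- c(rep(4, 6), x, rep(4, 3))
    expect_equal(use_scores(ease, rep(5, 4))$ease_of_use, 4)
  }

  for (s in 1:25) {
    items <- withr::with_seed(s, sample(1:7, 15, replace = TRUE))
    got <- use_scores(items[1:11], items[12:15])
    expect_equal(got$ease_of_use, mean(items[c(1:6, 9:11)]))
    expect_equal(got$satisfaction, mean(items[12:15]))
  }

  expect_error(use_scores(rep(8, 11), rep(7, 4)), "1..7")
  expect_error(use_scores(rep(7, 10), rep(7, 4)), "11")
  flagged <- use_scores(c(NA, rep(4, 10)), rep(4, 4))
  expect_true(flagged$missing_flag)
  expect_equal(flagged$ease_of_use, 4)
})

test_that("correlation matrices match the base oracles with the table's marks", {
  df <- withr::with_seed(12, data.frame(x = rnorm(30), y = rnorm(30),
                                        z = rnorm(30)))
  df$w <- df$x * 2 + rnorm(30, 0, 0.1)  # strongly correlated
  got <- correlation_matrix(df)
  expect_equal(diag(got$r), rep(1, 4), ignore_attr = TRUE)
  for (i in 1:3) for (j in (i + 1):4) {
    ref <- stats::cor.test(df[[i]], df[[j]])
    expect_equal(got$r[i, j], unname(ref$estimate), tolerance = 1e-9)
    expect_equal(got$p[i, j], ref$p.value, tolerance = 1e-9)
  }
  expect_equal(got$mark["x", "w"], "**")

  const <- correlation_matrix(data.frame(a = rep(1, 10), b = rnorm(10)))
  expect_true(is.na(const$r["a", "b"]))

  # dagger convention: large but nonsignificant r gets "+"
  small <- withr::with_seed(3, {
    x <- rnorm(5); data.frame(x = x, y = x + rnorm(5, 0, 1.4))
  })
  cm <- correlation_matrix(small)
  if (!is.na(cm$r["x", "y"]) && abs(cm$r["x", "y"]) > 0.5 &&
      cm$p["x", "y"] >= 0.05)
    expect_equal(cm$mark["x", "y"], "+")
})
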