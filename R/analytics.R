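#' Per-member engagement rates
#'
#' Engagement is the percentage of surveys completed out of prompts
#' received, computed separately for random and deviation prompts and
#' pooled overall per member. Incomplete and missed surveys both count
#' as non-complete. A member-kind cell with zero prompts received has
#' an undefined (not zero) rate, flagged via `undefined`.
#'
#' @param log a finalized response log ([responses_to_log()]); must
#'   contain no pending rows.
#' @return data.frame: `member_id`, `role`, `kind` (random, deviation,
#'   overall), `n_received`, `n_complete`, `rate_pct`, `undefined`.
#' @export
engagement <- function(log) {
  if (any(log$status == "pending"))
    stop("log contains pending surveys; finalize before computing rates",
         call. = FALSE)
  cell <- function(member, role, kind, rows) {
    n <- nrow(rows)
    nc <- sum(rows$status == "complete")
    data.frame(member_id = member, role = role, kind = kind,
               n_received = n, n_complete = nc,
               rate_pct = if (n > 0) 100 * nc / n else NA_real_,
               undefined = n == 0)
  }
  out <- NULL
  for (m in unique(log$member_id)) {
    g <- log[log$member_id == m, , drop = FALSE]
    role <- g$role[1]
    for (k in c("random", "deviation"))
      out <- rbind(out, cell(m, role, k, g[g$kind == k, , drop = FALSE]))
    out <- rbind(out, cell(m, role, "overall", g))
  }
  rownames(out) <- NULL
  out
}

#' Pooled engagement across members
#'
#' Two aggregations are available: `"pooled"` divides total completes
#' by total prompts across all members; `"member_mean"` averages the
#' per-member rates (members with zero prompts of the kind are
#' dropped). Study summaries of this design do not pin down which is
#' used, so both are exposed and neither is privileged.
#'
#' @param log a finalized response log.
#' @param kind `"random"`, `"deviation"` or `"overall"`.
#' @param method `"pooled"` or `"member_mean"`.
#' @return the engagement percentage (scalar).
#' @export
pooled_engagement <- function(log, kind = "overall",
                              method = c("pooled", "member_mean")) {
  method <- match.arg(method)
  e <- engagement(log)
  e <- e[e$kind == kind & !e$undefined, , drop = FALSE]
  if (nrow(e) == 0L) return(NA_real_)
  if (method == "pooled") 100 * sum(e$n_complete) / sum(e$n_received)
  else mean(e$rate_pct)
}

icc_bands <- data.frame(
  lo = c(-Inf, 0.31, 0.51, 0.71, 0.91),
  band = c("lack", "weak", "moderate", "strong", "very strong")
)

#' Agreement band for an ICC(1) value
#'
#' Maps an ICC(1) estimate to the conventional agreement bands:
#' below .31 lack, .31--.50 weak, .51--.70 moderate, .71--.90 strong,
#' .91 and above very strong. Negative estimates fall in "lack".
#'
#' @param icc numeric ICC(1) value(s).
#' @return character band label(s).
#' @export
icc_band <- function(icc) {
  icc_bands$band[findInterval(icc, icc_bands$lo)]
}

#' One-way random-effects ICC(1) for sibling pairs
#'
#' Estimates agreement between the two children of each family from
#' the one-way random-effects ANOVA:
#' `ICC(1) = (MSB - MSW) / (MSB + (k - 1) MSW)` with `k = 2`, where
#' MSB and MSW are the between- and within-family mean squares.
#' Negative estimates are reported as computed (not clipped) and fall
#' in the "lack" band. Agreement bands follow the standard cut points
#' .31/.51/.71/.91, and sibling scores may be aggregated to one
#' family value when `ICC(1) >= .51` (the a priori cutoff indicating
#' between-family variation exceeds within-family variation).
#'
#' @param pairs a two-column matrix/data.frame (one row per family) or
#'   a data.frame with columns `family` and `value` containing exactly
#'   two children per family. At least 3 families, no missing values.
#' @return an `icc_result`: `icc1`, `band`, `aggregate`, `msb`, `msw`,
#'   `n_families`, `k`, `undefined`.
#' @export
icc1 <- function(pairs) {
  if (is.data.frame(pairs) && all(c("family", "value") %in% names(pairs))) {
    counts <- table(pairs$family)
    if (any(counts != 2L))
      stop("every family must contribute exactly 2 children", call. = FALSE)
    fam <- split(pairs$value, pairs$family)
    m <- do.call(rbind, fam)
  } else {
    m <- as.matrix(pairs)
    if (ncol(m) != 2L)
      stop("every family must contribute exactly 2 children", call. = FALSE)
  }
  if (anyNA(m)) stop("missing values are not allowed", call. = FALSE)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 families", call. = FALSE)
  k <- 2L
  gm <- mean(m)
  fm <- rowMeans(m)
  msb <- k * sum((fm - gm)^2) / (n - 1)
  msw <- sum((m - fm)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0) {
    return(structure(list(icc1 = NA_real_, band = NA_character_,
                          aggregate = NA, msb = msb, msw = msw,
                          n_families = n, k = k, undefined = TRUE),
                     class = "icc_result"))
  }
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  band <- icc_band(icc)
  structure(list(icc1 = icc, band = band, aggregate = icc >= 0.51,
                 msb = msb, msw = msw, n_families = n, k = k,
                 undefined = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$undefined) cat("ICC(1): undefined (zero total variance)\n")
  else cat(sprintf("ICC(1) = %.3f (%s agreement); aggregate children: %s\n",
                   x$icc1, x$band, if (x$aggregate) "yes" else "no"))
  invisible(x)
}

#' Aggregate sibling values when agreement warrants it
#'
#' If the agreement gate is open (`ICC(1) >= .51`) each family's two
#' child scores are replaced by their mean; otherwise the children are
#' kept separate and the result is flagged unaggregated.
#'
#' @param pairs as in [icc1()] (matrix or family/value data.frame).
#' @param agreement an [icc1()] result.
#' @return list: `values` (data.frame `family`, `value` — one row per
#'   family if aggregated, two otherwise), `aggregated` flag.
#' @export
aggregate_children <- function(pairs, agreement) {
  stopifnot(inherits(agreement, "icc_result"))
  if (is.data.frame(pairs) && all(c("family", "value") %in% names(pairs))) {
    fam <- names(split(pairs$value, pairs$family))
    m <- do.call(rbind, split(pairs$value, pairs$family))
  } else {
    m <- as.matrix(pairs)
    fam <- if (is.null(rownames(m))) as.character(seq_len(nrow(m)))
           else rownames(m)
  }
  if (isTRUE(agreement$aggregate)) {
    list(values = data.frame(family = fam, value = rowMeans(m)),
         aggregated = TRUE)
  } else {
    list(values = data.frame(family = rep(fam, each = 2L),
                             child = rep(1:2, times = length(fam)),
                             value = as.vector(t(m))),
         aggregated = FALSE)
  }
}

#' Paired comparison with Cohen's dz
#'
#' Paired t test on per-family values: `t = mean(d) / (sd(d) / sqrt(n))`
#' with the sample (n - 1) standard deviation, two-sided p from the t
#' distribution on `n - 1` df, and the paired-form effect size
#' `dz = mean(d) / sd(d)`. Note dz is computed on the difference
#' scores; pooled-SD variants of Cohen's d give different numbers.
#' Interpretation uses the conventional benchmarks (0.20 small,
#' 0.50 medium, 0.80 large). Identical vectors give t = 0, dz = 0,
#' p = 1; a constant nonzero difference has zero variance and is
#' returned flagged with undefined statistics.
#'
#' @param a,b equal-length numeric vectors (pairwise complete, n >= 2
#'   after dropping incomplete pairs).
#' @return a `paired_comparison`: `t_stat`, `df`, `p_two_sided`,
#'   `cohens_d`, `interpretation`, `mean_diff`, `n`,
#'   `zero_variance` flag.
#' @export
paired_comparison <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length",
                                   call. = FALSE)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d <- a - b
  md <- mean(d)
  sdd <- sd(d)
  if (sdd == 0) {
    if (md == 0) {
      return(structure(list(t_stat = 0, df = n - 1L, p_two_sided = 1,
                            cohens_d = 0, interpretation = "negligible",
                            mean_diff = 0, n = n, zero_variance = TRUE),
                       class = "paired_comparison"))
    }
    return(structure(list(t_stat = NA_real_, df = n - 1L,
                          p_two_sided = NA_real_, cohens_d = NA_real_,
                          interpretation = NA_character_, mean_diff = md,
                          n = n, zero_variance = TRUE),
                     class = "paired_comparison"))
  }
  tstat <- md / (sdd / sqrt(n))
  dz <- md / sdd
  interp <- c("negligible", "small", "medium", "large")[
    findInterval(abs(dz), c(-Inf, 0.20, 0.50, 0.80))]
  structure(list(t_stat = tstat, df = n - 1L,
                 p_two_sided = 2 * pt(-abs(tstat), n - 1L),
                 cohens_d = dz, interpretation = interp,
                 mean_diff = md, n = n, zero_variance = FALSE),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  if (x$zero_variance && is.na(x$t_stat))
    cat(sprintf("paired t: undefined (zero-variance differences, mean diff %.3f)\n",
                x$mean_diff))
  else
    cat(sprintf("t(%d) = %.3f, p = %.4f, dz = %.3f (%s)\n",
                x$df, x$t_stat, x$p_two_sided, x$cohens_d, x$interpretation))
  invisible(x)
}

#' Endorsement percentage table
#'
#' For each role-by-prompt-kind group, the percentage of answered
#' surveys endorsing each label (emotion or activity). Columns sum to
#' 100 up to rounding. Groups with no answered surveys are omitted
#' with a warning. Use [format_endorsement()] to render zero counts as
#' "-" and (optionally) relabel emotions.
#'
#' @param log a response log.
#' @param question `"emotion"` or `"activity"`.
#' @param catalog a [survey_catalog()] fixing label order.
#' @return numeric matrix, rows = labels, columns = `role.kind`
#'   groups; attribute `counts` holds the count matrix.
#' @export
endorsement_table <- function(log, question = c("emotion", "activity"),
                              catalog = survey_catalog()) {
  question <- match.arg(question)
  labels <- if (question == "emotion") catalog$emotions else catalog$activities
  roles <- intersect(c("mother", "father", "child"), unique(log$role))
  kinds <- intersect(c("random", "deviation"), unique(log$kind))
  cols <- list()
  cnts <- list()
  for (r in roles) for (k in kinds) {
    g <- log[log$role == r & log$kind == k & !is.na(log[[question]]), ,
             drop = FALSE]
    nm <- paste(r, k, sep = ".")
    if (nrow(g) == 0L) {
      warning("no answered surveys for group ", nm, "; column omitted",
              call. = FALSE)
      next
    }
    cnt <- table(factor(g[[question]], levels = labels))
    cols[[nm]] <- 100 * as.numeric(cnt) / nrow(g)
    cnts[[nm]] <- as.numeric(cnt)
  }
  if (length(cols) == 0L) stop("no answered surveys in log", call. = FALSE)
  pct <- do.call(cbind, cols)
  rownames(pct) <- labels
  attr(pct, "counts") <- do.call(cbind, cnts)
  pct
}

#' Render an endorsement table for reporting
#'
#' Formats percentages to two decimals with a trailing percent sign
#' and renders zero-count labels as "-"; emotion rows can be
#' relabelled through an alias map (e.g. relaxed to "content").
#'
#' @param pct matrix from [endorsement_table()].
#' @param aliases optional named relabelling vector such as
#'   [emotion_aliases()].
#' @param digits decimal places. Default 2.
#' @return character matrix.
#' @export
format_endorsement <- function(pct, aliases = NULL, digits = 2) {
  counts <- attr(pct, "counts")
  out <- matrix(sprintf(paste0("%.", digits, "f%%"), pct),
                nrow = nrow(pct), dimnames = dimnames(pct))
  out[counts == 0] <- "-"
  if (!is.null(aliases)) {
    hit <- rownames(out) %in% names(aliases)
    rownames(out)[hit] <- aliases[rownames(out)[hit]]
  }
  out
}

#' USE questionnaire subscale scores
#'
#' Items are answered on a 1 (strongly disagree) to 7 (strongly
#' agree) Likert scale. The ease-of-use subscale has 11 items but
#' items 7--8 are excluded for their poor factor loadings, so the
#' score is the mean of the 9 retained items; satisfaction is the
#' mean of its 4 items. Missing items are skipped (available-item
#' mean) and flagged.
#'
#' @param ease_items numeric vector of the 11 ease-of-use responses
#'   (items 7--8 may be `NA`; they are ignored either way).
#' @param satisfaction_items numeric vector of the 4 satisfaction
#'   responses.
#' @return a `use_scores` list: `ease_of_use`, `satisfaction`,
#'   `ease_items_used`, `missing_flag`.
#' @export
use_scores <- function(ease_items, satisfaction_items) {
  if (length(ease_items) != 11L)
    stop("`ease_items` must have 11 entries (items 7-8 may be NA)",
         call. = FALSE)
  if (length(satisfaction_items) != 4L)
    stop("`satisfaction_items` must have 4 entries", call. = FALSE)
  retained <- c(1:6, 9:11)
  check <- function(v) {
    v <- v[!is.na(v)]
    if (any(v < 1 | v > 7 | v %% 1 != 0))
      stop("USE items must be integers in 1..7", call. = FALSE)
  }
  check(ease_items[retained]); check(satisfaction_items)
  ease_vals <- ease_items[retained]
  missing <- anyNA(ease_vals) || anyNA(satisfaction_items)
  structure(list(ease_of_use = mean(ease_vals, na.rm = TRUE),
                 satisfaction = mean(satisfaction_items, na.rm = TRUE),
                 ease_items_used = retained,
                 missing_flag = missing),
            class = "use_scores")
}

#' Pairwise Pearson correlation table
#'
#' Pairwise-complete Pearson correlations between member-level
#' metrics, with two-sided significance stars (* p < .05, ** p < .01)
#' and a dagger flag for non-significant correlations larger than .50
#' in magnitude. Constant variables yield undefined (NA) entries.
#'
#' @param df data.frame of numeric variables.
#' @return a `correlation_matrix` list: `r`, `p`, `n`, `mark`
#'   (character: "", "*", "**", or "+" for the dagger convention).
#' @export
correlation_matrix <- function(df) {
  df <- as.data.frame(df)
  v <- names(df)
  p <- length(v)
  r <- pmat <- nmat <- matrix(NA_real_, p, p, dimnames = list(v, v))
  mark <- matrix("", p, p, dimnames = list(v, v))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    x <- df[[i]]; y <- df[[j]]
    ok <- !is.na(x) & !is.na(y)
    nmat[i, j] <- sum(ok)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    if (i == j) { r[i, j] <- 1; pmat[i, j] <- 0; next }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- unname(ct$estimate)
    pmat[i, j] <- ct$p.value
    mark[i, j] <- if (pmat[i, j] < 0.01) "**"
      else if (pmat[i, j] < 0.05) "*"
      else if (abs(r[i, j]) > 0.50) "+"
      else ""
  }
  structure(list(r = r, p = pmat, n = nmat, mark = mark),
            class = "correlation_matrix")
}
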