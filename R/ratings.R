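# Ground-truth derivation from rater Likert tables and inter-rater
# agreement statistics (Fleiss' kappa, absolute-agreement ICC).

# Domains scored per subtask: needle positioning + needle entry label
# subtask 1; needle driving/tissue trauma, suture placement, and tissue
# approximation label subtask 2. (Knot tying, domain 6, is out of scope.)
SUBTASK_DOMAINS <- list(`1` = 1:2, `2` = 3:5)

#' Per-rater ordinal subtask scores from a ratings table
#'
#' Averages, for each (segment, rater), the Likert scores of the domains
#' relevant to the requested subtask.
#'
#' @param table Long-format ratings: segment_id, participant_id, subtask,
#'   rater_id, domain, score.
#' @param subtask 1 or 2.
#' @return data.frame: segment_id, participant_id, rater_id, score (ordinal,
#'   in [1, 5]).
#' @export
aggregate_race <- function(table, subtask) {
  subtask <- as.integer(subtask)
  stopifnot(subtask %in% 1:2)
  doms <- SUBTASK_DOMAINS[[as.character(subtask)]]
  tab <- table[table$subtask == subtask, , drop = FALSE]
  if (nrow(tab) == 0L) stopf("no rows for subtask %d", subtask)
  key <- interaction(tab$segment_id, tab$rater_id, drop = TRUE)
  miss <- tapply(tab$domain, key, function(d) !all(doms %in% d))
  if (any(miss)) {
    stopf("missing required domain(s) for subtask %d in: %s", subtask,
          paste(head(names(miss)[miss], 3), collapse = ", "))
  }
  tab <- tab[tab$domain %in% doms, , drop = FALSE]
  agg <- stats::aggregate(score ~ segment_id + participant_id + rater_id,
                          data = tab, FUN = mean)
  agg[order(agg$segment_id, agg$rater_id), ]
}

#' Map an ordinal RACE score to a 3-level skill class
#'
#' Class 1 (inexperienced) below `t_low`, class 2 (competent) in
#' `[t_low, t_high)`, class 3 (experienced) at or above `t_high`. The cut
#' points are not part of the published scoring rule; the defaults are the
#' tertile cuts of the 1-5 scale and every report surfaces the thresholds
#' used.
#'
#' @param score Ordinal score(s) in [1, 5]; vectorized.
#' @param thresholds `c(t_low, t_high)` with `1 < t_low < t_high < 5`.
#' @return Integer class(es) in {1, 2, 3}.
#' @export
assign_skill_class <- function(score, thresholds = c(7 / 3, 11 / 3)) {
  if (length(thresholds) != 2L || !(1 < thresholds[1]) ||
      !(thresholds[1] < thresholds[2]) || !(thresholds[2] < 5)) {
    stopf("thresholds must satisfy 1 < t_low < t_high < 5")
  }
  if (any(score < 1 | score > 5)) stopf("scores must lie in [1, 5]")
  ifelse(score < thresholds[1], 1L,
         ifelse(score < thresholds[2], 2L, 3L))
}

#' Majority vote over three rater classes
#'
#' Returns the modal label when a strict majority exists. The three-way tie
#' (1, 2, 3) is resolved to the ordinal median, 2 — a deterministic rule that
#' respects the ordinal scale.
#'
#' @param per_rater_classes Integer vector of exactly 3 labels in {1, 2, 3}.
#' @return list(class, vote_margin) where vote_margin is the winning count
#'   minus the runner-up count (0 for the three-way tie).
#' @export
majority_vote <- function(per_rater_classes) {
  stopifnot(length(per_rater_classes) == 3L)
  counts <- tabulate(per_rater_classes, nbins = 3L)
  if (max(counts) == 1L) {
    return(list(class = 2L, vote_margin = 0L))
  }
  win <- which.max(counts)
  sorted <- sort(counts, decreasing = TRUE)
  list(class = as.integer(win), vote_margin = as.integer(sorted[1] - sorted[2]))
}

#' Derive per-segment skill labels from a ratings table
#'
#' Chains [aggregate_race()], [assign_skill_class()] per rater, and
#' [majority_vote()]. With `granularity = "participant"` the per-rater
#' scores are first averaged over all of a participant's segments of the
#' subtask, and every segment inherits the participant-level label.
#'
#' @inheritParams aggregate_race
#' @param thresholds Passed to [assign_skill_class()].
#' @param granularity "segment" (default) or "participant".
#' @return data.frame: segment_id, participant_id, class, vote_margin, and
#'   the per-rater classes as columns rater1..rater3; thresholds attached as
#'   attribute `thresholds`.
#' @export
derive_skill_labels <- function(table, subtask,
                                thresholds = c(7 / 3, 11 / 3),
                                granularity = c("segment", "participant")) {
  granularity <- match.arg(granularity)
  agg <- aggregate_race(table, subtask)
  if (granularity == "participant") {
    pagg <- stats::aggregate(score ~ participant_id + rater_id, data = agg,
                             FUN = mean)
    agg$score <- pagg$score[match(
      paste(agg$participant_id, agg$rater_id),
      paste(pagg$participant_id, pagg$rater_id)
    )]
  }
  agg$class <- assign_skill_class(agg$score, thresholds)
  segs <- unique(agg[, c("segment_id", "participant_id")])
  res <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
    cls <- agg$class[agg$segment_id == segs$segment_id[i]][
      order(agg$rater_id[agg$segment_id == segs$segment_id[i]])]
    mv <- majority_vote(cls)
    data.frame(
      segment_id = segs$segment_id[i],
      participant_id = segs$participant_id[i],
      class = mv$class, vote_margin = mv$vote_margin,
      rater1 = cls[1], rater2 = cls[2], rater3 = cls[3],
      stringsAsFactors = FALSE
    )
  }))
  attr(res, "thresholds") <- thresholds
  res
}

#' Fleiss' kappa for multi-rater categorical agreement
#'
#' Chance-corrected agreement kappa = (Pbar - Pbar_e) / (1 - Pbar_e) for
#' `n_items` items each rated by the same number of raters, from the
#' item-by-category count table. The confidence interval is a seeded
#' item-level percentile bootstrap.
#'
#' @param counts Items x categories matrix of rating counts; each row sums
#'   to the (constant) number of raters.
#' @param conf_level CI level (default 0.95).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Bootstrap seed.
#' @return list with statistic = "fleiss_kappa", value, ci_low, ci_high,
#'   n_items, n_raters, degenerate (TRUE when expected agreement is 1 and
#'   kappa is undefined).
#' @export
fleiss_kappa <- function(counts, conf_level = 0.95, n_boot = 2000,
                         seed = 1L) {
  counts <- as.matrix(counts)
  r <- rowSums(counts)
  if (nrow(counts) < 1L || any(r != r[1]) || r[1] < 2) {
    stopf("every item must be rated by the same number (>= 2) of raters")
  }
  k <- .fleiss_point(counts)
  if (is.na(k)) {
    return(list(statistic = "fleiss_kappa", value = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_,
                n_items = nrow(counts), n_raters = as.integer(r[1]),
                degenerate = TRUE))
  }
  bk <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(counts), replace = TRUE)
      .fleiss_point(counts[idx, , drop = FALSE])
    }, numeric(1))
  })
  a <- (1 - conf_level) / 2
  ci <- stats::quantile(bk, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(statistic = "fleiss_kappa", value = k,
       ci_low = min(ci[1], k), ci_high = max(ci[2], k),
       n_items = nrow(counts), n_raters = as.integer(r[1]),
       degenerate = FALSE)
}

.fleiss_point <- function(counts) {
  n <- nrow(counts)
  r <- sum(counts[1, ])
  p_j <- colSums(counts) / (n * r)
  P_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (abs(1 - Pe) < 1e-12) return(NA_real_)
  (Pbar - Pe) / (1 - Pe)
}

#' Absolute-agreement intraclass correlation, ICC(2,1)
#'
#' Single-measure two-way random-effects absolute-agreement ICC from the
#' two-way ANOVA mean squares:
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`.
#' The confidence interval uses the F-distribution bounds of McGraw & Wong
#' (1996). `average = TRUE` returns the average-measure variant ICC(2,k).
#'
#' @param scores Items x raters numeric matrix, complete.
#' @param conf_level CI level (default 0.95).
#' @param average Average-measure variant instead of single-measure.
#' @return list with statistic = "icc", value, ci_low, ci_high, n_items,
#'   n_raters, degenerate.
#' @export
icc_absolute <- function(scores, conf_level = 0.95, average = FALSE) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2 || k < 2 || anyNA(scores)) {
    stopf("need a complete matrix with >= 2 items and >= 2 raters")
  }
  gm <- mean(scores)
  rm_ <- rowMeans(scores); cm <- colMeans(scores)
  SSR <- k * sum((rm_ - gm)^2)
  SSC <- n * sum((cm - gm)^2)
  SST <- sum((scores - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (SST < 1e-12) {
    return(list(statistic = "icc", value = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, n_items = n, n_raters = k,
                degenerate = TRUE))
  }
  icc1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  alpha <- 1 - conf_level
  # McGraw & Wong case 2A bounds for the single-measure coefficient.
  a <- (k * icc1) / (n * (1 - icc1))
  b <- 1 + (k * icc1 * (n - 1)) / (n * (1 - icc1))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  F1 <- stats::qf(1 - alpha / 2, n - 1, v)
  F2 <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - F1 * MSE) /
    (F1 * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (F2 * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * F2 * MSR)
  if (average) {
    icc_v <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
    lo <- lo * k / (1 + (k - 1) * lo)
    hi <- hi * k / (1 + (k - 1) * hi)
  } else {
    icc_v <- icc1
  }
  list(statistic = "icc", value = icc_v,
       ci_low = min(lo, icc_v), ci_high = max(hi, icc_v),
       n_items = n, n_raters = k, degenerate = FALSE)
}

#' Item-by-category count table from per-rater class labels
#'
#' @param labels data.frame from [derive_skill_labels()] (uses columns
#'   rater1..rater3), or a matrix items x raters of class labels.
#' @param n_categories Number of categories (default 3).
#' @return items x categories count matrix suitable for [fleiss_kappa()].
#' @export
rating_counts <- function(labels, n_categories = 3L) {
  m <- if (is.data.frame(labels)) {
    as.matrix(labels[, c("rater1", "rater2", "rater3")])
  } else {
    as.matrix(labels)
  }
  t(apply(m, 1L, tabulate, nbins = n_categories))
}
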