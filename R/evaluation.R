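# Subject-independent model selection and assessment: repeated random
# participant splits with grouped inner folds, grid search scored by mean
# cross-validation weighted F1, the study's confusion/precision/recall/F1
# metrics, and paired t-tests with Holm correction across modalities.

#' Build a repeated subject-independent split plan
#'
#' Each repeat draws `n_train` training and `n_test` held-out test
#' participants at random (disjoint), and partitions the training
#' participants into `k` grouped inner folds. All leakage invariants hold
#' by construction; [audit_leakage()] re-checks them explicitly.
#'
#' @param participants Character vector of participant ids.
#' @param n_train,n_test Participants per repeat (study: 16 and 7).
#' @param k Inner folds over training participants (study: 4).
#' @param repeats Number of repeats (study: 10).
#' @param strata Optional per-participant class labels (named by
#'   participant id). When given, train/test selection and fold assignment
#'   cycle over the classes so that every subset covers all classes where
#'   counts allow; the default (NULL) is the study's plain random
#'   partition.
#' @param seed Integer seed.
#' @return An `sf_split_plan`: list(repeats = list of list(train, test,
#'   folds), seed, params).
#' @export
make_split_plan <- function(participants, n_train = 16, n_test = 7, k = 4,
                            repeats = 10, strata = NULL, seed = 1L) {
  participants <- as.character(participants)
  if (length(participants) < n_train + n_test) {
    stopf("need at least %d participants, got %d", n_train + n_test,
          length(participants))
  }
  if (n_train < k) stopf("cannot split %d participants into %d folds",
                         n_train, k)
  reps <- with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      if (is.null(strata)) {
        sel <- sample(participants, n_train + n_test)
      } else {
        # class-interleaved order: shuffled members of shuffled classes,
        # taken round-robin, so any prefix covers the classes
        by_cls <- split(participants, strata[participants])
        by_cls <- lapply(by_cls[sample.int(length(by_cls))], sample)
        len <- max(vapply(by_cls, length, 1L))
        sel <- unlist(lapply(seq_len(len), function(i) {
          unlist(lapply(by_cls, function(m) if (i <= length(m)) m[i]))
        }), use.names = FALSE)[seq_len(n_train + n_test)]
      }
      test <- sel[seq_len(n_test)]
      train <- sel[(n_test + 1):(n_train + n_test)]
      fold_id <- if (is.null(strata)) {
        rep(seq_len(k), length.out = n_train)[sample.int(n_train)]
      } else {
        # cycle folds within each class (offset per class) so every fold's
        # validation set mixes classes whenever counts allow
        id <- integer(n_train)
        cls <- strata[train]
        for (cc in unique(cls)) {
          j <- which(cls == cc)
          off <- match(cc, unique(cls)) - 1L
          id[j] <- ((seq_along(j) - 1L + off) %% k) + 1L
        }
        id
      }
      folds <- lapply(seq_len(k), function(f) {
        list(train = train[fold_id != f], val = train[fold_id == f])
      })
      list(train = train, test = test, folds = folds)
    })
  })
  structure(list(repeats = reps, seed = seed,
                 params = list(n_train = n_train, n_test = n_test, k = k)),
            class = "sf_split_plan")
}

#' Audit a split plan for participant leakage
#'
#' Scans every (train, test) pair and every inner (fold-train, fold-val)
#' pair for participant overlap, and checks that folds partition the
#' training participants.
#'
#' @param plan An `sf_split_plan`.
#' @return data.frame of violations (zero rows when the plan is clean).
#' @export
audit_leakage <- function(plan) {
  bad <- list()
  for (r in seq_along(plan$repeats)) {
    rep_ <- plan$repeats[[r]]
    if (length(intersect(rep_$train, rep_$test)) > 0L) {
      bad[[length(bad) + 1L]] <- data.frame(
        repeat_ = r, fold = NA_integer_, kind = "train_test_overlap")
    }
    seen <- character(0)
    for (f in seq_along(rep_$folds)) {
      fl <- rep_$folds[[f]]
      if (length(intersect(fl$train, fl$val)) > 0L) {
        bad[[length(bad) + 1L]] <- data.frame(
          repeat_ = r, fold = f, kind = "fold_overlap")
      }
      seen <- c(seen, fl$val)
    }
    if (!setequal(seen, rep_$train) || anyDuplicated(seen)) {
      bad[[length(bad) + 1L]] <- data.frame(
        repeat_ = r, fold = NA_integer_, kind = "folds_not_partition")
    }
  }
  if (length(bad) == 0L) {
    data.frame(repeat_ = integer(0), fold = integer(0),
               kind = character(0))
  } else {
    do.call(rbind, bad)
  }
}

#' Confusion-matrix metrics for 3-class predictions
#'
#' Per-class precision `TP / (TP + FP)`, recall `TP / (TP + FN)`, F1 as
#' their harmonic mean, accuracy as trace over total, and the
#' support-weighted F1 `sum(F1_i * Support_i) / sum(Support_i)`. A class
#' never predicted gets precision 0 (with a warning), the scikit-style
#' convention.
#'
#' @param true_labels,predicted_labels Equal-length integer vectors over
#'   {1, 2, 3}.
#' @return An `sf_metrics` list: confusion (3x3, rows = actual), tp/fp/fn,
#'   precision/recall/f1 per class, accuracy, weighted_f1,
#'   weighted_precision, weighted_recall, support.
#' @export
compute_metrics <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stopf("label vectors must have equal length")
  }
  if (!all(c(true_labels, predicted_labels) %in% 1:3)) {
    stopf("labels must lie in {1, 2, 3}")
  }
  cm <- matrix(0L, 3L, 3L, dimnames = list(actual = 1:3, predicted = 1:3))
  for (i in seq_along(true_labels)) {
    cm[true_labels[i], predicted_labels[i]] <-
      cm[true_labels[i], predicted_labels[i]] + 1L
  }
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  support <- rowSums(cm)
  denom_p <- tp + fp
  if (any(denom_p == 0L & support > 0L)) {
    warnf("class(es) never predicted; precision set to 0: %s",
          paste(which(denom_p == 0L & support > 0L), collapse = ", "))
  }
  precision <- ifelse(denom_p > 0, tp / denom_p, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(
    confusion = cm, tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1,
    accuracy = sum(tp) / sum(cm),
    weighted_f1 = sum(f1 * support) / sum(support),
    weighted_precision = sum(precision * support) / sum(support),
    weighted_recall = sum(recall * support) / sum(support),
    support = support
  ), class = "sf_metrics")
}

#' @export
print.sf_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f  weighted F1 %.3f  (n = %d)\n",
              x$accuracy, x$weighted_f1, sum(x$support)))
  print(x$confusion)
  invisible(x)
}

# Canonical string for deterministic lexicographic tie-breaking of configs.
config_key <- function(cfg) {
  flds <- sort(setdiff(names(cfg), "seed"))
  paste(vapply(flds, function(f) sprintf("%s=%s", f, format(cfg[[f]])), ""),
        collapse = ";")
}

# Train one model on a windows subset and score another subset.
fit_and_score <- function(cfg, windows_train, windows_val, wcfg,
                          balance_seed = NULL, patience = 10) {
  if (!is.null(balance_seed)) {
    windows_train <- balance_downsample(windows_train, balance_seed)$windows
  }
  tb <- tensorize(windows_train, wcfg)
  vb <- tensorize(windows_val, wcfg)
  norm <- fit_apply_normalizer(tb, vb)
  tb <- norm$batches[[1]]; vb <- norm$batches[[2]]
  norm$batches <- NULL
  gc(FALSE)
  model <- build_model(cfg, dim(tb$data)[2:4])
  model <- train_model(model, tb, vb, patience = patience)
  pred <- predict_model(model, vb)
  list(model = model, normalizer = norm$normalizer,
       metrics = compute_metrics(vb$labels, pred$labels))
}

#' Grid search with grouped cross-validation
#'
#' For every configuration in `grid`, trains on each inner fold's training
#' participants and scores weighted F1 on the fold's validation
#' participants; selects the configuration with the highest mean score.
#' Ties break deterministically by lexicographic configuration order. A
#' fold whose training windows miss a class is skipped with a warning.
#'
#' @param grid list of `sf_model_config`.
#' @param folds list of list(train, val) participant-id folds.
#' @param windows list of labeled `sf_window` (all training participants).
#' @param wcfg An `sf_window_config`.
#' @param balance_seed Seed for per-fold majority downsampling (NULL =
#'   no balancing inside folds).
#' @return list(best = `sf_model_config`, scores = data.frame of mean CV
#'   weighted F1 per config).
#' @export
grid_search <- function(grid, folds, windows, wcfg, balance_seed = NULL,
                        patience = 10) {
  if (length(grid) == 0L) stopf("empty grid")
  keys <- vapply(grid, config_key, "")
  ord <- order(keys)
  pids <- vapply(windows, function(w) w$participant_id, "")
  scores <- numeric(length(grid))
  for (gi in ord) {
    cfg <- grid[[gi]]
    fold_scores <- c()
    for (fl in folds) {
      wt <- windows[pids %in% fl$train]
      wv <- windows[pids %in% fl$val]
      if (length(wv) == 0L) next
      lt <- vapply(wt, function(w) as.integer(w$label), 1L)
      if (length(unique(lt)) < 3L) {
        warnf("fold skipped: training windows missing a class")
        next
      }
      fs <- fit_and_score(cfg, wt, wv, wcfg, balance_seed, patience)
      fold_scores <- c(fold_scores, fs$metrics$weighted_f1)
    }
    scores[gi] <- if (length(fold_scores)) mean(fold_scores) else -Inf
  }
  best_i <- ord[which.max(scores[ord])]
  list(best = grid[[best_i]],
       scores = data.frame(config = keys, mean_weighted_f1 = scores))
}

#' Repeated subject-independent experiment over modalities
#'
#' For each repeat of the plan and each modality: grid search on the
#' training participants' inner folds, retrain the selected configuration
#' on all training participants (one inner fold held out for early
#' stopping), and evaluate once on the repeat's held-out participants.
#' Reports per-run metrics and the pooled metrics over all repeats'
#' test predictions.
#'
#' @param windows_by_modality Named list (e.g. eeg116, eeg32, gaze,
#'   combined) of labeled `sf_window` lists built from the same cohort.
#' @param plan An `sf_split_plan`.
#' @param grid list of `sf_model_config` (a single config skips fold-level
#'   search only if the grid has length 1 and `skip_single` is TRUE).
#' @param wcfg An `sf_window_config`.
#' @param balance_seed Seed for majority-class downsampling of training
#'   windows (NULL disables balancing).
#' @param skip_single Skip the inner CV when the grid has one point
#'   (default TRUE; the selection is forced either way).
#' @param patience Early-stopping patience forwarded to [train_model()].
#' @param ensemble Seed-ensemble size per repeat: each repeat trains this
#'   many models from distinct derived seeds and averages their softmax
#'   probabilities on the held-out windows (default 1, a single model).
#' @param verbose Progress messages.
#' @return An `sf_experiment`: per-modality list(per_run = list of
#'   `sf_metrics`, pooled = `sf_metrics`, runs = data.frame(run, accuracy,
#'   weighted_f1), best_configs).
#' @export
run_experiment <- function(windows_by_modality, plan, grid, wcfg,
                           balance_seed = 1L, skip_single = TRUE,
                           patience = 10, ensemble = 1L,
                           verbose = FALSE) {
  stopifnot(length(names(windows_by_modality)) ==
              length(windows_by_modality))
  out <- list()
  for (mod in names(windows_by_modality)) {
    windows <- windows_by_modality[[mod]]
    pids <- vapply(windows, function(w) w$participant_id, "")
    per_run <- list(); best_cfgs <- list()
    pooled_true <- integer(0); pooled_pred <- integer(0)
    runs <- data.frame(run = integer(0), accuracy = numeric(0),
                       weighted_f1 = numeric(0))
    for (r in seq_along(plan$repeats)) {
      rep_ <- plan$repeats[[r]]
      train_w <- windows[pids %in% rep_$train]
      test_w <- windows[pids %in% rep_$test]
      if (length(test_w) == 0L) stopf("repeat %d has no test windows", r)
      best <- if (length(grid) == 1L && skip_single) {
        grid[[1]]
      } else {
        grid_search(grid, rep_$folds, train_w, wcfg, balance_seed,
                    patience)$best
      }
      # retrain on folds 2..k, early-stop on fold 1's validation subjects;
      # each repeat (and each ensemble member) trains from its own seed,
      # so the repeats capture initialization stochasticity as well as
      # partition stochasticity
      val_pids <- rep_$folds[[1]]$val
      tr_pids <- vapply(train_w, function(w) w$participant_id, "")
      wt <- train_w[!(tr_pids %in% val_pids)]
      if (!is.null(balance_seed)) {
        wt <- balance_downsample(wt, balance_seed)$windows
      }
      tb <- tensorize(wt, wcfg)
      vb <- tensorize(train_w[tr_pids %in% val_pids], wcfg)
      eb <- tensorize(test_w, wcfg)
      norm <- fit_apply_normalizer(tb, vb, eb)
      tb <- norm$batches[[1]]; vb <- norm$batches[[2]]
      eb <- norm$batches[[3]]
      norm$batches <- NULL
      gc(FALSE)
      probs <- matrix(0, length(eb$labels), 3L)
      for (e_i in seq_len(ensemble)) {
        cfg_e <- best
        cfg_e$seed <- derive_seed(best$seed, "repeat", r, "member", e_i)
        mdl <- train_model(build_model(cfg_e, dim(tb$data)[2:4]), tb, vb,
                           patience = patience)
        probs <- probs + predict_model(mdl, eb)$probs / ensemble
      }
      pred_labels <- max.col(probs, ties.method = "first")
      m <- compute_metrics(eb$labels, pred_labels)
      per_run[[r]] <- m
      best_cfgs[[r]] <- best
      pooled_true <- c(pooled_true, eb$labels)
      pooled_pred <- c(pooled_pred, pred_labels)
      runs <- rbind(runs, data.frame(run = r, accuracy = m$accuracy,
                                     weighted_f1 = m$weighted_f1))
      if (verbose) {
        message(sprintf("[%s] run %d/%d: acc %.3f wF1 %.3f", mod, r,
                        length(plan$repeats), m$accuracy, m$weighted_f1))
      }
    }
    out[[mod]] <- list(
      per_run = per_run,
      pooled = compute_metrics(pooled_true, pooled_pred),
      runs = runs, best_configs = best_cfgs
    )
  }
  structure(out, class = "sf_experiment")
}

#' Paired comparisons across runs with Holm correction
#'
#' Two-tailed paired t-tests on per-run scores matched by run index, for
#' every pair of named score vectors (or a supplied subset of pairs), with
#' the Holm step-down adjustment across the whole family. All-zero
#' differences give p = 1 exactly.
#'
#' @param scores Named list of equal-length numeric per-run score vectors.
#' @param pairs Optional 2-column character matrix of name pairs; default
#'   all unordered pairs.
#' @param alternative Passed to [stats::t.test()] (default two-sided).
#' @return data.frame: a, b, mean_diff, t, df, p, p_holm.
#' @export
paired_tests <- function(scores, pairs = NULL,
                         alternative = "two.sided") {
  nms <- names(scores)
  stopifnot(length(nms) >= 2L)
  lens <- vapply(scores, length, 1L)
  if (length(unique(lens)) != 1L) stopf("score vectors must match in length")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(nms, 2L))
  }
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- scores[[pairs[i, 1]]]; b <- scores[[pairs[i, 2]]]
    d <- a - b
    if (all(abs(d - 0) < 1e-15) || stats::sd(d) < 1e-15) {
      data.frame(a = pairs[i, 1], b = pairs[i, 2], mean_diff = mean(d),
                 t = 0, df = length(d) - 1, p = 1)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
      data.frame(a = pairs[i, 1], b = pairs[i, 2], mean_diff = mean(d),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }
  }))
  res$p_holm <- stats::p.adjust(res$p, method = "holm")
  res
}

#' Wilcoxon signed-rank alternative for paired run comparisons
#'
#' Extension beyond the study's analysis, for when the normality of paired
#' differences over a small number of runs is in doubt.
#'
#' @inheritParams paired_tests
#' @return data.frame: a, b, V, p, p_holm.
#' @export
paired_tests_wilcoxon <- function(scores, pairs = NULL) {
  nms <- names(scores)
  if (is.null(pairs)) pairs <- t(utils::combn(nms, 2L))
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- scores[[pairs[i, 1]]]; b <- scores[[pairs[i, 2]]]
    if (all(abs(a - b) < 1e-15)) {
      data.frame(a = pairs[i, 1], b = pairs[i, 2], V = NA_real_, p = 1)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
      data.frame(a = pairs[i, 1], b = pairs[i, 2],
                 V = unname(wt$statistic), p = wt$p.value)
    }
  }))
  res$p_holm <- stats::p.adjust(res$p, method = "holm")
  res
}
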