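# Windowed tensorization: label-preserving sliding windows with 50%
# overlap, end-of-signal zero-padding with step masks, (N, T, L_step, F)
# batches, training-set channel-wise z-scoring, and majority-class
# downsampling.

#' Windowing configuration
#'
#' Windows of `L` seconds with 50% overlap at the 512 Hz fused rate are
#' subdivided into `T = 10` temporal steps. The nominal per-step length is
#' `L x 51.2` samples; for `L = 3` that is non-integer, so the realized step
#' length is `round(L x 51.2)` with the final step absorbing the remainder
#' (and the tensor's step axis zero-filled to the nominal length where the
#' final step is shorter).
#'
#' @param L Window length in seconds, one of 3, 5, 10.
#' @param overlap Overlap fraction (fixed at 0.5 in the study design).
#' @param T_steps Temporal steps per window (fixed at 10).
#' @param rate Sampling rate of aligned segments, Hz.
#' @return An `sf_window_config` with derived fields `n_samples`
#'   (`L * rate`), `step_len` (`round(L * rate / T_steps)`) and `hop`.
#' @export
window_config <- function(L = 5, overlap = 0.5, T_steps = 10, rate = EEG_RATE) {
  if (!(L %in% c(3, 5, 10))) stopf("window length must be 3, 5 or 10 s")
  if (overlap < 0 || overlap >= 1) stopf("overlap must be in [0, 1)")
  n_samples <- as.integer(round(L * rate))
  structure(list(
    L = L, overlap = overlap, T_steps = as.integer(T_steps),
    rate = rate, n_samples = n_samples,
    step_len = as.integer(round(n_samples / T_steps)),
    hop = as.integer(round(n_samples * (1 - overlap)))
  ), class = "sf_window_config")
}

#' Closed-form sliding-window count
#'
#' Number of windows for a segment of `n` samples with window `w` and hop
#' `h`: `floor((n - w) / h) + 1` when `n >= w`, else a single (padded)
#' window.
#'
#' @param n_samples Segment length in samples.
#' @param cfg An `sf_window_config`.
#' @return Integer window count (>= 1).
#' @export
window_count <- function(n_samples, cfg) {
  if (n_samples >= cfg$n_samples) {
    as.integer((n_samples - cfg$n_samples) %/% cfg$hop + 1L)
  } else {
    1L
  }
}

#' Cut an aligned segment into labeled sliding windows
#'
#' Windows start at multiples of half the window length; every window
#' inherits the parent segment's label. Segments shorter than one window
#' yield a single short window, flagged for downstream padding rather than
#' dropped.
#'
#' @param segment An `sf_segment` with a `label` field attached (see
#'   [label_segments()]).
#' @param cfg An `sf_window_config`.
#' @return list of `sf_window`: list(data = time x F matrix, n_real, label,
#'   participant_id, subtask, segment_id).
#' @export
slide_windows <- function(segment, cfg) {
  x <- t(segment$data)  # time x features
  n <- nrow(x)
  if (n < 1L) stopf("empty segment")
  lab <- segment$label
  if (is.null(lab)) stopf("segment carries no label; run label_segments()")
  seg_id <- segment$segment_id %||%
    sprintf("%s_t%d_s%d", segment$participant_id, segment$trial,
            segment$subtask)
  k <- window_count(n, cfg)
  lapply(seq_len(k), function(i) {
    from <- (i - 1L) * cfg$hop + 1L
    to <- min(n, from + cfg$n_samples - 1L)
    structure(list(
      data = x[from:to, , drop = FALSE], n_real = to - from + 1L,
      label = lab, participant_id = segment$participant_id,
      subtask = segment$subtask, segment_id = seg_id
    ), class = "sf_window")
  })
}

#' Zero-pad a window and derive its step mask
#'
#' Zeros are appended at the end of the signals to reach the full window
#' length. After subdivision into `T` steps, a step is masked out (FALSE)
#' iff it contains only padded samples; a partially padded step stays TRUE.
#'
#' @param window An `sf_window`.
#' @param cfg An `sf_window_config`.
#' @return The window with `data` extended to `cfg$n_samples` rows, plus
#'   `mask` (length-`T` logical) and unchanged `n_real`.
#' @export
pad_and_mask <- function(window, cfg) {
  n <- nrow(window$data)
  if (n > cfg$n_samples) stopf("window longer than the configured length")
  if (n < 1L || window$n_real < 1L) stopf("window contains no data")
  if (n < cfg$n_samples) {
    window$data <- rbind(
      window$data,
      matrix(0, cfg$n_samples - n, ncol(window$data))
    )
  }
  starts <- step_starts(cfg)
  window$mask <- window$n_real > starts
  window
}

# 0-based start sample of each of the T steps; the last step absorbs the
# rounding remainder when L * rate is not divisible by T.
step_starts <- function(cfg) {
  s <- (seq_len(cfg$T_steps) - 1L) * cfg$step_len
  pmin(s, cfg$n_samples)
}

#' Stack padded windows into an (N, T, L_step, F) batch
#'
#' Feature order is fixed (EEG block then gaze block, as produced by
#' alignment). With `L = 5` and `F = 136` each window is (10, 256, 136).
#'
#' @param windows list of `sf_window` (padded or not; padding is applied
#'   here via [pad_and_mask()] when absent).
#' @param cfg An `sf_window_config`.
#' @return An `sf_batch`: list(data = 4-D array (N, T, L_step, F),
#'   mask = (N, T) logical, n_real, labels, participant_ids, subtask,
#'   features, cfg).
#' @export
tensorize <- function(windows, cfg) {
  if (length(windows) == 0L) stopf("no windows to tensorize")
  Fdim <- ncol(windows[[1]]$data)
  if (any(vapply(windows, function(w) ncol(w$data), 1L) != Fdim)) {
    stopf("windows disagree on feature count")
  }
  windows <- lapply(windows, function(w) {
    if (is.null(w$mask)) pad_and_mask(w, cfg) else w
  })
  if (any(vapply(windows, function(w) nrow(w$data), 1L) != cfg$n_samples)) {
    stopf("windows disagree on length")
  }
  N <- length(windows)
  S <- cfg$step_len
  starts <- step_starts(cfg)
  data <- array(0, dim = c(N, cfg$T_steps, S, Fdim))
  mask <- matrix(FALSE, N, cfg$T_steps)
  for (i in seq_len(N)) {
    w <- windows[[i]]
    for (t in seq_len(cfg$T_steps)) {
      from <- starts[t] + 1L
      to <- if (t == cfg$T_steps) cfg$n_samples else starts[t + 1L]
      len <- min(S, to - from + 1L)
      if (len > 0L) {
        data[i, t, seq_len(len), ] <- w$data[from:(from + len - 1L), ]
      }
    }
    mask[i, ] <- w$mask
  }
  structure(list(
    data = data, mask = mask,
    n_real = vapply(windows, function(w) w$n_real, 1L),
    labels = vapply(windows, function(w) as.integer(w$label), 1L),
    participant_ids = vapply(windows, function(w) w$participant_id, ""),
    subtask = windows[[1]]$subtask,
    features = colnames(windows[[1]]$data) %||% as.character(seq_len(Fdim)),
    cfg = cfg
  ), class = "sf_batch")
}

#' Subset an `sf_batch` by window index or by feature
#' @param batch An `sf_batch`.
#' @param i Window indices (default all).
#' @param features Feature indices or names (default all).
#' @return The subsetted `sf_batch`.
#' @export
batch_subset <- function(batch, i = NULL, features = NULL) {
  i <- i %||% seq_len(dim(batch$data)[1])
  f <- features %||% seq_along(batch$features)
  if (is.character(f)) f <- match(f, batch$features)
  batch$data <- batch$data[i, , , f, drop = FALSE]
  batch$mask <- batch$mask[i, , drop = FALSE]
  batch$n_real <- batch$n_real[i]
  batch$labels <- batch$labels[i]
  batch$participant_ids <- batch$participant_ids[i]
  batch$features <- batch$features[f]
  batch
}

# Sample-level mask of real (non-padded) samples for one window: TRUE for
# the first n_real samples laid out over the step grid.
real_sample_mask <- function(n_real, cfg) {
  starts <- step_starts(cfg)
  S <- cfg$step_len
  m <- matrix(FALSE, cfg$T_steps, S)
  for (t in seq_len(cfg$T_steps)) {
    from <- starts[t]
    to <- if (t == cfg$T_steps) cfg$n_samples else starts[t + 1L]
    len <- min(S, to - from)
    if (len > 0L) m[t, seq_len(len)] <- (from + seq_len(len)) <= n_real
  }
  m
}

#' Fit channel-wise z-scoring on a training batch and apply it
#'
#' Means and standard deviations are computed per feature over *real*
#' (non-padded) training samples only, then applied to the training batch
#' and any further batches. Padded samples remain exactly zero afterwards,
#' so padding stays neutral for the masked model. Zero-variance features
#' get their SD floored at 1e-8 with a warning.
#'
#' @param train_batch An `sf_batch` used to fit the statistics.
#' @param ... Further `sf_batch`es to transform with the training
#'   statistics.
#' @return list(normalizer = list(mean, sd), batches = list of transformed
#'   batches, training batch first).
#' @export
fit_apply_normalizer <- function(train_batch, ...) {
  others <- list(...)
  Fdim <- dim(train_batch$data)[4]
  N <- dim(train_batch$data)[1]
  cfg <- train_batch$cfg
  sum_x <- numeric(Fdim); sum_x2 <- numeric(Fdim); n_tot <- 0
  for (i in seq_len(N)) {
    m <- real_sample_mask(train_batch$n_real[i], cfg)
    sel <- which(m)
    xi <- matrix(train_batch$data[i, , , ], ncol = Fdim)
    sum_x <- sum_x + colSums(xi[sel, , drop = FALSE])
    sum_x2 <- sum_x2 + colSums(xi[sel, , drop = FALSE]^2)
    n_tot <- n_tot + length(sel)
  }
  mu <- sum_x / n_tot
  sd_ <- sqrt(pmax(sum_x2 / n_tot - mu^2, 0))
  if (any(sd_ < 1e-8)) {
    warnf("%d zero-variance feature(s); sd floored at 1e-8",
          sum(sd_ < 1e-8))
    sd_ <- pmax(sd_, 1e-8)
  }
  normalizer <- list(mean = mu, sd = sd_)
  batches <- lapply(c(list(train_batch), others), apply_normalizer,
                    normalizer = normalizer)
  list(normalizer = normalizer, batches = batches)
}

#' Apply a fitted normalizer to a batch (padding stays exactly zero)
#' @param batch An `sf_batch`.
#' @param normalizer list(mean, sd) from [fit_apply_normalizer()].
#' @return The normalized `sf_batch`.
#' @export
apply_normalizer <- function(batch, normalizer) {
  d <- dim(batch$data)
  cfg <- batch$cfg
  for (i in seq_len(d[1])) {
    xi <- matrix(batch$data[i, , , ], ncol = d[4])
    xi <- sweep(sweep(xi, 2, normalizer$mean, "-"), 2, normalizer$sd, "/")
    keep <- as.vector(real_sample_mask(batch$n_real[i], cfg))
    xi[!keep, ] <- 0
    batch$data[i, , , ] <- array(xi, dim = d[2:4])
  }
  batch
}

#' Randomly downsample majority classes to the minority count
#'
#' Seeded sampling without replacement per class; already-balanced input is
#' returned unchanged (up to order). The removal log mirrors the study's
#' report of how many windows were discarded.
#'
#' @param windows list of `sf_window`.
#' @param seed Integer seed.
#' @return list(windows, removed = count removed, kept_per_class).
#' @export
balance_downsample <- function(windows, seed = 1L) {
  labels <- vapply(windows, function(w) as.integer(w$label), 1L)
  counts <- tabulate(labels, nbins = 3L)
  if (any(counts == 0L)) stopf("every class needs at least one window")
  m <- min(counts)
  keep <- with_seed(seed, {
    sort(unlist(lapply(1:3, function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > m) sample(idx, m) else idx
    })))
  })
  list(windows = windows[keep], removed = length(windows) - length(keep),
       kept_per_class = rep(m, 3L))
}

#' Persist / restore a batch container
#'
#' Stores the batch's datasets (data, mask, labels, participant_ids,
#' n_real) with the window configuration as attributes in a single-file
#' container.
#'
#' @param batch An `sf_batch`.
#' @param path File path.
#' @return `path`, invisibly (writer); the `sf_batch` (reader).
#' @export
write_batch <- function(batch, path) {
  saveRDS(batch, path)
  invisible(path)
}

#' @rdname write_batch
#' @export
read_batch <- function(path) {
  b <- readRDS(path)
  stopifnot(inherits(b, "sf_batch"))
  b
}
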