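# Preprocessing chain for both modalities: channel exclusion, 60 Hz notch,
# 0.2-250 Hz band-pass, common average reference, PCA artifact removal,
# surface (Hjorth) Laplacian for EEG; smoothing, imputation and spline
# resampling onto the 512 Hz EEG timeline for gaze. All steps are
# deterministic and, except artifact removal, linear.

#' Drop named EEG channels from a recording
#'
#' Default exclusion list is the eight poor-quality channels (F8, POz, AF4,
#' AF8, F6, FC3 and the mastoids M1, M2), leaving 116 usable channels for
#' the default montage.
#'
#' @param recording An `sf_recording`.
#' @param names Channel names to drop.
#' @return The recording with channels removed (montage rows too, when the
#'   recording carries one).
#' @export
exclude_channels <- function(recording, names = EXCLUDED_CHANNELS) {
  if (length(names) == 0L) return(recording)
  if (anyDuplicated(names)) {
    warnf("duplicate channel names in exclusion list; removing once")
    names <- unique(names)
  }
  unknown <- setdiff(names, recording$eeg_channels)
  if (length(unknown) > 0L) {
    stopf("unknown channel name(s): %s", paste(unknown, collapse = ", "))
  }
  keep <- !(recording$eeg_channels %in% names)
  recording$eeg <- recording$eeg[keep, , drop = FALSE]
  recording$eeg_channels <- recording$eeg_channels[keep]
  recording
}

#' Zero-phase 60 Hz notch filter
#'
#' Second-order IIR notch (Q = 30) applied forward-backward
#' (zero phase). Attenuation at `f0` exceeds 20 dB while the passband at
#' +/- 5 Hz is essentially untouched.
#'
#' @param series Numeric vector or channels x time matrix.
#' @param fs Sampling rate, Hz.
#' @param f0 Notch frequency, Hz (default 60).
#' @param q Quality factor (default 30).
#' @return Filtered series, same shape.
#' @export
notch_filter <- function(series, fs, f0 = 60, q = 30) {
  if (f0 >= fs / 2) stopf("notch frequency must be below Nyquist")
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  flt <- signal::Arma(b = b, a = a)
  pad <- round(2 * fs)
  apply_rows(series, function(x) filtfilt_padded(flt, x, pad))
}

# Zero-phase filtering with odd-reflection padding at both ends, which
# suppresses filtfilt's edge transients (important for the 0.2 Hz
# high-pass, whose impulse response spans seconds).
filtfilt_padded <- function(flt, x, pad) {
  n <- length(x)
  p <- min(n - 1L, pad)
  if (p < 1L) return(signal::filtfilt(flt, x))
  left <- 2 * x[1] - x[(p + 1L):2]
  right <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- signal::filtfilt(flt, c(left, x, right))
  y[(p + 1L):(p + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order (24 dB/octave) high-pass and low-pass Butterworth edges in
#' cascade, each realized as two second-order sections (Butterworth Q
#' factors 0.5412 and 1.3066) applied forward-backward. Second-order
#' sections are used instead of a direct-form order-4 filter because the
#' 0.2 Hz edge at a 512 Hz rate puts direct-form poles so close to the
#' unit circle that double precision loses ~10 digits. Default band
#' 0.2-250 Hz; the upper edge sits below the 256 Hz Nyquist frequency.
#'
#' @inheritParams notch_filter
#' @param low,high Band edges, Hz.
#' @return Filtered series, same shape; DC offset removed.
#' @export
bandpass_filter <- function(series, fs, low = 0.2, high = 250) {
  ny <- fs / 2
  if (!(low > 0 && low < high && high < ny)) {
    stopf("band edges must satisfy 0 < low < high < Nyquist (%g Hz)", ny)
  }
  qs <- 1 / (2 * cos(pi / 8 * c(1, 3)))  # Butterworth pair Q factors
  hp <- lapply(qs, function(q) biquad(low, fs, q, "high"))
  lp <- lapply(qs, function(q) biquad(high, fs, q, "low"))
  pad <- round(2 * fs)
  apply_rows(series, function(x) {
    for (s in c(hp, lp)) x <- filtfilt_padded(s, x, pad)
    x
  })
}

# RBJ audio-cookbook biquad sections (bilinear transform, matched at f0).
biquad <- function(f0, fs, q, type = c("low", "high")) {
  type <- match.arg(type)
  w0 <- 2 * pi * f0 / fs
  cw <- cos(w0)
  alpha <- sin(w0) / (2 * q)
  if (type == "low") {
    b <- c((1 - cw) / 2, 1 - cw, (1 - cw) / 2)
  } else {
    b <- c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
  }
  a <- c(1 + alpha, -2 * cw, 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

apply_rows <- function(series, f) {
  if (is.matrix(series)) {
    out <- t(apply(series, 1L, f))
    dimnames(out) <- dimnames(series)
    out
  } else {
    f(series)
  }
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean over all channels from each channel.
#'
#' @param eeg channels x time matrix (>= 2 channels).
#' @return Re-referenced matrix; column means are zero.
#' @export
common_average_reference <- function(eeg) {
  if (!is.matrix(eeg) || nrow(eeg) < 2L) stopf("need >= 2 channels")
  sweep(eeg, 2L, colMeans(eeg), "-")
}

#' Nearest-neighbour map for the surface Laplacian
#'
#' k-nearest-neighbour graph (Euclidean, in the montage's 2-D layout).
#'
#' @param montage data.frame with columns name, x, y (e.g. [eeg_montage()]),
#'   already restricted to the channels present in the data.
#' @param k Neighbours per channel (default 4).
#' @return Named list: channel name -> character vector of neighbour names.
#' @export
neighbor_map <- function(montage, k = 4) {
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  out <- lapply(seq_len(nrow(montage)), function(i) {
    montage$name[order(d[i, ])[2:(k + 1)]]
  })
  names(out) <- montage$name
  out
}

#' Surface (Hjorth) Laplacian
#'
#' Subtracts from each channel the mean of its spatial neighbours, reducing
#' volume-conduction effects. Not idempotent: applying it twice is a
#' different (sharper) operator.
#'
#' @param eeg channels x time matrix with rownames.
#' @param nbmap Named list channel -> neighbour names ([neighbor_map()]).
#' @return Laplacian-referenced matrix.
#' @export
spatial_laplacian <- function(eeg, nbmap) {
  chs <- rownames(eeg)
  if (is.null(chs)) stopf("eeg must carry channel rownames")
  missing_ch <- setdiff(chs, names(nbmap))
  if (length(missing_ch) > 0L) {
    stopf("channel(s) absent from neighbor map: %s",
          paste(missing_ch, collapse = ", "))
  }
  out <- eeg
  for (ch in chs) {
    nb <- intersect(nbmap[[ch]], chs)
    if (length(nb) < 1L) stopf("channel %s has no neighbors in data", ch)
    out[ch, ] <- eeg[ch, ] - colMeans(eeg[nb, , drop = FALSE])
  }
  out
}

#' PCA-based artifact removal (transparent stand-in)
#'
#' The study's recordings were cleaned interactively with blind source
#' separation and topographical PCA in vendor software; that procedure is
#' not reproducible programmatically. This function is a deterministic,
#' transparent stand-in: principal components of the channel covariance
#' whose scalp loadings correlate (|r|) with a frontal ocular template above
#' `template_cor`, or which individually exceed `variance_fraction` of total
#' variance, are projected out and the signal reconstructed. `mode = "off"`
#' is an exact no-op.
#'
#' @param eeg channels x time matrix with rownames.
#' @param montage Layout for the channels present (template weight grows
#'   with the y coordinate toward the forehead).
#' @param variance_fraction Remove any component explaining more than this
#'   fraction of variance (default 0.25).
#' @param template_cor Loading-template correlation threshold (default 0.9).
#' @param mode "pca" (default) or "off".
#' @return list(eeg, removed = indices of removed components).
#' @export
clean_artifacts <- function(eeg, montage, variance_fraction = 0.25,
                            template_cor = 0.9, mode = c("pca", "off")) {
  mode <- match.arg(mode)
  if (mode == "off") return(list(eeg = eeg, removed = integer(0)))
  chs <- rownames(eeg)
  lay <- montage[match(chs, montage$name), ]
  template <- pmax(lay$y, 0)^2
  ctr <- eeg - rowMeans(eeg)
  sv <- svd(ctr, nu = nrow(eeg), nv = 0)
  varfrac <- sv$d^2 / sum(sv$d^2)
  cors <- apply(sv$u, 2L, function(u) {
    if (stats::sd(template) < 1e-12) return(0)
    abs(stats::cor(u, template))
  })
  remove <- which(varfrac > variance_fraction | cors > template_cor)
  if (length(remove) == 0L) return(list(eeg = eeg, removed = integer(0)))
  U <- sv$u[, remove, drop = FALSE]
  cleaned <- ctr - U %*% (t(U) %*% ctr) + rowMeans(eeg)
  dimnames(cleaned) <- dimnames(eeg)
  list(eeg = cleaned, removed = remove)
}

#' Smooth and impute the gaze signals
#'
#' Missing samples of the 19 continuous signals are replaced by the
#' per-signal mean of observed values, then a centred 3-point moving average
#' is applied (shrinking window at the edges, so `[1,2,3,4]` becomes
#' `[1.5, 2, 3, 3.5]`). The categorical eye-movement-type index is never
#' averaged: missing entries become 3 (unclassified) and a majority-of-3
#' smoother is applied (ties keep the centre sample).
#'
#' @param gaze 20 x time matrix with the standard signal rownames.
#' @return Smoothed matrix without missing values; the type index stays in
#'   {1, 2, 3}.
#' @export
smooth_impute_gaze <- function(gaze) {
  stopifnot(is.matrix(gaze), !is.null(rownames(gaze)))
  out <- gaze
  cont <- setdiff(rownames(gaze), "eye_movement_type")
  for (s in cont) {
    x <- gaze[s, ]
    obs <- !is.na(x)
    if (!any(obs)) stopf("gaze signal entirely missing: %s", s)
    x[!obs] <- mean(x[obs])
    out[s, ] <- zoo::rollapply(x, 3, mean, partial = TRUE, align = "center")
  }
  if ("eye_movement_type" %in% rownames(gaze)) {
    idx <- gaze["eye_movement_type", ]
    idx[is.na(idx)] <- 3
    out["eye_movement_type", ] <- zoo::rollapply(idx, 3, function(w) {
      tb <- table(w)
      if (max(tb) > 1) as.numeric(names(tb)[which.max(tb)])
      else w[ceiling(length(w) / 2)]
    }, partial = TRUE, align = "center")
  }
  out
}

#' Align gaze onto the EEG timeline for one segment
#'
#' Slices both streams to the event-delimited segment, resamples each
#' continuous gaze signal from 50 Hz to the 512 Hz EEG timeline with a cubic
#' smoothing spline, carries the categorical type index by previous-value
#' hold, and stacks rows EEG-then-gaze. No normalization happens here;
#' z-scoring is a windowing-stage concern so that its statistics can be
#' restricted to training participants.
#'
#' @param recording Preprocessed `sf_recording`.
#' @param subtask 1 or 2 (segment delimited by `subtask<k>_start/end`
#'   events).
#' @param spline_spar Smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` (default) lets generalized
#'   cross-validation choose it per signal.
#' @return An `sf_segment`: list(data = (channels+20) x time matrix,
#'   features, subtask, participant_id, trial, duration, rate).
#' @export
align_modalities <- function(recording, subtask, spline_spar = NULL) {
  lab_s <- sprintf("subtask%d_start", subtask)
  lab_e <- sprintf("subtask%d_end", subtask)
  ev <- recording$events
  if (!(lab_s %in% ev$label && lab_e %in% ev$label)) {
    stopf("events must contain %s and %s", lab_s, lab_e)
  }
  t0 <- ev$time_ms[ev$label == lab_s][1]
  t1 <- ev$time_ms[ev$label == lab_e][1]
  if (t1 <= t0) stopf("segment end precedes start")
  if (is.unsorted(recording$eeg_time_ms, strictly = TRUE) ||
      is.unsorted(recording$gaze_time_ms, strictly = TRUE)) {
    stopf("stream timestamps must be strictly increasing")
  }
  if (t0 < recording$eeg_time_ms[1] || t1 > max(recording$eeg_time_ms) ||
      t0 < recording$gaze_time_ms[1] || t1 > max(recording$gaze_time_ms)) {
    stopf("segment [%g, %g] ms outside stream coverage", t0, t1)
  }
  ei <- which(recording$eeg_time_ms >= t0 & recording$eeg_time_ms <= t1)
  tt <- recording$eeg_time_ms[ei]
  # gaze support slightly widened so the spline is anchored at the edges
  gi <- which(recording$gaze_time_ms >= t0 - 100 &
              recording$gaze_time_ms <= t1 + 100)
  gt <- recording$gaze_time_ms[gi]
  if (length(gi) < 4L) stopf("too few gaze samples covering segment")
  gz <- recording$gaze[, gi, drop = FALSE]
  if (anyNA(gz)) stopf("gaze must be imputed before alignment")
  res <- matrix(0, nrow(gz), length(tt),
                dimnames = list(rownames(gz), NULL))
  for (s in rownames(gz)) {
    if (s == "eye_movement_type") {
      res[s, ] <- stats::approx(gt, gz[s, ], xout = tt, method = "constant",
                                f = 0, rule = 2)$y
    } else if (stats::sd(gz[s, ]) < 1e-10) {
      res[s, ] <- mean(gz[s, ])
    } else {
      fit <- if (is.null(spline_spar)) {
        stats::smooth.spline(gt, gz[s, ])
      } else {
        stats::smooth.spline(gt, gz[s, ], spar = spline_spar)
      }
      res[s, ] <- stats::predict(fit, tt)$y
    }
  }
  data <- rbind(recording$eeg[, ei, drop = FALSE], res)
  rownames(data) <- c(recording$eeg_channels, rownames(gz))
  structure(list(
    data = data, features = rownames(data), subtask = as.integer(subtask),
    participant_id = recording$participant_id, trial = recording$trial,
    duration = (t1 - t0) / 1000, rate = EEG_RATE
  ), class = "sf_segment")
}

#' Run the full preprocessing chain on one recording
#'
#' Order mirrors the numbered preprocessing list: channel exclusion, 60 Hz
#' notch, 0.2-250 Hz band-pass, common average reference, artifact removal,
#' surface Laplacian for EEG; moving-average smoothing plus mean imputation
#' for gaze; then per-subtask alignment onto the EEG timeline.
#'
#' @param recording Raw `sf_recording`.
#' @param montage Full layout including excluded channels.
#' @param exclude Channel names to drop first (default: the standard eight).
#' @param artifact_mode "pca" or "off" (see [clean_artifacts()]).
#' @param laplacian_k Neighbours for the Laplacian graph.
#' @return list of `sf_segment`, one per subtask present in the events.
#' @export
preprocess_recording <- function(recording, montage = eeg_montage(),
                                 exclude = EXCLUDED_CHANNELS,
                                 artifact_mode = "pca", laplacian_k = 4) {
  rec <- exclude_channels(recording, exclude)
  rec$eeg <- notch_filter(rec$eeg, fs = EEG_RATE)
  rec$eeg <- bandpass_filter(rec$eeg, fs = EEG_RATE)
  rec$eeg <- common_average_reference(rec$eeg)
  lay <- montage[montage$name %in% rec$eeg_channels, ]
  rec$eeg <- clean_artifacts(rec$eeg, lay, mode = artifact_mode)$eeg
  rec$eeg <- spatial_laplacian(rec$eeg, neighbor_map(lay, k = laplacian_k))
  rec$gaze <- smooth_impute_gaze(rec$gaze)
  subtasks <- sort(unique(as.integer(sub(
    "subtask(\\d)_start", "\\1",
    grep("_start$", rec$events$label, value = TRUE)
  ))))
  lapply(subtasks, function(s) align_modalities(rec, s))
}
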