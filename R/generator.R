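# Synthetic cohort generator: seeded multimodal stand-ins for the study's
# recordings (EEG 512 Hz + eye tracking 50 Hz + trigger events + three-rater
# RACE-style Likert tables), with class-dependent structure in frontal theta
# power, occipital alpha power, and fixation duration.

EEG_RATE <- 512
GAZE_RATE <- 50
EXCLUDED_CHANNELS <- c("F8", "POz", "AF4", "AF8", "F6", "FC3", "M1", "M2")

GAZE_SIGNALS <- c(
  "gaze_point_x", "gaze_point_y",
  "gaze_point_3d_x", "gaze_point_3d_y", "gaze_point_3d_z",
  "gaze_dir_left_x", "gaze_dir_left_y", "gaze_dir_left_z",
  "gaze_dir_right_x", "gaze_dir_right_y", "gaze_dir_right_z",
  "pupil_pos_left_x", "pupil_pos_left_y", "pupil_pos_left_z",
  "pupil_pos_right_x", "pupil_pos_right_y", "pupil_pos_right_z",
  "pupil_diam_left", "pupil_diam_right",
  "eye_movement_type"
)

#' Synthetic EEG montage with a 2-D scalp layout
#'
#' Builds a named channel layout: `n_usable` generic channels placed on a unit
#' disc by a sunflower (golden-angle) arrangement, plus the eight named
#' channels that the preprocessing chain excludes by default, placed at fixed
#' scalp-plausible coordinates. Channels with y > 0.45 form the frontal group
#' and y < -0.45 the occipital group; these groups carry the class-dependent
#' theta and alpha structure and define the ocular-template weighting used by
#' artifact cleaning.
#'
#' @param n_usable Number of usable (non-excluded) channels. Default 116.
#' @return A data.frame with columns `name`, `x`, `y`, `group`,
#'   `excluded` (logical).
#' @export
eeg_montage <- function(n_usable = 116) {
  stopifnot(n_usable >= 8)
  i <- seq_len(n_usable)
  r <- sqrt((i - 0.5) / n_usable)
  th <- i * pi * (3 - sqrt(5))
  usable <- data.frame(
    name = sprintf("CH%03d", i),
    x = r * cos(th), y = r * sin(th),
    excluded = FALSE, stringsAsFactors = FALSE
  )
  bad <- data.frame(
    name = EXCLUDED_CHANNELS,
    x = c(0.65, 0.00, 0.30, 0.60, 0.50, -0.35, -0.95, 0.95),
    y = c(0.55, -0.55, 0.80, 0.75, 0.60, 0.30, -0.30, -0.30),
    excluded = TRUE, stringsAsFactors = FALSE
  )
  m <- rbind(usable, bad)
  m$group <- ifelse(m$y > 0.45, "frontal",
    ifelse(m$y < -0.45, "occipital", "central"))
  m
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study design: 23 participants, class mix from the
#' recruited pool (11 inexperienced, 7 competent, 5 experienced out of 23),
#' 116 usable EEG channels recorded at 512 Hz, 20 eye-tracking signals at
#' 50 Hz, and per-class segment-duration ranges under which experienced
#' trials can be shorter than the 5 s window so that zero-padding is
#' exercised.
#'
#' @param n_participants Cohort size.
#' @param class_proportions Probability over classes 1 (inexperienced),
#'   2 (competent), 3 (experienced); must sum to 1.
#' @param eeg_channels Number of usable EEG channels; raw recordings carry
#'   `eeg_channels + 8` channels, the extra eight being the named excluded
#'   set.
#' @param trial_duration_range_per_class List of three `c(min, max)` segment
#'   durations in seconds, one per class.
#' @param trials_per_participant Anastomoses per participant (study: 2).
#' @param effect_size Dimensionless class-separation strength; 0 makes the
#'   generated data exchangeable across classes.
#' @param line_noise_amp Amplitude of the additive 60 Hz mains component, uV.
#' @param gaze_dropout_prob Per-sample probability a gaze sample is missing.
#' @param rater_noise_sd SD (Likert units) of per-rater scoring noise.
#' @param class_assignment "multinomial" (default; independent draws from
#'   `class_proportions`) or "stratified" (deterministic counts as close to
#'   the proportions as possible, shuffled) — the latter guarantees every
#'   class is represented in small cohorts.
#' @param seed Master seed; every stream derives its own sub-seed from it.
#' @return An object of class `sf_generator_config`.
#' @export
generator_config <- function(n_participants = 23,
                             class_proportions = c(11, 7, 5) / 23,
                             eeg_channels = 116,
                             trial_duration_range_per_class = list(
                               c(30, 70), c(15, 45), c(4, 25)
                             ),
                             trials_per_participant = 2,
                             effect_size = 1,
                             line_noise_amp = 5,
                             gaze_dropout_prob = 0.05,
                             rater_noise_sd = 0.5,
                             class_assignment = c("multinomial",
                                                  "stratified"),
                             seed = 1L) {
  class_assignment <- match.arg(class_assignment)
  if (length(class_proportions) != 3L || any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    stopf("class_proportions must be 3 non-negative values summing to 1")
  }
  if (n_participants < 1) stopf("n_participants must be positive")
  if (length(trial_duration_range_per_class) != 3L) {
    stopf("trial_duration_range_per_class needs one (min,max) range per class")
  }
  for (r in trial_duration_range_per_class) {
    if (length(r) != 2L || any(r <= 0) || r[2] < r[1]) {
      stopf("segment duration ranges must be positive and ordered")
    }
  }
  if (effect_size < 0) stopf("effect_size must be >= 0")
  if (gaze_dropout_prob < 0 || gaze_dropout_prob >= 1) {
    stopf("gaze_dropout_prob must be in [0, 1)")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    class_proportions = class_proportions,
    eeg_channels = as.integer(eeg_channels),
    gaze_signals = 20L,
    eeg_rate = EEG_RATE,
    gaze_rate = GAZE_RATE,
    trial_duration_range_per_class = trial_duration_range_per_class,
    trials_per_participant = as.integer(trials_per_participant),
    effect_size = effect_size,
    line_noise_amp = line_noise_amp,
    gaze_dropout_prob = gaze_dropout_prob,
    rater_noise_sd = rater_noise_sd,
    class_assignment = class_assignment,
    seed = as.integer(seed)
  ), class = "sf_generator_config")
}

# 1/f-shaped Gaussian background, scaled to `rms` uV. Synthesis happens at
# the next highly composite length (fast mixed-radix FFT) and is truncated.
pink_noise <- function(n, fs, rms = 10) {
  m <- stats::nextn(n)
  x <- stats::rnorm(m)
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)
  s <- 1 / sqrt(pmax(f, 1))
  y <- Re(stats::fft(stats::fft(x) * s, inverse = TRUE))[seq_len(n)] / m
  y * rms / stats::sd(y)
}

# Stochastic narrow-band activity: Gaussian noise confined to the band by
# spectral masking, scaled to the RMS of a sinusoid of amplitude `amp`.
# (Band power is stochastic, as in real rhythms; a fixed sinusoid would
# give every trial a spurious constant-frequency fingerprint.)
band_osc <- function(t, f_range, amp) {
  n <- length(t)
  fs <- 1 / (t[2] - t[1])
  m <- stats::nextn(n)
  x <- stats::rnorm(m)
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)
  keep <- f >= f_range[1] & f <= f_range[2]
  if (!any(keep)) return(numeric(n))
  y <- Re(stats::fft(stats::fft(x) * keep, inverse = TRUE))[seq_len(n)] / m
  y * (amp / sqrt(2)) / max(stats::sd(y), 1e-12)
}

# Multiplicative class gains: experienced (class 3) has stronger frontal
# theta and weaker occipital alpha; effect_size = 0 gives gain 1 everywhere.
class_gain <- function(true_class, effect_size, sign = 1) {
  exp(sign * 0.4 * effect_size * (true_class - 2))
}

#' Synthesize one trial's raw EEG
#'
#' 1/f background noise on every channel, plus a class-scaled theta (4-8 Hz)
#' oscillation on frontal channels and a class-scaled (inversely) alpha
#' (8-13 Hz) oscillation on occipital channels, plus a shared-phase 60 Hz
#' mains component of amplitude `config$line_noise_amp`.
#'
#' @param duration Seconds (> 0).
#' @param true_class Skill class 1, 2, or 3.
#' @param config An `sf_generator_config`.
#' @param seed Integer seed for this trial's EEG stream.
#' @param montage Channel layout (default: full raw montage including the
#'   excluded channels).
#' @return channels x time matrix (uV) with rownames set to channel names.
#' @export
synthesize_eeg <- function(duration, true_class, config, seed,
                           montage = eeg_montage(config$eeg_channels)) {
  if (duration <= 0) stopf("duration must be positive")
  n <- max(2L, round(duration * config$eeg_rate))
  t <- (seq_len(n) - 1) / config$eeg_rate
  with_seed(seed, {
    phi_line <- stats::runif(1, 0, 2 * pi)
    line <- config$line_noise_amp * sin(2 * pi * 60 * t + phi_line)
    g_theta <- class_gain(true_class, config$effect_size, +1)
    g_alpha <- class_gain(true_class, config$effect_size, -1)
    eeg <- matrix(0, nrow(montage), n, dimnames = list(montage$name, NULL))
    for (ch in seq_len(nrow(montage))) {
      x <- pink_noise(n, config$eeg_rate, rms = 10)
      if (montage$group[ch] == "frontal") {
        x <- x + band_osc(t, c(4, 8), 5 * g_theta)
      } else if (montage$group[ch] == "occipital") {
        x <- x + band_osc(t, c(8, 13), 6 * g_alpha)
      }
      eeg[ch, ] <- x + line
    }
    eeg
  })
}

#' Synthesize one trial's eye-tracking export
#'
#' Emits the 20 named signals of a Tobii-like export at 50 Hz: screen gaze
#' point, 3-D gaze point, left/right gaze direction, left/right 3-D pupil
#' position, left/right pupil diameter, and the categorical eye-movement-type
#' index (1 fixation, 2 saccade, 3 missing). Gaze alternates fixations and
#' saccades; mean fixation duration scales with class when `effect_size > 0`
#' (experienced participants fixate longer). A `gaze_dropout_prob` fraction
#' of samples is set to NA with type index 3.
#'
#' @inheritParams synthesize_eeg
#' @return 20 x time matrix with rownames = signal names.
#' @export
synthesize_gaze <- function(duration, true_class, config, seed) {
  if (duration <= 0) stopf("duration must be positive")
  n <- max(2L, round(duration * config$gaze_rate))
  t <- (seq_len(n) - 1) / config$gaze_rate
  with_seed(seed, {
    mean_fix <- 0.25 * exp(0.35 * config$effect_size * (true_class - 2))
    # Build fixation/saccade regime covering the trial.
    x <- numeric(n); y <- numeric(n); typ <- integer(n)
    pos <- c(stats::runif(1, 300, 1620), stats::runif(1, 200, 880))
    i <- 1L
    while (i <= n) {
      fix_dur <- stats::rgamma(1, shape = 4, rate = 4 / mean_fix)
      n_fix <- max(1L, round(fix_dur * config$gaze_rate))
      idx <- i:min(n, i + n_fix - 1L)
      x[idx] <- pos[1] + stats::rnorm(length(idx), 0, 5)
      y[idx] <- pos[2] + stats::rnorm(length(idx), 0, 5)
      typ[idx] <- 1L
      i <- i + n_fix
      if (i > n) break
      new_pos <- c(stats::runif(1, 300, 1620), stats::runif(1, 200, 880))
      n_sac <- max(1L, round(stats::runif(1, 0.02, 0.05) * config$gaze_rate))
      idx <- i:min(n, i + n_sac - 1L)
      w <- seq_along(idx) / length(idx)
      x[idx] <- pos[1] + w * (new_pos[1] - pos[1])
      y[idx] <- pos[2] + w * (new_pos[2] - pos[2])
      typ[idx] <- 2L
      pos <- new_pos
      i <- i + n_sac
    }
    x3 <- (x - 960) * 0.5
    y3 <- (y - 540) * 0.5
    z3 <- 600 + 5 * sin(2 * pi * 0.05 * t + stats::runif(1, 0, 2 * pi))
    dir_from_eye <- function(eye_x) {
      v <- rbind(x3 - eye_x, y3, z3)
      nv <- sqrt(colSums(v^2))
      sweep(v, 2, nv, "/")
    }
    dl <- dir_from_eye(-32); dr <- dir_from_eye(32)
    slow <- function(base, amp) {
      base + amp * sin(2 * pi * 0.03 * t + stats::runif(1, 0, 2 * pi))
    }
    gaze <- rbind(
      x, y, x3, y3, z3, dl, dr,
      slow(-32, 0.5), slow(2, 0.5), slow(45, 0.5),
      slow(32, 0.5), slow(2, 0.5), slow(45, 0.5),
      slow(3.5, 0.2) + stats::rnorm(n, 0, 0.03),
      slow(3.5, 0.2) + stats::rnorm(n, 0, 0.03),
      typ
    )
    rownames(gaze) <- GAZE_SIGNALS
    if (config$gaze_dropout_prob > 0) {
      drop <- stats::runif(n) < config$gaze_dropout_prob
      gaze[seq_len(19), drop] <- NA_real_
      gaze["eye_movement_type", drop] <- 3
    }
    gaze
  })
}

#' Synthesize noisy three-rater Likert tables for a cohort
#'
#' Each rater scores every segmented subtask on five RACE-style domains.
#' A rater's score is the class-mapped ideal score (1.8, 3.0, 4.2 for
#' classes 1-3) plus Gaussian noise, rounded and clipped to the 1-5 Likert
#' range.
#'
#' @param cohort An `sf_cohort` (ratings slot may be empty).
#' @param rater_noise_sd Noise SD in Likert units.
#' @param seed Integer seed.
#' @return Long-format data.frame: segment_id, participant_id, trial,
#'   subtask, rater_id, domain, score.
#' @export
synthesize_ratings <- function(cohort, rater_noise_sd, seed) {
  ideal <- c(1.8, 3.0, 4.2)
  segs <- cohort_segment_index(cohort)
  with_seed(seed, {
    rows <- expand.grid(
      domain = 1:5, rater_id = 1:3, seg = seq_len(nrow(segs)),
      KEEP.OUT.ATTRS = FALSE
    )
    base <- ideal[segs$true_class[rows$seg]]
    score <- round(base + stats::rnorm(nrow(rows), 0, rater_noise_sd))
    score <- pmin(5L, pmax(1L, as.integer(score)))
    data.frame(
      segment_id = segs$segment_id[rows$seg],
      participant_id = segs$participant_id[rows$seg],
      trial = segs$trial[rows$seg],
      subtask = segs$subtask[rows$seg],
      rater_id = rows$rater_id,
      domain = rows$domain,
      score = score,
      stringsAsFactors = FALSE
    )
  })
}

# Enumerate (trial x subtask) segments of a cohort with true classes.
cohort_segment_index <- function(cohort) {
  out <- do.call(rbind, lapply(cohort$trials, function(tr) {
    data.frame(
      participant_id = tr$participant_id, trial = tr$trial,
      subtask = 1:2, stringsAsFactors = FALSE
    )
  }))
  out$segment_id <- sprintf("%s_t%d_s%d", out$participant_id, out$trial,
                            out$subtask)
  cls <- cohort$participants$true_class
  names(cls) <- cohort$participants$participant_id
  out$true_class <- unname(cls[out$participant_id])
  out[, c("segment_id", "participant_id", "trial", "subtask", "true_class")]
}

#' Generate a full synthetic cohort
#'
#' Draws a skill class per participant from `class_proportions`, then for
#' every participant and trial synthesizes a raw recording holding both
#' subtask segments (lead-in, subtask 1, inter-subtask gap, subtask 2,
#' tail) with trigger events at segment boundaries, and finally a noisy
#' three-rater ratings table. Fully deterministic for a fixed config
#' (including its seed).
#'
#' @param config An `sf_generator_config`.
#' @return An `sf_cohort`: `participants` (data.frame with true classes),
#'   `trials` (list of `sf_recording`), `ratings` (data.frame), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sf_generator_config"))
  montage <- eeg_montage(config$eeg_channels)
  classes <- with_seed(derive_seed(config$seed, "classes"), {
    if (config$class_assignment == "stratified") {
      n <- config$n_participants
      counts <- floor(n * config$class_proportions)
      rem <- n - sum(counts)
      if (rem > 0) {
        extra <- order(n * config$class_proportions - counts,
                       decreasing = TRUE)[seq_len(rem)]
        counts[extra] <- counts[extra] + 1
      }
      sample(rep.int(1:3, counts))
    } else {
      sample(1:3, config$n_participants, replace = TRUE,
             prob = config$class_proportions)
    }
  })
  pids <- sprintf("P%02d", seq_len(config$n_participants))
  participants <- data.frame(
    participant_id = pids, true_class = classes, stringsAsFactors = FALSE
  )
  trials <- list()
  for (p in seq_along(pids)) {
    cls <- classes[p]
    rng <- config$trial_duration_range_per_class[[cls]]
    for (tr in seq_len(config$trials_per_participant)) {
      durs <- with_seed(derive_seed(config$seed, "durs", pids[p], tr), {
        stats::runif(2, rng[1], rng[2])
      })
      lead <- 1; gap <- 2; tail <- 1
      total <- lead + durs[1] + gap + durs[2] + tail
      eeg <- synthesize_eeg(total, cls, config,
                            derive_seed(config$seed, "eeg", pids[p], tr),
                            montage = montage)
      gaze <- synthesize_gaze(total, cls, config,
                              derive_seed(config$seed, "gaze", pids[p], tr))
      ev <- data.frame(
        label = c("subtask1_start", "subtask1_end",
                  "subtask2_start", "subtask2_end"),
        time_ms = 1000 * c(lead, lead + durs[1],
                           lead + durs[1] + gap,
                           lead + durs[1] + gap + durs[2]),
        stringsAsFactors = FALSE
      )
      trials[[length(trials) + 1L]] <- structure(list(
        eeg = eeg,
        eeg_channels = rownames(eeg),
        eeg_time_ms = (seq_len(ncol(eeg)) - 1) * 1000 / config$eeg_rate,
        gaze = gaze,
        gaze_signals = rownames(gaze),
        gaze_time_ms = (seq_len(ncol(gaze)) - 1) * 1000 / config$gaze_rate,
        events = ev,
        participant_id = pids[p],
        trial = tr
      ), class = "sf_recording")
    }
  }
  cohort <- structure(list(
    participants = participants, trials = trials, ratings = NULL,
    config = config, montage = montage
  ), class = "sf_cohort")
  cohort$ratings <- synthesize_ratings(
    cohort, config$rater_noise_sd, derive_seed(config$seed, "ratings")
  )
  cohort
}

#' @export
print.sf_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d participants (classes %s), %d trials, %d rating rows\n",
    nrow(x$participants),
    paste(table(factor(x$participants$true_class, 1:3)), collapse = "/"),
    length(x$trials), nrow(x$ratings)
  ))
  invisible(x)
}
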