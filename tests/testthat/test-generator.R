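# Synthetic cohort generator: determinism, class structure, signal content.

test_that("identical seed and config give identical cohorts", {
  a <- tiny_cohort(seed = 11)
  b <- tiny_cohort(seed = 11)
  expect_identical(a$participants, b$participants)
  expect_identical(a$trials, b$trials)
  expect_identical(a$ratings, b$ratings)
  c2 <- tiny_cohort(seed = 12)
  expect_false(identical(a$trials[[1]]$eeg, c2$trials[[1]]$eeg))
})

test_that("class assignment reproduces the seeded multinomial draw", {
  cfg <- generator_config(n_participants = 23, seed = 5)
  co <- generate_cohort(cfg)
  expected <- skillfuse:::with_seed(
    skillfuse:::derive_seed(5, "classes"),
    sample(1:3, 23, replace = TRUE, prob = c(11, 7, 5) / 23)
  )
  expect_identical(co$participants$true_class, expected)
})

test_that("stratified assignment hits the rounded class counts", {
  cfg <- tiny_config(n_participants = 12,
                     class_proportions = rep(1, 3) / 3,
                     class_assignment = "stratified")
  co <- generate_cohort(cfg)
  expect_equal(unname(table(factor(co$participants$true_class, 1:3))),
               rep(4L, 3), ignore_attr = TRUE)
})

test_that("generator rejects invalid configurations", {
  expect_error(generator_config(class_proportions = c(0.5, 0.5, 0.5)),
               "proportions")
  expect_error(generator_config(
    trial_duration_range_per_class = list(c(-1, 2), c(1, 2), c(1, 2))),
    "positive")
  expect_error(generator_config(effect_size = -1), "effect_size")
})

test_that("synthetic EEG carries a 60 Hz line peak and class-scaled theta", {
  cfg <- tiny_config(eeg_channels = 24, effect_size = 2,
                     line_noise_amp = 8)
  mont <- eeg_montage(24)
  eeg <- synthesize_eeg(8, 2, cfg, seed = 3, montage = mont)
  expect_equal(nrow(eeg), 24 + 8)
  # periodogram oracle: 60 Hz bin dominates its neighborhood
  x <- eeg[1, ]
  n <- length(x)
  freqs <- (seq_len(n) - 1) * 512 / n
  sp <- Mod(stats::fft(x))^2
  band <- which(freqs > 50 & freqs < 70)
  peak_f <- freqs[band][which.max(sp[band])]
  expect_lt(abs(peak_f - 60), 0.5)

  # theta band power on frontal channels separates classes 1 and 3
  frontal <- mont$name[mont$group == "frontal"][1:4]
  theta_power <- function(cls, seed) {
    e <- synthesize_eeg(8, cls, cfg, seed = seed, montage = mont)
    sapply(frontal, function(ch) {
      y <- e[ch, ]
      f <- (seq_along(y) - 1) * 512 / length(y)
      mean(Mod(stats::fft(y))[f >= 4 & f <= 8]^2)
    })
  }
  p1 <- unlist(lapply(1:6, function(s) theta_power(1, s)))
  p3 <- unlist(lapply(1:6, function(s) theta_power(3, s)))
  expect_lt(stats::t.test(p1, p3)$p.value, 0.01)
  expect_lt(mean(p1), mean(p3))
})

test_that("zero effect size removes class-dependent structure", {
  cfg <- tiny_config(effect_size = 0)
  mont <- eeg_montage(16)
  # identical sub-seed, different class: streams must coincide exactly
  e1 <- synthesize_eeg(4, 1, cfg, seed = 9, montage = mont)
  e3 <- synthesize_eeg(4, 3, cfg, seed = 9, montage = mont)
  expect_identical(e1, e3)
  g1 <- synthesize_gaze(4, 1, cfg, seed = 9)
  g3 <- synthesize_gaze(4, 3, cfg, seed = 9)
  expect_identical(g1, g3)
})

test_that("gaze export has 20 named signals with a categorical index", {
  cfg <- tiny_config(gaze_dropout_prob = 0)
  g <- synthesize_gaze(10, 2, cfg, seed = 4)
  expect_equal(nrow(g), 20)
  expect_identical(rownames(g), skillfuse:::GAZE_SIGNALS)
  expect_false(anyNA(g))
  expect_true(all(g["eye_movement_type", ] %in% 1:2))
})

test_that("dropout marks samples missing with type index 3", {
  cfg <- tiny_config(gaze_dropout_prob = 0.3)
  g <- synthesize_gaze(20, 2, cfg, seed = 4)
  miss <- is.na(g["gaze_point_x", ])
  expect_gt(mean(miss), 0.2)
  expect_lt(mean(miss), 0.4)
  expect_true(all(g["eye_movement_type", miss] == 3))
  expect_true(all(g["eye_movement_type", ] %in% 1:3))
})

test_that("longer fixations for experienced participants", {
  cfg <- tiny_config(effect_size = 2, gaze_dropout_prob = 0)
  fix_lengths <- function(cls) {
    unlist(lapply(1:5, function(s) {
      idx <- synthesize_gaze(30, cls, cfg, seed = s)["eye_movement_type", ]
      r <- rle(idx)
      r$lengths[r$values == 1]
    }))
  }
  f1 <- fix_lengths(1); f3 <- fix_lengths(3)
  expect_gt(mean(f3), mean(f1))
})

test_that("ratings stay on the Likert scale and respond to noise", {
  co <- tiny_cohort(n_participants = 6)
  expect_true(all(co$ratings$score >= 1 & co$ratings$score <= 5))
  # zero noise: all raters identical, perfect downstream agreement
  r0 <- synthesize_ratings(co, rater_noise_sd = 0, seed = 1)
  wide <- stats::reshape(
    r0[r0$domain == 1, c("segment_id", "rater_id", "score")],
    direction = "wide", idvar = "segment_id", timevar = "rater_id"
  )
  expect_true(all(wide[, 2] == wide[, 3] & wide[, 2] == wide[, 4]))
  labs0 <- derive_skill_labels(r0, subtask = 1)
  k0 <- fleiss_kappa(rating_counts(labs0), n_boot = 50)
  if (!k0$degenerate) expect_equal(k0$value, 1)
  # moderate noise: kappa strictly inside (0, 1)
  co2 <- tiny_cohort(n_participants = 8, seed = 21)
  rn <- synthesize_ratings(co2, rater_noise_sd = 0.8, seed = 2)
  labs <- derive_skill_labels(rn, subtask = 1)
  k <- fleiss_kappa(rating_counts(labs), n_boot = 50)
  expect_gt(k$value, 0)
  expect_lt(k$value, 1)
})

test_that("every trial holds both subtask segments inside its span", {
  co <- tiny_cohort()
  for (tr in co$trials) {
    expect_setequal(tr$events$label,
                    c("subtask1_start", "subtask1_end",
                      "subtask2_start", "subtask2_end"))
    expect_true(all(tr$events$time_ms >= 0 &
                    tr$events$time_ms <= max(tr$eeg_time_ms)))
    expect_true(all(diff(tr$eeg_time_ms) > 0))
    expect_true(all(diff(tr$gaze_time_ms) > 0))
  }
})

test_that("cohort round-trips through plain-text files", {
  co <- tiny_cohort(n_participants = 2, eeg_channels = 8)
  d <- withr::local_tempdir()
  man1 <- write_cohort(co, d)
  co2 <- read_cohort(d)
  expect_equal(co2$participants, co$participants)
  expect_equal(co2$trials[[1]]$eeg, co$trials[[1]]$eeg, tolerance = 1e-8)
  expect_equal(co2$ratings$score, co$ratings$score)
  # regenerating from the same seed reproduces identical file checksums
  d2 <- withr::local_tempdir()
  man2 <- write_cohort(generate_cohort(co$config), d2)
  expect_identical(man1$files, man2$files)
})
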