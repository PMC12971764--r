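# Preprocessing chain: filters against FFT oracles, referencing schemes,
# artifact stand-in, gaze smoothing, and cross-modal alignment.

test_that("channel exclusion removes the standard 8 and validates names", {
  co <- tiny_cohort(eeg_channels = 116)
  rec <- co$trials[[1]]
  expect_equal(nrow(rec$eeg), 124)
  out <- exclude_channels(rec)
  expect_equal(nrow(out$eeg), 116)
  expect_false(any(skillfuse:::EXCLUDED_CHANNELS %in% out$eeg_channels))
  expect_identical(exclude_channels(rec, character(0)), rec)
  expect_warning(dup <- exclude_channels(rec, c("M1", "M1")), "duplicate")
  expect_equal(nrow(dup$eeg), 123)
  expect_error(exclude_channels(rec, "NOPE"), "unknown channel")
})

test_that("notch filter removes 60 Hz and passes DC and 10 Hz", {
  fs <- 512
  t <- seq(0, 4, by = 1 / fs)
  tone60 <- sin(2 * pi * 60 * t)
  out <- notch_filter(tone60, fs)
  expect_lt(sqrt(mean(out^2)), 0.1 * sqrt(mean(tone60^2)))
  dc <- rep(1.5, length(t))
  expect_equal(notch_filter(dc, fs), dc, tolerance = 1e-6)
  tone10 <- sin(2 * pi * 10 * t)
  a_in <- fft_amplitude(tone10, fs, 10)
  a_out <- fft_amplitude(notch_filter(tone10, fs), fs, 10)
  expect_lt(abs(a_out - a_in) / a_in, 0.01)
  expect_error(notch_filter(tone10, fs = 100, f0 = 60), "Nyquist")
})

test_that("band-pass keeps 50 Hz, kills DC and slow drift", {
  fs <- 512
  t <- seq(0, 100, by = 1 / fs)
  x50 <- sin(2 * pi * 50 * t)
  a_in <- fft_amplitude(x50, fs, 50)
  a_out <- fft_amplitude(bandpass_filter(x50, fs), fs, 50)
  expect_lt(abs(a_out - a_in) / a_in, 0.02)
  with_dc <- x50 + 7
  expect_lt(abs(mean(bandpass_filter(with_dc, fs))), 0.01)
  drift <- sin(2 * pi * 0.01 * t)
  a_d <- fft_amplitude(bandpass_filter(drift, fs), fs, 0.01)
  expect_lt(a_d / fft_amplitude(drift, fs, 0.01), 0.1)
  expect_error(bandpass_filter(x50, fs, low = 10, high = 5), "edges")
  expect_error(bandpass_filter(x50, fs, high = 300), "edges")
})

test_that("common average reference zeroes the channel mean", {
  set.seed(2)
  eeg <- matrix(rnorm(5 * 100), 5, 100)
  out <- common_average_reference(eeg)
  expect_lt(max(abs(colMeans(out))), 1e-10)
  # reference-free contrasts unchanged
  expect_equal(out[1, ] - out[2, ], eeg[1, ] - eeg[2, ], tolerance = 1e-12)
  same <- matrix(rep(rnorm(100), each = 4), 4, 100)
  expect_equal(max(abs(common_average_reference(same))), 0)
  expect_error(common_average_reference(eeg[1, , drop = FALSE]), ">= 2")
})

test_that("surface Laplacian matches the hand-computed star graph", {
  # 5-node star: center C with 4 neighbors; neighbors mutually neighbored
  chs <- c("C", "N1", "N2", "N3", "N4")
  nb <- list(C = c("N1", "N2", "N3", "N4"),
             N1 = "C", N2 = "C", N3 = "C", N4 = "C")
  eeg <- matrix(0, 5, 3, dimnames = list(chs, NULL))
  eeg["C", ] <- c(4, 8, -2)  # single active channel
  lap <- spatial_laplacian(eeg, nb)
  expect_equal(lap["C", ], c(4, 8, -2))
  for (n in c("N1", "N2", "N3", "N4")) {
    expect_equal(lap[n, ], -c(4, 8, -2))
  }
  # uniform field maps to zero
  uni <- matrix(5, 5, 3, dimnames = list(chs, NULL))
  expect_equal(max(abs(spatial_laplacian(uni, nb))), 0)
  # non-idempotence on the active-channel pattern
  expect_false(isTRUE(all.equal(spatial_laplacian(lap, nb), lap)))
  expect_error(spatial_laplacian(eeg, nb[-1]), "absent")
})

test_that("preprocessing operators are linear", {
  fs <- 512
  set.seed(4)
  x <- matrix(rnorm(4 * 2048), 4, 2048,
              dimnames = list(paste0("CH", 1:4), NULL))
  y <- matrix(rnorm(4 * 2048), 4, 2048, dimnames = dimnames(x))
  nb <- list(CH1 = c("CH2", "CH3"), CH2 = c("CH1", "CH4"),
             CH3 = c("CH1", "CH4"), CH4 = c("CH2", "CH3"))
  chain <- function(m) {
    spatial_laplacian(common_average_reference(
      bandpass_filter(notch_filter(m, fs), fs)), nb)
  }
  a <- 1.7; b <- -0.6
  expect_equal(chain(a * x + b * y), a * chain(x) + b * chain(y),
               tolerance = 1e-8)
})

test_that("artifact stand-in removes a frontal blink pattern", {
  mont <- eeg_montage(24)
  mont <- mont[!mont$excluded, ]
  set.seed(9)
  n <- 2048
  eeg <- matrix(rnorm(nrow(mont) * n), nrow(mont), n,
                dimnames = list(mont$name, NULL))
  # strong slow frontal template riding on the noise
  blink <- pmax(mont$y, 0)^2
  slow <- 25 * sin(2 * pi * 1.5 * (1:n) / 512)
  contaminated <- eeg + blink %o% slow
  res <- clean_artifacts(contaminated, mont)
  expect_gt(length(res$removed), 0)
  frontal <- mont$group == "frontal"
  pow <- function(m) mean(m[frontal, ]^2) / mean(m[!frontal, ]^2)
  expect_lt(pow(res$eeg), pow(contaminated))
  # no-op mode is exact identity
  off <- clean_artifacts(contaminated, mont, mode = "off")
  expect_identical(off$eeg, contaminated)
  expect_length(off$removed, 0)
})

test_that("gaze smoothing follows the documented shrinking-window rule", {
  g <- matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("gaze_point_x", NULL))
  out <- smooth_impute_gaze(g)
  expect_equal(unname(out[1, ]), c(1.5, 2, 3, 3.5))
})

test_that("imputation fills gaps with the observed mean; index stays categorical", {
  g <- rbind(
    gaze_point_x = c(2, NA, 2, 2, NA, 2),
    eye_movement_type = c(1, 3, 1, 2, 3, 2)
  )
  out <- smooth_impute_gaze(g)
  expect_equal(unname(out["gaze_point_x", ]), rep(2, 6))
  expect_true(all(out["eye_movement_type", ] %in% 1:3))
  all_gone <- rbind(gaze_point_x = rep(NA_real_, 4),
                    eye_movement_type = rep(3, 4))
  expect_error(smooth_impute_gaze(all_gone), "entirely missing")
})

test_that("alignment resamples constants and lines exactly, stacks 136 rows", {
  co <- tiny_cohort(n_participants = 1, eeg_channels = 116, seed = 3)
  rec <- exclude_channels(co$trials[[1]])
  rec$gaze <- smooth_impute_gaze(rec$gaze)
  # overwrite two gaze signals with known functions of time
  tms <- rec$gaze_time_ms
  rec$gaze["gaze_point_x", ] <- 3.25
  rec$gaze["gaze_point_y", ] <- 0.004 * tms + 1
  seg <- align_modalities(rec, 1)
  expect_equal(nrow(seg$data), 136)
  expect_equal(seg$features[1:116], rec$eeg_channels)
  x <- seg$data["gaze_point_x", ]
  expect_equal(max(abs(x - 3.25)), 0, tolerance = 1e-6)
  ei <- which(rec$eeg_time_ms >= 1000 & rec$eeg_time_ms <= max(tms))
  y <- seg$data["gaze_point_y", ]
  tt <- rec$eeg_time_ms[which(rec$eeg_time_ms >= co$trials[[1]]$events$time_ms[1] &
                              rec$eeg_time_ms <= co$trials[[1]]$events$time_ms[2])]
  expect_equal(y, 0.004 * tt + 1, tolerance = 1e-6)
  # categorical index held, not interpolated
  expect_true(all(seg$data["eye_movement_type", ] %in% 1:3))
  # errors on out-of-coverage segments
  rec2 <- rec
  rec2$events$time_ms[2] <- max(rec$eeg_time_ms) + 1000
  expect_error(align_modalities(rec2, 1), "coverage")
})
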