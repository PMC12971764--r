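# Sliding windows, padding/masking, tensorization, normalization,
# balancing.

fake_segment <- function(dur_s, Fd = 4, label = 2, rate = 512,
                         pid = "P01") {
  n <- round(dur_s * rate)
  data <- matrix(seq_len(n * Fd), Fd, n)
  rownames(data) <- paste0("f", seq_len(Fd))
  structure(list(data = data, features = rownames(data), subtask = 1L,
                 participant_id = pid, trial = 1L, duration = dur_s,
                 rate = rate, label = label, segment_id = paste0(pid, "_s")),
            class = "sf_segment")
}

test_that("window counts follow the closed form", {
  cfg <- window_config(L = 5)
  w10 <- slide_windows(fake_segment(10), cfg)
  expect_length(w10, 3)
  starts <- unname(sapply(w10, function(w) w$data[1, 1]))
  expect_equal(starts, 1 + c(0, 1280, 2560) * 4)   # hop = 2.5 s
  expect_length(slide_windows(fake_segment(5), cfg), 1)
  short <- slide_windows(fake_segment(3.2), cfg)
  expect_length(short, 1)
  expect_lt(short[[1]]$n_real, cfg$n_samples)
})

test_that("window-count closed form matches brute-force enumeration", {
  set.seed(5)
  for (i in 1:200) {
    L <- sample(c(3, 5, 10), 1)
    cfg <- window_config(L = L)
    n <- sample(200:12000, 1)
    brute <- 0
    start <- 0
    while (start + cfg$n_samples <= n) {
      brute <- brute + 1
      start <- start + cfg$hop
    }
    if (brute == 0) brute <- 1  # short segment: one padded window
    expect_identical(window_count(n, cfg), as.integer(brute))
  }
})

test_that("padding masks exactly the fully padded steps", {
  cfg <- window_config(L = 5)
  full <- pad_and_mask(slide_windows(fake_segment(5), cfg)[[1]], cfg)
  expect_true(all(full$mask))
  half <- pad_and_mask(slide_windows(fake_segment(2.5), cfg)[[1]], cfg)
  expect_equal(nrow(half$data), cfg$n_samples)
  expect_identical(half$mask, rep(c(TRUE, FALSE), each = 5))
  # padded region is exactly zero
  expect_equal(max(abs(half$data[(half$n_real + 1):cfg$n_samples, ])), 0)
  # mask bounds: unmasked span covers the data within one step
  expect_gte(sum(half$mask) * cfg$step_len, half$n_real)
  expect_lt(sum(half$mask) * cfg$step_len - cfg$step_len, half$n_real)
  w <- slide_windows(fake_segment(6), cfg)[[1]]
  w$data <- rbind(w$data, w$data)
  expect_error(pad_and_mask(w, cfg), "longer")
})

test_that("tensorize produces (N, 10, L*51.2, F) with label inheritance", {
  cfg <- window_config(L = 5)
  segs <- list(fake_segment(10, label = 1), fake_segment(7.5, label = 3))
  windows <- unlist(lapply(segs, slide_windows, cfg = cfg),
                    recursive = FALSE)
  b <- tensorize(windows, cfg)
  expect_equal(dim(b$data), c(5, 10, 256, 4))
  expect_equal(b$labels, c(1, 1, 1, 3, 3))
  expect_equal(window_config(L = 10)$step_len, 512)
  # L = 3: nominal 153.6 becomes 154 with the remainder in the final step
  cfg3 <- window_config(L = 3)
  expect_equal(cfg3$step_len, 154)
  b3 <- tensorize(slide_windows(fake_segment(3), cfg3), cfg3)
  expect_equal(dim(b3$data)[3], 154)
  # final step holds only the remaining 150 samples; its tail is zero
  expect_equal(max(abs(b3$data[1, 10, 151:154, ])), 0)
  expect_gt(max(abs(b3$data[1, 10, 1:150, ])), 0)
})

test_that("batches concatenate along N via subset round trip", {
  cfg <- window_config(L = 5)
  b <- tensorize(slide_windows(fake_segment(12.5), cfg), cfg)
  expect_equal(dim(b$data)[1], 4)
  sub <- batch_subset(b, i = 1:2)
  expect_equal(dim(sub$data), c(2, 10, 256, 4))
  gsub <- batch_subset(b, features = c("f2", "f4"))
  expect_equal(gsub$features, c("f2", "f4"))
  expect_equal(dim(gsub$data)[4], 2)
})

test_that("normalization uses real training samples only; padding stays 0", {
  cfg <- window_config(L = 5)
  train <- tensorize(list(slide_windows(fake_segment(2.5), cfg)[[1]]), cfg)
  test_b <- tensorize(list(slide_windows(fake_segment(5), cfg)[[1]]), cfg)
  res <- suppressWarnings(fit_apply_normalizer(train, test_b))
  tb <- res$batches[[1]]
  m <- skillfuse:::real_sample_mask(tb$n_real[1], cfg)
  x <- matrix(tb$data[1, , , ], ncol = 4)
  real <- x[as.vector(m), ]
  expect_equal(colMeans(real), rep(0, 4), tolerance = 1e-8)
  pads <- x[!as.vector(m), ]
  expect_equal(max(abs(pads)), 0)
  # shifted test batch does not get re-centred (no leakage)
  eb <- res$batches[[2]]
  xe <- matrix(eb$data[1, , , ], ncol = 4)
  expect_gt(max(abs(colMeans(xe))), 0.1)
})

test_that("constant features are floored, not NaN", {
  cfg <- window_config(L = 5)
  w <- slide_windows(fake_segment(5), cfg)[[1]]
  w$data[, 2] <- 3.3
  expect_warning(res <- fit_apply_normalizer(tensorize(list(w), cfg)),
                 "zero-variance")
  expect_true(all(is.finite(res$batches[[1]]$data)))
})

test_that("balancing downsamples to the minority count, seeded", {
  cfg <- window_config(L = 5)
  mk <- function(lab, n, pid) {
    unlist(lapply(seq_len(n), function(i) {
      slide_windows(fake_segment(5, label = lab, pid = paste0(pid, i)), cfg)
    }), recursive = FALSE)
  }
  ws <- c(mk(1, 8, "a"), mk(2, 4, "b"), mk(3, 4, "c"))
  bal <- balance_downsample(ws, seed = 3)
  expect_equal(bal$removed, 4)
  labs <- sapply(bal$windows, function(w) w$label)
  expect_equal(unname(table(labs)), rep(4L, 3), ignore_attr = TRUE)
  bal2 <- balance_downsample(ws, seed = 3)
  expect_identical(sapply(bal$windows, function(w) w$segment_id),
                   sapply(bal2$windows, function(w) w$segment_id))
  balanced <- c(mk(1, 2, "x"), mk(2, 2, "y"), mk(3, 2, "z"))
  expect_equal(balance_downsample(balanced, 1)$removed, 0)
  expect_error(balance_downsample(mk(1, 3, "q"), 1), "class")
})

test_that("batch containers round-trip", {
  cfg <- window_config(L = 5)
  b <- tensorize(slide_windows(fake_segment(7.5), cfg), cfg)
  p <- withr::local_tempfile(fileext = ".rds")
  write_batch(b, p)
  expect_equal(read_batch(p), b)
})
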