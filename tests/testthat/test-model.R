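# Classifier: architecture contracts, analytic gradients vs numerical
# differentiation, training behavior, masking semantics.

test_that("softmax output is a probability simplex; attention sums to 1", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, c(4, 16, 3))
  b <- random_batch(N = 5, n_pad_steps = 1)
  fw <- skillfuse:::forward_pass(m$params, b$data, b$mask, cfg, m$dims)
  expect_equal(rowSums(fw$probs), rep(1, 5), tolerance = 1e-6)
  expect_true(all(fw$probs >= 0))
  expect_equal(rowSums(fw$alpha), rep(1, 5), tolerance = 1e-12)
  expect_equal(max(abs(fw$alpha[, 4])), 0)  # padded step gets zero weight
})

test_that("parameter count matches layer-by-layer arithmetic", {
  cfg <- model_config(conv_filters = 4, kernel_size = 3, lstm_units = 8,
                      attn_units = 5, dense_units = 6, seed = 1)
  m <- build_model(cfg, c(4, 16, 3))
  # conv: (3*3)*4 + 4; pool/flatten: 0; P = floor((16-3+1)/2)*4 = 28
  # lstm: (28 + 8 + 1)*4*8; attention: 8*5 + 5 + 5
  # dense: 8*6 + 6; out: 6*3 + 3
  expected <- (3 * 3 * 4 + 4) + (28 + 8 + 1) * 32 + (8 * 5 + 5 + 5) +
    (8 * 6 + 6) + (6 * 3 + 3)
  expect_equal(n_params(m), expected)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- model_config(conv_filters = 2, kernel_size = 3, pool_size = 2,
                      lstm_units = 4, attn_units = 3, dense_units = 4,
                      dropout = 0, l2 = 0.01, seed = 5)
  Tn <- 3; S <- 8; Fd <- 2; N <- 4
  m <- build_model(cfg, c(Tn, S, Fd))
  set.seed(3)
  X <- array(rnorm(N * Tn * S * Fd), dim = c(N, Tn, S, Fd))
  mask <- matrix(TRUE, N, Tn); mask[2, 3] <- FALSE; mask[3, 2:3] <- FALSE
  y <- c(1, 2, 3, 1); w <- c(1, 1.5, 0.7)
  lg <- skillfuse:::loss_and_grads(m$params, X, mask, y, w, cfg, m$dims)
  num_grad <- function(nm, idx, eps = 1e-6) {
    p1 <- m$params; p1[[nm]][idx] <- p1[[nm]][idx] + eps
    p2 <- m$params; p2[[nm]][idx] <- p2[[nm]][idx] - eps
    (skillfuse:::loss_and_grads(p1, X, mask, y, w, cfg, m$dims)$loss -
     skillfuse:::loss_and_grads(p2, X, mask, y, w, cfg, m$dims)$loss) /
      (2 * eps)
  }
  for (nm in names(m$params)) {
    set.seed(nchar(nm) + 1)
    for (idx in sample(length(m$params[[nm]]),
                       min(4, length(m$params[[nm]])))) {
      ng <- num_grad(nm, idx)
      ag <- lg$grads[[nm]][idx]
      expect_lt(abs(ng - ag) / max(1e-4, abs(ng) + abs(ag)), 1e-5)
    }
  }
})

test_that("a tiny distinct set is memorized and training is deterministic", {
  b <- random_batch(N = 8, Tn = 4, S = 16, Fd = 3)
  cfg <- tiny_model_config(epochs = 200, learning_rate = 0.01)
  m1 <- train_model(build_model(cfg, c(4, 16, 3)), b, patience = 1000)
  expect_equal(mean(predict_model(m1, b)$labels == b$labels), 1)
  expect_lte(m1$stopped_epoch, 200)
  m2 <- train_model(build_model(cfg, c(4, 16, 3)), b, patience = 1000)
  expect_identical(m1$params, m2$params)
  p1 <- predict_model(m1, b); p2 <- predict_model(m1, b)
  expect_identical(p1$probs, p2$probs)
})

test_that("equal class weights reduce to unweighted cross-entropy", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, c(4, 16, 3))
  b <- random_batch(N = 6)
  lw <- skillfuse:::loss_and_grads(m$params, b$data, b$mask, b$labels,
                                   rep(1, 3), cfg, m$dims)
  pr <- skillfuse:::forward_pass(m$params, b$data, b$mask, cfg,
                                 m$dims)$probs
  manual <- mean(-log(pr[cbind(1:6, b$labels)]))
  expect_equal(lw$loss, manual, tolerance = 1e-8)
})

test_that("scaling all class weights leaves Adam training unchanged", {
  b <- random_batch(N = 8)
  cfg <- tiny_model_config(epochs = 15)
  m1 <- train_model(build_model(cfg, c(4, 16, 3)), b,
                    class_weights = c(1, 1.4, 0.8), patience = 100)
  m2 <- train_model(build_model(cfg, c(4, 16, 3)), b,
                    class_weights = 3 * c(1, 1.4, 0.8), patience = 100)
  rel <- max(abs(unlist(m1$params) - unlist(m2$params))) /
    max(abs(unlist(m1$params)))
  expect_lt(rel, 1e-2)
})

test_that("class weights follow the balanced convention", {
  w <- compute_class_weights(rep(1:3, c(200, 100, 100)))
  expect_equal(w, c(2 / 3, 4 / 3, 4 / 3))
  expect_equal(compute_class_weights(rep(1:3, each = 50)), rep(1, 3))
  expect_equal(compute_class_weights(rep(1:3, c(400, 200, 200))), w)
  expect_error(compute_class_weights(c(1, 1, 2)), "classes")
})

test_that("perturbing masked steps leaves the logits unchanged", {
  b <- random_batch(N = 6, Tn = 4, n_pad_steps = 2)
  cfg <- tiny_model_config(epochs = 10)
  m <- train_model(build_model(cfg, c(4, 16, 3)), b, patience = 100)
  base <- predict_model(m, b)
  b2 <- b
  set.seed(99)
  b2$data[, 3:4, , ] <- rnorm(length(b2$data[, 3:4, , ])) * 50
  pert <- predict_model(m, b2)
  expect_lt(max(abs(base$probs - pert$probs)), 1e-5)
  # sanity: perturbing an unmasked step does change them
  b3 <- b
  b3$data[, 1, , ] <- b3$data[, 1, , ] + 1
  expect_gt(max(abs(base$probs - predict_model(m, b3)$probs)), 1e-5)
})

test_that("shape mismatches are rejected", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, c(4, 16, 3))
  b <- random_batch(N = 2, Tn = 4, S = 12, Fd = 3)
  expect_error(predict_model(m, b), "match")
  expect_error(build_model(cfg, c(4, 2, 3)), "kernel")
})

test_that("models round-trip through the checkpoint writer", {
  cfg <- tiny_model_config(epochs = 3)
  m <- train_model(build_model(cfg, c(4, 16, 3)), random_batch(N = 6),
                   patience = 10)
  p <- withr::local_tempfile(fileext = ".rds")
  write_model(m, p)
  m2 <- read_model(p)
  expect_identical(m2$params, m$params)
  expect_true(file.exists(paste0(p, ".json")))
})
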