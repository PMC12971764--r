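# CNN-LSTM classifier with masked additive attention, implemented directly
# as dense linear algebra: per-timestep 1-D convolution (im2col + BLAS),
# max pooling, flatten, a single LSTM layer over the T steps, additive
# attention whose softmax excludes padded steps, dropout, dense ReLU, and a
# softmax output over the three skill classes. Training minimizes
# class-weighted categorical cross-entropy with L2 penalties on the
# convolution and LSTM kernels, via Adam with early stopping. Analytic
# gradients throughout (verified against numerical differentiation in the
# test suite).

#' Model hyperparameter configuration
#'
#' The searched values in the study were: LSTM units {50, 100, 150, 200},
#' convolution filters {32, 64, 128}, kernel size {3, 5}, dropout
#' {0.5, 0.6, 0.8}, L2 {0.1, 0.01, 0.001}, epochs {50, 100}, batch size
#' {64, 128, 256}. Any positive values are accepted so that reduced
#' desk-scale presets can be run; the defaults below are such a preset.
#'
#' @param conv_filters Number of convolution filters.
#' @param kernel_size Convolution kernel length (samples).
#' @param pool_size Max-pooling width (non-overlapping; default 2).
#' @param lstm_units LSTM hidden size.
#' @param attn_units Width of the additive-attention projection.
#' @param dropout Dropout rate after the attention context and the dense
#'   layer.
#' @param l2 L2 penalty coefficient on the convolution and LSTM kernels.
#' @param dense_units Width of the penultimate dense ReLU layer.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param optimizer Optimizer name ("adam").
#' @param learning_rate Step size.
#' @param clip_norm Global gradient-norm ceiling (gradients are rescaled
#'   when their joint L2 norm exceeds it); `Inf` (default) disables
#'   clipping.
#' @param seed Seed governing initialization, shuffling and dropout.
#' @return An `sf_model_config`.
#' @export
model_config <- function(conv_filters = 8, kernel_size = 3, pool_size = 2,
                         lstm_units = 24, attn_units = 16, dropout = 0.5,
                         l2 = 0.001, dense_units = 16, epochs = 40,
                         batch_size = 64, optimizer = "adam",
                         learning_rate = 1e-3, clip_norm = Inf,
                         seed = 1L) {
  stopifnot(conv_filters >= 1, kernel_size >= 1, pool_size >= 1,
            lstm_units >= 1, attn_units >= 1, dense_units >= 1,
            dropout >= 0, dropout < 1, l2 >= 0, epochs >= 1,
            batch_size >= 1, learning_rate > 0, clip_norm > 0)
  if (optimizer != "adam") stopf("only the adam optimizer is implemented")
  structure(as.list(environment()), class = "sf_model_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Build an untrained CNN-LSTM-attention model
#'
#' @param cfg An `sf_model_config`.
#' @param input_shape `c(T, L_step, F)` per-window shape.
#' @return An `sf_model` with seeded Glorot-initialized parameters.
#' @export
build_model <- function(cfg, input_shape) {
  stopifnot(length(input_shape) == 3L)
  Tn <- input_shape[1]; S <- input_shape[2]; Fdim <- input_shape[3]
  if (cfg$kernel_size > S) stopf("kernel longer than a step")
  C_out <- S - cfg$kernel_size + 1L
  P_len <- C_out %/% cfg$pool_size
  if (P_len < 1L) stopf("pooling leaves no output")
  P <- P_len * cfg$conv_filters
  U <- cfg$lstm_units; A <- cfg$attn_units; D <- cfg$dense_units
  params <- with_seed(derive_seed(cfg$seed, "init"), {
    p <- list(
      Wc = glorot(cfg$kernel_size * Fdim, cfg$conv_filters),
      bc = numeric(cfg$conv_filters),
      Wx = glorot(P, 4 * U),
      Wh = glorot(U, 4 * U),
      bl = numeric(4 * U),
      Wa = glorot(U, A),
      ba = numeric(A),
      va = stats::runif(A, -sqrt(3 / A), sqrt(3 / A)),
      W1 = glorot(U, D),
      b1 = numeric(D),
      W2 = glorot(D, 3L),
      b2 = numeric(3L)
    )
    # forget-gate bias at 1 (standard LSTM initialization aid)
    p$bl[(U + 1):(2 * U)] <- 1
    p
  })
  structure(list(
    cfg = cfg, input_shape = input_shape, params = params,
    dims = list(C_out = C_out, P_len = P_len, P = P, U = U, A = A, D = D,
                S = S, Fd = Fdim),
    history = NULL, stopped_epoch = NA_integer_
  ), class = "sf_model")
}

#' Parameter count of a model
#' @param model An `sf_model`.
#' @return Integer total number of trainable scalars.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, 1L))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# im2col for one timestep across the batch: returns (N*C_out) x (k*F),
# column block j holds the signal shifted by j - 1 samples.
im2col_step <- function(Xt, k, C_out) {
  N <- dim(Xt)[1]; Fdim <- dim(Xt)[3]
  blocks <- vector("list", k)
  for (j in seq_len(k)) {
    b <- Xt[, j:(j + C_out - 1L), , drop = FALSE]
    dim(b) <- c(N * C_out, Fdim)
    blocks[[j]] <- b
  }
  do.call(cbind, blocks)
}

# Precompute the per-step im2col matrices for a window set, so that
# training epochs are pure BLAS (the same matrices serve the forward and
# the backward pass of every epoch).
precompute_conv_inputs <- function(X, cfg, dims) {
  Tn <- dim(X)[2]; S <- dim(X)[3]; Fdim <- dim(X)[4]; N <- dim(X)[1]
  lapply(seq_len(Tn), function(t) {
    im2col_step(array(X[, t, , , drop = FALSE], dim = c(N, S, Fdim)),
                cfg$kernel_size, dims$C_out)
  })
}

# Full forward pass. X: (N, T, S, F) array, mask: (N, T) logical.
# drop_masks: optional list(d1 = N x U, d2 = N x D) already scaled by
# 1/(1-p) (inverted dropout); NULL = inference. Cpre: optional output of
# precompute_conv_inputs for X.
forward_pass <- function(params, X, mask, cfg, dims, drop_masks = NULL,
                         keep_cache = FALSE, Cpre = NULL) {
  N <- nrow(mask); Tn <- ncol(mask)
  S <- dims$S %||% dim(X)[3]; Fdim <- dims$Fd %||% dim(X)[4]
  k <- cfg$kernel_size; C_out <- dims$C_out; P_len <- dims$P_len
  K <- cfg$conv_filters; P <- dims$P; U <- dims$U
  H <- array(0, dim = c(N, Tn, U))
  cache <- if (keep_cache) {
    list(relu = vector("list", Tn), arg1 = vector("list", Tn),
         hin = vector("list", Tn), gates = vector("list", Tn),
         cst = vector("list", Tn), tanh_c = vector("list", Tn))
  }
  h_prev <- matrix(0, N, U); c_prev <- matrix(0, N, U)
  h_all_prev <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    C <- if (is.null(Cpre)) {
      im2col_step(array(X[, t, , , drop = FALSE], dim = c(N, S, Fdim)),
                  k, C_out)
    } else {
      Cpre[[t]]
    }
    Z <- C %*% params$Wc
    Z <- sweep(Z, 2L, params$bc, "+")
    Apos <- Z > 0
    Act <- Z * Apos
    Aarr <- array(Act, dim = c(N, C_out, K))
    i1 <- seq(1L, by = cfg$pool_size, length.out = P_len)
    slabs <- lapply(seq_len(cfg$pool_size), function(o) {
      Aarr[, i1 + o - 1L, , drop = FALSE]
    })
    M <- Reduce(pmax, slabs)
    # winner masks, earliest slab claims ties (deterministic routing)
    sel <- vector("list", cfg$pool_size)
    claimed <- array(FALSE, dim = dim(M))
    for (o in seq_len(cfg$pool_size)) {
      eq <- (slabs[[o]] == M) & !claimed
      sel[[o]] <- eq
      claimed <- claimed | eq
    }
    hin <- M
    dim(hin) <- c(N, P)
    G <- hin %*% params$Wx + h_prev %*% params$Wh
    G <- sweep(G, 2L, params$bl, "+")
    gi <- sigmoid(G[, 1:U, drop = FALSE])
    gf <- sigmoid(G[, (U + 1):(2 * U), drop = FALSE])
    gg <- tanh(G[, (2 * U + 1):(3 * U), drop = FALSE])
    go <- sigmoid(G[, (3 * U + 1):(4 * U), drop = FALSE])
    c_t <- gf * c_prev + gi * gg
    tc <- tanh(c_t)
    h_t <- go * tc
    H[, t, ] <- h_t
    if (keep_cache) {
      cache$relu[[t]] <- Apos
      cache$arg1[[t]] <- sel
      cache$hin[[t]] <- hin
      cache$gates[[t]] <- list(i = gi, f = gf, g = gg, o = go,
                               c_prev = c_prev, h_prev = h_prev)
      cache$cst[[t]] <- c_t
      cache$tanh_c[[t]] <- tc
    }
    h_prev <- h_t; c_prev <- c_t
  }
  # additive attention with masked softmax over the T steps
  E <- matrix(-Inf, N, Tn)
  Uatt <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    u <- tanh(sweep(H[, t, , drop = FALSE][, 1, ] %*% params$Wa, 2L,
                    params$ba, "+"))
    if (N == 1L) u <- matrix(u, 1L)
    Uatt[[t]] <- u
    E[, t] <- drop(u %*% params$va)
  }
  E[!mask] <- -Inf
  Emax <- apply(E, 1L, max)
  W <- exp(E - Emax)
  W[!mask] <- 0
  alpha <- W / rowSums(W)
  ctx <- matrix(0, N, U)
  for (t in seq_len(Tn)) {
    ctx <- ctx + alpha[, t] * matrix(H[, t, ], N, U)
  }
  ctx_d <- if (is.null(drop_masks)) ctx else ctx * drop_masks$d1
  Z1 <- sweep(ctx_d %*% params$W1, 2L, params$b1, "+")
  A1 <- Z1 * (Z1 > 0)
  A1_d <- if (is.null(drop_masks)) A1 else A1 * drop_masks$d2
  logits <- sweep(A1_d %*% params$W2, 2L, params$b2, "+")
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits, alpha = alpha)
  if (keep_cache) {
    out$cache <- c(cache, list(
      H = H, Uatt = Uatt, ctx = ctx, ctx_d = ctx_d, Z1 = Z1, A1 = A1,
      A1_d = A1_d, X = X, mask = mask
    ))
  }
  out
}

# Class-weighted cross-entropy loss and analytic gradients for one batch.
# y in {1,2,3}; w = per-class weights; drop_masks as in forward_pass.
loss_and_grads <- function(params, X, mask, y, w, cfg, dims,
                           drop_masks = NULL, Cpre = NULL) {
  N <- nrow(mask); Tn <- ncol(mask)
  S <- dims$S %||% dim(X)[3]; Fdim <- dims$Fd %||% dim(X)[4]
  k <- cfg$kernel_size; C_out <- dims$C_out; P_len <- dims$P_len
  K <- cfg$conv_filters; P <- dims$P; U <- dims$U
  fw <- forward_pass(params, X, mask, cfg, dims, drop_masks,
                     keep_cache = TRUE, Cpre = Cpre)
  cache <- fw$cache
  wn <- w[y]
  eps <- 1e-12
  ce <- -log(pmax(fw$probs[cbind(seq_len(N), y)], eps))
  loss <- mean(wn * ce) +
    cfg$l2 * (sum(params$Wc^2) + sum(params$Wx^2) + sum(params$Wh^2))
  g <- lapply(params, function(p) p * 0)
  # output layer
  dlogits <- fw$probs
  dlogits[cbind(seq_len(N), y)] <- dlogits[cbind(seq_len(N), y)] - 1
  dlogits <- dlogits * (wn / N)
  g$W2 <- t(cache$A1_d) %*% dlogits
  g$b2 <- colSums(dlogits)
  dA1_d <- dlogits %*% t(params$W2)
  dA1 <- if (is.null(drop_masks)) dA1_d else dA1_d * drop_masks$d2
  dZ1 <- dA1 * (cache$Z1 > 0)
  g$W1 <- t(cache$ctx_d) %*% dZ1
  g$b1 <- colSums(dZ1)
  dctx_d <- dZ1 %*% t(params$W1)
  dctx <- if (is.null(drop_masks)) dctx_d else dctx_d * drop_masks$d1
  # attention backward
  alpha <- fw$alpha
  H <- cache$H
  dalpha <- matrix(0, N, Tn)
  dH_att <- array(0, dim = c(N, Tn, U))
  for (t in seq_len(Tn)) {
    Ht <- matrix(H[, t, ], N, U)
    dalpha[, t] <- rowSums(dctx * Ht)
    dH_att[, t, ] <- alpha[, t] * dctx
  }
  dE <- alpha * (dalpha - rowSums(alpha * dalpha))
  for (t in seq_len(Tn)) {
    u <- cache$Uatt[[t]]
    det <- dE[, t]
    g$va <- g$va + drop(t(u) %*% det)
    dpre <- (det %o% params$va) * (1 - u^2)
    g$Wa <- g$Wa + t(matrix(H[, t, ], N, U)) %*% dpre
    g$ba <- g$ba + colSums(dpre)
    dH_att[, t, ] <- dH_att[, t, ] + dpre %*% t(params$Wa)
  }
  # LSTM BPTT + conv backward per step
  dh_next <- matrix(0, N, U); dc_next <- matrix(0, N, U)
  for (t in rev(seq_len(Tn))) {
    gt <- cache$gates[[t]]
    tc <- cache$tanh_c[[t]]
    dh <- matrix(dH_att[, t, ], N, U) + dh_next
    do_ <- dh * tc
    dc <- dc_next + dh * gt$o * (1 - tc^2)
    di <- dc * gt$g
    dg <- dc * gt$i
    df <- dc * gt$c_prev
    dc_next <- dc * gt$f
    dG <- cbind(
      di * gt$i * (1 - gt$i),
      df * gt$f * (1 - gt$f),
      dg * (1 - gt$g^2),
      do_ * gt$o * (1 - gt$o)
    )
    g$Wx <- g$Wx + t(cache$hin[[t]]) %*% dG
    g$Wh <- g$Wh + t(gt$h_prev) %*% dG
    g$bl <- g$bl + colSums(dG)
    dh_next <- dG %*% t(params$Wh)
    dhin <- dG %*% t(params$Wx)
    # conv/pool backward for this step
    dM <- array(dhin, dim = c(N, P_len, K))
    dA <- array(0, dim = c(N, C_out, K))
    i1 <- seq(1L, by = cfg$pool_size, length.out = P_len)
    for (o in seq_len(cfg$pool_size)) {
      dA[, i1 + o - 1L, ] <- dM * cache$arg1[[t]][[o]]
    }
    dZ <- matrix(dA, N * C_out, K) * cache$relu[[t]]
    C <- if (is.null(Cpre)) {
      im2col_step(array(X[, t, , , drop = FALSE], dim = c(N, S, Fdim)),
                  k, C_out)
    } else {
      Cpre[[t]]
    }
    g$Wc <- g$Wc + t(C) %*% dZ
    g$bc <- g$bc + colSums(dZ)
  }
  g$Wc <- g$Wc + 2 * cfg$l2 * params$Wc
  g$Wx <- g$Wx + 2 * cfg$l2 * params$Wx
  g$Wh <- g$Wh + 2 * cfg$l2 * params$Wh
  list(loss = loss, grads = g, probs = fw$probs)
}

#' Class weights inversely proportional to class frequencies
#'
#' The "balanced" convention: `w_c = n_total / (n_classes * n_c)`.
#'
#' @param labels Integer labels in {1, 2, 3}.
#' @return Numeric weight per class (length 3).
#' @export
compute_class_weights <- function(labels) {
  counts <- tabulate(labels, nbins = 3L)
  if (any(counts == 0L)) stopf("all 3 classes must be present")
  length(labels) / (3 * counts)
}

unweighted_val_loss <- function(model, batch, Cpre = NULL) {
  fw <- forward_pass(model$params, batch$data, batch$mask, model$cfg,
                     model$dims, Cpre = Cpre)
  y <- batch$labels
  mean(-log(pmax(fw$probs[cbind(seq_along(y), y)], 1e-12)))
}

#' Train the classifier
#'
#' Minimizes class-weighted categorical cross-entropy with Adam, monitoring
#' the (unweighted) validation loss when a validation batch is given;
#' training stops once that loss has not improved for `patience`
#' consecutive epochs, restoring the best parameters. Fully seeded:
#' identical seeds give identical final weights.
#'
#' Mini-batches are drawn once (seeded) and kept fixed across epochs, with
#' the processing order reshuffled each epoch; this lets the convolution's
#' im2col matrices be precomputed per batch and reused by every epoch's
#' forward and backward pass.
#'
#' @param model An `sf_model` from [build_model()].
#' @param train_batch Normalized `sf_batch`.
#' @param val_batch Optional normalized `sf_batch` for early stopping.
#' @param class_weights Length-3 weights (default: computed from the
#'   training labels).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param verbose Print per-epoch losses.
#' @return The trained `sf_model` with `history` and `stopped_epoch`.
#' @export
train_model <- function(model, train_batch, val_batch = NULL,
                        class_weights = NULL, patience = 10,
                        verbose = FALSE) {
  cfg <- model$cfg
  N <- dim(train_batch$data)[1]
  if (N < 1L) stopf("empty training batch")
  y <- train_batch$labels
  w <- class_weights %||% compute_class_weights(y)
  params <- model$params
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8
  step <- 0L
  U <- model$dims$U; D <- model$dims$D
  best_val <- Inf; best_params <- params; bad <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  # im2col matrices are cached across epochs only while they fit in a
  # fixed memory budget; beyond it they are rebuilt on the fly.
  pre_budget <- getOption("skillfuse.im2col_budget", 1.6e9)
  bytes_per_window <- 8 * prod(dim(train_batch$data)[2]) *
    model$dims$C_out * cfg$kernel_size * dim(train_batch$data)[4]
  use_pre <- N * bytes_per_window <= pre_budget
  use_val_pre <- !is.null(val_batch) &&
    dim(val_batch$data)[1] * bytes_per_window <= 0.25 * pre_budget
  with_seed(derive_seed(cfg$seed, "train"), {
    # fixed seeded batch partition; im2col precomputed once per batch
    idx <- sample.int(N)
    starts <- seq(1L, N, by = cfg$batch_size)
    batches <- lapply(starts, function(s) {
      bi <- idx[s:min(N, s + cfg$batch_size - 1L)]
      Xb <- train_batch$data[bi, , , , drop = FALSE]
      out <- list(bi = bi,
                  mask = train_batch$mask[bi, , drop = FALSE])
      if (use_pre) {
        # with the im2col cache the raw tensor is never touched again
        out$Cpre <- precompute_conv_inputs(Xb, cfg, model$dims)
      } else {
        out$X <- Xb
      }
      out
    })
    val_Cpre <- if (use_val_pre) {
      precompute_conv_inputs(val_batch$data, cfg, model$dims)
    }
    gc(FALSE)
    for (ep in seq_len(cfg$epochs)) {
      ep_loss <- 0; nb <- 0L
      for (b in batches[sample.int(length(batches))]) {
        bi <- b$bi
        nb_i <- length(bi)
        dm <- if (cfg$dropout > 0) {
          keep <- 1 - cfg$dropout
          list(
            d1 = matrix(stats::rbinom(nb_i * U, 1, keep), nb_i, U) / keep,
            d2 = matrix(stats::rbinom(nb_i * D, 1, keep), nb_i, D) / keep
          )
        }
        lg <- loss_and_grads(params, b$X %||% NULL, b$mask, y[bi], w, cfg,
                             model$dims, dm, Cpre = b$Cpre)
        clip <- cfg$clip_norm %||% Inf
        if (is.finite(clip)) {
          gnorm <- sqrt(sum(vapply(lg$grads, function(g) sum(g^2),
                                   numeric(1))))
          if (gnorm > clip) {
            lg$grads <- lapply(lg$grads, function(g) g * (clip / gnorm))
          }
        }
        step <- step + 1L
        for (nm in names(params)) {
          gn <- lg$grads[[nm]]
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gn
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gn^2
          mhat <- mstate[[nm]] / (1 - b1^step)
          vhat <- vstate[[nm]] / (1 - b2^step)
          params[[nm]] <- params[[nm]] -
            cfg$learning_rate * mhat / (sqrt(vhat) + epsa)
        }
        ep_loss <- ep_loss + lg$loss * nb_i
        nb <- nb + nb_i
      }
      model$params <- params
      vl <- if (!is.null(val_batch)) {
        unweighted_val_loss(model, val_batch, Cpre = val_Cpre)
      } else {
        ep_loss / nb
      }
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                     val_loss = vl))
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                        ep_loss / nb, vl))
      }
      if (vl < best_val - 1e-9) {
        best_val <- vl; best_params <- params; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
    model$params <- best_params
    model$history <- hist
    model$stopped_epoch <- nrow(hist)
  })
  model
}

#' Predict class probabilities and labels for a batch
#'
#' Deterministic inference (no dropout). Data inside masked (fully padded)
#' steps cannot influence the output: those steps receive zero attention
#' weight and lie after all real data in the sequence.
#'
#' @param model A trained `sf_model`.
#' @param batch An `sf_batch` shaped like the model input.
#' @return list(probs = N x 3 matrix, labels = argmax classes,
#'   alpha = N x T attention weights).
#' @export
predict_model <- function(model, batch) {
  d <- dim(batch$data)
  if (!all(d[2:4] == model$input_shape)) {
    stopf("batch shape (%s) does not match model input (%s)",
          paste(d[2:4], collapse = ","),
          paste(model$input_shape, collapse = ","))
  }
  fw <- forward_pass(model$params, batch$data, batch$mask, model$cfg,
                     model$dims)
  list(probs = fw$probs, labels = max.col(fw$probs, ties.method = "first"),
       alpha = fw$alpha)
}

#' @export
print.sf_model <- function(x, ...) {
  cat(sprintf(
    "CNN-LSTM-attention model: input (%s), %d filters (k=%d), %d LSTM units, %d params%s\n",
    paste(x$input_shape, collapse = ", "), x$cfg$conv_filters,
    x$cfg$kernel_size, x$cfg$lstm_units, n_params(x),
    if (is.null(x$history)) " (untrained)" else
      sprintf(", trained %d epochs", x$stopped_epoch)
  ))
  invisible(x)
}

#' Save / load a trained model with its config and history
#' @param model An `sf_model`.
#' @param path Base path; parameters and a JSON sidecar of config/history
#'   are written under it.
#' @return `path` invisibly (writer); an `sf_model` (reader).
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  side <- paste0(path, ".json")
  jsonlite::write_json(
    list(config = unclass(model$cfg),
         input_shape = model$input_shape,
         stopped_epoch = model$stopped_epoch,
         history = model$history),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "sf_model"))
  m
}
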