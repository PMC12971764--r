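# Small shared fixtures, built in code.

tiny_config <- function(seed = 7, n_participants = 3, eeg_channels = 16,
                        effect_size = 1, ...) {
  generator_config(
    n_participants = n_participants, eeg_channels = eeg_channels,
    trial_duration_range_per_class = list(c(6, 8), c(5, 7), c(3, 6)),
    trials_per_participant = 1, effect_size = effect_size, seed = seed, ...
  )
}

tiny_cohort <- function(...) generate_cohort(tiny_config(...))

# A synthetic batch with controllable padding, for model-level tests.
random_batch <- function(N = 6, Tn = 4, S = 16, Fd = 3, n_pad_steps = 0,
                         seed = 1) {
  set.seed(seed)
  X <- array(stats::rnorm(N * Tn * S * Fd), dim = c(N, Tn, S, Fd))
  mask <- matrix(TRUE, N, Tn)
  n_real <- rep(Tn * S, N)
  if (n_pad_steps > 0) {
    mask[, (Tn - n_pad_steps + 1):Tn] <- FALSE
    n_real <- rep((Tn - n_pad_steps) * S, N)
    X[, (Tn - n_pad_steps + 1):Tn, , ] <- 0
  }
  structure(list(
    data = X, mask = mask, n_real = n_real,
    labels = rep_len(1:3, N), participant_ids = as.character(seq_len(N)),
    subtask = 1L, features = as.character(seq_len(Fd)),
    cfg = NULL
  ), class = "sf_batch")
}

tiny_model_config <- function(...) {
  args <- list(conv_filters = 4, kernel_size = 3, lstm_units = 8,
               attn_units = 4, dense_units = 8, dropout = 0, l2 = 0,
               epochs = 30, batch_size = 8, learning_rate = 5e-3,
               seed = 2)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

# sine-wave amplitude via FFT, used as an independent oracle for filters
fft_amplitude <- function(x, fs, f) {
  n <- length(x)
  sp <- abs(stats::fft(x)) / n * 2
  sp[round(f * n / fs) + 1]
}
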