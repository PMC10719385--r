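# Shared fixtures, built once per test run. The small experiment keeps the
# full acquisition geometry (sampling rate, trial layout, channel counts)
# but fewer trials per session, so preprocessing stays cheap.

.fixtures <- new.env(parent = emptyenv())

small_generator_config <- function(...) {
  generator_config(n_trials_per_session = 10L, ...)
}

get_small_experiment <- function() {
  if (is.null(.fixtures$exp))
    .fixtures$exp <- generate_experiment(small_generator_config(), seed = 71L)
  .fixtures$exp
}

get_small_envexp <- function(modality = "EMG") {
  key <- paste0("env_", modality)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- preprocess_modality(get_small_experiment(), modality)
  .fixtures[[key]]
}

# quick training configuration for tests that only need a working model
tiny_model_config <- function(...) {
  model_config(res_filters = 16L, fc_units = 20L, epochs = 10L, ...)
}

# balanced, linearly separable window tensor for capacity/attribution tests
separable_dataset <- function(n_per_class = 100L, T_win = 20L, C = 8L,
                              shift = 1.5, seed = 9L,
                              classes = c("DII", "DV", "NoMove")) {
  with_seed <- mmgdecode:::with_seed
  with_seed(seed, {
    n <- n_per_class * length(classes)
    X <- array(stats::rnorm(n * T_win * C), c(n, T_win, C))
    y <- factor(rep(classes, each = n_per_class), levels = classes)
    X[seq_len(n_per_class), , 1] <- X[seq_len(n_per_class), , 1] + shift
    X[n_per_class + seq_len(n_per_class), , 2] <-
      X[n_per_class + seq_len(n_per_class), , 2] + shift
    list(X = X, y = y)
  })
}
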