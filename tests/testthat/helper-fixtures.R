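# Shared fixtures, built in code. Heavy artifacts are memoized in this
# environment so several test files (and several test_that blocks) can share
# one construction.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a deterministic multi-channel test recording: known sinusoids + noise
make_test_recording <- function(n_channels = 21, rate = 250, duration = 300,
                                seed = 123, channel_names = default_montage()) {
  set.seed(seed)
  S <- rate * duration
  t <- seq_len(S) / rate
  sig <- matrix(stats::rnorm(n_channels * S, sd = 20), n_channels, S)
  for (c in seq_len(n_channels)) {
    sig[c, ] <- sig[c, ] + 40 * sin(2 * pi * (4 + c %% 7) * t)
  }
  new_eeg_recording(sig, rate, channel_names[seq_len(n_channels)],
                    subject_meta = list(age = 44, gender = "F",
                                        pathological = FALSE),
                    report_text = "IMPRESSION: Test recording.",
                    id = sprintf("test%03d", seed))
}

# tiny encoder configuration used by fast unit tests
tiny_encoder <- function(seed = 1) {
  set.seed(seed)
  deep4_encoder(n_channels = 3, input_samples = 130, widths = c(2, 3, 3, 4),
                kernel = 4, pool = 2, dropout = 0, embedding_dim = 5)
}

# finite-difference gradient of f at x (numeric vector), forward differences
fd_grad <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  vapply(seq_along(x), function(i) {
    x2 <- x
    x2[i] <- x2[i] + eps
    (f(x2) - f0) / eps
  }, 0)
}

# a tiny 2-class paired corpus for fast training-behaviour tests
tiny_corpus_prep <- function(n = 12, seed = 5) {
  memo(sprintf("tiny_corpus_%d_%d", n, seed), function() {
    corpus <- generate_corpus(corpus_spec(n_recordings = n, seed = seed))
    prepare_paired_data(corpus)
  })
}

tiny_train_cfg <- function(...) {
  args <- list(epochs = 3, batch_size = 8, seed = 1,
               eeg_widths = c(4, 8, 8, 8), proj_hidden = 32,
               projection_dim = 16)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(train_config, args)
}


# an "easy" two-class world whose backgrounds differ by class (posterior
# alpha only in the normal class): training dynamics converge in a few
# dozen steps, suitable for fast unit tests of the optimization behaviour.
easy_corpus_prep <- function(n = 16, seed = 8) {
  memo(sprintf("easy_corpus_%d_%d", n, seed), function() {
    classes <- default_classes()
    classes$normal_alpha$events <- default_background()
    spec <- corpus_spec(n_recordings = n, classes = classes,
                       background = list(), seed = seed)
    prepare_paired_data(generate_corpus(spec))
  })
}
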