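# Shared fixtures, built once per test run. Sizes are kept small; the
# acceptance tests build their own larger inputs.

# A small dry-montage recording with the default effect, preprocessed and
# cut to the window of interest (60 trials, 20% errors).
fixture_epochs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- generate_recording(montage("dry20"), errp_model(),
                                n_trials = 60, error_fraction = 0.2,
                                seed = 404)
      cache <<- extract_interest_window(preprocess_recording(rec))
    }
    cache
  }
})

# Epoch set with a deterministic class-dependent offset: trivially
# separable, used for overfit/leakage sanity checks.
separable_epochs <- function(n_trials = 32, n_channels = 4, n_samples = 64,
                             rate = 250, seed = 1, offset = 5) {
  withr::with_seed(seed, {
    labels <- rep(c("error", "true"), length.out = n_trials)
    dat <- array(rnorm(n_trials * n_channels * n_samples),
                 dim = c(n_trials, n_channels, n_samples))
    dat[labels == "error", , ] <- dat[labels == "error", , ] + offset
    epoch_set(dat, labels, rate, paste0("ch", seq_len(n_channels)),
              onset_index = 1L)
  })
}

# Pure-noise epochs with labels independent of the data (permutation null).
null_epochs <- function(n_trials = 60, n_channels = 6, n_samples = 64,
                        seed = 2) {
  withr::with_seed(seed, {
    labels <- sample(rep(c("error", "true"), length.out = n_trials))
    dat <- array(rnorm(n_trials * n_channels * n_samples),
                 dim = c(n_trials, n_channels, n_samples))
    epoch_set(dat, labels, 250, paste0("ch", seq_len(n_channels)),
              onset_index = 1L)
  })
}
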