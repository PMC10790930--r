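#' Generate a continuous synthetic EEG recording
#'
#' Simulates one subject's continuous multichannel EEG for a sequence of
#' observed robot actions. Exactly `round(n_trials * error_fraction)` trials
#' are scheduled as errors (fixed-count scheduling, uniformly shuffled), so
#' the simulated totals match the experimental protocol exactly (e.g. 100
#' errors out of 500 at 20%). Error trials carry the two-bump evoked
#' template of [errp_model()] projected onto the montage's frontocentral
#' weights; all trials carry the shared evoked component; background noise
#' is white or 1/f-shaped, plus an optional common 50 Hz mains component.
#'
#' @param montage a [montage()] specification.
#' @param errp an [errp_model()].
#' @param n_trials number of observed actions (>= 1).
#' @param error_fraction fraction of error trials in \[0, 1\].
#' @param inter_trial_interval onset-to-onset spacing in seconds; must be at
#'   least 1.2 s so that epochs of the standard window do not overlap.
#' @param seed integer seed; identical `(seed, params)` give identical
#'   recordings.
#' @param lead_in seconds of signal before the first onset (and after the
#'   last epoch ends).
#' @return an object of class `subject_recording` with fields `samples`
#'   (channels x time matrix, µV), `events` (data.frame of `sample`,
#'   `label`), `montage`, `rate`, `seed`.
#' @examples
#' rec <- generate_recording(montage("gel16"), errp_model(), n_trials = 10,
#'                           error_fraction = 0.2, seed = 1)
#' table(rec$events$label)
#' @export
generate_recording <- function(montage, errp = errp_model(), n_trials,
                               error_fraction, inter_trial_interval = 2,
                               seed = 1, lead_in = 1) {
  stopifnot(inherits(montage, "montage_spec"), inherits(errp, "errp_model"))
  if (n_trials < 1) stop("n_trials must be >= 1")
  stop_if_not_scalar_prob(error_fraction, "error_fraction")
  if (inter_trial_interval < 1.2)
    stop("inter_trial_interval shorter than the 1.2 s epoch span")

  fs <- montage$sampling_rate
  nc <- length(montage$channel_names)
  n_err <- round(n_trials * error_fraction)
  onsets_s <- lead_in + (seq_len(n_trials) - 1) * inter_trial_interval
  n_time <- ceiling((lead_in + n_trials * inter_trial_interval + 1.2) * fs)
  onset_idx <- round(onsets_s * fs) + 1L

  with_seed(seed, {
    labels <- sample(c(rep("error", n_err), rep("true", n_trials - n_err)))
    x <- background_noise(nc, n_time, fs, errp$noise_sd, errp$noise_spectrum)
    if (errp$line_noise_amplitude > 0) {
      tt <- (seq_len(n_time) - 1) / fs
      line <- errp$line_noise_amplitude * sin(2 * pi * 50 * tt +
                                              stats::runif(1, 0, 2 * pi))
      x <- x + matrix(line, nc, n_time, byrow = TRUE)
    }
    ep_len <- round(1.0 * fs)
    rel_t <- (seq_len(ep_len) - 1) / fs
    w <- montage$frontocentral_weights
    jit <- stats::rnorm(n_trials, 0, errp$trial_latency_jitter_sd)
    for (i in seq_len(n_trials)) {
      tpl <- errp_template(errp, rel_t, jitter = jit[i])
      evoked <- tpl$shared
      if (labels[i] == "error") evoked <- evoked + tpl$errp
      cols <- onset_idx[i]:(onset_idx[i] + ep_len - 1L)
      x[, cols] <- x[, cols] + outer(w, evoked)
    }
    rownames(x) <- montage$channel_names
    structure(list(samples = x,
                   events = data.frame(sample = onset_idx, label = labels,
                                       stringsAsFactors = FALSE),
                   montage = montage, rate = fs, seed = seed, errp = errp),
              class = "subject_recording")
  })
}

# channels x time background noise at standard deviation `sd` per channel.
# 1/f noise is spectrally shaped white noise (amplitude ~ f^(-1/2) per bin,
# i.e. power ~ 1/f), rescaled to the requested sd.
background_noise <- function(nc, n_time, fs, sd, spectrum) {
  if (sd == 0) return(matrix(0, nc, n_time))
  if (spectrum == "white")
    return(matrix(stats::rnorm(nc * n_time, 0, sd), nc, n_time))
  n_fft <- stats::nextn(n_time, c(2, 3, 5))
  k <- seq_len(n_fft) - 1
  f <- pmin(k, n_fft - k) * fs / n_fft
  amp <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- matrix(0, nc, n_time)
  for (c in seq_len(nc)) {
    wn <- stats::rnorm(n_fft)
    shaped <- Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) / n_fft
    shaped <- shaped[seq_len(n_time)]
    x[c, ] <- shaped * (sd / stats::sd(shaped))
  }
  x
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf(
    "<subject_recording: %d ch x %d samples @ %g Hz, %d events (%d error)>\n",
    nrow(x$samples), ncol(x$samples), x$rate, nrow(x$events),
    sum(x$events$label == "error")))
  invisible(x)
}

#' Construct an epoch set
#'
#' The common container for epoched EEG: a trials x channels x time array
#' with per-trial class labels. Epoch windows are half-open `[start, stop)`,
#' so a (-0.2, 1.0) s window at 250 Hz has exactly 300 samples.
#'
#' @param data numeric array, trials x channels x time.
#' @param labels character/factor vector, one of `"error"`/`"true"` per trial.
#' @param rate sampling rate in Hz.
#' @param channel_names channel labels, length = dim(data)\[2\].
#' @param onset_index 1-based sample index of the action onset (t = 0)
#'   within the epoch.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, rate, channel_names, onset_index) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  labels <- as.character(labels)
  if (length(labels) != dim(data)[1])
    stop("labels length must equal number of trials")
  if (!all(labels %in% c("error", "true")))
    stop("labels must be 'error' or 'true'")
  if (length(channel_names) != dim(data)[2])
    stop("channel_names length must equal number of channels")
  structure(list(data = data, labels = labels, rate = rate,
                 channel_names = channel_names,
                 onset_index = as.integer(onset_index)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set: %d trials (%d error) x %d ch x %d samples @ %g Hz>\n",
              d[1], sum(x$labels == "error"), d[2], d[3], x$rate))
  invisible(x)
}

# Times (s, relative to onset) of the samples of an epoch set.
epoch_times <- function(epochs) {
  (seq_len(dim(epochs$data)[3]) - epochs$onset_index) / epochs$rate
}

#' Epoch a recording using the ground-truth event list
#'
#' Cuts fixed-length epochs directly around the stored event onsets, without
#' any filtering — the oracle path used to test downstream stages
#' independently of the preprocessing chain. Windows are half-open
#' `[start, stop)`. Events whose window falls outside the recording are
#' dropped with a warning.
#'
#' @param recording a `subject_recording`.
#' @param window numeric length-2, epoch window in seconds relative to
#'   onset, default `c(-0.2, 1.0)`.
#' @return an [epoch_set()].
#' @export
epoch_ground_truth <- function(recording, window = c(-0.2, 1.0)) {
  stopifnot(inherits(recording, "subject_recording"), length(window) == 2,
            window[1] < window[2])
  cut_epochs(recording$samples, recording$events, recording$rate, window,
             rownames(recording$samples))
}

# Shared epoch-cutting core (also used by the preprocessing chain).
cut_epochs <- function(samples, events, fs, window, channel_names) {
  start_off <- round(window[1] * fs)
  len <- round((window[2] - window[1]) * fs)
  n_time <- ncol(samples)
  first <- events$sample + start_off
  keep <- first >= 1 & (first + len - 1) <= n_time
  if (any(!keep))
    warning(sprintf("dropped %d epoch(s) extending beyond the recording",
                    sum(!keep)))
  events <- events[keep, , drop = FALSE]
  dat <- array(0, dim = c(nrow(events), nrow(samples), len))
  for (i in seq_len(nrow(events))) {
    i0 <- events$sample[i] + start_off
    dat[i, , ] <- samples[, i0:(i0 + len - 1L)]
  }
  epoch_set(dat, events$label, fs, channel_names,
            onset_index = -start_off + 1L)
}
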