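#' Preprocessing configuration
#'
#' Parameters of the offline EEG pipeline, applied in this fixed order:
#' linear detrend, zero-padding, 50 Hz notch (4th-order IIR band-stop,
#' 2 Hz wide), 1–10 Hz band-pass (4th-order Butterworth), common average
#' reference, downsampling to `target_rate` (only when the source rate is
#' higher), epoching, baseline correction, and finally the window-of-interest
#' cut via [extract_interest_window()]. All filters are applied zero-phase
#' (forward-backward), preserving component latencies.
#'
#' @param notch_hz mains frequency (Hz).
#' @param notch_halfwidth half-width of the band-stop (Hz).
#' @param band band-pass edges (Hz).
#' @param target_rate common output rate (Hz).
#' @param epoch_window epoch window (s), half-open, relative to onset.
#' @param baseline_window baseline window (s) whose mean is subtracted per
#'   trial and channel.
#' @param interest_window analysis window (s) handed to the classifiers.
#' @param pad_seconds zero-padding added to each end before filtering and
#'   removed afterwards (suppresses edge transients).
#' @return an object of class `preproc_config`.
#' @export
preproc_config <- function(notch_hz = 50, notch_halfwidth = 1,
                           band = c(1, 10), target_rate = 250,
                           epoch_window = c(-0.2, 1.0),
                           baseline_window = c(-0.2, 0),
                           interest_window = c(0.2, 0.8),
                           pad_seconds = 1) {
  stopifnot(band[1] < band[2], length(epoch_window) == 2,
            epoch_window[1] < epoch_window[2])
  if (interest_window[1] < epoch_window[1] ||
      interest_window[2] > epoch_window[2])
    stop("interest window must lie inside the epoch window")
  structure(list(notch_hz = notch_hz, notch_halfwidth = notch_halfwidth,
                 band = band, target_rate = target_rate,
                 epoch_window = epoch_window,
                 baseline_window = baseline_window,
                 interest_window = interest_window,
                 pad_seconds = pad_seconds),
            class = "preproc_config")
}

#' Preprocess a continuous recording into baseline-corrected epochs
#'
#' Runs the full pipeline described in [preproc_config()] and cuts
#' stimulus-locked epochs of 1.2 s (by default: 200 ms pre-onset baseline
#' plus 1 s post-onset). Recordings at a rate above `target_rate` are
#' downsampled after the common average reference; with an integer rate
#' ratio this is plain decimation, safe because the band-pass has already
#' limited the signal to 10 Hz.
#'
#' @param recording a `subject_recording`.
#' @param cfg a [preproc_config()].
#' @return an [epoch_set()] at `target_rate` (or the recording rate if that
#'   is lower), baseline-corrected over `cfg$baseline_window`.
#' @export
preprocess_recording <- function(recording, cfg = preproc_config()) {
  stopifnot(inherits(recording, "subject_recording"),
            inherits(cfg, "preproc_config"))
  if (!all(is.finite(recording$samples)))
    stop("recording contains non-finite samples")
  fs <- recording$rate
  if (!fs %in% c(250, 500))
    warning(sprintf("unusual sampling rate %g Hz", fs))

  x <- detrend_linear(recording$samples)

  npad <- round(cfg$pad_seconds * fs)
  if (npad > 0) {
    z <- matrix(0, nrow(x), npad)
    x <- cbind(z, x, z)
  }
  nyq <- fs / 2
  notch <- signal::butter(2, c(cfg$notch_hz - cfg$notch_halfwidth,
                               cfg$notch_hz + cfg$notch_halfwidth) / nyq,
                          type = "stop")
  bp <- signal::butter(2, cfg$band / nyq, type = "pass")
  for (ch in seq_len(nrow(x))) {
    v <- signal::filtfilt(notch, x[ch, ])
    x[ch, ] <- signal::filtfilt(bp, v)
  }
  if (npad > 0) x <- x[, (npad + 1):(ncol(x) - npad), drop = FALSE]

  # common average reference: remove the instantaneous mean across channels
  x <- sweep(x, 2, colMeans(x))

  events <- recording$events
  if (fs > cfg$target_rate) {
    if (fs %% cfg$target_rate == 0) {
      d <- fs %/% cfg$target_rate
      x <- x[, seq(1, ncol(x), by = d), drop = FALSE]
    } else {
      d <- fs / cfg$target_rate
      x <- t(apply(x, 1, function(v)
        signal::resample(v, p = cfg$target_rate, q = fs)))
    }
    events$sample <- floor((events$sample - 1) / d) + 1L
    fs <- cfg$target_rate
  }

  ep <- cut_epochs(x, events, fs, cfg$epoch_window,
                   recording$montage$channel_names)
  baseline_correct(ep, cfg$baseline_window)
}

# Remove a per-channel linear trend fitted over the whole recording.
detrend_linear <- function(x) {
  n <- ncol(x)
  b <- cbind(1, seq_len(n))
  coefs <- solve(crossprod(b), crossprod(b, t(x)))
  x - t(b %*% coefs)
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and channel, the mean over the baseline window.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param epochs an [epoch_set()].
#' @param baseline_window window (s) relative to onset, half-open.
#' @return the corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, baseline_window = c(-0.2, 0)) {
  tt <- epoch_times(epochs)
  idx <- which(tt >= baseline_window[1] & tt < baseline_window[2])
  if (length(idx) == 0) stop("baseline window contains no samples")
  if (dim(epochs$data)[1] > 0) {
    bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
    epochs$data <- epochs$data - as.vector(bl)  # recycles over time dim
  }
  epochs
}

#' Cut the window of interest out of an epoch set
#'
#' Restricts each epoch to the analysis window (default 200–800 ms after
#' onset; 150 samples at 250 Hz), carrying labels through unchanged.
#'
#' @param epochs an [epoch_set()].
#' @param window half-open window (s) relative to onset; defaults to the
#'   `interest_window` of [preproc_config()].
#' @return an [epoch_set()] covering only the requested window.
#' @export
extract_interest_window <- function(epochs, window = c(0.2, 0.8)) {
  if (inherits(window, "preproc_config")) window <- window$interest_window
  tt <- epoch_times(epochs)
  eps <- 1e-9
  idx <- which(tt >= window[1] - eps & tt < window[2] - eps)
  if (length(idx) == 0)
    stop("interest window lies outside the epoch span")
  expected <- round((window[2] - window[1]) * epochs$rate)
  if (length(idx) != expected)
    stop("interest window extends beyond the epoch span")
  epoch_set(epochs$data[, , idx, drop = FALSE], epochs$labels, epochs$rate,
            epochs$channel_names,
            onset_index = epochs$onset_index - idx[1] + 1L)
}
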