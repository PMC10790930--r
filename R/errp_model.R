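#' Generative model of the error-related potential
#'
#' Parameterizes the single-trial evoked response added to error trials: a
#' negative frontocentral deflection around 200 ms (N200) followed by a
#' delayed positivity around 450 ms, each modelled as a Gaussian bump in
#' time. Both classes additionally share a small common evoked component so
#' that "true" trials are not pure noise; the expected error-minus-true
#' difference wave equals exactly the two-bump template.
#'
#' The morphology (latencies, a negativity then a positivity) is fixed by
#' the ErrP literature; single-trial amplitudes and the background
#' noise level are free parameters of the simulation, calibrated so the
#' downstream classifiers land in a plausible decoding range (see the
#' methods vignette).
#'
#' @param n200_latency,n200_width,n200_amplitude Gaussian bump of the
#'   negativity: center (s), standard deviation (s), amplitude (µV,
#'   negative).
#' @param p300_latency,p300_width,p300_amplitude same for the delayed
#'   positivity (µV, positive).
#' @param trial_latency_jitter_sd per-trial latency jitter (s) applied to
#'   both bumps jointly.
#' @param subject_amplitude_scale multiplier on both bump amplitudes,
#'   emulating between-subject amplitude differences.
#' @param noise_sd background noise standard deviation per channel (µV).
#' @param noise_spectrum `"one_over_f"` (spectrally shaped, EEG-like) or
#'   `"white"`.
#' @param shared_amplitude amplitude (µV) of the evoked component common to
#'   both classes (a positivity at 300 ms).
#' @param line_noise_amplitude amplitude (µV) of a common 50 Hz mains
#'   component added to every channel (exercises the notch filter).
#' @return an object of class `errp_model`.
#' @examples
#' m <- errp_model()                      # default effect
#' null <- errp_model(n200_amplitude = 0, p300_amplitude = 0)  # null model
#' @export
errp_model <- function(n200_latency = 0.2, n200_width = 0.045,
                       n200_amplitude = -6.5,
                       p300_latency = 0.45, p300_width = 0.09,
                       p300_amplitude = 8,
                       trial_latency_jitter_sd = 0.02,
                       subject_amplitude_scale = 1,
                       noise_sd = 6, noise_spectrum = c("one_over_f", "white"),
                       shared_amplitude = 2,
                       line_noise_amplitude = 1) {
  noise_spectrum <- match.arg(noise_spectrum)
  m <- structure(list(
    n200_latency = n200_latency, n200_width = n200_width,
    n200_amplitude = n200_amplitude,
    p300_latency = p300_latency, p300_width = p300_width,
    p300_amplitude = p300_amplitude,
    trial_latency_jitter_sd = trial_latency_jitter_sd,
    subject_amplitude_scale = subject_amplitude_scale,
    noise_sd = noise_sd, noise_spectrum = noise_spectrum,
    shared_amplitude = shared_amplitude,
    line_noise_amplitude = line_noise_amplitude), class = "errp_model")
  validate_errp_model(m)
  m
}

validate_errp_model <- function(m) {
  if (m$n200_width <= 0 || m$p300_width <= 0)
    stop("bump widths must be > 0")
  if (m$noise_sd < 0) stop("noise_sd must be >= 0")
  amps <- c(m$n200_amplitude, m$p300_amplitude, m$shared_amplitude)
  if (!all(is.finite(amps))) stop("amplitudes must be finite")
  if (m$trial_latency_jitter_sd < 0) stop("latency jitter sd must be >= 0")
  invisible(m)
}

#' @export
print.errp_model <- function(x, ...) {
  cat(sprintf(paste0("<errp_model: N200 %.1f uV @ %.0f ms, positivity %.1f uV",
                     " @ %.0f ms, noise %.1f uV (%s)>\n"),
              x$n200_amplitude, 1000 * x$n200_latency, x$p300_amplitude,
              1000 * x$p300_latency, x$noise_sd, x$noise_spectrum))
  invisible(x)
}

# Evoked templates sampled at `times` (s, relative to action onset).
# Returns a list with the error-specific component (difference wave) and the
# shared component; the jitter argument shifts both bumps.
errp_template <- function(model, times, jitter = 0) {
  bump <- function(amp, lat, wid)
    amp * exp(-((times - lat - jitter)^2) / (2 * wid^2))
  scale <- model$subject_amplitude_scale
  list(
    errp = scale * (bump(model$n200_amplitude, model$n200_latency,
                         model$n200_width) +
                    bump(model$p300_amplitude, model$p300_latency,
                         model$p300_width)),
    shared = bump(model$shared_amplitude, 0.3, 0.07)
  )
}
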