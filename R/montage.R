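#' EEG montage specifications
#'
#' A montage specification names the electrode set, its sampling rate and a
#' per-channel spatial weight in \[0, 1\] describing how strongly the
#' frontocentral error-related potential projects onto each electrode.
#' Three montages are built in:
#'
#' * `gel64` — 64-channel gel cap (extended 10-05 labels) at 250 Hz,
#' * `gel16` — a fixed 16-channel frontocentral subset of `gel64` at 250 Hz
#'   (the exact subset used in the original recordings is not published; this
#'   list is a documented assumption, see the methods vignette),
#' * `dry20` — 20-channel dry headset (10-20 labels) at 500 Hz.
#'
#' @param name one of `"gel64"`, `"gel16"`, `"dry20"`, or `"custom"`.
#' @param channel_names ordered electrode labels; required for `"custom"`.
#' @param sampling_rate sampling rate in Hz; required for `"custom"`.
#' @param frontocentral_weights optional numeric vector in \[0, 1\], one per
#'   channel; defaults to [frontocentral_weights()] of the channel names.
#' @return an object of class `montage_spec` with fields `name`,
#'   `channel_names`, `sampling_rate`, `frontocentral_weights`.
#' @examples
#' m <- montage("dry20")
#' m$sampling_rate
#' @export
montage <- function(name = c("gel64", "gel16", "dry20", "custom"),
                    channel_names = NULL, sampling_rate = NULL,
                    frontocentral_weights = NULL) {
  name <- match.arg(name)
  builtin <- list(
    gel64 = list(channels = .gel64_channels, rate = 250),
    gel16 = list(channels = .gel16_channels, rate = 250),
    dry20 = list(channels = .dry20_channels, rate = 500)
  )
  if (name == "custom") {
    if (is.null(channel_names) || is.null(sampling_rate))
      stop("custom montage requires `channel_names` and `sampling_rate`")
  } else {
    channel_names <- channel_names %||% builtin[[name]]$channels
    sampling_rate <- sampling_rate %||% builtin[[name]]$rate
  }
  w <- frontocentral_weights %||% frontocentral_weights(channel_names)
  spec <- structure(list(name = name, channel_names = channel_names,
                         sampling_rate = sampling_rate,
                         frontocentral_weights = w),
                    class = "montage_spec")
  validate_montage(spec)
  spec
}

validate_montage <- function(spec) {
  expected <- c(gel64 = 64L, gel16 = 16L, dry20 = 20L)
  n <- length(spec$channel_names)
  if (spec$name %in% names(expected) && n != expected[[spec$name]])
    stop(sprintf("montage '%s' must have %d channels, got %d",
                 spec$name, expected[[spec$name]], n))
  if (anyDuplicated(spec$channel_names))
    stop("duplicated channel names in montage")
  if (!is.numeric(spec$sampling_rate) || spec$sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  if (length(spec$frontocentral_weights) != n ||
      any(spec$frontocentral_weights < 0 | spec$frontocentral_weights > 1))
    stop("frontocentral_weights must be one value in [0, 1] per channel")
  if (spec$name != "custom" && !all(c("Fz", "Cz") %in% spec$channel_names))
    stop("built-in montages must contain Fz and Cz")
  invisible(spec)
}

#' @export
print.montage_spec <- function(x, ...) {
  cat(sprintf("<montage_spec '%s': %d channels @ %g Hz>\n",
              x$name, length(x$channel_names), x$sampling_rate))
  invisible(x)
}

#' Frontocentral topography weights for electrode labels
#'
#' Maps 10-20/10-05 electrode labels to a scalar in \[0, 1\] describing the
#' strength of the error-related potential at that site: maximal on the
#' frontocentral midline (Fz, FCz, Cz), decaying towards lateral, posterior
#' and prefrontal sites.
#'
#' @param channel_names character vector of electrode labels.
#' @return numeric vector in \[0, 1\], one weight per label.
#' @export
frontocentral_weights <- function(channel_names) {
  exact <- c(Fz = 1, FCz = 1, Cz = 1,
             FC1 = 0.9, FC2 = 0.9,
             F1 = 0.8, F2 = 0.8, C1 = 0.8, C2 = 0.8, FC3 = 0.8, FC4 = 0.8,
             CPz = 0.6, AFz = 0.6, F3 = 0.6, F4 = 0.6, C3 = 0.6, C4 = 0.6,
             CP1 = 0.5, CP2 = 0.5,
             FC5 = 0.4, FC6 = 0.4, F5 = 0.4, F6 = 0.4, C5 = 0.4, C6 = 0.4)
  vapply(channel_names, function(ch) {
    if (ch %in% names(exact)) return(exact[[ch]])
    if (grepl("^(F|C|AF)[0-9z]", ch)) return(0.25)
    if (grepl("^CP", ch)) return(0.25)
    0.1
  }, numeric(1), USE.NAMES = FALSE)
}

.gel64_channels <- c(
  "Fp1", "Fz", "F3", "F7", "FT9", "FC5", "FC1", "C3", "T7", "TP9", "CP5",
  "CP1", "Pz", "P3", "P7", "O1", "Oz", "O2", "P4", "P8", "TP10", "CP6",
  "CP2", "Cz", "C4", "T8", "FT10", "FC6", "FC2", "F4", "F8", "Fp2", "AF7",
  "AF3", "AFz", "F1", "F5", "FT7", "FC3", "C1", "C5", "TP7", "CP3", "P1",
  "P5", "PO7", "PO3", "POz", "PO4", "PO8", "P6", "P2", "CPz", "CP4", "TP8",
  "C6", "C2", "FC4", "FT8", "F6", "AF8", "AF4", "F2", "Iz")

.gel16_channels <- c(
  "Fz", "F1", "F2", "F3", "F4", "FC1", "FC2", "FC3", "FC4", "Cz", "C1",
  "C2", "C3", "C4", "CP1", "CP2")

.dry20_channels <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz", "C4", "T8",
  "P7", "P3", "Pz", "P4", "P8", "O1", "O2", "Oz")
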