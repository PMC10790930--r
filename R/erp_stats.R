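#' Grand-average waveforms and the difference wave
#'
#' Averages epochs over trials per condition, then over a named channel
#' group (e.g. Fz alone, or C3/Cz/C4), and returns the error, true and
#' error-minus-true difference traces.
#'
#' @param epochs an [epoch_set()].
#' @param channel_group character vector of channel names to average over.
#' @return an object of class `erp_waveform`: list with `times`, numeric
#'   traces `error`, `true`, `difference` (µV), per-condition trial counts
#'   `n_trials`, and `rate`.
#' @export
grand_average <- function(epochs, channel_group) {
  missing <- setdiff(channel_group, epochs$channel_names)
  if (length(missing) > 0)
    stop(sprintf("channel(s) not in epochs: %s",
                 paste(missing, collapse = ", ")))
  ci <- match(channel_group, epochs$channel_names)
  cond_trace <- function(cond) {
    sel <- epochs$labels == cond
    if (!any(sel)) return(rep(NA_real_, dim(epochs$data)[3]))
    sub <- epochs$data[sel, ci, , drop = FALSE]
    apply(sub, 3, mean)  # mean over trials then channels = overall mean
  }
  err <- cond_trace("error")
  tru <- cond_trace("true")
  structure(list(times = epoch_times(epochs), error = err, true = tru,
                 difference = err - tru,
                 n_trials = c(error = sum(epochs$labels == "error"),
                              true = sum(epochs$labels == "true")),
                 rate = epochs$rate, channel_group = channel_group),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("<erp_waveform over %s: %d error / %d true trials>\n",
              paste(x$channel_group, collapse = ","),
              x$n_trials["error"], x$n_trials["true"]))
  invisible(x)
}

#' Signal-to-noise ratio of the error-minus-true difference wave
#'
#' One value per subject and component interval: the amplitude of the
#' channel-group-averaged difference trace within the interval divided by
#' the standard deviation of that trace across the samples of the same
#' interval (a dimensionless ratio, invariant to rescaling the data).
#' Conventional intervals are 0.1–0.3 s for the N200 and 0.3–0.6 s for the
#' delayed positivity.
#'
#' @param epochs an [epoch_set()].
#' @param channel_group channels averaged before the contrast.
#' @param interval half-open interval (s) relative to onset.
#' @param amplitude `"mean"` (default; absolute value of the interval mean)
#'   or `"peak"` (largest absolute value in the interval).
#' @return a single numeric SNR value.
#' @export
erp_snr <- function(epochs, channel_group, interval = c(0.1, 0.3),
                    amplitude = c("mean", "peak")) {
  amplitude <- match.arg(amplitude)
  ga <- grand_average(epochs, channel_group)
  idx <- which(ga$times >= interval[1] - 1e-9 & ga$times < interval[2] - 1e-9)
  if (length(idx) < 3) stop("interval must contain at least 3 samples")
  d <- ga$difference[idx]
  noise <- stats::sd(d)
  amp <- if (amplitude == "mean") abs(mean(d)) else max(abs(d))
  if (noise == 0) {
    if (amp == 0) return(0)  # identically-zero difference trace
    stop("degenerate difference trace: zero variance within the interval")
  }
  amp / noise
}

#' Bootstrap mean with a percentile confidence interval
#'
#' Resamples the values with replacement `n_boot` times, takes the mean of
#' each resample, and summarizes the bootstrap distribution by its mean and
#' percentile quantiles at the Bonferroni-corrected levels
#' `alpha / (2 m)` and `1 - alpha / (2 m)`.
#'
#' @param values numeric vector (>= 2 values unless all equal).
#' @param n_boot number of bootstrap iterations (default 5000).
#' @param alpha nominal level of the confidence interval (default 0.05).
#' @param bonferroni_m number of simultaneous comparisons the interval is
#'   corrected for (default 1, i.e. no correction).
#' @param seed integer seed for the resampling.
#' @return an object of class `bootstrap_summary`: list with `mean`,
#'   `ci_low`, `ci_high`, `n_boot`, `alpha`, `bonferroni_m`, `n`.
#' @export
bootstrap_mean <- function(values, n_boot = 5000, alpha = 0.05,
                           bonferroni_m = 1, seed = 1) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty input")
  if (n_boot < 1) stop("n_boot must be >= 1")
  q <- c(alpha / (2 * bonferroni_m), 1 - alpha / (2 * bonferroni_m))
  boots <- with_seed(seed, {
    n <- length(values)
    vapply(seq_len(n_boot),
           function(i) mean(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  ci <- unname(stats::quantile(boots, q, type = 7))
  structure(list(mean = mean(boots), ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, alpha = alpha, bonferroni_m = bonferroni_m,
                 n = length(values)),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("<bootstrap mean %.4f [%.4f, %.4f] (n=%d, B=%d, m=%d)>\n",
              x$mean, x$ci_low, x$ci_high, x$n, x$n_boot, x$bonferroni_m))
  invisible(x)
}

#' Significance verdict from the overlap of two bootstrap CIs
#'
#' Disjoint confidence intervals indicate a strong difference (`"p<0.01"`);
#' overlapping intervals where neither mean lies inside the other's
#' interval indicate a moderate difference (`"p<0.05"`); anything else is
#' `"n.s."`. Symmetric in its arguments.
#'
#' @param a,b [bootstrap_mean()] summaries computed at the same alpha.
#' @return one of `"p<0.01"`, `"p<0.05"`, `"n.s."`.
#' @export
ci_overlap_verdict <- function(a, b) {
  stopifnot(inherits(a, "bootstrap_summary"), inherits(b, "bootstrap_summary"))
  if (!isTRUE(all.equal(a$alpha, b$alpha)))
    stop("summaries must use the same alpha")
  disjoint <- a$ci_high < b$ci_low || b$ci_high < a$ci_low
  if (disjoint) return("p<0.01")
  a_in_b <- a$mean >= b$ci_low && a$mean <= b$ci_high
  b_in_a <- b$mean >= a$ci_low && b$mean <= a$ci_high
  if (!a_in_b && !b_in_a) "p<0.05" else "n.s."
}
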