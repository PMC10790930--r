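#' Time-domain feature extraction
#'
#' Computes five statistics per channel and trial over the window of
#' interest: mean amplitude, skewness, kurtosis, standard deviation, and
#' peak-to-peak amplitude. Columns are ordered channel-major (all five
#' statistics of channel 1, then channel 2, ...). Skewness and kurtosis use
#' the classical biased moment estimators (e1071 type 1); the standard
#' deviation uses the sample (n-1) convention. For a constant channel the
#' moment ratios are undefined and are set to 0 with a warning.
#'
#' @param epochs an [epoch_set()], already cut to the window of interest.
#' @return an object of class `feature_matrix`: list with `x` (trials x
#'   5*channels numeric matrix) and `labels`.
#' @export
extract_features <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[1] == 0) stop("empty epoch set")
  nt <- d[1]; nc <- d[2]; ns <- d[3]
  # rows = (trial, channel) pairs, channel fastest
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = nt * nc, byrow = TRUE)
  mu <- rowMeans(flat)
  ctr <- flat - mu
  m2 <- rowMeans(ctr^2)
  sdv <- sqrt(rowSums(ctr^2) / (ns - 1))
  skew <- ifelse(m2 > 0, rowMeans(ctr^3) / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, rowMeans(ctr^4) / m2^2 - 3, 0)
  if (any(m2 == 0))
    warning(sprintf("%d constant channel-trial(s): skewness/kurtosis set to 0",
                    sum(m2 == 0)))
  p2p <- apply(flat, 1, max) - apply(flat, 1, min)
  feats <- cbind(mean = mu, skewness = skew, kurtosis = kurt, sd = sdv,
                 ptp = p2p)
  # rows are channel-fastest within trial; fold into trials x (5*channels)
  x <- matrix(0, nt, 5L * nc)
  for (s in 1:5)
    x[, seq(s, by = 5, length.out = nc)] <-
      matrix(feats[, s], nt, nc, byrow = TRUE)
  colnames(x) <- as.vector(t(outer(epochs$channel_names,
                                   colnames(feats), paste, sep = "_")))
  structure(list(x = x, labels = epochs$labels), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d trials x %d features>\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

# ROC-AUC with the error class as positive; higher score = more error-like.
roc_auc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(response = as.character(labels),
                                 predictor = as.numeric(scores),
                                 levels = c("true", "error"),
                                 direction = "<", quiet = TRUE)))
}
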