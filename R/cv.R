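#' Repeated stratified cross-validated evaluation of a classifier family
#'
#' Outer repeated stratified k-fold (default 5 splits x 10 repeats = 50
#' folds). Every part of each pipeline — feature standardization, PCA, the
#' inner grid search, xDAWN filters and prototypes, CNN weights — is fitted
#' strictly inside the training folds. Per fold the train and test ROC-AUC
#' are recorded and summarized with [bootstrap_mean()] (5,000 iterations by
#' default), optionally Bonferroni-corrected across the comparisons of a
#' larger report.
#'
#' @param epochs an [epoch_set()] cut to the window of interest.
#' @param model one of `"lda"`, `"svc"`, `"riemann"`, `"cnn"`.
#' @param splits,repeats outer protocol (5 and 10 reproduce the full
#'   protocol; smaller values scale the experiment down).
#' @param seed integer seed; identical seeds give identical scores for the
#'   deterministic families and reproducible scores for the CNN.
#' @param cnn_cfg optional [cnn_config()] override for `model = "cnn"`.
#' @param n_boot,bonferroni_m bootstrap summary parameters.
#' @return an object of class `cv_scores`: `model`, `train_scores`,
#'   `test_scores` (length `splits * repeats`), and `train_summary` /
#'   `test_summary` ([bootstrap_mean()] objects).
#' @export
evaluate_cv <- function(epochs, model = c("lda", "svc", "riemann", "cnn"),
                        splits = 5, repeats = 10, seed = 1, cnn_cfg = NULL,
                        n_boot = 5000, bonferroni_m = 1) {
  model <- match.arg(model)
  stopifnot(inherits(epochs, "epoch_set"))
  y <- epochs$labels
  if (min(table(y)) < splits) stop("fewer trials per class than folds")
  feats <- if (model %in% c("lda", "svc")) extract_features(epochs) else NULL

  train_scores <- numeric(0); test_scores <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- with_seed(derive_seed(seed, r), stratified_folds(y, splits))
    for (f in seq_len(splits)) {
      tr <- which(fold != f); te <- which(fold == f)
      fit_seed <- derive_seed(seed, r * 1000 + f)
      sc <- fit_and_score(epochs, feats, model, tr, te, fit_seed, cnn_cfg)
      train_scores <- c(train_scores, sc$train)
      test_scores <- c(test_scores, sc$test)
    }
  }
  structure(list(model = model, splits = splits, repeats = repeats,
                 train_scores = train_scores, test_scores = test_scores,
                 train_summary = bootstrap_mean(train_scores, n_boot,
                                                bonferroni_m = bonferroni_m,
                                                seed = derive_seed(seed, 777)),
                 test_summary = bootstrap_mean(test_scores, n_boot,
                                               bonferroni_m = bonferroni_m,
                                               seed = derive_seed(seed, 778))),
            class = "cv_scores")
}

fit_and_score <- function(epochs, feats, model, tr, te, seed, cnn_cfg) {
  if (model %in% c("lda", "svc")) {
    f_tr <- list(x = feats$x[tr, , drop = FALSE], labels = feats$labels[tr])
    f_te <- list(x = feats$x[te, , drop = FALSE], labels = feats$labels[te])
    class(f_tr) <- class(f_te) <- "feature_matrix"
    fit <- fit_linear(f_tr, model, seed = seed)
    list(train = roc_auc(f_tr$labels, predict_score(fit, f_tr)),
         test = roc_auc(f_te$labels, predict_score(fit, f_te)))
  } else {
    e_tr <- subset_epochs(epochs, tr)
    e_te <- subset_epochs(epochs, te)
    fit <- if (model == "riemann") fit_riemann(e_tr, seed = seed)
           else fit_cnn(e_tr, cfg = cnn_cfg, seed = seed)
    list(train = roc_auc(e_tr$labels, predict_score(fit, e_tr)),
         test = roc_auc(e_te$labels, predict_score(fit, e_te)))
  }
}

#' Subset an epoch set by trial index
#'
#' @param epochs an [epoch_set()].
#' @param idx integer trial indices to keep.
#' @return the reduced [epoch_set()].
#' @export
subset_epochs <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$labels[idx],
            epochs$rate, epochs$channel_names, epochs$onset_index)
}

#' @export
print.cv_scores <- function(x, ...) {
  cat(sprintf("<cv_scores %s: %d x %d folds>\n", x$model, x$splits, x$repeats))
  cat("  train: "); print(x$train_summary)
  cat("  test:  "); print(x$test_summary)
  invisible(x)
}

#' Calibrate the online BCI decoder
#'
#' Splits the calibration epochs stratified into 70% training, 15%
#' validation and 15% test, trains the CNN with the validation set driving
#' the plateau schedule and weight selection, and reports the held-out test
#' ROC-AUC as the decoder's quality. The returned object predicts per-trial
#' error probabilities for new epochs via [predict_score()].
#'
#' @param epochs calibration [epoch_set()] (interest window), typically 400
#'   trials at 50% error prevalence.
#' @param cfg optional [cnn_config()].
#' @param seed integer seed.
#' @return an object of class `bci_decoder`: list with `model` (the
#'   [fit_cnn()] result), `test_auc`, `split` (index vectors), and
#'   `threshold` (0.5).
#' @export
calibrate_bci <- function(epochs, cfg = NULL, seed = 1) {
  y <- epochs$labels
  if (min(table(y)) < 7) stop("too few trials per class for a 70/15/15 split")
  sp <- with_seed(derive_seed(seed, 1), {
    idx <- lapply(split(seq_along(y), y), function(i) i[sample.int(length(i))])
    pick <- function(part) unlist(lapply(idx, function(i) {
      n <- length(i); n_tr <- round(0.7 * n); n_va <- round(0.15 * n)
      switch(part, train = i[seq_len(n_tr)],
             val = i[n_tr + seq_len(n_va)],
             test = i[(n_tr + n_va + 1):n])
    }), use.names = FALSE)
    list(train = pick("train"), val = pick("val"), test = pick("test"))
  })
  fit <- fit_cnn(subset_epochs(epochs, sp$train), cfg = cfg,
                 seed = derive_seed(seed, 2),
                 validation = subset_epochs(epochs, sp$val))
  te <- subset_epochs(epochs, sp$test)
  auc <- roc_auc(te$labels, predict_score(fit, te))
  structure(list(model = fit, test_auc = auc, split = sp, threshold = 0.5),
            class = "bci_decoder")
}

#' @export
predict_score.bci_decoder <- function(object, newdata, ...)
  predict_score(object$model, newdata, ...)

#' @export
print.bci_decoder <- function(x, ...) {
  cat(sprintf("<bci_decoder: test ROC-AUC %.3f (%d/%d/%d split)>\n",
              x$test_auc, length(x$split$train), length(x$split$val),
              length(x$split$test)))
  invisible(x)
}
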