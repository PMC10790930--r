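#' Fit the feature-based linear classifiers (LDA or RBF-SVC)
#'
#' Pipeline: standardize each feature (mean 0, unit variance, fitted on the
#' training data only), project onto the minimal set of leading principal
#' components whose cumulative variance reaches 95%, then fit the
#' classifier with hyperparameters tuned by a stratified 5-fold inner grid
#' search maximizing ROC-AUC:
#'
#' * `lda` — the covariance estimator (`moment` or `mle`) is tuned; this is
#'   the estimator-level knob MASS exposes (numerically equivalent solver
#'   variants are not distinguished in R).
#' * `svc` — RBF kernel; cost `C` over `10^(-2..3)` and kernel coefficient
#'   `gamma` over `10^(-4..1)`, both log-spaced.
#'
#' @param features a [extract_features()] result (or a list with `x` and
#'   `labels`).
#' @param model `"lda"` or `"svc"`.
#' @param seed integer seed controlling the inner-fold assignment.
#' @param inner_folds folds of the inner grid search (default 5).
#' @return an object of class `linear_pipeline` with a [predict_score()]
#'   method.
#' @export
fit_linear <- function(features, model = c("lda", "svc"), seed = 1,
                       inner_folds = 5) {
  model <- match.arg(model)
  x <- features$x
  y <- as.character(features$labels)
  if (length(unique(y)) < 2) stop("training data contains a single class")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= 0.95)[1]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  xp <- xs %*% rot

  grid <- switch(model,
    lda = data.frame(method = c("moment", "mle"), stringsAsFactors = FALSE),
    svc = expand.grid(cost = 10^(-2:3), gamma = 10^(-4:1)))

  fold <- with_seed(seed, stratified_folds(y, inner_folds))
  cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(seq_len(inner_folds), function(f) {
      tr <- fold != f; te <- !tr
      if (length(unique(y[te])) < 2) return(NA_real_)
      fit <- fit_inner(xp[tr, , drop = FALSE], y[tr], model, grid[g, , drop = FALSE])
      roc_auc(y[te], score_inner(fit, xp[te, , drop = FALSE], model))
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- grid[which.max(cv_auc), , drop = FALSE]
  fit <- fit_inner(xp, y, model, best)

  structure(list(model = model, center = ctr, scale = scl, rotation = rot,
                 n_components = k, best = best, cv_auc = max(cv_auc),
                 fit = fit),
            class = "linear_pipeline")
}

fit_inner <- function(x, y, model, pars) {
  if (model == "lda") {
    MASS::lda(x, grouping = factor(y, levels = c("true", "error")),
              method = pars$method)
  } else {
    e1071::svm(x, factor(y, levels = c("true", "error")), type = "C-classification",
               kernel = "radial", cost = pars$cost, gamma = pars$gamma,
               scale = FALSE)
  }
}

score_inner <- function(fit, x, model) {
  if (model == "lda") {
    stats::predict(fit, x)$posterior[, "error"]
  } else {
    dv <- attr(stats::predict(fit, x, decision.values = TRUE),
               "decision.values")
    # e1071 names the column "<first>/<second>"; positive values vote for
    # the first label. Orient so that higher = error.
    if (grepl("^error/", colnames(dv)[1])) dv[, 1] else -dv[, 1]
  }
}

#' Classifier score for new data
#'
#' Returns, per trial, a score that is larger for trials more likely to be
#' an error observation (for probabilistic models this is the posterior
#' probability of the error class).
#'
#' @param object a fitted classifier pipeline.
#' @param newdata matching input (a `feature_matrix` for linear pipelines,
#'   an [epoch_set()] for the Riemannian and CNN models).
#' @param ... unused.
#' @return numeric vector of scores, one per trial.
#' @export
predict_score <- function(object, newdata, ...) UseMethod("predict_score")

#' @export
predict_score.linear_pipeline <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else newdata
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  xp <- xs %*% object$rotation
  unname(score_inner(object$fit, xp, object$model))
}

#' @export
print.linear_pipeline <- function(x, ...) {
  cat(sprintf("<linear_pipeline %s: %d PCs, tuned %s>\n", x$model,
              x$n_components,
              paste(names(x$best), unlist(x$best), sep = "=", collapse = ", ")))
  invisible(x)
}
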