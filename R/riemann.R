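#' Riemannian tangent-space classifier for event-related potentials
#'
#' Builds xDAWN-augmented special covariance matrices per trial, maps them
#' into the tangent space of the symmetric-positive-definite manifold at
#' the geometric mean of the training covariances, and classifies the
#' resulting Euclidean vectors with an LDA (default estimator, no
#' hyperparameter search).
#'
#' Per class, the xDAWN spatial filters maximize the ratio of evoked
#' (class-average) power to total single-trial power; each trial `X` is
#' augmented with the filtered class prototypes `P_k` to the super-trial
#' `[W1'P1; W2'P2; W1'X; W2'X]` whose covariance (plus a small shrinkage
#' ridge guaranteeing positive definiteness on short windows) is the trial's
#' manifold representation.
#'
#' @param epochs an [epoch_set()] cut to the window of interest.
#' @param seed integer seed (kept for interface uniformity; the fit is
#'   deterministic).
#' @param nfilter xDAWN spatial filters per class (default 4).
#' @param shrinkage covariance shrinkage coefficient towards the scaled
#'   identity, in \[0, 1\] (default 0.05).
#' @return an object of class `riemann_pipeline` with a [predict_score()]
#'   method.
#' @export
fit_riemann <- function(epochs, seed = 1, nfilter = 4, shrinkage = 0.05) {
  stopifnot(inherits(epochs, "epoch_set"))
  y <- epochs$labels
  if (length(unique(y)) < 2) stop("training data contains a single class")
  d <- dim(epochs$data)
  classes <- c("true", "error")

  protos <- lapply(classes, function(cl)
    apply(epochs$data[y == cl, , , drop = FALSE], c(2, 3), mean))
  names(protos) <- classes

  # total covariance over all single trials
  r_tot <- matrix(0, d[2], d[2])
  for (i in seq_len(d[1])) {
    xi <- epochs$data[i, , ]
    xi <- xi - rowMeans(xi)
    r_tot <- r_tot + tcrossprod(xi)
  }
  r_tot <- r_tot / (d[1] * (d[3] - 1))
  r_tot <- r_tot + 1e-10 * mean(diag(r_tot)) * diag(d[2])

  filters <- lapply(classes, function(cl) {
    p <- protos[[cl]] - rowMeans(protos[[cl]])
    s_ev <- tcrossprod(p) / (d[3] - 1)
    xdawn_filters(s_ev, r_tot, nfilter)
  })
  names(filters) <- classes

  covs <- augmented_covs(epochs$data, protos, filters, shrinkage)
  gm <- spd_geometric_mean(covs)
  gm_isqrt <- sym_powm(gm, -0.5)
  tv <- t(vapply(covs, function(c) tangent_vec(c, gm_isqrt),
                 numeric(ncol(gm) * (ncol(gm) + 1) / 2)))

  # the 136-dim tangent space routinely exceeds the training-trial count,
  # so LDA's collinearity warning is structural here, not a data problem
  fit <- withCallingHandlers(
    MASS::lda(tv, grouping = factor(y, levels = classes)),
    warning = function(w) {
      if (grepl("collinear", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(protos = protos, filters = filters, shrinkage = shrinkage,
                 gm_isqrt = gm_isqrt, fit = fit, nfilter = nfilter),
            class = "riemann_pipeline")
}

#' @export
predict_score.riemann_pipeline <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "epoch_set"))
  covs <- augmented_covs(newdata$data, object$protos, object$filters,
                         object$shrinkage)
  tv <- t(vapply(covs, function(c) tangent_vec(c, object$gm_isqrt),
                 numeric(nrow(object$gm_isqrt) * (nrow(object$gm_isqrt) + 1) / 2)))
  unname(stats::predict(object$fit, tv)$posterior[, "error"])
}

#' @export
print.riemann_pipeline <- function(x, ...) {
  cat(sprintf("<riemann_pipeline: %d xDAWN filters/class, %dx%d covariances>\n",
              x$nfilter, nrow(x$gm_isqrt), nrow(x$gm_isqrt)))
  invisible(x)
}

# Generalized eigenvectors maximizing w' s_ev w / w' r_tot w.
xdawn_filters <- function(s_ev, r_tot, nfilter) {
  l <- chol(r_tot)
  li <- backsolve(l, diag(nrow(l)), transpose = TRUE)  # inv(L'), lower
  m <- li %*% s_ev %*% t(li)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE)
  w <- t(li) %*% ev$vectors[, seq_len(nfilter), drop = FALSE]
  w
}

augmented_covs <- function(data, protos, filters, shrinkage) {
  nt <- dim(data)[1]
  p_aug <- rbind(t(filters[["true"]]) %*% protos[["true"]],
                 t(filters[["error"]]) %*% protos[["error"]])
  w_all <- cbind(filters[["true"]], filters[["error"]])
  n_time <- dim(data)[3]
  lapply(seq_len(nt), function(i) {
    xf <- t(w_all) %*% data[i, , ]
    a <- rbind(p_aug, xf)
    c <- tcrossprod(a) / (n_time - 1)
    (1 - shrinkage) * c + shrinkage * mean(diag(c)) * diag(nrow(c))
  })
}

# Symmetric matrix power via eigendecomposition.
sym_powm <- function(m, p) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  e$vectors %*% (vals^p * t(e$vectors))
}

sym_logm <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% (log(pmax(e$values, 1e-12)) * t(e$vectors))
}

sym_expm <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

#' Geometric (Karcher) mean of symmetric positive-definite matrices
#'
#' Fixed-point iteration under the affine-invariant metric: repeatedly maps
#' the matrices to the tangent space at the current estimate, averages, and
#' maps back, until the tangent-space mean vanishes.
#'
#' @param covs list of SPD matrices of equal dimension.
#' @param tol convergence tolerance on the Frobenius norm of the
#'   tangent-space mean.
#' @param max_iter iteration cap.
#' @return the SPD geometric mean matrix.
#' @export
spd_geometric_mean <- function(covs, tol = 1e-8, max_iter = 50) {
  m <- Reduce(`+`, covs) / length(covs)
  for (it in seq_len(max_iter)) {
    m_sqrt <- sym_powm(m, 0.5)
    m_isqrt <- sym_powm(m, -0.5)
    tan_mean <- Reduce(`+`, lapply(covs, function(c)
      sym_logm(m_isqrt %*% c %*% m_isqrt))) / length(covs)
    if (sqrt(sum(tan_mean^2)) < tol) break
    m <- m_sqrt %*% sym_expm(tan_mean) %*% m_sqrt
    m <- (m + t(m)) / 2
  }
  m
}

# Tangent-space coordinates of SPD matrix c at reference with inverse
# square root gm_isqrt: upper triangle of log(gm^-1/2 c gm^-1/2), with
# off-diagonal entries scaled by sqrt(2) to preserve the norm.
tangent_vec <- function(c, gm_isqrt) {
  s <- sym_logm(gm_isqrt %*% c %*% gm_isqrt)
  ut <- upper.tri(s)
  c(diag(s), sqrt(2) * s[ut])
}
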