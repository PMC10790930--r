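#' Configuration of the compact convolutional EEG classifier
#'
#' The architecture follows the compact depthwise/separable design
#' established for EEG decoding: (1) a temporal convolution with `f1`
#' kernels of length `kernel_length` (= sampling rate / 2, i.e. learned
#' band-pass filters), batch-normalized, then a depthwise spatial
#' convolution across channels with multiplier `depth_mult` (max-norm 1),
#' batch norm, ELU, average pooling by `pool1` and dropout; (2) a separable
#' convolution (depthwise temporal kernel of length `sep_kernel_length`,
#' then pointwise mixing to `f2` maps), batch norm, ELU, average pooling by
#' `pool2`, dropout; (3) a dense softmax over the two classes (max-norm
#' 0.25). Trained with categorical cross-entropy and Adam; the learning
#' rate is divided by `plateau_factor` when the validation loss fails to
#' improve for `plateau_patience` consecutive epochs.
#'
#' @param n_channels EEG channels of the input.
#' @param n_samples time samples of the input window (150 for the standard
#'   0.2–0.8 s window at 250 Hz).
#' @param kernel_length temporal kernel length; 125 at 250 Hz.
#' @param f1 temporal filters. @param depth_mult spatial filters per
#'   temporal filter. @param f2 pointwise filters.
#' @param sep_kernel_length depthwise kernel length of block 2.
#' @param pool1,pool2 average-pooling lengths.
#' @param dropout dropout rate.
#' @param lr initial Adam learning rate. @param batch mini-batch size.
#' @param epochs maximum training epochs.
#' @param plateau_factor,plateau_patience learning-rate plateau schedule.
#' @param val_fraction fraction of the training set held out as validation
#'   when no explicit validation set is given.
#' @param early_stop_patience epochs without validation improvement before
#'   training stops early (`Inf` disables early stopping).
#' @return an object of class `cnn_config`.
#' @export
cnn_config <- function(n_channels, n_samples = 150, kernel_length = 125,
                       f1 = 8, depth_mult = 2, f2 = 16,
                       sep_kernel_length = 16, pool1 = 4, pool2 = 8,
                       dropout = 0.5, lr = 0.01, batch = 16, epochs = 300,
                       plateau_factor = 10, plateau_patience = 5,
                       val_fraction = 0.15, early_stop_patience = Inf) {
  t1 <- n_samples %/% pool1
  t2 <- t1 %/% pool2
  if (t2 < 1) stop("input window too short for the pooling chain")
  structure(list(n_channels = n_channels, n_samples = n_samples,
                 kernel_length = kernel_length, f1 = f1,
                 depth_mult = depth_mult, f2 = f2,
                 sep_kernel_length = sep_kernel_length,
                 pool1 = pool1, pool2 = pool2, dropout = dropout, lr = lr,
                 batch = batch, epochs = epochs,
                 plateau_factor = plateau_factor,
                 plateau_patience = plateau_patience,
                 val_fraction = val_fraction,
                 early_stop_patience = early_stop_patience,
                 bn_momentum = 0.99, bn_eps = 1e-3,
                 t1 = t1, t2 = t2), class = "cnn_config")
}

#' Trainable parameter count of the CNN
#'
#' Sums the trainable parameters layer by layer (convolution kernels
#' without biases, batch-norm scale and shift, dense weights and bias).
#'
#' @param cfg a [cnn_config()].
#' @return integer parameter count.
#' @export
cnn_param_count <- function(cfg) {
  m <- cfg$f1 * cfg$depth_mult
  as.integer(
    cfg$kernel_length * cfg$f1 +            # temporal conv
    2 * cfg$f1 +                            # BN 1
    cfg$n_channels * m +                    # depthwise spatial conv
    2 * m +                                 # BN 2
    cfg$sep_kernel_length * m +             # separable: depthwise temporal
    m * cfg$f2 +                            # separable: pointwise
    2 * cfg$f2 +                            # BN 3
    cfg$f2 * cfg$t2 * 2 + 2)                # dense softmax
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

cnn_init <- function(cfg) {
  m <- cfg$f1 * cfg$depth_mult
  list(
    k1 = glorot(cfg$kernel_length, cfg$kernel_length * cfg$f1,
                c(cfg$kernel_length, cfg$f1)),
    g1 = rep(1, cfg$f1), b1 = rep(0, cfg$f1),
    wd = glorot(cfg$n_channels, cfg$n_channels * cfg$depth_mult,
                c(cfg$n_channels, m)),
    g2 = rep(1, m), b2 = rep(0, m),
    ks = glorot(cfg$sep_kernel_length, cfg$sep_kernel_length,
                c(cfg$sep_kernel_length, m)),
    wp = glorot(m, cfg$f2, c(m, cfg$f2)),
    g3 = rep(1, cfg$f2), b3 = rep(0, cfg$f2),
    wo = glorot(cfg$f2 * cfg$t2, 2, c(cfg$f2 * cfg$t2, 2)),
    bo = rep(0, 2))
}

# Band structure of the stacked temporal-convolution matrix: linear
# indices of every in-band entry together with the (tap, filter) index of
# the kernel element living there; precomputed once per configuration so
# that assembling the matrix and accumulating its gradient are single
# vectorized operations.
conv1_band_index <- function(cfg) {
  t_len <- cfg$n_samples; k_len <- cfg$kernel_length
  pad <- (k_len - 1) %/% 2
  nrows <- cfg$f1 * t_len
  lin <- vector("list", k_len * cfg$f1)
  par_idx <- vector("list", k_len * cfg$f1)
  slot <- 0L
  for (j in seq_len(k_len)) {
    t_idx <- seq_len(t_len)
    u_idx <- t_idx + j - pad - 1L
    ok <- u_idx >= 1L & u_idx <= t_len
    t_idx <- t_idx[ok]; u_idx <- u_idx[ok]
    for (f in seq_len(cfg$f1)) {
      slot <- slot + 1L
      lin[[slot]] <- (f - 1L) * t_len + t_idx + (u_idx - 1L) * nrows
      par_idx[[slot]] <- rep.int(j + (f - 1L) * k_len, length(t_idx))
    }
  }
  par_idx <- unlist(par_idx)
  list(lin = unlist(lin), par_idx = par_idx, n_par = k_len * cfg$f1,
       complete = length(unique(par_idx)) == k_len * cfg$f1)
}

conv1_band_matrix <- function(k1, cfg, idx) {
  kb <- matrix(0, cfg$f1 * cfg$n_samples, cfg$n_samples)
  kb[idx$lin] <- k1[idx$par_idx]
  kb
}

elu <- function(x) {
  neg <- x < 0
  x[neg] <- expm1(x[neg])
  x
}
# gradient from pre-activation x and activation y = elu(x)
elu_grad <- function(x, y) {
  g <- y + 1
  g[x > 0] <- 1
  g
}

# Batch norm over row groups (used for the temporal-convolution output,
# whose feature maps are stacked row blocks): `gmap` maps each row to its
# group; statistics pool the whole (time, channel, batch) extent.
bn_row_fwd <- function(x, gmap, n_per_group, gamma, beta, eps, training,
                       run_mean, run_var, momentum) {
  if (training) {
    mu <- row_group_sums(x, length(gamma)) / n_per_group
    v <- row_group_sums(x^2, length(gamma)) / n_per_group - mu^2
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- (x - mu[gmap]) * inv_sd[gmap]
  y <- xhat * gamma[gmap] + beta[gmap]
  list(y = y, xhat = xhat, inv_sd = inv_sd, run_mean = run_mean,
       run_var = run_var)
}

bn_row_bwd <- function(dy, cache, gmap, n_per_group, gamma) {
  k <- length(gamma)
  dgamma <- row_group_sums(dy * cache$xhat, k)
  dbeta <- row_group_sums(dy, k)
  dxhat <- dy * gamma[gmap]
  s1 <- row_group_sums(dxhat, k) / n_per_group
  s2 <- row_group_sums(dxhat * cache$xhat, k) / n_per_group
  dx <- (dxhat - s1[gmap] - cache$xhat * s2[gmap]) * cache$inv_sd[gmap]
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Sums of a (k*t) x n matrix over its k contiguous row blocks.
row_group_sums <- function(x, k) {
  t_len <- nrow(x) %/% k
  dim(x) <- c(t_len, k, ncol(x))
  rowSums(colSums(x))
}

bn_fwd <- function(x, gamma, beta, eps, training, run_mean, run_var,
                   momentum) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, inv_sd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, xhat = xhat, inv_sd = inv_sd, run_mean = run_mean,
       run_var = run_var)
}

bn_bwd <- function(dy, cache, gamma) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2, s1 / n) - sweep(cache$xhat, 2, s2 / n, "*")
  dx <- sweep(dx, 2, cache$inv_sd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Forward pass. x: array (batch, channels, time). Returns class
# probabilities (2 x batch, rows ordered true/error) and, in training mode,
# every intermediate needed by cnn_backward. Internal layout: time-major
# matrices whose row order is (time, batch), so that reshapes between the
# convolutional and channel views are plain `dim<-` reinterpretations.
cnn_forward <- function(par, cfg, bn_state, x, training = FALSE,
                        band_idx = NULL, momentum = cfg$bn_momentum,
                        use_dropout = training) {
  b <- dim(x)[1]; nc <- cfg$n_channels; t_len <- cfg$n_samples
  f1 <- cfg$f1; d_m <- cfg$depth_mult; m <- f1 * d_m; f2 <- cfg$f2
  t1 <- cfg$t1; t2 <- cfg$t2
  cb <- nc * b
  band_idx <- band_idx %||% conv1_band_index(cfg)

  # columns ordered batch-fastest within channel: (t, b, c)
  xmat <- matrix(aperm(x, c(3, 1, 2)), t_len, cb)
  kb <- conv1_band_matrix(par$k1, cfg, band_idx)
  y1 <- kb %*% xmat                                   # (f1*t) x (b*c)

  gmap1 <- rep(seq_len(f1), each = t_len)
  bn1 <- bn_row_fwd(y1, gmap1, t_len * cb, par$g1, par$b1, cfg$bn_eps,
                    training, bn_state$m1, bn_state$v1, momentum)

  z <- matrix(0, t_len * b, m)
  dw_in <- vector("list", f1)
  for (f in seq_len(f1)) {
    yf <- bn1$y[((f - 1L) * t_len + 1L):(f * t_len), , drop = FALSE]
    dim(yf) <- c(t_len * b, nc)                       # rows (t, b), cols c
    dw_in[[f]] <- yf
    cols <- (f - 1L) * d_m + seq_len(d_m)
    z[, cols] <- yf %*% par$wd[, cols, drop = FALSE]
  }
  bn2 <- bn_fwd(z, par$g2, par$b2, cfg$bn_eps, training,
                bn_state$m2, bn_state$v2, momentum)
  e1 <- elu(bn2$y)

  arr <- e1
  dim(arr) <- c(t_len, b, m)
  p1in <- arr[seq_len(cfg$pool1 * t1), , , drop = FALSE]
  dim(p1in) <- c(cfg$pool1, t1, b, m)
  pool1 <- colMeans(p1in)                              # (t1, b, m)

  if (use_dropout) {
    mask1 <- array(stats::rbinom(t1 * b * m, 1, 1 - cfg$dropout) /
                   (1 - cfg$dropout), c(t1, b, m))
    d1 <- pool1 * mask1
  } else { mask1 <- NULL; d1 <- pool1 }

  pad_l <- (cfg$sep_kernel_length - 1) %/% 2
  u <- array(0, c(t1, b, m))
  for (j in seq_len(cfg$sep_kernel_length)) {
    src <- seq_len(t1) + j - pad_l - 1L
    ok <- src >= 1L & src <= t1
    if (!any(ok)) next
    u[ok, , ] <- u[ok, , ] +
      d1[src[ok], , , drop = FALSE] *
      rep(par$ks[j, ], each = sum(ok) * b)
  }
  umat <- matrix(u, t1 * b, m)
  v <- umat %*% par$wp                                  # (t1*b, f2)
  bn3 <- bn_fwd(v, par$g3, par$b3, cfg$bn_eps, training,
                bn_state$m3, bn_state$v3, momentum)
  e2 <- elu(bn3$y)

  arr2 <- array(e2, c(t1, b, f2))
  p2in <- arr2[seq_len(cfg$pool2 * t2), , , drop = FALSE]
  dim(p2in) <- c(cfg$pool2, t2, b, f2)
  pool2 <- colMeans(p2in)                              # (t2, b, f2)

  if (use_dropout) {
    mask2 <- array(stats::rbinom(t2 * b * f2, 1, 1 - cfg$dropout) /
                   (1 - cfg$dropout), c(t2, b, f2))
    d2 <- pool2 * mask2
  } else { mask2 <- NULL; d2 <- pool2 }

  fl <- matrix(aperm(d2, c(1, 3, 2)), t2 * f2, b)
  logits <- crossprod(par$wo, fl) + par$bo             # 2 x b
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  probs <- sweep(ex, 2, colSums(ex), "/")
  rownames(probs) <- c("true", "error")

  out <- list(probs = probs,
              bn_state = list(m1 = bn1$run_mean, v1 = bn1$run_var,
                              m2 = bn2$run_mean, v2 = bn2$run_var,
                              m3 = bn3$run_mean, v3 = bn3$run_var))
  if (training)
    out$cache <- list(xmat = xmat, bn1 = bn1, bn2 = bn2, bn3 = bn3,
                      dw_in = dw_in, z = z, e1_pre = bn2$y, e1 = e1,
                      d1 = d1, mask1 = mask1, u = u, umat = umat,
                      e2_pre = bn3$y, e2 = e2, mask2 = mask2, fl = fl,
                      b = b)
  out
}

cnn_backward <- function(par, cfg, fwd, dlogits, band_idx) {
  ca <- fwd$cache
  b <- ca$b; nc <- cfg$n_channels; t_len <- cfg$n_samples
  f1 <- cfg$f1; d_m <- cfg$depth_mult; m <- f1 * d_m; f2 <- cfg$f2
  t1 <- cfg$t1; t2 <- cfg$t2; cb <- nc * b
  g <- list()

  g$wo <- ca$fl %*% t(dlogits)
  g$bo <- rowSums(dlogits)
  dfl <- par$wo %*% dlogits                              # (t2*f2) x b
  dd2 <- aperm(array(dfl, c(t2, f2, b)), c(1, 3, 2))     # (t2, b, f2)
  if (!is.null(ca$mask2)) dd2 <- dd2 * ca$mask2

  dp2 <- array(0, c(t1, b, f2))
  dp2[seq_len(cfg$pool2 * t2), , ] <-
    dd2[rep(seq_len(t2), each = cfg$pool2), , , drop = FALSE] / cfg$pool2
  de2 <- matrix(dp2, t1 * b, f2) * elu_grad(ca$e2_pre, ca$e2)
  bn3b <- bn_bwd(de2, ca$bn3, par$g3)
  g$g3 <- bn3b$dgamma; g$b3 <- bn3b$dbeta
  dv <- bn3b$dx

  g$wp <- crossprod(ca$umat, dv)
  dumat <- dv %*% t(par$wp)
  du <- array(dumat, c(t1, b, m))

  pad_l <- (cfg$sep_kernel_length - 1) %/% 2
  dd1 <- array(0, c(t1, b, m))
  g$ks <- matrix(0, cfg$sep_kernel_length, m)
  for (j in seq_len(cfg$sep_kernel_length)) {
    src <- seq_len(t1) + j - pad_l - 1L
    ok <- src >= 1L & src <= t1
    if (!any(ok)) next
    dd1[src[ok], , ] <- dd1[src[ok], , ] +
      du[ok, , , drop = FALSE] * rep(par$ks[j, ], each = sum(ok) * b)
    prod_jm <- ca$d1[src[ok], , , drop = FALSE] * du[ok, , , drop = FALSE]
    g$ks[j, ] <- colSums(matrix(prod_jm, sum(ok) * b, m))
  }
  if (!is.null(ca$mask1)) dd1 <- dd1 * ca$mask1

  dp1 <- array(0, c(t_len, b, m))
  dp1[seq_len(cfg$pool1 * t1), , ] <-
    dd1[rep(seq_len(t1), each = cfg$pool1), , , drop = FALSE] / cfg$pool1
  de1 <- matrix(dp1, t_len * b, m) * elu_grad(ca$e1_pre, ca$e1)
  bn2b <- bn_bwd(de1, ca$bn2, par$g2)
  g$g2 <- bn2b$dgamma; g$b2 <- bn2b$dbeta
  dz <- bn2b$dx

  g$wd <- matrix(0, nc, m)
  dy1n <- matrix(0, f1 * t_len, cb)
  for (f in seq_len(f1)) {
    cols <- (f - 1L) * d_m + seq_len(d_m)
    g$wd[, cols] <- crossprod(ca$dw_in[[f]], dz[, cols, drop = FALSE])
    dmat <- dz[, cols, drop = FALSE] %*% t(par$wd[, cols, drop = FALSE])
    dim(dmat) <- c(t_len, cb)                          # (t, b, c) view
    dy1n[((f - 1L) * t_len + 1L):(f * t_len), ] <- dmat
  }
  gmap1 <- rep(seq_len(f1), each = t_len)
  bn1b <- bn_row_bwd(dy1n, ca$bn1, gmap1, t_len * cb, par$g1)
  g$g1 <- bn1b$dgamma; g$b1 <- bn1b$dbeta

  dkb <- bn1b$dx %*% t(ca$xmat)
  vals <- rowsum(dkb[band_idx$lin], band_idx$par_idx, reorder = TRUE)
  if (band_idx$complete) {
    g$k1 <- matrix(as.numeric(vals), cfg$kernel_length, f1)
  } else {
    gk <- numeric(band_idx$n_par)
    gk[as.integer(rownames(vals))] <- vals
    g$k1 <- matrix(gk, cfg$kernel_length, f1)
  }
  g
}

adam_init <- function(par)
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0)

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

max_norm_cols <- function(w, max_norm) {
  nrm <- sqrt(colSums(w^2))
  over <- nrm > max_norm
  if (any(over)) w[, over] <- sweep(w[, over, drop = FALSE], 2,
                                    max_norm / nrm[over], "*")
  w
}

#' Fit the compact convolutional EEG classifier
#'
#' Trains the network of [cnn_config()] on interest-window epochs with
#' categorical cross-entropy, Adam, dropout and the learning-rate plateau
#' schedule. A validation set (explicit, or split off `val_fraction` of the
#' training data, stratified) drives the plateau schedule and selects the
#' best epoch's weights. Fully deterministic for a fixed seed.
#'
#' @param epochs training [epoch_set()] (interest window).
#' @param cfg a [cnn_config()]; defaults to the standard configuration for
#'   the epoch dimensions.
#' @param seed integer seed (initialization, shuffling, dropout, split).
#' @param validation optional explicit validation [epoch_set()].
#' @return an object of class `cnn_model` with a [predict_score()] method
#'   and a `history` data.frame (per-epoch train/validation loss, lr).
#' @export
fit_cnn <- function(epochs, cfg = NULL, seed = 1, validation = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  cfg <- cfg %||% cnn_config(n_channels = d[2], n_samples = d[3],
                             kernel_length = round(epochs$rate / 2))
  if (cfg$n_channels != d[2] || cfg$n_samples != d[3])
    stop("cnn_config dimensions do not match the epochs")
  y_all <- epochs$labels

  with_seed(seed, {
    if (is.null(validation) && cfg$val_fraction > 0) {
      fold <- stratified_folds(y_all, round(1 / cfg$val_fraction))
      val_idx <- which(fold == 1)
      tr_idx <- which(fold != 1)
    } else {
      tr_idx <- seq_along(y_all); val_idx <- integer(0)
    }
    x_tr <- epochs$data[tr_idx, , , drop = FALSE]
    y_tr <- y_all[tr_idx]
    if (!is.null(validation)) {
      x_val <- validation$data; y_val <- validation$labels
    } else if (length(val_idx) > 0) {
      x_val <- epochs$data[val_idx, , , drop = FALSE]; y_val <- y_all[val_idx]
    } else { x_val <- NULL; y_val <- NULL }

    par <- cnn_init(cfg)
    bn_state <- list(m1 = rep(0, cfg$f1), v1 = rep(1, cfg$f1),
                     m2 = rep(0, cfg$f1 * cfg$depth_mult),
                     v2 = rep(1, cfg$f1 * cfg$depth_mult),
                     m3 = rep(0, cfg$f2), v3 = rep(1, cfg$f2))
    opt <- adam_init(par)
    band_idx <- conv1_band_index(cfg)
    lr <- cfg$lr
    onehot <- function(y) rbind(true = y == "true", error = y == "error") * 1

    n_tr <- length(y_tr)
    best <- list(loss = Inf, par = par, bn = bn_state)
    since_improve <- 0
    hist <- data.frame()

    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n_tr)
      losses <- c()
      for (start in seq(1, n_tr, by = cfg$batch)) {
        idx <- ord[start:min(start + cfg$batch - 1, n_tr)]
        if (length(idx) < 2) next
        xb <- x_tr[idx, , , drop = FALSE]
        yb <- onehot(y_tr[idx])
        fwd <- cnn_forward(par, cfg, bn_state, xb, training = TRUE,
                           band_idx = band_idx)
        bn_state <- fwd$bn_state
        p <- pmax(fwd$probs, 1e-12)
        losses <- c(losses, -mean(colSums(yb * log(p))))
        dlogits <- (fwd$probs - yb) / length(idx)
        grads <- cnn_backward(par, cfg, fwd, dlogits, band_idx)
        st <- adam_step(par, grads, opt, lr)
        par <- st$par; opt <- st$state
        par$wd <- max_norm_cols(par$wd, 1)
        par$wo <- max_norm_cols(par$wo, 0.25)
      }
      monitor <- if (!is.null(x_val)) {
        fv <- cnn_forward(par, cfg, bn_state, x_val, training = FALSE,
                          band_idx = band_idx)
        pv <- pmax(fv$probs, 1e-12)
        -mean(colSums(onehot(y_val) * log(pv)))
      } else mean(losses)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                     val_loss = monitor, lr = lr))
      if (monitor < best$loss - 1e-5) {
        best <- list(loss = monitor, par = par, bn = bn_state)
        since_improve <- 0
      } else {
        since_improve <- since_improve + 1
        if (since_improve %% cfg$plateau_patience == 0)
          lr <- lr / cfg$plateau_factor
        if (since_improve >= cfg$early_stop_patience) break
      }
    }
    # precise batch-norm statistics: replace the running estimates by the
    # population moments of the selected weights over the training data
    # (dropout off), so short trainings evaluate with matched statistics
    bn_final <- list(m1 = 0 * best$bn$m1, v1 = 0 * best$bn$v1,
                     m2 = 0 * best$bn$m2, v2 = 0 * best$bn$v2,
                     m3 = 0 * best$bn$m3, v3 = 0 * best$bn$v3)
    n_chunks <- 0
    for (start in seq(1, n_tr, by = 64)) {
      idx <- start:min(start + 63, n_tr)
      if (length(idx) < 2) next
      n_chunks <- n_chunks + 1
      fwd <- cnn_forward(best$par, cfg, bn_final, x_tr[idx, , , drop = FALSE],
                         training = TRUE, band_idx = band_idx,
                         momentum = (n_chunks - 1) / n_chunks,
                         use_dropout = FALSE)
      bn_final <- fwd$bn_state
    }
    structure(list(par = best$par, bn_state = bn_final, cfg = cfg,
                   history = hist, val_loss = best$loss, seed = seed),
              class = "cnn_model")
  })
}

#' @export
predict_score.cnn_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "epoch_set")) newdata$data else newdata
  fwd <- cnn_forward(object$par, object$cfg, object$bn_state, x,
                     training = FALSE)
  unname(fwd$probs["error", ])
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model: %d ch x %d samples, %d parameters, %d epochs>\n",
              x$cfg$n_channels, x$cfg$n_samples, cnn_param_count(x$cfg),
              nrow(x$history)))
  invisible(x)
}
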