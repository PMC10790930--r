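# Minimal fully-connected network engine shared by the human-feedback
# policy and the DDPG actor/critic: ReLU hidden layers, softmax or linear
# output, hand-derived backprop, Adam updates. All functions are pure with
# respect to the ambient RNG (initialization draws from the current stream).

mlp_new <- function(sizes, out = c("softmax", "linear")) {
  out <- match.arg(out)
  n_layers <- length(sizes) - 1
  w <- vector("list", n_layers); b <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    fan_in <- sizes[i]; fan_out <- sizes[i + 1]
    lim <- if (i < n_layers) sqrt(2 / fan_in)      # He for ReLU layers
           else sqrt(6 / (fan_in + fan_out))       # glorot for the head
    w[[i]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim),
                     fan_in, fan_out)
    b[[i]] <- rep(0, fan_out)
  }
  structure(list(w = w, b = b, sizes = sizes, out = out), class = "mlp")
}

# x: n x in. Returns activations per layer plus the output (post softmax
# for softmax heads; `logits` holds the pre-softmax values).
mlp_forward <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n_layers <- length(net$w)
  acts <- vector("list", n_layers + 1)
  acts[[1]] <- x
  for (i in seq_len(n_layers)) {
    z <- acts[[i]] %*% net$w[[i]]
    z <- z + rep(net$b[[i]], each = nrow(z))
    acts[[i + 1]] <- if (i < n_layers) pmax(z, 0) else z
  }
  logits <- acts[[n_layers + 1]]
  out <- if (net$out == "softmax") {
    e <- exp(logits - apply(logits, 1, max))
    e / rowSums(e)
  } else logits
  list(acts = acts, logits = logits, out = out)
}

# dlogits: gradient of the loss w.r.t. the pre-softmax/linear output.
# Returns parameter gradients and the gradient w.r.t. the input.
mlp_backward <- function(net, fwd, dlogits) {
  n_layers <- length(net$w)
  gw <- vector("list", n_layers); gb <- vector("list", n_layers)
  delta <- dlogits
  for (i in rev(seq_len(n_layers))) {
    gw[[i]] <- crossprod(fwd$acts[[i]], delta)
    gb[[i]] <- colSums(delta)
    if (i > 1) {
      delta <- delta %*% t(net$w[[i]])
      delta <- delta * (fwd$acts[[i]] > 0)
    } else {
      delta <- delta %*% t(net$w[[i]])
    }
  }
  list(w = gw, b = gb, dx = delta)
}

mlp_adam_init <- function(net)
  list(mw = lapply(net$w, function(p) p * 0),
       vw = lapply(net$w, function(p) p * 0),
       mb = lapply(net$b, function(p) p * 0),
       vb = lapply(net$b, function(p) p * 0), t = 0)

mlp_adam_step <- function(net, grads, state, lr, beta1 = 0.9,
                          beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (i in seq_along(net$w)) {
    state$mw[[i]] <- beta1 * state$mw[[i]] + (1 - beta1) * grads$w[[i]]
    state$vw[[i]] <- beta2 * state$vw[[i]] + (1 - beta2) * grads$w[[i]]^2
    net$w[[i]] <- net$w[[i]] -
      lr * (state$mw[[i]] / c1) / (sqrt(state$vw[[i]] / c2) + eps)
    state$mb[[i]] <- beta1 * state$mb[[i]] + (1 - beta1) * grads$b[[i]]
    state$vb[[i]] <- beta2 * state$vb[[i]] + (1 - beta2) * grads$b[[i]]^2
    net$b[[i]] <- net$b[[i]] -
      lr * (state$mb[[i]] / c1) / (sqrt(state$vb[[i]] / c2) + eps)
  }
  list(net = net, state = state)
}
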