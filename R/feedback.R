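#' Feedback events and feedback channels
#'
#' A feedback event records one observed robot action together with the
#' oracle-correct action, the delivered binary evaluation (`"positive"` /
#' `"negative"`) and the channel that produced it (`oracle`, `noisy`,
#' `bci_sim`, `bci_full`). Channels transform the perfect oracle label:
#' keyboard noise flips it with a fixed probability; the simulated BCI
#' passes it through a 2x2 confusion channel; the full BCI chain generates
#' one synthetic EEG epoch conditioned on the true correctness,
#' preprocesses it and lets a calibrated decoder predict the label.
#'
#' @name feedback
NULL

new_feedback_event <- function(state, action, optimal, label, source,
                               collision = FALSE) {
  stopifnot(label %in% c("positive", "negative"))
  structure(list(state = state, action = action, optimal = optimal,
                 label = label, source = source, collision = collision),
            class = "feedback_event")
}

#' @rdname feedback
#' @param world a [grid_world()] with an active episode.
#' @param action executed action index (1..6).
#' @param position cell the action was taken from (defaults to the agent).
#' @param collision collision flag of the executed transition.
#' @return a `feedback_event`.
#' @export
oracle_feedback <- function(world, action, position = world$agent,
                            collision = FALSE) {
  opt <- optimal_action(world, position, method = "bfs")
  new_feedback_event(observe(world, position), action, opt,
                     if (action == opt) "positive" else "negative",
                     "oracle", collision)
}

#' @rdname feedback
#' @param event a `feedback_event`.
#' @param flip_prob probability of flipping the label.
#' @param seed optional seed; by default the ambient RNG stream is used.
#' @export
noisy_feedback <- function(event, flip_prob, seed = NULL) {
  stop_if_not_scalar_prob(flip_prob, "flip_prob")
  flip <- if (is.null(seed)) stats::runif(1) < flip_prob
          else with_seed(seed, stats::runif(1) < flip_prob)
  if (flip)
    event$label <- if (event$label == "positive") "negative" else "positive"
  event$source <- "noisy"
  event
}

#' @rdname feedback
#' @param accuracy per-class probability of passing the true label through
#'   unchanged; either a single value or
#'   `c(positive = ..., negative = ...)`.
#' @export
bci_sim_feedback <- function(event, accuracy, seed = NULL) {
  if (length(accuracy) == 1) accuracy <- c(positive = accuracy,
                                           negative = accuracy)
  stopifnot(all(accuracy >= 0 & accuracy <= 1),
            all(c("positive", "negative") %in% names(accuracy)))
  keep <- if (is.null(seed)) stats::runif(1) < accuracy[[event$label]]
          else with_seed(seed, stats::runif(1) < accuracy[[event$label]])
  if (!keep)
    event$label <- if (event$label == "positive") "negative" else "positive"
  event$source <- "bci_sim"
  event
}

#' @rdname feedback
#' @param decoder a [calibrate_bci()] result.
#' @param errp the [errp_model()] used to generate the evoked response.
#' @param montage the [montage()] the decoder was calibrated on.
#' @param cfg the [preproc_config()] of the decoding chain.
#' @export
bci_full_feedback <- function(event, decoder, errp, montage,
                              cfg = preproc_config(), seed = NULL) {
  stopifnot(inherits(decoder, "bci_decoder"))
  gen_seed <- if (is.null(seed)) sample.int(.Machine$integer.max, 1)
              else as.integer(seed)
  rec <- generate_recording(montage, errp, n_trials = 1,
                            error_fraction = as.numeric(event$label ==
                                                        "negative"),
                            seed = gen_seed)
  ep <- extract_interest_window(preprocess_recording(rec, cfg),
                                cfg$interest_window)
  p_err <- predict_score(decoder, ep)
  event$label <- if (p_err >= decoder$threshold) "negative" else "positive"
  event$source <- "bci_full"
  event
}

#' Build a feedback channel closure
#'
#' Convenience constructor used by [train_hf_policy()] and
#' [run_experiment()]: returns a function mapping an oracle
#' `feedback_event` to the delivered event.
#'
#' @param type `"oracle"`, `"noisy"`, `"bci_sim"`, or `"bci_full"`.
#' @param flip_prob label flip probability for `"noisy"`.
#' @param accuracy per-class correct-decision probability for `"bci_sim"`.
#' @param decoder,errp,montage,cfg components of the `"bci_full"` chain.
#' @return function of one `feedback_event`.
#' @export
feedback_channel <- function(type = c("oracle", "noisy", "bci_sim",
                                      "bci_full"),
                             flip_prob = 0.3, accuracy = 0.77,
                             decoder = NULL, errp = NULL, montage = NULL,
                             cfg = preproc_config()) {
  type <- match.arg(type)
  switch(type,
    oracle = function(ev) ev,
    noisy = function(ev) noisy_feedback(ev, flip_prob),
    bci_sim = function(ev) bci_sim_feedback(ev, accuracy),
    bci_full = function(ev) bci_full_feedback(ev, decoder, errp, montage,
                                              cfg))
}

#' Train the human-feedback policy
#'
#' Online supervised learning of the probability that each action receives
#' positive feedback: a fully connected network (8 inputs, one hidden layer
#' of 32 rectified units, 6 softmax outputs). The robot acts epsilon-greedy
#' on the current policy (epsilon decaying linearly from `eps_start` to
#' `eps_end` over the label budget; or purely randomly with
#' `pure_random = TRUE`); every executed action yields one feedback event,
#' appended to an append-only replay store. After a warm-up of one batch,
#' each new label triggers one training step on a mini-batch stratified to
#' 10% collision / 90% non-collision transitions (when enough collision
#' samples exist). The executed action's softmax output is trained towards
#' its binary label with binary cross-entropy and Adam.
#'
#' @param world a [grid_world()].
#' @param channel a [feedback_channel()] (default: perfect oracle).
#' @param n_labels feedback budget (default 1000).
#' @param batch mini-batch size. @param lr Adam learning rate.
#' @param collision_frac collision fraction per batch.
#' @param eps_start,eps_end epsilon schedule over the label budget.
#' @param updates_per_label gradient steps (each on a freshly stratified
#'   batch) per incoming feedback label.
#' @param pure_random act uniformly at random instead of epsilon-greedy.
#' @param seed integer seed.
#' @return an object of class `hf_policy`: the network, the configuration
#'   and the feedback log (data.frame).
#' @export
train_hf_policy <- function(world, channel = feedback_channel("oracle"),
                            n_labels = 1000, batch = 20, lr = 0.001,
                            collision_frac = 0.1, eps_start = 1,
                            eps_end = 0.1, updates_per_label = 4,
                            pure_random = FALSE, seed = 1) {
  if (n_labels < batch) stop("n_labels must be at least the batch size")
  with_seed(seed, {
    net <- mlp_new(c(8, 32, 6), out = "softmax")
    opt <- mlp_adam_init(net)
    states <- matrix(0, n_labels, 8)
    actions <- integer(n_labels); labels01 <- integer(n_labels)
    collisions <- logical(n_labels); sources <- character(n_labels)
    world_reset(world)
    for (i in seq_len(n_labels)) {
      if (world$done) world_reset(world)
      obs <- observe(world)
      eps <- eps_start + (eps_end - eps_start) * (i - 1) / max(n_labels - 1, 1)
      act <- if (pure_random || stats::runif(1) < eps) sample.int(6, 1)
             else which.max(mlp_forward(net, obs)$out)
      opt_act <- optimal_action(world, method = "bfs")
      tr <- world_step(world, act)
      ev <- new_feedback_event(obs, act, opt_act,
                               if (act == opt_act) "positive" else "negative",
                               "oracle", tr$collision)
      ev <- channel(ev)
      states[i, ] <- obs; actions[i] <- act
      labels01[i] <- as.integer(ev$label == "positive")
      collisions[i] <- ev$collision; sources[i] <- ev$source
      if (i >= batch) {
        for (u in seq_len(updates_per_label)) {
          sel <- hf_batch_indices(collisions[seq_len(i)], batch,
                                  collision_frac)
          res <- hf_policy_step(net, opt, states[sel, , drop = FALSE],
                                actions[sel], labels01[sel], lr)
          net <- res$net; opt <- res$state
        }
      }
    }
    structure(list(net = net, states = states,
                   config = list(n_labels = n_labels, batch = batch,
                                 lr = lr, collision_frac = collision_frac,
                                 eps_start = eps_start, eps_end = eps_end,
                                 updates_per_label = updates_per_label,
                                 pure_random = pure_random, seed = seed),
                   log = data.frame(action = actions, label = labels01,
                                    collision = collisions,
                                    source = sources)),
              class = "hf_policy")
  })
}

# Collision-stratified batch: ceiling(frac * batch) collision samples when
# available, the rest non-collision; shortfalls filled from the other pool.
hf_batch_indices <- function(collision_flags, batch, frac) {
  coll <- which(collision_flags); noncoll <- which(!collision_flags)
  n_coll <- min(ceiling(frac * batch), length(coll))
  n_non <- min(batch - n_coll, length(noncoll))
  sel <- c(if (n_coll > 0) coll[sample.int(length(coll), n_coll)],
           if (n_non > 0) noncoll[sample.int(length(noncoll), n_non)])
  if (length(sel) < batch) {
    pool <- setdiff(seq_along(collision_flags), sel)
    sel <- c(sel, pool[sample.int(length(pool),
                                  min(batch - length(sel), length(pool)))])
  }
  sel
}

hf_policy_step <- function(net, opt, states, actions, labels01, lr) {
  n <- nrow(states)
  fwd <- mlp_forward(net, states)
  p <- fwd$out
  pa <- pmin(pmax(p[cbind(seq_len(n), actions)], 1e-7), 1 - 1e-7)
  # d BCE / d logit_j through the softmax, touching only the executed
  # action's output: coef * (1[j = a] - p_j) with coef = (p_a - y)/(1 - p_a)
  coef <- (pa - labels01) / (1 - pa) / n
  dlogits <- -p * coef
  dlogits[cbind(seq_len(n), actions)] <- coef * (1 - pa)
  grads <- mlp_backward(net, fwd, dlogits)
  mlp_adam_step(net, grads, opt, lr)
}

#' Action probabilities and greedy action of a trained HF policy
#'
#' @param policy an `hf_policy`.
#' @param obs 8-dimensional observation (or n x 8 matrix).
#' @return `hf_probs`: matrix of per-action probabilities (rows sum to 1);
#'   `hf_action`: integer greedy action index.
#' @export
hf_probs <- function(policy, obs) mlp_forward(policy$net, obs)$out

#' @rdname hf_probs
#' @export
hf_action <- function(policy, obs) {
  unname(apply(hf_probs(policy, obs), 1, which.max))
}

#' @export
print.hf_policy <- function(x, ...) {
  cat(sprintf("<hf_policy: %d labels (%.0f%% positive), sources: %s>\n",
              nrow(x$log), 100 * mean(x$log$label),
              paste(unique(x$log$source), collapse = ",")))
  invisible(x)
}
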