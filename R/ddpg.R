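#' Configuration of the discrete-action DDPG learner
#'
#' Defaults are the full training protocol: discount 0.9, soft-update
#' factor 0.005, actor/critic Adam learning rates 0.003/0.001, 20 network
#' updates per environment step, exploration probability decaying linearly
#' from 1 to 0 at global step 125,000, and 8,000 episodes of at most 160
#' steps. `priority_fraction` is the share of each replay batch filled with
#' stored transitions of highest reward (ceiling rule, ties broken
#' uniformly at random); the remainder is drawn uniformly without
#' replacement.
#'
#' @param gamma discount factor. @param tau soft-update coefficient.
#' @param actor_lr,critic_lr Adam learning rates.
#' @param updates_per_step gradient updates per environment step.
#' @param batch_size replay batch size. @param buffer_capacity replay
#'   capacity (oldest transitions overwritten).
#' @param epsilon_start,epsilon_end,epsilon_end_step linear exploration
#'   schedule over global environment steps.
#' @param episodes,max_steps training protocol.
#' @param priority_fraction highest-reward share of each batch.
#' @param hidden hidden layer sizes of actor and critic.
#' @param target_action action representation inside the TD target:
#'   `"expected"` (default) evaluates the target critic at every one-hot
#'   action and averages under the target actor's softmax — the critic is
#'   then only ever queried at the one-hot inputs it is trained on;
#'   `"soft"` evaluates it once at the softmax probability vector itself;
#'   `"hard"` at the one-hot of the argmax.
#' @param q_clip two-element range the TD target is clipped to. For the
#'   sparse navigation task every return lies in `[0, 1]` (a single unit
#'   reward on task termination, discounting otherwise), so the default
#'   removes bootstrapped value run-away without biasing any attainable
#'   value; set to `c(-Inf, Inf)` to disable (e.g. for shaped rewards).
#' @param actor_execution how the actor acts when not exploring:
#'   `"sample"` (default) draws from its softmax — the stochastic policy
#'   the actor objective actually optimizes, which cannot be trapped in
#'   the deterministic loops an argmax policy falls into at any state it
#'   gets wrong — or `"greedy"` takes the argmax.
#' @param actor_entropy weight of an entropy bonus in the actor
#'   objective. A saturated softmax has vanishing policy gradients, so an
#'   actor that commits to an action while the critic is still inaccurate
#'   can never be corrected; a small bonus keeps the gradients alive.
#'   Set to 0 to disable.
#' @return an object of class `ddpg_config`.
#' @export
ddpg_config <- function(gamma = 0.9, tau = 0.005, actor_lr = 0.003,
                        critic_lr = 0.001, updates_per_step = 20,
                        batch_size = 64, buffer_capacity = 200000,
                        epsilon_start = 1, epsilon_end = 0,
                        epsilon_end_step = 125000, episodes = 8000,
                        max_steps = 160, priority_fraction = 0.1,
                        hidden = c(64, 64),
                        target_action = c("expected", "soft", "hard"),
                        q_clip = c(0, 1),
                        actor_execution = c("sample", "greedy"),
                        actor_entropy = 0.01) {
  stopifnot(gamma > 0, gamma < 1, tau > 0, tau <= 1,
            epsilon_start >= epsilon_end,
            length(q_clip) == 2, q_clip[1] <= q_clip[2])
  target_action <- match.arg(target_action)
  actor_execution <- match.arg(actor_execution)
  structure(list(gamma = gamma, tau = tau, actor_lr = actor_lr,
                 critic_lr = critic_lr, updates_per_step = updates_per_step,
                 batch_size = batch_size, buffer_capacity = buffer_capacity,
                 epsilon_start = epsilon_start, epsilon_end = epsilon_end,
                 epsilon_end_step = epsilon_end_step, episodes = episodes,
                 max_steps = max_steps, priority_fraction = priority_fraction,
                 hidden = hidden, target_action = target_action,
                 q_clip = q_clip, actor_execution = actor_execution,
                 actor_entropy = actor_entropy),
            class = "ddpg_config")
}

#' Exploration probability at a global step
#'
#' Linear interpolation from `epsilon_start` at step 0 to `epsilon_end` at
#' `epsilon_end_step`, constant afterwards.
#'
#' @param cfg a [ddpg_config()].
#' @param step global environment step count (0-based).
#' @return numeric epsilon.
#' @export
epsilon_at <- function(cfg, step) {
  frac <- min(step, cfg$epsilon_end_step) / cfg$epsilon_end_step
  cfg$epsilon_start + (cfg$epsilon_end - cfg$epsilon_start) * frac
}

#' Create a DDPG agent
#'
#' Actor: observation (8) to a softmax distribution over the 6 actions.
#' Critic: observation plus 6-dimensional action representation to a
#' scalar value. Target copies of both start identical to the online
#' networks.
#'
#' @param cfg a [ddpg_config()].
#' @return an object of classes `ddpg_agent`/`environment` (mutable).
#' @export
ddpg_agent <- function(cfg = ddpg_config()) {
  a <- new.env(parent = emptyenv())
  a$cfg <- cfg
  a$actor <- mlp_new(c(8, cfg$hidden, 6), out = "softmax")
  a$critic <- mlp_new(c(14, cfg$hidden, 1), out = "linear")
  a$actor_t <- a$actor
  a$critic_t <- a$critic
  a$actor_opt <- mlp_adam_init(a$actor)
  a$critic_opt <- mlp_adam_init(a$critic)
  a$step <- 0L
  class(a) <- c("ddpg_agent", "environment")
  a
}

#' @export
print.ddpg_agent <- function(x, ...) {
  cat(sprintf("<ddpg_agent: hidden %s, global step %d>\n",
              paste(x$cfg$hidden, collapse = "/"), x$step))
  invisible(x)
}

#' Select an action with HF-guided epsilon-greedy exploration
#'
#' With probability epsilon (from [epsilon_at()] at the agent's global
#' step) the exploratory action is taken: an action suggested by the HF
#' policy when `hf` is given (drawn from its softmax output, which is
#' near-deterministic where the policy is confident and keeps exploring
#' where it is not — a deterministic argmax would lock the agent into
#' loops at any state the policy gets wrong), otherwise a uniformly random
#' action (the sparse baseline). With probability 1 - epsilon the actor
#' acts: by default a draw from its softmax output (see the
#' `actor_execution` argument of [ddpg_config()]), or its argmax under
#' `actor_execution = "greedy"`.
#'
#' @param agent a [ddpg_agent()].
#' @param state 8-dimensional observation.
#' @param hf an `hf_policy` or `NULL`.
#' @param step global step override (defaults to the agent's counter).
#' @param hf_greedy take the HF policy's argmax instead of sampling.
#' @return integer action index.
#' @export
select_action <- function(agent, state, hf = NULL, step = agent$step,
                          hf_greedy = FALSE) {
  eps <- epsilon_at(agent$cfg, step)
  if (eps > 0 && stats::runif(1) < eps) {
    if (is.null(hf)) sample.int(6, 1)
    else if (hf_greedy) hf_action(hf, state)
    else sample.int(6, 1, prob = hf_probs(hf, state))
  } else {
    p <- mlp_forward(agent$actor, state)$out
    if (identical(agent$cfg$actor_execution, "greedy")) which.max(p)
    else sample.int(6, 1, prob = p)
  }
}

#' Soft-update the target networks
#'
#' `target <- tau * online + (1 - tau) * target` for every actor and
#' critic parameter.
#'
#' @param agent a [ddpg_agent()].
#' @param tau override of the configured coefficient.
#' @return the agent, invisibly.
#' @export
soft_update <- function(agent, tau = agent$cfg$tau) {
  mix <- function(tgt, on) {
    for (i in seq_along(on$w)) {
      tgt$w[[i]] <- tau * on$w[[i]] + (1 - tau) * tgt$w[[i]]
      tgt$b[[i]] <- tau * on$b[[i]] + (1 - tau) * tgt$b[[i]]
    }
    tgt
  }
  agent$actor_t <- mix(agent$actor_t, agent$actor)
  agent$critic_t <- mix(agent$critic_t, agent$critic)
  invisible(agent)
}

# Replay buffer with preallocated storage and ring overwrite.
replay_buffer <- function(capacity) {
  b <- new.env(parent = emptyenv())
  b$capacity <- capacity
  b$state <- matrix(0, capacity, 8); b$next_state <- matrix(0, capacity, 8)
  b$action <- integer(capacity); b$reward <- numeric(capacity)
  b$done <- numeric(capacity)
  b$n <- 0L; b$pos <- 0L; b$written <- 0L
  class(b) <- c("replay_buffer", "environment")
  b
}

buffer_add <- function(buf, tr) {
  buf$pos <- (buf$pos %% buf$capacity) + 1L
  buf$state[buf$pos, ] <- tr$state
  buf$next_state[buf$pos, ] <- tr$next_state
  buf$action[buf$pos] <- tr$action
  buf$reward[buf$pos] <- tr$reward
  # bootstrap mask: true task termination, not the episode timeout
  buf$done[buf$pos] <- as.numeric(tr$terminal %||% tr$done)
  buf$n <- min(buf$n + 1L, buf$capacity)
  buf$written <- buf$written + 1L
  invisible(buf)
}

#' Sample a reward-prioritized replay batch
#'
#' `ceiling(priority_fraction * batch_size)` slots are filled with
#' stored transitions of highest reward (ties broken uniformly at
#' random, so equal-reward transitions are exchangeable rather than a
#' fixed set being replayed in every batch); the remaining slots are
#' drawn uniformly without replacement from the rest of the buffer.
#'
#' @param buf a replay buffer. @param batch_size batch size.
#' @param priority_fraction highest-reward share.
#' @return integer vector of buffer row indices.
#' @export
sample_batch <- function(buf, batch_size, priority_fraction = 0.1) {
  if (buf$n < batch_size) stop("replay buffer holds fewer transitions than the batch size")
  idx <- seq_len(buf$n)
  r <- buf$reward[idx]
  # equal rewards make prioritization vacuous: plain uniform sample
  if (max(r) == min(r)) return(idx[sample.int(buf$n, batch_size)])
  k <- min(ceiling(priority_fraction * batch_size), buf$n)
  # random tie-break among equal rewards: without it the same few
  # transitions would be replayed in every batch and overfit
  top <- idx[order(-r, stats::runif(buf$n))][seq_len(k)]
  rest <- setdiff(idx, top)
  c(top, rest[sample.int(length(rest), batch_size - k)])
}

#' One DDPG update on a batch
#'
#' Critic regression on the one-step bootstrapped target
#' `r + gamma * (1 - done) * Q_target(s', actor_target(s'))`, with stored
#' actions one-hot encoded; actor ascent on the critic's value of its own
#' action distribution; then a soft target update. Under the default
#' `"expected"` target-action mode the critic is only ever evaluated at
#' one-hot actions — the distribution it is trained on — and both the TD
#' target and the actor objective are exact expectations over the six
#' actions under the (target) actor's softmax, which makes the actor
#' gradient exact and avoids querying the critic at probability-vector
#' inputs it has never seen.
#'
#' @param agent a [ddpg_agent()].
#' @param buf replay buffer. @param idx batch indices from [sample_batch()].
#' @return list of `critic_loss` and `actor_value` diagnostics, invisibly.
#' @export
ddpg_update <- function(agent, buf, idx) {
  cfg <- agent$cfg
  s <- buf$state[idx, , drop = FALSE]
  s2 <- buf$next_state[idx, , drop = FALSE]
  r <- buf$reward[idx]; dn <- buf$done[idx]
  n <- length(idx)
  a_onehot <- matrix(0, n, 6)
  a_onehot[cbind(seq_len(n), buf$action[idx])] <- 1
  # critic value of every one-hot action for each state in `s` (n x 6)
  q_all <- function(net, s) {
    srep <- s[rep(seq_len(nrow(s)), 6), , drop = FALSE]
    arep <- matrix(0, 6 * nrow(s), 6)
    arep[cbind(seq_len(6 * nrow(s)), rep(1:6, each = nrow(s)))] <- 1
    matrix(mlp_forward(net, cbind(srep, arep))$out, nrow(s), 6)
  }

  p2 <- mlp_forward(agent$actor_t, s2)$out
  q2 <- switch(cfg$target_action,
    expected = rowSums(p2 * q_all(agent$critic_t, s2)),
    soft = as.numeric(mlp_forward(agent$critic_t, cbind(s2, p2))$out),
    hard = {
      hard <- matrix(0, n, 6)
      hard[cbind(seq_len(n), max.col(p2, ties.method = "first"))] <- 1
      as.numeric(mlp_forward(agent$critic_t, cbind(s2, hard))$out)
    })
  target <- pmin(pmax(r + cfg$gamma * (1 - dn) * q2, cfg$q_clip[1]),
                 cfg$q_clip[2])

  fwd_c <- mlp_forward(agent$critic, cbind(s, a_onehot))
  q <- as.numeric(fwd_c$out)
  dq <- matrix(2 * (q - target) / n, ncol = 1)
  g_c <- mlp_backward(agent$critic, fwd_c, dq)
  st <- mlp_adam_step(agent$critic, g_c, agent$critic_opt, cfg$critic_lr)
  agent$critic <- st$net; agent$critic_opt <- st$state

  fwd_a <- mlp_forward(agent$actor, s)
  p <- fwd_a$out
  if (cfg$target_action == "expected") {
    # exact gradient of -mean_i sum_a p_ia Q(s_i, a) w.r.t. the logits
    qa <- q_all(agent$critic, s)
    v <- rowSums(p * qa)
    dlogits <- -p * (qa - v) / n
    actor_value <- mean(v)
  } else {
    fwd_ca <- mlp_forward(agent$critic, cbind(s, p))
    dcrit <- mlp_backward(agent$critic, fwd_ca,
                          matrix(-1 / n, n, 1))        # d(-mean Q)/dQ
    dp <- dcrit$dx[, 9:14, drop = FALSE]
    # through the softmax: dz_j = p_j * (g_j - sum_k g_k p_k)
    gp <- rowSums(dp * p)
    dlogits <- p * (dp - gp)
    actor_value <- mean(as.numeric(fwd_ca$out))
  }
  if (cfg$actor_entropy > 0) {
    # gradient of -beta * H(p) w.r.t. the logits: beta * p * (log p + H)
    lp <- log(pmax(p, 1e-12))
    ent <- -rowSums(p * lp)
    dlogits <- dlogits + cfg$actor_entropy * p * (lp + ent) / n
  }
  g_a <- mlp_backward(agent$actor, fwd_a, dlogits)
  st <- mlp_adam_step(agent$actor, g_a, agent$actor_opt, cfg$actor_lr)
  agent$actor <- st$net; agent$actor_opt <- st$state

  if (!all(is.finite(q)))
    stop("non-finite critic values during update")
  soft_update(agent)
  invisible(list(critic_loss = mean((q - target)^2),
                 actor_value = actor_value))
}

#' Train a DDPG agent on the navigation task
#'
#' Runs the full loop: HF-guided (or uniform) epsilon-greedy action
#' selection, replay storage, `updates_per_step` prioritized-batch updates
#' per environment step, soft target updates, and per-episode SPL
#' recording ([spl()]; the shortest path length is taken at episode start,
#' the taken path length counts executed moves including collision-blocked
#' attempts).
#'
#' @param world a [grid_world()].
#' @param hf an `hf_policy` guiding exploration, or `NULL` for the sparse
#'   baseline.
#' @param cfg a [ddpg_config()].
#' @param seed integer seed.
#' @param agent optionally a pre-built [ddpg_agent()] to continue training.
#' @return an object of class `run_curve`: data.frame with one row per
#'   episode (`episode`, `success`, `shortest`, `taken`, `spl`) plus the
#'   agent and config as attributes.
#' @export
train_ddpg <- function(world, hf = NULL, cfg = ddpg_config(), seed = 1,
                       agent = NULL) {
  with_seed(seed, {
    if (is.null(agent)) agent <- ddpg_agent(cfg)
    buf <- replay_buffer(cfg$buffer_capacity)
    curve <- data.frame(episode = integer(0), success = logical(0),
                        shortest = numeric(0), taken = integer(0),
                        spl = numeric(0))
    for (ep in seq_len(cfg$episodes)) {
      obs <- world_reset(world)
      shortest <- world$dist[cell_id(world, world$agent)]
      taken <- 0L; success <- FALSE
      while (!world$done && taken < cfg$max_steps) {
        act <- select_action(agent, obs, hf = hf, step = agent$step)
        tr <- world_step(world, act)
        buffer_add(buf, tr)
        obs <- tr$next_state
        taken <- taken + 1L
        agent$step <- agent$step + 1L
        success <- success || tr$success
        if (buf$n >= cfg$batch_size) {
          for (u in seq_len(cfg$updates_per_step))
            ddpg_update(agent, buf,
                        sample_batch(buf, cfg$batch_size,
                                     cfg$priority_fraction))
        }
      }
      curve <- rbind(curve,
                     data.frame(episode = ep, success = success,
                                shortest = shortest, taken = taken,
                                spl = spl(success, shortest, taken)))
    }
    structure(curve, class = c("run_curve", "data.frame"),
              seed = seed, agent = agent, cfg = cfg)
  })
}
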