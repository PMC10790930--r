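test_that("the exploration schedule is piecewise linear with exact endpoints", {
  cfg <- ddpg_config()
  expect_equal(epsilon_at(cfg, 0), 1.0)
  expect_equal(epsilon_at(cfg, 62500), 0.5)
  expect_equal(epsilon_at(cfg, 125000), 0.0)
  expect_equal(epsilon_at(cfg, 300000), 0.0)
  steps <- seq(0, 2e5, by = 5000)
  eps <- vapply(steps, function(s) epsilon_at(cfg, s), numeric(1))
  expect_true(all(diff(eps) <= 0))
})

test_that("soft updates interpolate and converge geometrically", {
  cfg <- ddpg_config(hidden = c(8))
  withr::with_seed(1, a <- ddpg_agent(cfg))
  online_w <- a$actor$w[[1]]
  withr::with_seed(2, a$actor_t <- errpRL:::mlp_new(c(8, 8, 6), "softmax"))
  start_t <- a$actor_t$w[[1]]
  soft_update(a, tau = 1)
  expect_equal(a$actor_t$w[[1]], online_w)

  withr::with_seed(2, a$actor_t <- errpRL:::mlp_new(c(8, 8, 6), "softmax"))
  soft_update(a, tau = 0)
  expect_equal(a$actor_t$w[[1]], start_t)

  withr::with_seed(2, a$actor_t <- errpRL:::mlp_new(c(8, 8, 6), "softmax"))
  d0 <- sqrt(sum((a$actor_t$w[[1]] - online_w)^2))
  for (k in 1:10) soft_update(a, tau = 0.005)
  dk <- sqrt(sum((a$actor_t$w[[1]] - online_w)^2))
  expect_equal(dk / d0, (1 - 0.005)^10, tolerance = 1e-10)
})

fill_buffer <- function(n, rewards) {
  buf <- errpRL:::replay_buffer(1000)
  withr::with_seed(3, {
    for (i in seq_len(n))
      errpRL:::buffer_add(buf, list(state = runif(8), action = sample(6, 1),
                                    reward = rewards[i], next_state = runif(8),
                                    done = FALSE, collision = FALSE,
                                    success = FALSE))
  })
  buf
}

test_that("replay batches contain the highest-reward transitions", {
  buf <- fill_buffer(100, c(rep(0, 99), 1))
  withr::with_seed(4, {
    for (i in 1:20) {
      idx <- sample_batch(buf, 20, 0.1)
      expect_length(idx, 20)
      expect_equal(anyDuplicated(idx), 0)
      expect_true(100 %in% idx)        # the single reward-1 transition
      expect_equal(sum(buf$reward[idx] == 1), 1)
    }
  })
  # ceiling rule: 16-sample batch at 10% -> 2 prioritized slots
  buf2 <- fill_buffer(50, c(rep(0, 48), 1, 1))
  withr::with_seed(5, {
    idx <- sample_batch(buf2, 16, 0.1)
    expect_true(all(c(49, 50) %in% idx))
  })
  expect_error(sample_batch(fill_buffer(5, rep(0, 5)), 16), "fewer")
})

test_that("equal rewards make the batch an unbiased uniform sample", {
  buf <- fill_buffer(40, rep(0, 40))
  counts <- integer(40)
  withr::with_seed(6, {
    for (i in 1:300) {
      idx <- sample_batch(buf, 10, 0.1)
      counts[idx] <- counts[idx] + 1
    }
  })
  # every slot selected with frequency near 10/40
  expect_gt(min(counts), 300 * 0.25 * 0.5)
  expect_lt(max(counts), 300 * 0.25 * 1.6)
})

test_that("the critic fits the immediate reward when gamma is irrelevant", {
  cfg <- ddpg_config(gamma = 0.9, hidden = c(16), batch_size = 8)
  withr::with_seed(7, {
    agent <- ddpg_agent(cfg)
    buf <- errpRL:::replay_buffer(100)
    s <- runif(8); s2 <- runif(8)
    for (i in 1:20)
      errpRL:::buffer_add(buf, list(state = s, action = 3, reward = 1,
                                    next_state = s2, done = TRUE,
                                    collision = FALSE, success = TRUE))
    for (k in 1:300) {
      d <- ddpg_update(agent, buf, sample_batch(buf, 8, 0.1))
    }
    onehot <- matrix(0, 1, 6); onehot[3] <- 1
    q <- errpRL:::mlp_forward(agent$critic, cbind(matrix(s, 1), onehot))$out
    # done transition: target = r exactly (the gamma term is masked)
    expect_equal(as.numeric(q), 1, tolerance = 0.1)
    p <- errpRL:::mlp_forward(agent$actor, matrix(s, 1))$out
    expect_equal(sum(p), 1, tolerance = 1e-9)  # softmax preserved
    expect_true(all(is.finite(unlist(agent$critic$w))))
  })
})

test_that("select_action respects the epsilon handover", {
  cfg <- ddpg_config(epsilon_end_step = 100, hidden = c(8),
                     actor_execution = "greedy")
  withr::with_seed(8, {
    agent <- ddpg_agent(cfg)
    s <- runif(8)
    greedy <- which.max(errpRL:::mlp_forward(agent$actor, s)$out)
    # far past the schedule: purely the actor's action
    acts <- vapply(1:20, function(i)
      select_action(agent, s, hf = NULL, step = 1000), numeric(1))
    expect_true(all(acts == greedy))
    # at step 0 with no HF: uniform random actions
    acts0 <- vapply(1:200, function(i)
      select_action(agent, s, hf = NULL, step = 0), numeric(1))
    expect_gt(length(unique(acts0)), 4)
  })
  # default execution samples the actor's softmax: a fresh (near-uniform)
  # actor yields varied post-handover actions
  cfg2 <- ddpg_config(epsilon_end_step = 100, hidden = c(8))
  withr::with_seed(9, {
    agent2 <- ddpg_agent(cfg2)
    s <- runif(8)
    acts2 <- vapply(1:100, function(i)
      select_action(agent2, s, hf = NULL, step = 1000), numeric(1))
    expect_gt(length(unique(acts2)), 2)
  })
})

test_that("zero episodes give an empty curve and training is seeded", {
  w <- grid_world(dims = c(5, 5, 3), wall = FALSE, max_steps = 20)
  cfg <- ddpg_config(episodes = 0, max_steps = 20, batch_size = 8,
                     updates_per_step = 1, hidden = c(8))
  curve <- train_ddpg(w, cfg = cfg, seed = 1)
  expect_equal(nrow(curve), 0)

  cfg2 <- ddpg_config(episodes = 3, max_steps = 20, batch_size = 8,
                      updates_per_step = 1, hidden = c(8),
                      epsilon_end_step = 100)
  w2 <- grid_world(dims = c(5, 5, 3), wall = FALSE, max_steps = 20)
  a <- train_ddpg(w2, cfg = cfg2, seed = 5)
  w3 <- grid_world(dims = c(5, 5, 3), wall = FALSE, max_steps = 20)
  b <- train_ddpg(w3, cfg = cfg2, seed = 5)
  expect_equal(as.data.frame(a), as.data.frame(b))
})
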