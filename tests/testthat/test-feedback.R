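desk_world <- function(max_steps = 50)
  grid_world(dims = c(9, 9, 5), max_steps = max_steps)

test_that("oracle feedback labels actions by agreement with the A* arrow", {
  w <- desk_world()
  withr::with_seed(1, world_reset(w))
  opt <- optimal_action(w, method = "bfs")
  ev_pos <- oracle_feedback(w, opt)
  expect_equal(ev_pos$label, "positive")
  wrong <- setdiff(1:6, opt)[1]
  ev_neg <- oracle_feedback(w, wrong)
  expect_equal(ev_neg$label, "negative")
  expect_equal(ev_neg$optimal, opt)
  expect_length(ev_neg$state, 8)
})

test_that("scheduled trials and oracle feedback agree on the error fraction", {
  w <- desk_world()
  sch <- schedule_trials(w, 300, 0.2, seed = 2)
  expect_equal(mean(sch$executed != sch$optimal), 0.2)
})

test_that("keyboard noise flips labels at the requested rate", {
  w <- desk_world()
  withr::with_seed(3, world_reset(w))
  ev <- oracle_feedback(w, optimal_action(w, method = "bfs"))
  expect_equal(noisy_feedback(ev, 0, seed = 1)$label, ev$label)
  expect_equal(noisy_feedback(ev, 1, seed = 1)$label, "negative")
  flips <- withr::with_seed(4, {
    vapply(seq_len(10000), function(i)
      noisy_feedback(ev, 0.3)$label != ev$label, logical(1))
  })
  # binomial 95% interval around 0.3 at n = 10,000
  expect_equal(mean(flips), 0.3, tolerance = 0.035)
})

test_that("the simulated BCI is a per-class confusion channel", {
  w <- desk_world()
  withr::with_seed(5, world_reset(w))
  opt <- optimal_action(w, method = "bfs")
  pos_ev <- oracle_feedback(w, opt)
  neg_ev <- oracle_feedback(w, setdiff(1:6, opt)[1])
  expect_equal(bci_sim_feedback(pos_ev, 1, seed = 1)$label, "positive")
  expect_equal(bci_sim_feedback(neg_ev, 1, seed = 1)$label, "negative")
  acc <- c(positive = 0.9, negative = 0.7)
  rates <- withr::with_seed(6, {
    keep_pos <- mean(vapply(1:4000, function(i)
      bci_sim_feedback(pos_ev, acc)$label == "positive", logical(1)))
    keep_neg <- mean(vapply(1:4000, function(i)
      bci_sim_feedback(neg_ev, acc)$label == "negative", logical(1)))
    c(keep_pos, keep_neg)
  })
  expect_equal(rates[1], 0.9, tolerance = 0.025)
  expect_equal(rates[2], 0.7, tolerance = 0.035)
  # chance-level channel: labels independent of the truth
  both <- withr::with_seed(7, {
    c(mean(vapply(1:2000, function(i)
        bci_sim_feedback(pos_ev, 0.5)$label == "positive", logical(1))),
      mean(vapply(1:2000, function(i)
        bci_sim_feedback(neg_ev, 0.5)$label == "positive", logical(1))))
  })
  expect_equal(both[1], both[2], tolerance = 0.06)
})

test_that("collision-stratified batches hold the requested composition", {
  flags <- c(rep(TRUE, 10), rep(FALSE, 90))
  withr::with_seed(8, {
    for (i in 1:20) {
      sel <- errpRL:::hf_batch_indices(flags, 20, 0.1)
      expect_length(sel, 20)
      expect_equal(sum(flags[sel]), 2)  # exactly 10% collision slots
    }
    # too few collision samples: batch filled from the other pool
    flags2 <- c(TRUE, rep(FALSE, 50))
    sel2 <- errpRL:::hf_batch_indices(flags2, 20, 0.1)
    expect_length(sel2, 20)
    expect_equal(sum(flags2[sel2]), 1)
  })
})

test_that("the HF policy outputs a simplex and keeps every feedback event", {
  w <- desk_world()
  hf <- train_hf_policy(w, n_labels = 60, seed = 9)
  expect_equal(nrow(hf$log), 60)  # append-only store: nothing discarded
  withr::with_seed(10, {
    obs <- matrix(runif(40 * 8), 40, 8)
    p <- hf_probs(hf, obs)
    expect_equal(dim(p), c(40, 6))
    expect_equal(unname(rowSums(p)), rep(1, 40), tolerance = 1e-9)
    expect_true(all(p >= 0))
  })
})

test_that("an oracle-fed HF policy reproduces the optimal action on
          states visited during training", {
  w <- desk_world()
  hf <- train_hf_policy(w, n_labels = 1000, seed = 11)
  states <- unique(hf$states)
  acts <- hf_action(hf, states)
  opt <- apply(states, 1, function(s) {
    pos <- round(s[1:3] * (w$dims - 1)) + 1
    optimal_action(w, pos, method = "bfs")
  })
  expect_gte(mean(acts == opt), 0.9)
})

test_that("agreement with the oracle degrades as feedback noise grows", {
  agreement <- function(flip, seed) {
    w <- desk_world()
    hf <- train_hf_policy(w, feedback_channel("noisy", flip_prob = flip),
                          n_labels = 600, seed = seed)
    states <- unique(hf$states)
    acts <- hf_action(hf, states)
    opt <- apply(states, 1, function(s)
      optimal_action(w, round(s[1:3] * (w$dims - 1)) + 1, method = "bfs"))
    mean(acts == opt)
  }
  levels <- c(0, 0.15, 0.3, 0.5)
  mean_agree <- vapply(levels, function(f)
    mean(vapply(1:3, function(s) agreement(f, 100 + s), numeric(1))),
    numeric(1))
  # non-increasing within a small stochastic slack, with a large total drop
  expect_true(all(diff(mean_agree) < 0.05))
  expect_gt(mean_agree[1] - mean_agree[4], 0.3)
})

test_that("uninformative feedback (flip 0.5) is no better than a constant
          action matched to the oracle's spatial bias", {
  w <- desk_world()
  hf <- train_hf_policy(w, feedback_channel("noisy", flip_prob = 0.5),
                        n_labels = 500, seed = 12)
  states <- unique(hf$states)
  acts <- hf_action(hf, states)
  opt <- apply(states, 1, function(s)
    optimal_action(w, round(s[1:3] * (w$dims - 1)) + 1, method = "bfs"))
  # the oracle action distribution is spatially biased (mostly forward/up
  # on the near side), so even a label-blind policy can match it at the
  # majority rate; informative feedback must do strictly better than that
  majority <- max(table(opt)) / length(opt)
  expect_lt(mean(acts == opt), majority + 0.1)
})
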