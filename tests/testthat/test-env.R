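test_that("resets stay inside the start region and are feasible", {
  w <- grid_world()
  withr::with_seed(1, {
    for (i in 1:200) {
      world_reset(w, new_goal = (i %% 20 == 0))
      expect_true(w$agent[1] %in% w$start_region$x)
      expect_true(w$agent[2] %in% w$start_region$y)
      expect_equal(w$agent[3], 1)
      expect_true(is.finite(w$dist[errpRL:::cell_id(w, w$agent)]))
      expect_gt(w$goal[2], w$wall_y)
    }
  })
})

test_that("reset sequences are reproducible and goals persist within a run", {
  seq_of <- function() {
    w <- grid_world(dims = c(9, 9, 5))
    withr::with_seed(42, {
      t(replicate(5, c(world_reset(w)[1:3], w$goal)))
    })
  }
  expect_identical(seq_of(), seq_of())
  w <- grid_world(dims = c(9, 9, 5))
  withr::with_seed(1, {
    world_reset(w); g1 <- w$goal
    world_reset(w); g2 <- w$goal
    world_reset(w, new_goal = TRUE)
  })
  expect_identical(g1, g2)
})

test_that("observations are length 8 in [0, 1]", {
  w <- grid_world(dims = c(9, 9, 5))
  withr::with_seed(3, {
    for (i in 1:20) {
      obs <- world_reset(w, new_goal = TRUE)
      expect_length(obs, 8)
      expect_true(all(obs >= 0 & obs <= 1))
    }
  })
})

test_that("stepping obeys collision, success and step-cap rules", {
  w <- grid_world(dims = c(5, 5, 3), wall = FALSE, max_steps = 160)
  withr::with_seed(4, world_reset(w))
  # place agent next to the goal deliberately
  w$agent <- w$goal + c(-1, 0, 0)
  tr <- world_step(w, 2)  # move +x onto the goal
  expect_true(tr$success); expect_true(tr$done)
  expect_equal(tr$reward, 1)
  expect_false(tr$collision)

  withr::with_seed(5, world_reset(w))
  w$agent <- c(1, w$agent[2], w$agent[3])
  tr <- world_step(w, 1)  # -x at the boundary
  expect_true(tr$collision)
  expect_equal(tr$reward, 0)
  expect_equal(w$agent[1], 1)  # agent unmoved

  # 160 no-progress steps exhaust the episode without success
  withr::with_seed(6, world_reset(w))
  w$agent <- c(1, w$agent[2], w$agent[3])
  n <- 0
  while (!w$done) { tr <- world_step(w, 1); n <- n + 1 }
  expect_equal(n, 160)
  expect_false(tr$success)
  expect_error(world_step(w, 1), "done")
  expect_error({world_reset(w); world_step(w, 7)}, "1..6")
})

test_that("collisions never move the agent and success excludes collision", {
  w <- grid_world(dims = c(7, 7, 5))
  withr::with_seed(7, {
    world_reset(w)
    for (i in 1:300) {
      if (w$done) world_reset(w)
      before <- w$agent
      tr <- world_step(w, sample.int(6, 1))
      if (tr$collision) {
        expect_identical(w$agent, before)
        expect_false(tr$success)
      }
    }
  })
})

test_that("rich reward is maximal at the goal and decays with distance", {
  w <- grid_world(dims = c(5, 5, 3), wall = FALSE)
  withr::with_seed(8, world_reset(w))
  expect_equal(rich_reward(w, w$goal), 1)
  # normalized corner-to-corner distance term: -k * sqrt(3)
  w$goal <- c(5, 5, 3)
  expect_equal(rich_reward(w, c(1, 1, 1), gain = 2), -2 * sqrt(3))
  near <- w$goal + c(-1, 0, 0)
  far <- w$goal + c(-3, 0, 0)
  expect_gt(rich_reward(w, near), rich_reward(w, far))
})

test_that("optimal action is the obvious move on an empty grid", {
  w <- grid_world(dims = c(5, 5, 3), wall = FALSE)
  w$goal <- c(4, 2, 1); w$dist <- errpRL:::bfs_dist(w, w$goal)
  w$agent <- c(3, 2, 1); w$done <- FALSE
  expect_equal(optimal_action(w, method = "astar"), 2)  # right
  expect_equal(optimal_action(w, method = "bfs"), 2)
  expect_equal(optimal_action(w, position = w$goal), 0L)  # degenerate
})

test_that("A* equals breadth-first search on random small worlds", {
  withr::with_seed(9, {
    for (i in 1:200) {
      dims <- c(sample(4:7, 1), sample(4:7, 1), sample(3:5, 1))
      w <- grid_world(dims = dims, wall = i %% 2 == 0, max_steps = 50)
      world_reset(w, new_goal = TRUE)
      bfs_len <- w$dist[errpRL:::cell_id(w, w$agent)]
      a <- astar_path(w, w$agent)
      expect_equal(a$length, bfs_len)
      # the A* action sequence really is a valid path of that length
      pos <- w$agent
      for (act in a$actions) pos <- pos + errpRL:::.action_deltas[act, ]
      expect_equal(pos, as.numeric(w$goal))
      # first-move equivalence under the shared tie-break rule
      expect_equal(optimal_action(w, method = "astar"),
                   optimal_action(w, method = "bfs"))
    }
  })
})

test_that("laser readings match hand counts in a built corridor", {
  w <- grid_world(dims = c(7, 7, 3), wall = FALSE, laser_max_range = 5)
  # corridor along x at y=4, z=2: block the walls around it
  w$blocked[, , ] <- TRUE
  w$blocked[, 4, 2] <- FALSE
  pos <- c(3, 4, 2)
  r <- lasers(w, pos)
  # rays: -x (2 free), +x (4 free), -y (0), +y (0), -z (0)
  expect_equal(r, c(2 / 5, 4 / 5, 0, 0, 0))
  # open space beyond range clips at 1
  w2 <- grid_world(dims = c(21, 21, 11), wall = FALSE, laser_max_range = 5)
  r2 <- lasers(w2, c(11, 11, 6))
  expect_equal(r2, rep(1, 5))
  # agent pressed against the wall reads 0 on the +y ray
  w3 <- grid_world(dims = c(9, 9, 5))
  r3 <- lasers(w3, c(5, w3$wall_y - 1, 1))
  expect_equal(r3[4], 0)
})

test_that("trial schedules have exact error counts and oracle consistency", {
  w <- grid_world(dims = c(9, 9, 5), max_steps = 50)
  sch <- schedule_trials(w, 200, 0.2, seed = 10)
  expect_equal(sum(sch$is_error), 40)
  expect_true(all((sch$executed == sch$optimal) == !sch$is_error))
  sch0 <- schedule_trials(w, 50, 0, seed = 11)
  expect_true(all(sch0$executed == sch0$optimal))
  sch5 <- schedule_trials(w, 400, 0.5, seed = 12)
  expect_equal(sum(sch5$is_error), 200)
  expect_identical(schedule_trials(w, 30, 0.3, seed = 13),
                   schedule_trials(w, 30, 0.3, seed = 13))
})
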