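#' Discretized 3-D navigation world
#'
#' The navigation task reduced to the level at which the reinforcement
#' learning problem is defined: a 3-D grid (default 21 x 21 x 11 cells)
#' with six unit moves (left/right = -x/+x, forward/backward = +y/-y,
#' down/up = -z/+z), an obstacle wall between start and goal side, five
#' laser distance sensors, sparse reward 1 at the goal, and an episode cap
#' of `max_steps` steps. Collisions (moves into blocked cells or outside
#' the grid) leave the agent in place and are non-terminal by default.
#'
#' The wall spans the full x extent at the middle y plane, rising from the
#' floor to a little over half the grid height, so the agent must climb
#' over it. The start region is a 6 (y) x 11 (x) area at floor level on the
#' near side; the goal is sampled at floor level on the far side.
#' Observations are 8-dimensional: the three cell coordinates normalized to
#' \[0, 1\] (dividing by `dim - 1`) plus five laser readings (free cells
#' before the first obstacle along -x, +x, -y, +y, -z, divided by
#' `laser_max_range` and clipped to \[0, 1\]).
#'
#' The returned object is an R environment (mutable): [world_reset()] and
#' [world_step()] update it in place, as conventional episodic-control
#' interfaces do.
#'
#' @param dims integer length-3 grid dimensions.
#' @param wall logical; build the obstacle wall.
#' @param laser_max_range laser range in cells.
#' @param max_steps episode step cap.
#' @param collision_terminal end the episode on collision.
#' @return an object of classes `grid_world`/`environment`.
#' @export
grid_world <- function(dims = c(21, 21, 11), wall = TRUE,
                       laser_max_range = 5, max_steps = 160,
                       collision_terminal = FALSE) {
  stopifnot(length(dims) == 3, all(dims >= 3))
  w <- new.env(parent = emptyenv())
  w$dims <- as.integer(dims)
  w$blocked <- array(FALSE, dim = dims)
  w$wall_y <- NA_integer_
  if (wall) {
    w$wall_y <- as.integer(ceiling(dims[2] / 2))
    top <- max(1L, round(dims[3] * 6 / 11))
    w$blocked[, w$wall_y, seq_len(top)] <- TRUE
  }
  nx <- dims[1]
  sx0 <- max(1L, (nx - 11L) %/% 2L + 1L)
  y_near <- if (is.na(w$wall_y)) dims[2] else w$wall_y - 1L
  w$start_region <- list(x = sx0:min(nx, sx0 + 10L),
                         y = seq_len(max(1L, min(6L, y_near))),
                         z = 1L)
  gy0 <- if (is.na(w$wall_y)) max(1L, dims[2] - 5L) else w$wall_y + 1L
  w$goal_region <- list(x = seq_len(nx), y = gy0:dims[2], z = 1L)
  w$laser_max_range <- laser_max_range
  w$max_steps <- as.integer(max_steps)
  w$collision_terminal <- collision_terminal
  w$agent <- NULL; w$goal <- NULL; w$dist <- NULL
  w$step_count <- 0L; w$done <- TRUE
  class(w) <- c("grid_world", "environment")
  w
}

#' @export
print.grid_world <- function(x, ...) {
  cat(sprintf("<grid_world %s, wall at y=%s, max %d steps>\n",
              paste(x$dims, collapse = "x"),
              ifelse(is.na(x$wall_y), "none", x$wall_y), x$max_steps))
  invisible(x)
}

# action deltas: left, right, forward, backward, down, up
.action_deltas <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 1, 0),
                        c(0, -1, 0), c(0, 0, -1), c(0, 0, 1))

#' Action labels of the six unit moves
#' @return character vector of length 6 in action-index order.
#' @export
action_labels <- function()
  c("left", "right", "forward", "backward", "down", "up")

cell_ok <- function(world, p)
  all(p >= 1L) && all(p <= world$dims) && !world$blocked[p[1], p[2], p[3]]

cell_id <- function(world, p)
  p[1] + world$dims[1] * (p[2] - 1L + world$dims[2] * (p[3] - 1L))

#' Laser distance readings
#'
#' Counts free cells before the first blocked cell or boundary along the
#' five sensor rays (-x, +x, -y, +y, -z), divides by the laser range and
#' clips to \[0, 1\].
#'
#' @param world a [grid_world()].
#' @param position integer cell (defaults to the agent).
#' @return numeric vector of 5 readings in \[0, 1\].
#' @export
lasers <- function(world, position = world$agent) {
  out <- numeric(5)
  for (r in 1:5) {
    d <- .action_deltas[c(1, 2, 4, 3, 5)[r], ]  # -x, +x, -y, +y, -z
    free <- 0L
    p <- position
    while (free < world$laser_max_range) {
      p <- p + d
      if (!cell_ok(world, p)) break
      free <- free + 1L
    }
    out[r] <- free / world$laser_max_range
  }
  pmin(out, 1)
}

# 8-dimensional observation: normalized position + lasers.
observe <- function(world, position = world$agent)
  c((position - 1) / (world$dims - 1), lasers(world, position))

#' Reset the world for a new episode
#'
#' Samples the agent start uniformly in the start region; the goal is
#' sampled uniformly in the goal region on the first reset (or when
#' `new_goal = TRUE`) and then stays fixed for the run, as in the original
#' task: the goal changes between runs, the start changes between
#' episodes. The observation carries no goal coordinates, so a fixed goal
#' per run is what makes the task learnable from the 8-dimensional state.
#' Pairs are resampled (up to `max_tries`) until a path exists; the step
#' counter is reset. Uses the current RNG stream (wrap in a seeded context
#' for reproducibility).
#'
#' @param world a [grid_world()].
#' @param new_goal resample the goal as well.
#' @param max_tries resampling bound before an error is raised.
#' @return the 8-dimensional observation of the start state, invisibly
#'   also stored in the world.
#' @export
world_reset <- function(world, new_goal = is.null(world$goal),
                        max_tries = 100) {
  for (k in seq_len(max_tries)) {
    s <- c(sample(world$start_region$x, 1), sample(world$start_region$y, 1),
           sample(world$start_region$z, 1))
    if (new_goal || is.null(world$goal)) {
      g <- c(sample(world$goal_region$x, 1), sample(world$goal_region$y, 1),
             sample(world$goal_region$z, 1))
      if (!cell_ok(world, g)) next
      dist <- bfs_dist(world, g)
    } else {
      g <- world$goal; dist <- world$dist
    }
    if (!cell_ok(world, s) || all(s == g)) next
    if (is.finite(dist[cell_id(world, s)])) {
      world$agent <- s; world$goal <- g; world$dist <- dist
      world$step_count <- 0L; world$done <- FALSE
      return(observe(world))
    }
  }
  stop("no feasible (start, goal) pair found")
}

#' Execute one action
#'
#' Moves the agent by one cell. Moves into blocked cells or outside the
#' grid are collisions: the agent stays in place. Reaching the goal yields
#' sparse reward 1 and ends the episode; the episode also ends when
#' `max_steps` is reached. All other rewards are 0.
#'
#' @param world a [grid_world()] (after [world_reset()]).
#' @param action integer action index 1–6 (see [action_labels()]).
#' @return a `transition` list: `state`, `action`, `reward`, `next_state`,
#'   `done`, `collision`, `success`.
#' @export
world_step <- function(world, action) {
  if (world$done) stop("episode is done; call world_reset()")
  if (!action %in% 1:6) stop("action index must be in 1..6")
  s_obs <- observe(world)
  target <- world$agent + .action_deltas[action, ]
  collision <- !cell_ok(world, target)
  if (!collision) world$agent <- target
  success <- !collision && all(world$agent == world$goal)
  world$step_count <- world$step_count + 1L
  # `terminal` marks true task termination; `done` additionally includes
  # the step-cap timeout, which ends the episode but is not a state of
  # the task itself (a value learner must keep bootstrapping through it)
  terminal <- success || (collision && world$collision_terminal)
  world$done <- terminal || world$step_count >= world$max_steps
  tr <- list(state = s_obs, action = action,
             reward = as.numeric(success), next_state = observe(world),
             done = world$done, terminal = terminal,
             collision = collision, success = success)
  class(tr) <- "transition"
  tr
}

#' Distance-shaped reward
#'
#' The sparse goal reward plus a negative term proportional to the
#' Euclidean distance between the normalized position and the normalized
#' goal — the richer baseline reward formulation.
#'
#' @param world a [grid_world()].
#' @param position integer cell (defaults to the agent).
#' @param gain positive scaling of the distance penalty.
#' @return numeric reward.
#' @export
rich_reward <- function(world, position = world$agent, gain = 1) {
  p <- (position - 1) / (world$dims - 1)
  g <- (world$goal - 1) / (world$dims - 1)
  as.numeric(all(position == world$goal)) - gain * sqrt(sum((p - g)^2))
}

# Breadth-first-search distance field from `from` over unblocked cells
# (exact shortest paths under unit-cost 6-connectivity).
bfs_dist <- function(world, from) {
  n <- prod(world$dims)
  dist <- rep(Inf, n)
  queue <- integer(n)
  head <- 1L; tail <- 1L
  id0 <- cell_id(world, from)
  dist[id0] <- 0
  queue[tail] <- id0; tail <- tail + 1L
  dx <- world$dims[1]; dxy <- world$dims[1] * world$dims[2]
  while (head < tail) {
    cur <- queue[head]; head <- head + 1L
    z <- (cur - 1L) %/% dxy
    rem <- cur - 1L - z * dxy
    y <- rem %/% dx
    x <- rem - y * dx
    p <- c(x + 1L, y + 1L, z + 1L)
    for (a in 1:6) {
      q <- p + .action_deltas[a, ]
      if (!cell_ok(world, q)) next
      qid <- cell_id(world, q)
      if (is.infinite(dist[qid])) {
        dist[qid] <- dist[cur] + 1
        queue[tail] <- qid; tail <- tail + 1L
      }
    }
  }
  dist
}

#' A* shortest path on the grid
#'
#' A* under 6-connected unit moves with the (admissible) Manhattan-distance
#' heuristic; ties on f are broken towards larger g (deeper nodes) and then
#' insertion order, and neighbors are expanded in fixed action-index order,
#' making the returned path deterministic.
#'
#' @param world a [grid_world()].
#' @param start,goal integer cells.
#' @return list with `length` (number of moves; 0 if start == goal, `Inf`
#'   if unreachable) and `actions` (integer action sequence).
#' @export
astar_path <- function(world, start, goal = world$goal) {
  if (!cell_ok(world, start)) stop("start cell is blocked")
  if (all(start == goal)) return(list(length = 0, actions = integer(0)))
  n <- prod(world$dims)
  g_sc <- rep(Inf, n); f_sc <- rep(Inf, n)
  came_act <- integer(n); came_from <- integer(n)
  open <- rep(FALSE, n); closed <- rep(FALSE, n)
  order_in <- rep(Inf, n); counter <- 0
  heur <- function(p) sum(abs(p - goal))
  dx <- world$dims[1]; dxy <- world$dims[1] * world$dims[2]
  unpack <- function(id) {
    z <- (id - 1L) %/% dxy
    rem <- id - 1L - z * dxy
    y <- rem %/% dx
    c(rem - y * dx + 1L, y + 1L, z + 1L)
  }
  sid <- cell_id(world, start); gid <- cell_id(world, goal)
  g_sc[sid] <- 0; f_sc[sid] <- heur(start)
  open[sid] <- TRUE; order_in[sid] <- counter
  while (any(open)) {
    oi <- which(open)
    # min f, tie-break: larger g, then earlier insertion
    key <- f_sc[oi] * n * 10 - g_sc[oi] + order_in[oi] / (n * 10)
    cur <- oi[which.min(key)]
    if (cur == gid) break
    open[cur] <- FALSE; closed[cur] <- TRUE
    p <- unpack(cur)
    for (a in 1:6) {
      q <- p + .action_deltas[a, ]
      if (!cell_ok(world, q)) next
      qid <- cell_id(world, q)
      if (closed[qid]) next
      cand <- g_sc[cur] + 1
      if (cand < g_sc[qid]) {
        g_sc[qid] <- cand
        f_sc[qid] <- cand + heur(q)
        came_act[qid] <- a; came_from[qid] <- cur
        if (!open[qid]) {
          open[qid] <- TRUE
          counter <- counter + 1
          order_in[qid] <- counter
        }
      }
    }
  }
  if (is.infinite(g_sc[gid])) return(list(length = Inf, actions = integer(0)))
  acts <- integer(0)
  cur <- gid
  while (cur != sid) {
    acts <- c(came_act[cur], acts)
    cur <- came_from[cur]
  }
  list(length = length(acts), actions = acts)
}

#' Optimal action at a cell (the "green arrow")
#'
#' The first move of a shortest obstacle-avoiding path from `position` to
#' the goal, with ties between equally short first moves broken by the
#' fixed action-index order. `method = "astar"` derives it from [astar_path()]
#' path lengths; `method = "bfs"` uses the cached breadth-first distance
#' field of the current episode (identical result, used by inner loops).
#'
#' @param world a [grid_world()].
#' @param position integer cell (defaults to the agent).
#' @param method `"astar"` or `"bfs"`.
#' @return integer action index in 1..6, or 0 if already at the goal
#'   (zero-length path).
#' @export
optimal_action <- function(world, position = world$agent,
                           method = c("astar", "bfs")) {
  method <- match.arg(method)
  if (all(position == world$goal)) return(0L)
  if (method == "bfs") {
    dist <- world$dist
    if (is.null(dist)) dist <- bfs_dist(world, world$goal)
    d0 <- dist[cell_id(world, position)]
    if (is.infinite(d0)) stop("goal unreachable from position")
    for (a in 1:6) {
      q <- position + .action_deltas[a, ]
      if (cell_ok(world, q) && dist[cell_id(world, q)] == d0 - 1)
        return(a)
    }
    stop("inconsistent distance field")
  }
  best <- astar_path(world, position)
  if (is.infinite(best$length)) stop("goal unreachable from position")
  # first action, ties by action order: accept any action whose successor
  # lies at shortest-path distance length - 1
  for (a in 1:6) {
    q <- position + .action_deltas[a, ]
    if (!cell_ok(world, q)) next
    if (all(q == world$goal)) return(a)
    if (astar_path(world, q)$length == best$length - 1) return(a)
  }
  stop("no optimal action found")
}

#' Schedule a sequence of observed robot actions
#'
#' Drives the world through `n` single robot movements of which exactly
#' `round(n * error_fraction)` (fixed-count, uniformly shuffled) are
#' erroneous: the executed action is the optimal action for correct trials
#' and a uniformly drawn non-optimal action for error trials. Episodes are
#' reset when they end. The schedule supplies the event labels of the
#' synthetic EEG and the calibration protocol.
#'
#' @param world a [grid_world()].
#' @param n number of movements.
#' @param error_fraction fraction of erroneous movements.
#' @param seed integer seed.
#' @return data.frame with one row per movement: `trial`, `is_error`,
#'   `optimal`, `executed`, plus the observation in columns `obs1..obs8`.
#' @export
schedule_trials <- function(world, n, error_fraction, seed = 1) {
  stop_if_not_scalar_prob(error_fraction, "error_fraction")
  n_err <- round(n * error_fraction)
  with_seed(seed, {
    flags <- sample(c(rep(TRUE, n_err), rep(FALSE, n - n_err)))
    world_reset(world)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      opt <- optimal_action(world, method = "bfs")
      act <- if (flags[i]) sample(setdiff(1:6, opt), 1) else opt
      obs <- observe(world)
      tr <- world_step(world, act)
      rows[[i]] <- c(trial = i, is_error = flags[i], optimal = opt,
                     executed = act, stats::setNames(obs, paste0("obs", 1:8)))
      if (tr$done) world_reset(world)
    }
    as.data.frame(do.call(rbind, rows))
  })
}
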