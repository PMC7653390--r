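#' Run one simulation
#'
#' Fixed-step simulation loop. Each step, agents are visited in a seeded
#' random order; every agent runs perception, then cognition, then the
#' behaviour matching its self-category: `TARGET_ORIENTED` agents take a
#' locomotion step, `WAIT` agents stand still, and `COOPERATIVE` agents
#' attempt a position swap with an adjacent cooperative partner (falling back
#' to a locomotion step, or standing, when none is available or the agent is
#' on swap cooldown). Speed histories are updated from realised
#' displacements, every position is recorded each step, and the run ends when
#' the walker reaches the target or the horizon `t_max` is exceeded (which
#' yields `crossed = FALSE`, not an error). Deterministic for a fixed seed.
#'
#' The walker's free-flow speed is drawn once per run from the scenario's
#' speed distribution, and its start x is jittered uniformly in
#' `+/- jitter_x` around the roster position.
#'
#' @param scenario a `ccoop_scenario`.
#' @param seed integer RNG seed for the run.
#' @param psychology enable the perception/cognition/behaviour layer
#'   (disable to reproduce the bare-locomotion deadlock).
#' @param locomotion `"osm"` (optimal-steps-style, default) or
#'   `"social-force"` (baseline).
#' @param jitter_x half-width (m) of the uniform jitter on the walker start x.
#' @return list with `trajectory` (a `ccoop_trajectory` data frame:
#'   `timeStep`, `pedestrianId`, `x`, `y`, `selfCategory`, frame interval
#'   `dt` as attribute) and `summary` (one-row data frame: `crossed`,
#'   `duration_in_area`, `mean_speed_inside`, `mean_speed_outside`,
#'   `n_swaps`, `seed`).
#' @export
run_simulation <- function(scenario, seed = scenario$params$seed,
                           psychology = TRUE,
                           locomotion = c("osm", "social-force"),
                           jitter_x = 0) {
  stopifnot(inherits(scenario, "ccoop_scenario"))
  locomotion <- match.arg(locomotion)
  p <- scenario$params
  set.seed(as.integer(seed))

  ag <- scenario$agents
  n <- nrow(ag)
  walker <- which(ag$role == "walker")
  if (jitter_x > 0 && length(walker) > 0) {
    ag$x[walker] <- ag$x[walker] + stats::runif(length(walker), -jitter_x, jitter_x)
  }
  if (length(walker) > 0) {
    ag$free_flow_speed[walker] <- sample_free_flow_speed(
      length(walker), p$v_free_mean, p$v_free_sd
    )
  }
  ag$self_category <- ifelse(ag$role == "walker", "TARGET_ORIENTED", "WAIT")
  ag$vx <- 0; ag$vy <- 0
  cooldown <- integer(n)

  n_steps <- floor(p$t_max / p$dt)
  hist_mat <- matrix(NA_real_, nrow = n, ncol = 0)  # speeds, one column per step
  frames_x <- matrix(NA_real_, nrow = n, ncol = n_steps + 1)
  frames_y <- matrix(NA_real_, nrow = n, ncol = n_steps + 1)
  frames_cat <- matrix(NA_character_, nrow = n, ncol = n_steps + 1)
  frames_x[, 1] <- ag$x; frames_y[, 1] <- ag$y; frames_cat[, 1] <- ag$self_category

  crossed <- FALSE
  n_swaps <- 0L
  last_frame <- 1L

  for (k in seq_len(n_steps)) {
    prev_x <- ag$x; prev_y <- ag$y
    acted <- logical(n)
    order_i <- sample.int(n)
    for (i in order_i) {
      if (acted[i]) next
      agent <- c(as.list(ag[i, ]), list(
        speed_history = if (ncol(hist_mat) > 0) hist_mat[i, ] else numeric(0),
        swap_cooldown = cooldown[i]
      ))
      pct <- perceive(agent, ag, p$r)
      if (psychology) {
        ag$self_category[i] <- update_cognition(agent, pct, p)
        agent$self_category <- ag$self_category[i]
      }
      cat_i <- ag$self_category[i]
      has_target <- ag$role[i] == "walker"
      if (cat_i == "WAIT") {
        acted[i] <- TRUE
        next
      }
      if (cat_i == "COOPERATIVE" && psychology && cooldown[i] == 0L) {
        partner <- find_swap_candidate(
          agent, pct, ag,
          target = if (has_target) scenario$target else NULL,
          max_reach = p$swap_reach
        )
        if (!is.na(partner)) {
          j <- match(partner, ag$id)
          if (cooldown[j] == 0L) {
            res <- execute_swap(
              a = list(x = ag$x[i], y = ag$y[i], self_category = ag$self_category[i]),
              b = list(x = ag$x[j], y = ag$y[j], self_category = ag$self_category[j]),
              r = p$swap_reach, dt = p$dt
            )
            if (res$swapped) {
              ag$x[i] <- res$a$x; ag$y[i] <- res$a$y
              ag$x[j] <- res$b$x; ag$y[j] <- res$b$y
              cooldown[i] <- 2L  # decremented at end of this step -> blocks next step
              cooldown[j] <- 2L
              acted[i] <- TRUE; acted[j] <- TRUE
              n_swaps <- n_swaps + 1L
              next
            }
          }
        }
        # no swap available: fall through to locomotion (or stand, for waiters)
      }
      if (has_target) {
        others <- cbind(ag$x[-i], ag$y[-i])
        if (locomotion == "osm") {
          newp <- osm_next_position(
            list(x = ag$x[i], y = ag$y[i], free_flow_speed = ag$free_flow_speed[i]),
            others, scenario
          )
          ag$x[i] <- newp[1]; ag$y[i] <- newp[2]
        } else {
          res <- social_force_step(
            list(x = ag$x[i], y = ag$y[i], vx = ag$vx[i], vy = ag$vy[i],
                 free_flow_speed = ag$free_flow_speed[i]),
            others, scenario
          )
          ag$x[i] <- res$position[1]; ag$y[i] <- res$position[2]
          ag$vx[i] <- res$velocity[1]; ag$vy[i] <- res$velocity[2]
        }
      }
      acted[i] <- TRUE
    }
    speeds <- sqrt((ag$x - prev_x)^2 + (ag$y - prev_y)^2) / p$dt
    hist_mat <- cbind(hist_mat, speeds)
    if (ncol(hist_mat) > p$n_history) {
      hist_mat <- hist_mat[, (ncol(hist_mat) - p$n_history + 1):ncol(hist_mat),
                           drop = FALSE]
    }
    cooldown <- pmax(cooldown - 1L, 0L)
    last_frame <- k + 1L
    frames_x[, last_frame] <- ag$x
    frames_y[, last_frame] <- ag$y
    frames_cat[, last_frame] <- ag$self_category
    if (length(walker) > 0 &&
        all(region_contains(scenario$target, cbind(ag$x[walker], ag$y[walker])))) {
      crossed <- TRUE
      break
    }
  }

  traj <- data.frame(
    timeStep = rep(seq_len(last_frame), each = n),
    pedestrianId = rep(ag$id, times = last_frame),
    x = as.vector(frames_x[, seq_len(last_frame)]),
    y = as.vector(frames_y[, seq_len(last_frame)]),
    selfCategory = as.vector(frames_cat[, seq_len(last_frame)]),
    stringsAsFactors = FALSE
  )
  traj <- traj[order(traj$timeStep, traj$pedestrianId), ]
  rownames(traj) <- NULL
  attr(traj, "frame_interval") <- p$dt
  class(traj) <- c("ccoop_trajectory", "data.frame")

  summary <- summarize_run(traj, scenario, crossed, n_swaps, seed)
  list(trajectory = traj, summary = summary)
}

summarize_run <- function(traj, scenario, crossed, n_swaps, seed) {
  p <- scenario$params
  walker_ids <- scenario$agents$id[scenario$agents$role == "walker"]
  if (length(walker_ids) == 0) {
    return(data.frame(crossed = crossed, duration_in_area = NA_real_,
                      mean_speed_inside = NA_real_, mean_speed_outside = NA_real_,
                      n_swaps = n_swaps, seed = as.integer(seed)))
  }
  wt <- traj[traj$pedestrianId == walker_ids[1], ]
  rs <- region_stats(wt, scenario$waiting_area, p$dt)
  data.frame(
    crossed = crossed,
    duration_in_area = rs$duration_in_area,
    mean_speed_inside = rs$v_inside,
    mean_speed_outside = rs$v_outside,
    n_swaps = n_swaps,
    seed = as.integer(seed)
  )
}

#' Run a batch of simulations
#'
#' Run `i` (1-based) uses seed `base_seed + i` and a walker start x jittered
#' uniformly in `+/- jitter_x`; waiting-crowd positions are identical across
#' runs. Run `i` of a batch is bitwise identical to
#' `run_simulation(scenario, base_seed + i, jitter_x = jitter_x)`.
#'
#' @param scenario a `ccoop_scenario`.
#' @param n_runs number of runs (>= 1).
#' @param base_seed integer; run i uses `base_seed + i`.
#' @param jitter_x half-width (m) of the uniform walker start jitter.
#' @param psychology,locomotion forwarded to [run_simulation()].
#' @return data frame with one [run_simulation()] summary row per run.
#' @export
run_batch <- function(scenario, n_runs = 100, base_seed = 0, jitter_x = 0.3,
                      psychology = TRUE, locomotion = "osm") {
  stopifnot(n_runs >= 1)
  out <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    out[[i]] <- run_simulation(
      scenario, seed = base_seed + i, psychology = psychology,
      locomotion = locomotion, jitter_x = jitter_x
    )$summary
  }
  do.call(rbind, out)
}
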