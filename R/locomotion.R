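#' Locomotion utility weights
#'
#' Weights of the step-disc utility used by the optimal-steps-style chooser:
#' `u(p) = -w_target * d_target(p) - w_agent * sum(exp(-gap_i / range_agent))
#' - w_obstacle * sum(exp(-gap_o / range_obstacle))`, where `gap` is the
#' surface-to-surface distance. The target term uses Euclidean distance to
#' the nearest point of the target region (the corridor is convex, so the
#' geodesic equals the Euclidean distance). Defaults are tuned only so that
#' the deadlock and crossing properties hold: repulsion shapes the path but
#' never overrides the hard non-overlap constraint, and is weak enough that
#' retreating from the crowd face never pays off against the target term.
#'
#' @param w_target,w_agent,w_obstacle non-negative dimensionless weights.
#' @param range_agent,range_obstacle repulsion e-folding ranges (m).
#' @return a list of class `ccoop_weights`.
#' @export
utility_weights <- function(w_target = 1, w_agent = 0.08, w_obstacle = 0.3,
                            range_agent = 0.3, range_obstacle = 0.3) {
  w <- list(w_target = w_target, w_agent = w_agent, w_obstacle = w_obstacle,
            range_agent = range_agent, range_obstacle = range_obstacle)
  if (any(vapply(w, function(x) !is.numeric(x) || length(x) != 1 || x < 0, logical(1)))) {
    stop("all weights must be single non-negative numbers")
  }
  if (range_agent <= 0 || range_obstacle <= 0) stop("repulsion ranges must be > 0")
  structure(w, class = "ccoop_weights")
}

#' Sample free-flow walking speeds
#'
#' Draws from a normal distribution with mean 1.34 m/s and s.d. 0.26 m/s
#' (the canonical empirical free-flow speed), truncated by rejection to
#' [0.5, 2.2] m/s. Uses the current RNG state, so draws are reproducible
#' under a fixed seed.
#'
#' @param n number of draws.
#' @param mean,sd distribution parameters (m/s).
#' @param lower,upper truncation bounds (m/s).
#' @return numeric vector of speeds.
#' @export
sample_free_flow_speed <- function(n = 1, mean = 1.34, sd = 0.26,
                                   lower = 0.5, upper = 2.2) {
  stopifnot(n >= 0, sd > 0, lower < upper)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(max(n - length(out), 1), mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Candidate footholds on the step disc
#'
#' 16 directions x 4 radii plus staying put, on a disc of radius `max_step`
#' around `pos`. Candidates are ordered so that deterministic tie-breaking
#' (smallest angle to the target direction, then smallest radius) falls out
#' of taking the first maximum.
#'
#' @param pos length-2 position.
#' @param max_step disc radius (m).
#' @param to_target unit-ish vector toward the target used to order candidates.
#' @return matrix with columns x, y; first row is `pos` itself.
#' @keywords internal
osm_candidates <- function(pos, max_step, to_target = c(0, 1)) {
  angles <- seq(0, 2 * pi, length.out = 17)[-17]
  base <- atan2(to_target[2], to_target[1])
  # order by absolute angular distance to the target direction
  rel <- ((angles - base + pi) %% (2 * pi)) - pi
  ord <- order(abs(rel), rel)  # tie (+/- same angle): deterministic sign rule
  radii <- max_step * (1:4) / 4
  grid <- expand.grid(r = radii, a = angles[ord])
  # ordering: for each angle (nearest to target first), radii ascending
  grid <- grid[order(match(grid$a, angles[ord]), grid$r), ]
  cand <- cbind(pos[1] + grid$r * cos(grid$a), pos[2] + grid$r * sin(grid$a))
  rbind(matrix(pos, ncol = 2), cand)
}

osm_utility <- function(p, target, neighbours, obstacles, weights, body_radius) {
  u <- -weights$w_target * region_distance(p, target)
  if (!is.null(neighbours) && nrow(neighbours) > 0) {
    gap <- sqrt((neighbours[, 1] - p[1])^2 + (neighbours[, 2] - p[2])^2) -
      2 * body_radius
    u <- u - weights$w_agent * sum(exp(-pmax(gap, 0) / weights$range_agent))
  }
  for (obs in obstacles) {
    gap <- region_distance(p, obs) - body_radius
    u <- u - weights$w_obstacle * exp(-max(gap, 0) / weights$range_obstacle)
  }
  u
}

# Admissibility of moving from `from` to `p`: the agent's disc must stay
# inside the domain, clear of obstacles, and at least one body diameter from
# every neighbour centre ALONG THE WHOLE SWEPT SEGMENT (an endpoint-only
# check lets a long stride tunnel between frames at high step lengths).
osm_admissible <- function(p, neighbours, obstacles, domain, body_radius,
                           from = p) {
  b <- rect_bounds(domain)
  if (p[1] < b["xmin"] + body_radius || p[1] > b["xmax"] - body_radius ||
      p[2] < b["ymin"] + body_radius || p[2] > b["ymax"] - body_radius) {
    return(FALSE)
  }
  if (!is.null(neighbours) && nrow(neighbours) > 0) {
    lim <- 2 * body_radius - 1e-9
    for (j in seq_len(nrow(neighbours))) {
      if (point_seg_dist(neighbours[j, ], from, p) < lim) return(FALSE)
    }
  }
  step_len <- sqrt(sum((p - from)^2))
  if (step_len > 0) {
    n_chk <- max(2L, ceiling(step_len / (body_radius / 2)) + 1L)
    ts <- seq(0, 1, length.out = n_chk)
    pts <- cbind(from[1] + ts * (p[1] - from[1]), from[2] + ts * (p[2] - from[2]))
  } else {
    pts <- matrix(p, ncol = 2)
  }
  for (obs in obstacles) {
    if (any(region_distance(pts, obs) < body_radius - 1e-9)) return(FALSE)
  }
  TRUE
}

#' Optimal-steps-style next position
#'
#' Picks the utility-maximising admissible foothold on a disc of radius
#' `free_flow_speed * dt` around the agent. Staying put is always a
#' candidate, and the agent only moves on a strict utility improvement, so a
#' fully blocked agent stays (recorded speed 0) rather than erroring. A
#' foothold is admissible when the agent's disc stays inside the domain,
#' clear of every obstacle, and at least one body diameter from every
#' neighbour centre.
#'
#' @param agent list with `x`, `y` and `free_flow_speed` (or a one-row data
#'   frame with those columns).
#' @param neighbours matrix/data frame of neighbour positions (columns x, y);
#'   may be NULL or empty.
#' @param scenario a `ccoop_scenario` (supplies target, obstacles, domain,
#'   body radius).
#' @param weights a `ccoop_weights`.
#' @param dt step interval (s).
#' @param target optional override of the target region.
#' @return length-2 numeric: the chosen next position.
#' @export
osm_next_position <- function(agent, neighbours, scenario, weights = scenario$weights,
                              dt = scenario$params$dt, target = scenario$target) {
  pos <- c(agent$x, agent$y)
  max_step <- agent$free_flow_speed * dt
  nb <- normalize_positions(neighbours)
  to_target <- region_centroid(target) - pos
  cand <- osm_candidates(pos, max_step, to_target)
  best <- pos
  best_u <- osm_utility(pos, target, nb, scenario$obstacles, weights,
                        scenario$params$body_radius)
  stay_u <- best_u
  for (i in 2:nrow(cand)) {
    p <- cand[i, ]
    if (!osm_admissible(p, nb, scenario$obstacles, scenario$domain_bounds,
                        scenario$params$body_radius, from = pos)) next
    u <- osm_utility(p, target, nb, scenario$obstacles, weights,
                     scenario$params$body_radius)
    if (u > best_u + 1e-12) {
      best <- p
      best_u <- u
    }
  }
  if (best_u <= stay_u + 1e-12) pos else best
}

normalize_positions <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) x <- cbind(x$x, x$y)
  x <- as.matrix(x)
  if (nrow(x) == 0) return(NULL)
  x
}

#' Social-force baseline step
#'
#' Classic driving-force-plus-exponential-repulsion integration, provided as
#' the baseline that exhibits the high-density deadlock. The driving force
#' relaxes the velocity toward `free_flow_speed` in the target direction with
#' time constant `tau`; agents and obstacles repel along the line of centres
#' with magnitude `A * exp(-gap / B)`. Integration uses Euler substeps of at
#' most 0.05 s for stability, the speed is capped at `free_flow_speed`, and
#' any substep that would overlap a neighbour or an obstacle is shortened
#' (same hard non-overlap rule as the optimal-steps chooser).
#'
#' @param agent list with `x`, `y`, `vx`, `vy`, `free_flow_speed` (missing
#'   velocity components default to 0).
#' @param neighbours neighbour positions (columns x, y); may be NULL.
#' @param scenario a `ccoop_scenario`.
#' @param dt step interval (s).
#' @param tau relaxation time (s).
#' @param A,B repulsion strength (m/s^2) and range (m).
#' @param target optional override of the target region.
#' @return list with `position` (length-2) and `velocity` (length-2).
#' @export
social_force_step <- function(agent, neighbours, scenario, dt = scenario$params$dt,
                              tau = 0.5, A = 5, B = 0.3, target = scenario$target) {
  pos <- c(agent$x, agent$y)
  vel <- c(agent$vx %||% 0, agent$vy %||% 0)
  v0 <- agent$free_flow_speed
  nb <- normalize_positions(neighbours)
  rb <- scenario$params$body_radius
  n_sub <- max(1L, ceiling(dt / 0.05))
  h <- dt / n_sub
  for (s in seq_len(n_sub)) {
    dirv <- region_centroid(target) - pos
    nd <- sqrt(sum(dirv^2))
    e_t <- if (nd > 1e-12) dirv / nd else c(0, 0)
    f <- (v0 * e_t - vel) / tau
    if (!is.null(nb)) {
      for (j in seq_len(nrow(nb))) {
        away <- pos - nb[j, ]
        d <- sqrt(sum(away^2))
        if (d < 1e-12) next
        gap <- d - 2 * rb
        f <- f + A * exp(-max(gap, 0) / B) * (away / d)
      }
    }
    for (obs in scenario$obstacles) {
      d <- region_distance(pos, obs)
      if (d < 1e-12) next
      # push away from the nearest obstacle point, approximated by finite differences
      g <- c(
        region_distance(pos + c(1e-4, 0), obs) - region_distance(pos - c(1e-4, 0), obs),
        region_distance(pos + c(0, 1e-4), obs) - region_distance(pos - c(0, 1e-4), obs)
      ) / 2e-4
      gn <- sqrt(sum(g^2))
      if (gn > 1e-9) {
        f <- f + A * exp(-max(d - rb, 0) / B) * (g / gn)
      }
    }
    vel <- vel + h * f
    spd <- sqrt(sum(vel^2))
    if (spd > v0) vel <- vel * (v0 / spd)
    step <- h * vel
    new_pos <- pos + step
    # hard non-overlap: shrink the substep until admissible
    shrink <- 1
    while (shrink > 1e-3 &&
           !osm_admissible(new_pos, nb, scenario$obstacles,
                           scenario$domain_bounds, rb, from = pos)) {
      shrink <- shrink / 2
      new_pos <- pos + shrink * step
    }
    if (shrink <= 1e-3 &&
        !osm_admissible(new_pos, nb, scenario$obstacles,
                        scenario$domain_bounds, rb, from = pos)) {
      new_pos <- pos
      vel <- c(0, 0)
    }
    pos <- new_pos
  }
  list(position = pos, velocity = vel)
}
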