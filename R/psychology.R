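#' Self-categories
#'
#' An agent's active self-category governs its behaviour repertoire:
#' `TARGET_ORIENTED` agents step toward their target, `WAIT` agents stand
#' still, and `COOPERATIVE` agents offer/seek position swaps. These are the
#' only reachable categories.
#'
#' @export
SELF_CATEGORIES <- c("TARGET_ORIENTED", "COOPERATIVE", "WAIT")

#' Perception sub-layer: neighbours within the search radius
#'
#' Returns exactly the agents whose centre lies within distance `r` of the
#' observer (closed ball: a neighbour at distance exactly `r` is included),
#' the observer excluded, sorted by distance then id.
#'
#' @param agent observer: a list or one-row data frame with `id`, `x`, `y`.
#' @param agents data frame of all agents with columns `id`, `x`, `y`.
#' @param r search radius (m), > 0.
#' @return a `ccoop_percept`: list with `observer_id`, `neighbour_ids`,
#'   `neighbour_positions` (matrix), `distances`.
#' @export
perceive <- function(agent, agents, r) {
  stopifnot(r > 0)
  d <- sqrt((agents$x - agent$x)^2 + (agents$y - agent$y)^2)
  keep <- which(agents$id != agent$id & d <= r)
  keep <- keep[order(d[keep], agents$id[keep])]
  structure(
    list(
      observer_id = agent$id,
      neighbour_ids = agents$id[keep],
      neighbour_positions = cbind(x = agents$x[keep], y = agents$y[keep]),
      distances = d[keep]
    ),
    class = "ccoop_percept"
  )
}

#' Cognition sub-layer: self-category switching
#'
#' Implements the cooperative-cognition rule. An agent whose speed over each
#' of the last `n_history` steps fell below `v_threshold` has "realised it
#' cannot move anymore" and switches to `COOPERATIVE`. Conversely, when the
#' mean of the last `n_history` speeds is at or above the threshold the agent
#' falls back to its role's default: `TARGET_ORIENTED` for a walker, `WAIT`
#' for a waiter. With fewer than `n_history` recorded speeds, or in the
#' intermediate regime, the category is unchanged. The rule reads only the
#' percept and the agent's own history -- no global state.
#'
#' @param agent list with `role` ("walker"/"waiter"), `self_category`, and
#'   `speed_history` (numeric vector, most recent last).
#' @param percept a `ccoop_percept` (unused by this shipped rule, which keys
#'   on the agent's own immobility; kept so drop-in cognition models receive
#'   the full perception output).
#' @param params a `ccoop_params` (uses `n_history`, `v_threshold`).
#' @return the new self-category (character scalar).
#' @export
update_cognition <- function(agent, percept, params) {
  n <- params$n_history
  h <- agent$speed_history
  h <- h[!is.na(h)]
  if (length(h) < n) return(agent$self_category)
  recent <- h[(length(h) - n + 1):length(h)]
  if (all(recent < params$v_threshold)) return("COOPERATIVE")
  if (mean(recent) >= params$v_threshold) {
    return(if (identical(agent$role, "walker")) "TARGET_ORIENTED" else "WAIT")
  }
  agent$self_category
}

#' Behaviour sub-layer: choose a swap partner
#'
#' Among the perceived neighbours that are themselves `COOPERATIVE`, strictly
#' closer to the agent's target than the agent, and within `max_reach`,
#' returns the id of the one minimising distance to the target; ties go to
#' the smaller id. `NA` when no such neighbour exists (e.g. the agent has no
#' target).
#'
#' @param agent list with `id`, `x`, `y`; must be `COOPERATIVE`.
#' @param percept a `ccoop_percept` for this agent.
#' @param agents data frame with `id`, `x`, `y`, `self_category`.
#' @param target the agent's target region, or NULL for none.
#' @param max_reach maximum partner distance (m); `Inf` means anywhere in the
#'   percept. A physical swap needs an adjacent partner, so the engine passes
#'   the `swap_reach` parameter here.
#' @return partner id (integer) or `NA_integer_`.
#' @export
find_swap_candidate <- function(agent, percept, agents, target, max_reach = Inf) {
  if (is.null(target)) return(NA_integer_)
  if (length(percept$neighbour_ids) == 0) return(NA_integer_)
  idx <- match(percept$neighbour_ids, agents$id)
  coop <- agents$self_category[idx] == "COOPERATIVE"
  within <- percept$distances <= max_reach
  d_agent <- region_distance(c(agent$x, agent$y), target)
  d_nb <- region_distance(cbind(agents$x[idx], agents$y[idx]), target)
  closer <- d_nb < d_agent - 1e-12
  ok <- which(coop & within & closer)
  if (length(ok) == 0) return(NA_integer_)
  ids <- percept$neighbour_ids[ok]
  ord <- order(d_nb[ok], ids)
  as.integer(ids[ord[1]])
}

#' Behaviour sub-layer: execute a position swap
#'
#' Two cooperative agents within mutual distance `r` exchange positions
#' exactly, within one simulation step; all other fields are preserved. Each
#' agent's instantaneous speed for the step is the swap displacement divided
#' by `dt`, and both agents carry a one-step swap cooldown. A precondition
#' violation rejects the swap and returns the agents unchanged with
#' `swapped = FALSE`.
#'
#' @param a,b agent lists with `x`, `y`, `self_category` (and any other
#'   fields, which are preserved).
#' @param r maximum mutual distance for a swap (m).
#' @param dt step interval (s) used to record the swap speed.
#' @return list with elements `a`, `b`, `swapped` (logical), `speed` (m/s,
#'   NA when rejected).
#' @export
execute_swap <- function(a, b, r, dt) {
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  if (!identical(a$self_category, "COOPERATIVE") ||
      !identical(b$self_category, "COOPERATIVE") || d > r) {
    return(list(a = a, b = b, swapped = FALSE, speed = NA_real_))
  }
  pa <- c(a$x, a$y)
  a$x <- b$x; a$y <- b$y
  b$x <- pa[1]; b$y <- pa[2]
  a$swap_cooldown <- 1L
  b$swap_cooldown <- 1L
  list(a = a, b = b, swapped = TRUE, speed = d / dt)
}
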