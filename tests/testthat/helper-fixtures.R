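# Shared test fixtures and independent brute-force oracles.

# Small scenario for engine tests: default study geometry unless overridden.
study_scenario <- function(dt = NULL, n_waiters = 13L) {
  params <- if (is.null(dt)) model_params() else model_params(dt = dt)
  build_reenactment_scenario(params, n_waiters = n_waiters)
}

# Brute-force pairwise distance matrix (oracle for spacing checks).
pairwise_min_dist <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(Inf)
  best <- Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      best <- min(best, sqrt(sum((pts[i, ] - pts[j, ])^2)))
    }
  }
  best
}

# Brute-force radius filter (oracle for perceive()).
brute_neighbours <- function(agent, agents, r) {
  ids <- c()
  for (k in seq_len(nrow(agents))) {
    if (agents$id[k] == agent$id) next
    d <- sqrt((agents$x[k] - agent$x)^2 + (agents$y[k] - agent$y)^2)
    if (d <= r) ids <- c(ids, agents$id[k])
  }
  if (length(ids) == 0) return(integer(0))
  d <- sqrt((agents$x - agent$x)^2 + (agents$y - agent$y)^2)
  as.integer(ids[order(d[match(ids, agents$id)], ids)])
}

# Brute-force swap-candidate rule (oracle for find_swap_candidate()).
brute_swap_candidate <- function(agent, agents, target, r, max_reach) {
  best_id <- NA_integer_
  best_d <- Inf
  d_self <- region_distance(c(agent$x, agent$y), target)
  for (k in seq_len(nrow(agents))) {
    if (agents$id[k] == agent$id) next
    dd <- sqrt((agents$x[k] - agent$x)^2 + (agents$y[k] - agent$y)^2)
    if (dd > r || dd > max_reach) next
    if (agents$self_category[k] != "COOPERATIVE") next
    dt_k <- region_distance(c(agents$x[k], agents$y[k]), target)
    if (dt_k >= d_self) next
    if (dt_k < best_d - 1e-12 ||
        (abs(dt_k - best_d) <= 1e-12 && agents$id[k] < best_id)) {
      best_d <- dt_k
      best_id <- agents$id[k]
    }
  }
  best_id
}

# Single-agent walker trajectory from a run.
walker_traj <- function(run, scenario) {
  wid <- scenario$agents$id[scenario$agents$role == "walker"][1]
  tr <- run$trajectory
  tr[tr$pedestrianId == wid, ]
}
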