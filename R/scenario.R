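#' Model parameters
#'
#' Bundles every tunable of the simulation. Defaults re-enact the crossing
#' study: a perception radius of 1 m, a 3-step speed history with a
#' cooperative-switch threshold of 0.2 m/s (far below free walking, above the
#' residual shuffling speed of an agent pressed against the crowd), a torso
#' radius of 0.195 m so that 14 agents at 5.30 ped/m^2 are geometrically
#' feasible, and a free-flow speed distribution with mean 1.34 m/s and
#' s.d. 0.26 m/s truncated to [0.5, 2.2]. The step interval dt plays the role of a stride
#' duration (a stepped locomotion model advances one stride per update);
#' its default is calibrated against the reported mean in-area crossing
#' duration of the re-enactment batch.
#'
#' @param dt simulation step interval (s).
#' @param r perception search radius (m).
#' @param n_history number of past steps in the speed history (>= 1).
#' @param v_threshold cooperative-switch speed threshold (m/s); must be below
#'   `v_free_mean`.
#' @param body_radius agent torso radius (m).
#' @param v_free_mean,v_free_sd free-flow speed distribution parameters (m/s).
#' @param swap_reach maximum centre distance at which a position swap is
#'   physically possible (m); at most `r`.
#' @param t_max simulation horizon (s).
#' @param seed default RNG seed for a run.
#' @return a validated list of class `ccoop_params`.
#' @export
model_params <- function(dt = 0.6, r = 1.0, n_history = 3, v_threshold = 0.2,
                         body_radius = 0.195, v_free_mean = 1.34,
                         v_free_sd = 0.26, swap_reach = 0.8, t_max = 60,
                         seed = 1L) {
  p <- list(
    dt = dt, r = r, n_history = as.integer(n_history),
    v_threshold = v_threshold, body_radius = body_radius,
    v_free_mean = v_free_mean, v_free_sd = v_free_sd,
    swap_reach = swap_reach, t_max = t_max, seed = as.integer(seed)
  )
  pos <- c("dt", "r", "v_threshold", "body_radius", "v_free_mean",
           "v_free_sd", "swap_reach", "t_max")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop(sprintf("parameter '%s' must be a single positive number", nm))
    }
    p[[nm]] <- as.numeric(p[[nm]])
  }
  if (p$n_history < 1L) stop("n_history must be >= 1")
  if (p$v_threshold >= p$v_free_mean) stop("v_threshold must be < v_free_mean")
  if (p$swap_reach > p$r) stop("swap_reach must not exceed the perception radius r")
  structure(p, class = "ccoop_params")
}

#' Deterministic grid placement of a waiting crowd
#'
#' Lays out `n` agents in a rectangular waiting area on a centred, row-major
#' grid (rows bottom-up, left to right within a row). Rows and columns are
#' inset from the area edges by `body_radius / 2`; when `n` does not fill the
#' grid, the bottom rows take the extra agents and short rows are centred at
#' the full rows' spacing, which staggers the ranks like a packed crowd.
#' Fails with a capacity error when no grid achieves a pairwise spacing of at
#' least `2 * body_radius`.
#'
#' @param n number of agents (>= 0).
#' @param area rectangular `ccoop_region`.
#' @param body_radius torso radius (m).
#' @return n x 2 matrix of positions (metres), all strictly inside `area`,
#'   pairwise distance >= `2 * body_radius`.
#' @export
place_waiting_crowd <- function(n, area, body_radius) {
  stopifnot(is_region(area), area$kind == "rectangle",
            is.numeric(body_radius), body_radius > 0)
  n <- as.integer(n)
  if (n < 0) stop("n must be >= 0")
  out <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
  if (n == 0L) return(out)
  b <- rect_bounds(area)
  if (n == 1L) {
    ctr <- region_centroid(area)
    return(matrix(ctr, ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  m <- body_radius / 2
  W <- (b["xmax"] - b["xmin"]) - 2 * m
  H <- (b["ymax"] - b["ymin"]) - 2 * m
  if (W <= 0 || H <= 0) stop("capacity error: area too small for body_radius inset")
  min_gap <- 2 * body_radius

  spacing <- function(total, k) if (k <= 1) Inf else total / (k - 1)
  best <- NULL
  for (cols in seq_len(n)) {
    rows <- ceiling(n / cols)
    dx <- spacing(W, cols)
    dy <- spacing(H, rows)
    if (min(dx, dy) >= min_gap) {
      score <- min(dx, dy)
      if (is.null(best) || score > best$score) {
        best <- list(cols = cols, rows = rows, dx = dx, dy = dy, score = score)
      }
    }
  }
  if (is.null(best)) {
    stop(sprintf("capacity error: cannot place %d agents with spacing >= %.3f m in a %.2f x %.2f m area",
                 n, min_gap, W + 2 * m, H + 2 * m))
  }
  cols <- best$cols; rows <- best$rows
  xs_full <- if (cols == 1) (b["xmin"] + b["xmax"]) / 2 else
    seq(b["xmin"] + m, b["xmax"] - m, length.out = cols)
  ys <- if (rows == 1) (b["ymin"] + b["ymax"]) / 2 else
    seq(b["ymin"] + m, b["ymax"] - m, length.out = rows)
  dx <- if (cols > 1) xs_full[2] - xs_full[1] else 0
  counts <- rep(n %/% rows, rows)
  extra <- n %% rows
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L

  pts <- matrix(NA_real_, nrow = n, ncol = 2, dimnames = list(NULL, c("x", "y")))
  idx <- 1L
  xc <- (b["xmin"] + b["xmax"]) / 2
  for (ri in seq_len(rows)) {
    k <- counts[ri]
    xs <- if (k == cols) xs_full else xc + dx * (seq_len(k) - (k + 1) / 2)
    for (ci in seq_len(k)) {
      pts[idx, ] <- c(xs[ci], ys[ri])
      idx <- idx + 1L
    }
  }
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  if (min(d) < min_gap - 1e-9) {
    stop("capacity error: grid layout violates minimum spacing")
  }
  pts
}

#' Build the crossing re-enactment scenario
#'
#' Constructs the study geometry: a 1.55 m x 1.70 m waiting area (2.635 m^2,
#' printed as 2.64 m^2) holding 13 waiting agents on a deterministic grid,
#' one walking agent starting in a source area below it, a target area above
#' it, and table obstacles flanking the waiting area so the only way to the
#' target leads through the crowd. Crossing density is (13 + 1) / 2.635 =
#' 5.3 ped/m^2. The origin is the bottom-left of the domain and the walking
#' direction is +y.
#'
#' @param params a `ccoop_params` object.
#' @param n_waiters number of waiting agents (default 13, the study crowd).
#' @return an object of class `ccoop_scenario` with fields `domain_bounds`,
#'   `waiting_area`, `source`, `target`, `obstacles`, `agents` (a data frame
#'   roster: id, x, y, role, free_flow_speed), `params`, `weights`.
#' @export
build_reenactment_scenario <- function(params = model_params(), n_waiters = 13L) {
  stopifnot(inherits(params, "ccoop_params"))
  waiting_area <- region_rect(1.00, 2.30, 2.55, 4.00)   # 1.55 x 1.70
  domain <- region_rect(0, 0, 3.55, 5.60)
  source <- region_rect(1.00, 0.00, 2.55, 0.50)
  # target reaches the far domain edge so an agent cannot step past it
  target <- region_rect(1.00, 4.70, 2.55, 5.55)
  obstacles <- list(
    region_rect(0.15, 2.00, 0.85, 4.30),  # left table strip
    region_rect(2.70, 2.00, 3.40, 4.30)   # right table strip
  )

  waiters <- place_waiting_crowd(n_waiters, waiting_area, params$body_radius)
  walker_start <- c(region_centroid(source)[1], 0.25)

  roster <- data.frame(
    id = seq_len(nrow(waiters) + 1L),
    x = c(walker_start[1], waiters[, 1]),
    y = c(walker_start[2], waiters[, 2]),
    role = c("walker", rep("waiter", nrow(waiters))),
    free_flow_speed = c(params$v_free_mean, rep(params$v_free_mean, nrow(waiters))),
    stringsAsFactors = FALSE
  )

  scn <- structure(
    list(
      domain_bounds = domain,
      waiting_area = waiting_area,
      source = source,
      target = target,
      obstacles = obstacles,
      agents = roster,
      params = params,
      weights = utility_weights()
    ),
    class = "ccoop_scenario"
  )
  validate_scenario(scn)
  scn
}

#' Validate a scenario against its structural invariants
#'
#' Checks that the waiting area, source and target lie inside the domain,
#' that source and target sit on opposite sides of the waiting area along the
#' walking (y) axis, that agent ids are unique and free-flow speeds positive,
#' and that no agent disc intersects an obstacle.
#'
#' @param scenario a `ccoop_scenario`.
#' @return the scenario, invisibly; stops on any violation.
#' @export
validate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "ccoop_scenario"))
  dom <- rect_bounds(scenario$domain_bounds)
  for (nm in c("waiting_area", "source", "target")) {
    b <- rect_bounds(scenario[[nm]])
    if (b["xmin"] < dom["xmin"] - 1e-9 || b["xmax"] > dom["xmax"] + 1e-9 ||
        b["ymin"] < dom["ymin"] - 1e-9 || b["ymax"] > dom["ymax"] + 1e-9) {
      stop(sprintf("region '%s' extends outside the domain", nm))
    }
  }
  wa <- rect_bounds(scenario$waiting_area)
  if (!(rect_bounds(scenario$source)["ymax"] <= wa["ymin"] &&
        rect_bounds(scenario$target)["ymin"] >= wa["ymax"])) {
    stop("source and target must flank the waiting area along the y axis")
  }
  ag <- scenario$agents
  if (anyDuplicated(ag$id) > 0) stop("agent ids must be unique")
  if (any(ag$free_flow_speed <= 0)) stop("free-flow speeds must be > 0")
  rb <- scenario$params$body_radius
  for (obs in scenario$obstacles) {
    if (any(region_distance(cbind(ag$x, ag$y), obs) < rb - 1e-9)) {
      stop("an agent disc intersects an obstacle")
    }
  }
  d <- as.matrix(stats::dist(cbind(ag$x, ag$y)))
  diag(d) <- Inf
  if (min(d) < 2 * rb - 1e-9) stop("agent discs overlap in the initial roster")
  invisible(scenario)
}

#' @export
print.ccoop_scenario <- function(x, ...) {
  cat("<crowdcoop scenario>\n")
  cat(sprintf("  waiting area: %.3f m^2, %d agents (%d waiters + %d walker)\n",
              region_area(x$waiting_area), nrow(x$agents),
              sum(x$agents$role == "waiter"), sum(x$agents$role == "walker")))
  cat(sprintf("  crossing density: %.2f ped/m^2\n",
              nrow(x$agents) / region_area(x$waiting_area)))
  cat(sprintf("  dt = %.2f s, r = %.2f m, n_history = %d, v_threshold = %.2f m/s\n",
              x$params$dt, x$params$r, x$params$n_history, x$params$v_threshold))
  invisible(x)
}

#' Read and write scenario configuration files
#'
#' Scenarios are stored as JSON with keys mirroring the scenario fields;
#' lengths in metres, times in seconds. Regions serialise as
#' `{kind, vertices}`; the agent roster as a record table; locomotion
#' utility weights under a `locomotion` block.
#'
#' @param scenario a `ccoop_scenario`.
#' @param path file path.
#' @return `read_scenario` returns a `ccoop_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "ccoop_scenario"))
  ser_region <- function(r) list(kind = r$kind, vertices = unname(r$vertices))
  obj <- list(
    domain_bounds = ser_region(scenario$domain_bounds),
    waiting_area = ser_region(scenario$waiting_area),
    source = ser_region(scenario$source),
    target = ser_region(scenario$target),
    obstacles = lapply(scenario$obstacles, ser_region),
    agents = scenario$agents,
    params = unclass(scenario$params),
    locomotion = unclass(scenario$weights)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_region <- function(r) {
    v <- matrix(unlist(r$vertices), ncol = 2, byrow = is.list(r$vertices))
    if (!is.list(r$vertices)) v <- as.matrix(r$vertices)
    if (identical(r$kind, "rectangle")) {
      region_rect(min(v[, 1]), min(v[, 2]), max(v[, 1]), max(v[, 2]))
    } else {
      region_polygon(v)
    }
  }
  params <- do.call(model_params, obj$params)
  weights <- do.call(utility_weights, obj$locomotion)
  scn <- structure(
    list(
      domain_bounds = de_region(obj$domain_bounds),
      waiting_area = de_region(obj$waiting_area),
      source = de_region(obj$source),
      target = de_region(obj$target),
      obstacles = lapply(seq_len(length(obj$obstacles$kind %||% obj$obstacles)),
                         function(i) NULL),
      agents = as.data.frame(obj$agents, stringsAsFactors = FALSE),
      params = params,
      weights = weights
    ),
    class = "ccoop_scenario"
  )
  # obstacles: jsonlite may simplify the list of regions into a data frame
  obs <- obj$obstacles
  if (is.data.frame(obs)) {
    scn$obstacles <- lapply(seq_len(nrow(obs)), function(i) {
      de_region(list(kind = obs$kind[i], vertices = obs$vertices[[i]]))
    })
  } else {
    scn$obstacles <- lapply(obs, de_region)
  }
  validate_scenario(scn)
  scn
}

`%||%` <- function(a, b) if (is.null(a)) b else a
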