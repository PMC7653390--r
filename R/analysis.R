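#' Instantaneous speeds of one agent
#'
#' `v(t) = sqrt(dx(t)^2 + dy(t)^2) / dT` for each consecutive frame pair of a
#' single-agent trajectory sampled at a uniform frame interval `dT` (0.04 s
#' for 25 fps video, the simulation step interval for simulated output).
#'
#' @param traj single-agent trajectory: data frame with columns `timeStep`,
#'   `x`, `y` (extra columns ignored), at least two frames.
#' @param dT frame interval in seconds.
#' @return a `ccoop_speed_series`: list with `agent_id`, `frame_interval`,
#'   `speeds` (length frames - 1; entry t belongs to the transition into
#'   frame t + 1) and `frames` (the frame index each speed lands on).
#' @export
instantaneous_speeds <- function(traj, dT) {
  stopifnot(is.data.frame(traj), nrow(traj) >= 2, dT > 0)
  if ("pedestrianId" %in% names(traj) && length(unique(traj$pedestrianId)) > 1) {
    stop("instantaneous_speeds() expects a single-agent trajectory")
  }
  traj <- traj[order(traj$timeStep), ]
  gaps <- diff(traj$timeStep)
  if (length(unique(gaps)) != 1) {
    stop("non-uniform frame spacing: frame indices must be equally spaced")
  }
  v <- sqrt(diff(traj$x)^2 + diff(traj$y)^2) / dT
  structure(
    list(
      agent_id = if ("pedestrianId" %in% names(traj)) traj$pedestrianId[1] else NA,
      frame_interval = dT,
      speeds = v,
      frames = traj$timeStep[-1]
    ),
    class = "ccoop_speed_series"
  )
}

#' Mean speed over selected frames
#'
#' Arithmetic mean of instantaneous speeds over the masked frames.
#'
#' @param series a `ccoop_speed_series`.
#' @param frame_mask logical vector over the speed entries (length
#'   `length(series$speeds)`), or NULL for all entries.
#' @return mean speed (m/s). An empty mask is an explicit error, not NaN.
#' @export
mean_speed <- function(series, frame_mask = NULL) {
  stopifnot(inherits(series, "ccoop_speed_series"))
  v <- series$speeds
  if (is.null(frame_mask)) frame_mask <- rep(TRUE, length(v))
  stopifnot(length(frame_mask) == length(v))
  if (!any(frame_mask)) stop("empty frame mask: no frames selected")
  mean(v[frame_mask])
}

#' Classify frames as inside the waiting area or in the free-flow region
#'
#' `inside` marks frames whose position lies in the closed waiting-area
#' rectangle. `outside` marks frames in the free-flow measurement region: a
#' rectangle of the same width extending `outside_margin` metres along -y,
#' ending `outside_gap` metres before the waiting area's entrance edge. The
#' gap keeps the standing/queueing zone at the crowd face out of the
#' free-flow estimate.
#'
#' @param traj single-agent trajectory (columns `timeStep`, `x`, `y`).
#' @param waiting_area rectangular `ccoop_region`.
#' @param outside_margin length (m) of the free-flow measurement region.
#' @param outside_gap setback (m) between that region and the entrance edge.
#' @return list of logical vectors `inside`, `outside`, one entry per frame.
#' @export
split_inside_outside <- function(traj, waiting_area, outside_margin = 1.5,
                                 outside_gap = 0.6) {
  stopifnot(is.data.frame(traj), is_region(waiting_area))
  traj <- traj[order(traj$timeStep), ]
  b <- rect_bounds(waiting_area)
  pts <- cbind(traj$x, traj$y)
  inside <- region_contains(waiting_area, pts)
  out_top <- b["ymin"] - outside_gap
  outside <- pts[, 1] >= b["xmin"] & pts[, 1] <= b["xmax"] &
    pts[, 2] >= out_top - outside_margin & pts[, 2] <= out_top
  list(inside = unname(inside), outside = unname(outside))
}

#' Time spent inside the waiting area
#'
#' Number of frames inside the closed waiting-area rectangle times the frame
#' interval.
#'
#' @inheritParams split_inside_outside
#' @param dT frame interval (s).
#' @return duration in seconds.
#' @export
duration_in_area <- function(traj, waiting_area, dT) {
  stopifnot(dT > 0)
  masks <- split_inside_outside(traj, waiting_area)
  sum(masks$inside) * dT
}

#' Region-averaged speed statistics for one agent
#'
#' Combines [instantaneous_speeds()], [split_inside_outside()] and
#' [duration_in_area()]: mean instantaneous speed over the frames inside the
#' waiting area and over the frames in the free-flow region, plus frame
#' counts and the in-area duration. A speed (a frame transition) is
#' attributed to the frame it lands on. Regions the trajectory never visits
#' yield `NA` means rather than errors.
#'
#' @inheritParams split_inside_outside
#' @param dT frame interval (s).
#' @return list with `v_inside`, `v_outside`, `n_inside`, `n_outside`,
#'   `duration_in_area`.
#' @export
region_stats <- function(traj, waiting_area, dT, outside_margin = 1.5,
                         outside_gap = 0.6) {
  traj <- traj[order(traj$timeStep), ]
  masks <- split_inside_outside(traj, waiting_area, outside_margin, outside_gap)
  ser <- instantaneous_speeds(traj, dT)
  m_in <- masks$inside[-1]
  m_out <- masks$outside[-1]
  list(
    v_inside = if (any(m_in)) mean_speed(ser, m_in) else NA_real_,
    v_outside = if (any(m_out)) mean_speed(ser, m_out) else NA_real_,
    n_inside = sum(masks$inside),
    n_outside = sum(masks$outside),
    duration_in_area = sum(masks$inside) * dT
  )
}

#' Displacement metrics of a waiting participant
#'
#' Metric 1: Euclidean distance between the trajectory's initial and end
#' position. Metric 2: maximum Euclidean distance from the initial position
#' over the whole trajectory.
#'
#' @param traj single-agent trajectory (columns `timeStep`, `x`, `y`), at
#'   least one frame.
#' @return list with `end_displacement` and `max_displacement` (metres);
#'   `end <= max` always.
#' @export
displacement_stats <- function(traj) {
  stopifnot(is.data.frame(traj), nrow(traj) >= 1)
  traj <- traj[order(traj$timeStep), ]
  d <- sqrt((traj$x - traj$x[1])^2 + (traj$y - traj$y[1])^2)
  list(end_displacement = d[length(d)], max_displacement = max(d))
}

#' Slow-down factor
#'
#' Ratio of the free-flow (outside) mean speed to the in-crowd (inside) mean
#' speed; 1.33/0.70 = 1.9, i.e. roughly a factor 2 at crossing density
#' 5.30 ped/m^2.
#'
#' @param v_outside,v_inside mean speeds (m/s); `v_inside` must be > 0.
#' @return dimensionless ratio.
#' @export
slowdown_factor <- function(v_outside, v_inside) {
  if (!is.numeric(v_inside) || v_inside <= 0) {
    stop("v_inside must be > 0 to form a slow-down factor")
  }
  v_outside / v_inside
}

#' Paired one-sided t-test on speed differences
#'
#' For per-participant speed pairs, tests whether the crowd slows walkers
#' down: with `d_i = v_in[i] - v_out[i]`, H0: mean(d) >= 0 against
#' H1: mean(d) < 0 at significance level `alpha`. The statistic is
#' `T = sqrt(N) * mean(d) / sd(d)` with the sample (N-1) standard deviation;
#' the critical value is the lower `alpha` quantile of the t distribution
#' with N - 1 degrees of freedom, and H0 is rejected iff `T < critical`.
#'
#' @param v_in,v_out equal-length numeric vectors (N >= 2).
#' @param alpha significance level.
#' @return list of class `ccoop_ttest` with `T`, `N`, `df`, `critical_value`,
#'   `p_value`, `reject_H0`.
#' @export
paired_onesided_ttest <- function(v_in, v_out, alpha = 0.05) {
  stopifnot(length(v_in) == length(v_out), length(v_in) >= 2)
  d <- v_in - v_out
  s <- stats::sd(d)
  if (s == 0) stop("zero variance in the paired differences: t statistic undefined")
  N <- length(d)
  T_stat <- sqrt(N) * mean(d) / s
  crit <- stats::qt(alpha, df = N - 1)
  structure(
    list(
      T = T_stat, N = N, df = N - 1,
      critical_value = crit,
      p_value = stats::pt(T_stat, df = N - 1),
      reject_H0 = T_stat < crit
    ),
    class = "ccoop_ttest"
  )
}

#' @export
print.ccoop_ttest <- function(x, ...) {
  cat(sprintf("Paired one-sided t-test (H1: mean difference < 0)\n"))
  cat(sprintf("  T = %.3f on %d d.f., critical value %.3f, p = %.3g -> %s H0\n",
              x$T, x$df, x$critical_value, x$p_value,
              if (x$reject_H0) "reject" else "keep"))
  invisible(x)
}

#' Kolmogorov-Smirnov distribution-fitting survey
#'
#' Fits each candidate family to the sample by maximum likelihood
#' (via `fitdistrplus::fitdist`) and computes a one-sample KS goodness-of-fit
#' p-value against the fitted distribution (asymptotic p-value, no
#' fitted-parameter correction -- a documented caveat). Only families with
#' p-value strictly greater than `p_keep` are retained, sorted by descending
#' p-value. A family that fails to fit is skipped with a warning.
#'
#' @param samples numeric vector, at least 20 values.
#' @param candidates character vector of distribution family names as
#'   understood by `fitdistrplus` / the `stats` d/p/q/r naming ("norm",
#'   "lnorm", "gamma", "weibull", "exp", ...).
#' @param p_keep retention threshold (strict).
#' @return data frame with columns `family`, `p_value` and a list column
#'   `estimate` of fitted parameter vectors; zero rows when nothing passes.
#' @export
ks_fit_survey <- function(samples,
                          candidates = c("norm", "lnorm", "gamma", "weibull", "exp"),
                          p_keep = 0.90) {
  stopifnot(is.numeric(samples))
  if (length(samples) < 20) stop("need at least 20 samples for the survey")
  if (length(candidates) == 0) stop("candidate list must be non-empty")
  rows <- list()
  for (fam in candidates) {
    fit <- tryCatch(
      suppressWarnings(fitdistrplus::fitdist(samples, fam)),
      error = function(e) {
        warning(sprintf("family '%s' failed to fit: %s", fam, conditionMessage(e)),
                call. = FALSE)
        NULL
      }
    )
    if (is.null(fit)) next
    pfun <- get(paste0("p", fam), mode = "function")
    ks <- tryCatch(
      suppressWarnings(do.call(stats::ks.test,
                               c(list(x = samples, y = pfun), as.list(fit$estimate)))),
      error = function(e) NULL
    )
    if (is.null(ks)) next
    rows[[fam]] <- list(family = fam, p_value = unname(ks$p.value),
                        estimate = fit$estimate)
  }
  kept <- Filter(function(r) r$p_value > p_keep, rows)
  kept <- kept[order(vapply(kept, `[[`, numeric(1), "p_value"), decreasing = TRUE)]
  out <- data.frame(
    family = vapply(kept, `[[`, character(1), "family"),
    p_value = vapply(kept, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  out$estimate <- I(lapply(kept, `[[`, "estimate"))
  out
}
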