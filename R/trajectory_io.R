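#' Write a trajectory table
#'
#' Flat tab-separated table with header
#' `timeStep pedestrianId x y selfCategory`, step indices starting at 1,
#' coordinates in metres printed at full double precision (so a write/read
#' round trip is bitwise exact and write -> read -> write is byte-identical).
#' The `selfCategory` column is omitted when absent (experiment-style files
#' carry only the four kinematic columns). UTF-8, '.' decimal separator.
#'
#' @param traj trajectory data frame (`timeStep`, `pedestrianId`, `x`, `y`,
#'   optionally `selfCategory`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(is.data.frame(traj),
            all(c("timeStep", "pedestrianId", "x", "y") %in% names(traj)))
  traj <- traj[order(traj$timeStep, traj$pedestrianId), ]
  has_cat <- "selfCategory" %in% names(traj)
  cols <- c("timeStep", "pedestrianId", "x", "y", if (has_cat) "selfCategory")
  lines <- c(
    paste(cols, collapse = "\t"),
    do.call(paste, c(
      list(
        format(traj$timeStep, scientific = FALSE, trim = TRUE),
        format(traj$pedestrianId, scientific = FALSE, trim = TRUE),
        sprintf("%.17g", traj$x),
        sprintf("%.17g", traj$y)
      ),
      if (has_cat) list(traj$selfCategory),
      list(sep = "\t")
    ))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a trajectory table
#'
#' Parses the tab-separated trajectory format written by
#' [write_trajectories()]. Files without the `selfCategory` column
#' (experiment-style input) are accepted. A malformed header, non-integer
#' frame indices, or duplicate `(timeStep, pedestrianId)` pairs raise parse
#' errors naming the offending line.
#'
#' @param path input file path.
#' @param frame_interval frame interval in seconds to attach to the result
#'   (e.g. 0.04 for 25 fps video); `NA` when unknown.
#' @return a `ccoop_trajectory` data frame sorted by (timeStep, pedestrianId).
#' @export
read_trajectories <- function(path, frame_interval = NA_real_) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("parse error: empty trajectory file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  base_cols <- c("timeStep", "pedestrianId", "x", "y")
  if (length(header) < 4 || !identical(header[1:4], base_cols)) {
    stop(sprintf("parse error at line 1: expected header starting '%s', got '%s'",
                 paste(base_cols, collapse = " "), lines[1]))
  }
  has_cat <- length(header) >= 5 && header[5] == "selfCategory"
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  n_expect <- if (has_cat) 5L else 4L
  bad <- which(lengths(parts) != n_expect)
  if (length(bad) > 0) {
    stop(sprintf("parse error at line %d: expected %d tab-separated fields",
                 bad[1] + 1L, n_expect))
  }
  get_col <- function(j) vapply(parts, `[[`, character(1), j)
  ts_raw <- get_col(1)
  ts <- suppressWarnings(as.numeric(ts_raw))
  not_int <- which(is.na(ts) | ts != floor(ts))
  if (length(not_int) > 0) {
    stop(sprintf("parse error at line %d: non-integer timeStep '%s'",
                 not_int[1] + 1L, ts_raw[not_int[1]]))
  }
  ids_raw <- get_col(2)
  ids <- suppressWarnings(as.integer(ids_raw))
  if (anyNA(ids)) {
    i <- which(is.na(ids))[1]
    stop(sprintf("parse error at line %d: bad pedestrianId '%s'", i + 1L, ids_raw[i]))
  }
  xy_x <- suppressWarnings(as.numeric(get_col(3)))
  xy_y <- suppressWarnings(as.numeric(get_col(4)))
  if (anyNA(xy_x) || anyNA(xy_y)) {
    i <- which(is.na(xy_x) | is.na(xy_y))[1]
    stop(sprintf("parse error at line %d: non-numeric coordinate", i + 1L))
  }
  dup <- which(duplicated(paste(ts, ids)))
  if (length(dup) > 0) {
    stop(sprintf("parse error at line %d: duplicate (timeStep, pedestrianId) pair (%s, %s)",
                 dup[1] + 1L, ts_raw[dup[1]], ids_raw[dup[1]]))
  }
  traj <- data.frame(
    timeStep = as.integer(ts), pedestrianId = ids, x = xy_x, y = xy_y,
    stringsAsFactors = FALSE
  )
  if (has_cat) traj$selfCategory <- get_col(5)
  traj <- traj[order(traj$timeStep, traj$pedestrianId), ]
  rownames(traj) <- NULL
  attr(traj, "frame_interval") <- frame_interval
  class(traj) <- c("ccoop_trajectory", "data.frame")
  traj
}

#' Generate a synthetic test trajectory
#'
#' Produces single-agent trajectories with known kinematics, standing in for
#' extracted video trajectories when exercising the analysis toolkit:
#' \describe{
#'   \item{constant_velocity}{straight line along +y at `speed`.}
#'   \item{out_and_back}{walks `amplitude` metres along +y at `speed`, then
#'     returns to the start (end displacement 0, max displacement
#'     `amplitude`).}
#'   \item{random_walk}{isotropic Gaussian steps with per-frame s.d.
#'     `speed / fps`; seeded and reproducible.}
#'   \item{blocked_then_cross}{stationary for the first half, then constant
#'     velocity along +y.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param speed nominal speed (m/s).
#' @param fps frames per second (> 0).
#' @param duration length in seconds (> 0); the trajectory has exactly
#'   `round(fps * duration)` frames.
#' @param seed RNG seed for stochastic kinds.
#' @param amplitude out-and-back amplitude (m).
#' @param start length-2 start position.
#' @param id pedestrian id.
#' @return a `ccoop_trajectory` with frame interval `1/fps`.
#' @export
generate_fixture <- function(kind = c("constant_velocity", "out_and_back",
                                      "random_walk", "blocked_then_cross"),
                             speed = 1.34, fps = 25, duration = 2, seed = 1L,
                             amplitude = 0.5, start = c(0, 0), id = 1L) {
  kind <- match.arg(kind)
  stopifnot(fps > 0, duration > 0, speed >= 0)
  n <- round(fps * duration)
  if (n < 1) stop("fps * duration must give at least one frame")
  dstep <- speed / fps
  xy <- switch(
    kind,
    constant_velocity = cbind(rep(start[1], n), start[2] + (seq_len(n) - 1) * dstep),
    out_and_back = {
      half <- ceiling(n / 2)
      up <- pmin((seq_len(half) - 1) * dstep, amplitude)
      down <- pmax(amplitude - seq_len(n - half) * dstep, 0)
      cbind(rep(start[1], n), start[2] + c(up, down))
    },
    random_walk = {
      set.seed(as.integer(seed))
      steps <- matrix(stats::rnorm(2 * (n - 1), 0, dstep), ncol = 2)
      cbind(start[1] + c(0, cumsum(steps[, 1])), start[2] + c(0, cumsum(steps[, 2])))
    },
    blocked_then_cross = {
      half <- ceiling(n / 2)
      cbind(rep(start[1], n),
            start[2] + c(rep(0, half), seq_len(n - half) * dstep))
    }
  )
  traj <- data.frame(
    timeStep = seq_len(n), pedestrianId = as.integer(id),
    x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE
  )
  attr(traj, "frame_interval") <- 1 / fps
  class(traj) <- c("ccoop_trajectory", "data.frame")
  traj
}

#' Split a multi-agent trajectory by agent
#'
#' @param traj a trajectory data frame.
#' @return named list of single-agent trajectories (names are pedestrian ids).
#' @export
split_by_agent <- function(traj) {
  out <- split(as.data.frame(traj), traj$pedestrianId)
  lapply(out, function(d) {
    attr(d, "frame_interval") <- attr(traj, "frame_interval")
    class(d) <- c("ccoop_trajectory", "data.frame")
    d
  })
}
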