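#' Options for per-trial metric computation
#'
#' @param depth_fraction Fraction of the alley length a sample must penetrate
#'   (measured from the alley entry at the pentagon vertex) for the alley to
#'   count as visited. The original task never defines alley entry; 0.10 is
#'   the package default.
#' @param min_step Minimum displacement (m) between successive position
#'   anchors used to estimate heading for the rotation-angle metric;
#'   suppresses jitter-induced heading noise.
#' @param speed_method `"path"` (mean speed = total path length / duration)
#'   or `"instantaneous"` (mean of per-step speeds).
#' @return A list of options.
#' @export
metric_options <- function(depth_fraction = 0.10, min_step = 0.05,
                           speed_method = c("path", "instantaneous")) {
  stopifnot(depth_fraction > 0, depth_fraction < 1, min_step > 0)
  list(depth_fraction = depth_fraction, min_step = min_step,
       speed_method = match.arg(speed_method))
}

.check_traj <- function(traj) {
  if (!is.data.frame(traj) || !all(c("time_s", "x_m", "y_m") %in% names(traj))) {
    stop("validation error: not a trajectory (need time_s, x_m, y_m)",
         call. = FALSE)
  }
  if (nrow(traj) < 2L) {
    stop("validation error: trajectory needs at least 2 samples", call. = FALSE)
  }
  traj
}

#' Total path length of a trajectory
#'
#' Sum of Euclidean distances between consecutive samples (m). Invariant
#' under time reparametrization and additive under concatenation.
#'
#' @param traj A [trajectory()] object.
#' @return Length in metres.
#' @export
total_path_length <- function(traj) {
  .check_traj(traj)
  sum(sqrt(diff(traj$x_m)^2 + diff(traj$y_m)^2))
}

#' Detect reward capture
#'
#' The trial succeeds if some sample comes within the capture radius of a
#' reward point of the trial's reward alleys at a time within the limit; the
#' first such event defines the time to reward and the reached alley.
#'
#' @param traj A [trajectory()] object.
#' @param spec A one-row trial specification (see [trial_spec()]).
#' @param maze A [build_maze()] object.
#' @return List with `success`, `time_to_reward`, `reached_alley` and
#'   `capture_index` (NA when unsuccessful).
#' @export
detect_success <- function(traj, spec, maze) {
  .check_traj(traj)
  rewards <- spec_rewards(spec)
  if (!length(rewards)) stop("protocol error: no reward alleys", call. = FALSE)
  limit <- spec$time_limit %||% 120
  cap2 <- maze$config$capture_radius^2
  best_i <- Inf
  best_alley <- NA_integer_
  for (a in rewards) {
    d2 <- (traj$x_m - maze$rewards[a, 1])^2 + (traj$y_m - maze$rewards[a, 2])^2
    hit <- which(d2 <= cap2 & traj$time_s <= limit)
    if (length(hit) && hit[1] < best_i) {
      best_i <- hit[1]
      best_alley <- a
    }
  }
  if (is.finite(best_i)) {
    list(success = TRUE, time_to_reward = traj$time_s[best_i],
         reached_alley = best_alley, capture_index = best_i)
  } else {
    list(success = FALSE, time_to_reward = NA_real_,
         reached_alley = NA_integer_, capture_index = NA_integer_)
  }
}

#' Ordered unique alleys visited by a trajectory
#'
#' An alley counts as visited when some sample lies deeper than
#' `depth_fraction * alley_length` into its corridor (depth measured from the
#' pentagon vertex). The start alley is always counted first; subsequent
#' alleys appear in order of first entry. Samples after reward capture are
#' ignored when `end_index` is given.
#'
#' @inheritParams detect_success
#' @param depth_fraction See [metric_options()].
#' @param start_alley Alley the trial started from (always counted).
#' @param end_index Last sample index to consider (e.g. the capture index).
#' @return Integer vector of alley ids in order of first entry.
#' @export
visited_alleys <- function(traj, maze, depth_fraction = 0.10,
                           start_alley = NULL, end_index = NULL) {
  .check_traj(traj)
  n <- nrow(traj)
  if (!is.null(end_index) && !is.na(end_index)) n <- min(n, end_index)
  x <- traj$x_m[seq_len(n)]
  y <- traj$y_m[seq_len(n)]
  ac <- .alley_coords(maze, x, y)
  cfg <- maze$config
  thresh <- depth_fraction * cfg$alley_length
  half_w <- cfg$alley_width / 2
  first_in <- rep(NA_real_, 5)
  for (i in 1:5) {
    inside <- ac$t[, i] >= thresh & ac$t[, i] <= cfg$alley_length &
      ac$s[, i] <= half_w
    w <- which(inside)
    if (length(w)) first_in[i] <- w[1]
  }
  if (!is.null(start_alley)) first_in[as.integer(start_alley)] <- 0
  ord <- order(first_in, na.last = NA)
  as.integer(ord)
}

#' Distance error (percent excess over the ideal path)
#'
#' `DE% = 100 * (total distance traveled - ideal distance) / ideal distance`.
#' On success, the traveled distance is the path up to reward capture plus
#' the residual straight-line gap from the capture sample to the reward
#' point (capture triggers within the capture radius, i.e. slightly before
#' the reward itself; closing the gap keeps the comparison with the ideal
#' path — which ends at the reward — like for like, and guarantees
#' `DE >= 0` by minimality). The ideal distance is that of the path from the
#' start alley to the alley actually reached; on failure the full recorded
#' path is compared against the nearer reward's ideal path.
#'
#' @inheritParams detect_success
#' @param success Optional precomputed [detect_success()] result.
#' @return DE in percent.
#' @export
distance_error <- function(traj, spec, maze, success = NULL) {
  .check_traj(traj)
  if (is.null(success)) success <- detect_success(traj, spec, maze)
  start <- spec$start_alley
  if (isTRUE(success$success)) {
    traveled <- .traveled_to_reward(traj, maze, success)
    ideal <- ideal_path(maze, start, success$reached_alley)$length
  } else {
    traveled <- total_path_length(traj)
    ideal <- min(vapply(spec_rewards(spec),
                        function(a) ideal_path(maze, start, a)$length,
                        numeric(1)))
  }
  if (!is.finite(ideal) || ideal <= 0) {
    stop("computation error: degenerate ideal path length", call. = FALSE)
  }
  100 * (traveled - ideal) / ideal
}

# Traveled distance of a successful trial: path up to the capture sample
# plus the residual straight-line gap to the reward point.
.traveled_to_reward <- function(traj, maze, success) {
  i <- success$capture_index
  reward <- maze$rewards[success$reached_alley, ]
  residual <- sqrt((traj$x_m[i] - reward[[1]])^2 + (traj$y_m[i] - reward[[2]])^2)
  path <- if (i >= 2L) total_path_length(traj[seq_len(i), ]) else 0
  unname(path + residual)
}

# Anchor-filtered displacement headings: keep a sample when it is at least
# min_step away from the previously kept sample. Returns headings (deg).
.anchored_headings <- function(x, y, min_step) {
  n <- length(x)
  keep <- integer(n)
  keep[1] <- 1L
  k <- 1L
  last <- 1L
  for (i in 2:n) {
    if ((x[i] - x[last])^2 + (y[i] - y[last])^2 >= min_step^2) {
      k <- k + 1L
      keep[k] <- i
      last <- i
    }
  }
  keep <- keep[seq_len(k)]
  if (k < 3L) return(NULL)
  atan2(diff(y[keep]), diff(x[keep])) * 180 / pi
}

#' Rotation angle (cumulative rotation in excess of the ideal path)
#'
#' The participant's rotations are the summed absolute heading changes (deg)
#' over successive displacement vectors of length at least `min_step`,
#' truncated at reward capture; the minimum rotations are those of the ideal
#' path (to the reached alley on success, the nearer reward otherwise).
#' `RA = participant's rotations - minimum rotations`; slight negative values
#' can arise from discretization and are reported as computed.
#'
#' @inheritParams distance_error
#' @param min_step See [metric_options()].
#' @return RA in degrees.
#' @export
rotation_angle <- function(traj, spec, maze, min_step = 0.05, success = NULL) {
  .check_traj(traj)
  if (is.null(success)) success <- detect_success(traj, spec, maze)
  n <- nrow(traj)
  if (isTRUE(success$success)) n <- success$capture_index
  h <- .anchored_headings(traj$x_m[seq_len(n)], traj$y_m[seq_len(n)], min_step)
  if (is.null(h)) {
    stop("computation error: stationary trajectory (all displacements below ",
         "min_step)", call. = FALSE)
  }
  participant_rot <- sum(abs(wrap_angle(diff(h))))
  start <- spec$start_alley
  min_rot <- if (isTRUE(success$success)) {
    ideal_path(maze, start, success$reached_alley)$min_rotation
  } else {
    ideals <- vapply(spec_rewards(spec),
                     function(a) ideal_path(maze, start, a)$length, numeric(1))
    nearest <- spec_rewards(spec)[which.min(ideals)]
    ideal_path(maze, start, nearest)$min_rotation
  }
  participant_rot - min_rot
}

#' Compute the seven per-trial navigation parameters
#'
#' Success, time to reward, visited alleys, total path length, duration,
#' mean speed, distance error and rotation angle for one trial. On success,
#' path-dependent metrics are truncated at reward capture and the duration is
#' the time of capture; otherwise the full recorded trajectory counts. A
#' stationary trajectory yields `ra_deg = NA` with `ra_error = TRUE`.
#'
#' @inheritParams detect_success
#' @param options A [metric_options()] list.
#' @return A one-row tibble with columns `success`, `time_to_reward_s`,
#'   `reached_alley`, `visited_n`, `visited_seq`, `tpl_m`, `duration_s`,
#'   `mean_speed_ms`, `de_pct`, `ra_deg`, `ra_error`.
#' @export
compute_trial_metrics <- function(traj, spec, maze, options = metric_options()) {
  .check_traj(traj)
  succ <- detect_success(traj, spec, maze)
  n <- if (isTRUE(succ$success)) max(succ$capture_index, 2L) else nrow(traj)
  sub <- traj[seq_len(n), ]
  tpl <- if (isTRUE(succ$success)) .traveled_to_reward(traj, maze, succ) else
    total_path_length(sub)
  duration <- if (isTRUE(succ$success)) succ$time_to_reward else
    traj$time_s[nrow(traj)] - traj$time_s[1]
  visited <- visited_alleys(traj, maze, depth_fraction = options$depth_fraction,
                            start_alley = spec$start_alley,
                            end_index = succ$capture_index)
  de <- distance_error(traj, spec, maze, success = succ)
  ra <- tryCatch(
    rotation_angle(traj, spec, maze, min_step = options$min_step,
                   success = succ),
    error = function(e) NA_real_
  )
  speed <- if (options$speed_method == "instantaneous") {
    steps <- sqrt(diff(sub$x_m)^2 + diff(sub$y_m)^2)
    dt <- diff(sub$time_s)
    mean(steps / dt)
  } else if (duration > 0) tpl / duration else NA_real_
  tibble::tibble(
    success = succ$success,
    time_to_reward_s = succ$time_to_reward,
    reached_alley = succ$reached_alley,
    visited_n = length(visited),
    visited_seq = paste(visited, collapse = ">"),
    tpl_m = tpl,
    duration_s = duration,
    mean_speed_ms = speed,
    de_pct = de,
    ra_deg = ra,
    ra_error = is.na(ra)
  )
}

#' Tidy per-trial metrics for a whole cohort
#'
#' One row per participant x recorded trial, joining the trial specification
#' (task, type, training/test counters) with [compute_trial_metrics()]
#' output. Missing trials simply have no row.
#'
#' @param cohort A [maze_cohort()].
#' @param maze Optional prebuilt [build_maze()]; defaults to the cohort's
#'   maze configuration.
#' @param options A [metric_options()] list.
#' @return A tibble.
#' @export
cohort_metrics <- function(cohort, maze = NULL, options = metric_options()) {
  stopifnot(inherits(cohort, "maze_cohort"))
  if (is.null(maze)) maze <- build_maze(cohort$maze_config)
  rows <- list()
  for (s in cohort$sessions) {
    for (idx in names(s$trials)) {
      spec <- protocol_row(cohort$protocol, as.integer(idx))
      m <- compute_trial_metrics(s$trials[[idx]], spec, maze, options)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(
          participant_id = s$participant_id,
          group = s$group,
          trial_index = spec$trial_index,
          task = spec$task,
          trial_type = spec$trial_type,
          training_index = spec$training_index,
          test_index = spec$test_index
        ),
        m
      )
    }
  }
  dplyr::bind_rows(rows)
}
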