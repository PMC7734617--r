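# Shared fixtures: built in code at test time, nothing on disk.

default_maze <- build_maze()
default_proto <- default_protocol(1)

# Sample a waypoint polyline at constant speed, inserting the breakpoints as
# extra samples (independent of the package's samplers; used to build
# trajectories with exactly known length and rotation).
traj_from_polyline <- function(pts, speed = 8, rate = 120) {
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  t_all <- sort(unique(c(seq(0, total / speed, by = 1 / rate),
                         cum / speed, total / speed)))
  s <- t_all * speed
  # drop near-duplicate arc positions (grid points adjacent to breakpoints),
  # whose interpolation round-off would otherwise scramble headings
  keep <- c(TRUE, diff(s) > 1e-6)
  t_all <- t_all[keep]
  s <- s[keep]
  trajectory(t_all,
             stats::approx(cum, pts[, 1], xout = s, rule = 2)$y,
             stats::approx(cum, pts[, 2], xout = s, rule = 2)$y,
             sampling_rate = rate)
}

# Ideal-path waypoints for start -> goal in the default maze.
ideal_waypoints <- function(start, goal, maze = default_maze) {
  ideal_path(maze, start, goal)$polyline
}

noiseless_agent <- function(strategy) {
  agent_config(strategy, initial_error_prob = 0, path_jitter_sd = 0,
               speed_sd = 0)
}

# Step-shaped participant x 16 matrices used for knee-detection checks:
# high level on trials 1..(step - 1), low level afterwards, Gaussian jitter.
step_matrices <- function(n_participants = 10, step = 4, high = 10, low = 2,
                          jitter_sd = 0.1) {
  mk <- function() {
    base <- matrix(rep(c(rep(high, step - 1), rep(low, 17 - step)),
                       each = n_participants),
                   n_participants, 16)
    base + stats::rnorm(n_participants * 16, 0, jitter_sd)
  }
  list(visited_n = mk(), tpl_m = mk(), de_pct = mk(), ra_deg = mk())
}

# Exhaustive-enumeration oracle for the two-sample Mann-Whitney p-value
# (no ties assumed).
mw_enum <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  Us <- apply(idx, 2, function(ii) sum(outer(pooled[ii], pooled[-ii], ">")))
  u_obs <- sum(outer(x, y, ">"))
  p_le <- mean(Us <= u_obs)
  p_ge <- mean(Us >= u_obs)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_le, p_ge)),
              less = p_le,
              greater = p_ge)
  list(U = u_obs, p = p)
}

# Metrics table for constructed per-participant training values: one row per
# participant x training trial with the four learning-curve metrics set to
# the given per-participant constants (used by correlation/comparison tests).
constant_training_metrics <- function(values_by_participant, group = "TD") {
  rows <- lapply(seq_along(values_by_participant), function(i) {
    v <- values_by_participant[i]
    tibble::tibble(
      participant_id = names(values_by_participant)[i],
      group = group,
      trial_index = c(1:5, 7:9, 11:13, 15:16, 18:20),
      task = "task1",
      trial_type = "training",
      training_index = 1:16,
      test_index = NA_integer_,
      success = TRUE,
      visited_n = v, tpl_m = v, de_pct = v, ra_deg = v,
      mean_speed_ms = v, duration_s = v
    )
  })
  dplyr::bind_rows(rows)
}
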