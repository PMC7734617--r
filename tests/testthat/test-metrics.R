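test_that("total path length: triangle, reversal, resampling, reparametrization", {
  tr <- trajectory(c(0, 1), c(0, 3), c(0, 4))
  expect_equal(total_path_length(tr), 5)

  # concatenation with the reverse doubles the length
  tr2 <- trajectory(c(0, 1, 2), c(0, 3, 0), c(0, 4, 0))
  expect_equal(total_path_length(tr2), 10)

  # densely resampled straight segment keeps its analytic length
  n <- 5000
  tr3 <- trajectory(seq(0, 1, length.out = n),
                    seq(0, 30, length.out = n),
                    seq(0, 40, length.out = n))
  expect_equal(total_path_length(tr3), 50, tolerance = 1e-9)

  # invariant under time reparametrization
  tr4 <- trajectory(cumsum(runif(n, 0.001, 1)),
                    seq(0, 30, length.out = n),
                    seq(0, 40, length.out = n))
  expect_equal(total_path_length(tr4), total_path_length(tr3))

  expect_error(total_path_length(trajectory(0:1, 0:1, 0:1)[1, ]), "2 samples")
})

test_that("success detection honours the capture radius and time limit", {
  m <- default_maze
  spec <- protocol_row(default_proto, 1)  # training: reward alley 3
  r3 <- m$rewards[3, ]
  # enters the capture zone at t = 30
  tr <- trajectory(c(0, 15, 30, 40), c(0, 10, r3[1], r3[1]),
                   c(123, 50, r3[2], r3[2]))
  s <- detect_success(tr, spec, m)
  expect_true(s$success)
  expect_equal(s$time_to_reward, 30)
  expect_equal(s$reached_alley, 3)
  # reaching the reward only after the 120 s limit is a failure
  tr_late <- trajectory(c(0, 125, 130), c(0, 1, r3[1]), c(123, 1, r3[2]))
  expect_false(detect_success(tr_late, spec, m)$success)
  # never leaving the center is a failure
  tr_center <- trajectory(c(0, 60, 119), c(0, 1, 0), c(0, 1, 2))
  expect_false(detect_success(tr_center, spec, m)$success)
})

test_that("visited alleys: ideal path, full tour, grazing threshold", {
  m <- default_maze
  tr <- ideal_trajectory(m, 1, 3)
  expect_equal(visited_alleys(tr, m, start_alley = 1), c(1L, 3L))

  # a tour poking into every alley
  L <- m$config$alley_length
  pts <- list(m$alley_ends[1, ])
  for (a in c(2, 3, 4, 5)) {
    pts[[length(pts) + 1L]] <- m$vertices[a, ]
    pts[[length(pts) + 1L]] <- m$vertices[a, ] + 0.5 * L * m$dirs[a, ]
    pts[[length(pts) + 1L]] <- m$vertices[a, ]
  }
  tour <- traj_from_polyline(do.call(rbind, pts))
  expect_length(visited_alleys(tour, m, start_alley = 1), 5)

  # grazing alley 2 at half the depth threshold does not count
  depth <- 0.10 * L
  graze <- function(frac) {
    p <- m$vertices[2, ] + frac * depth * m$dirs[2, ]
    traj_from_polyline(rbind(m$alley_ends[1, ], m$vertices[1, ], c(0, 0),
                             m$vertices[2, ], p))
  }
  expect_equal(visited_alleys(graze(0.5), m, start_alley = 1), 1L)
  expect_equal(visited_alleys(graze(1.1), m, start_alley = 1), c(1L, 2L))
})

test_that("distance error: ideal trace is 0, doubling the path gives 100 %", {
  m <- default_maze
  spec <- protocol_row(default_proto, 1)
  tr <- ideal_trajectory(m, 1, 3)
  expect_equal(distance_error(tr, spec, m), 0, tolerance = 1e-9)

  # a detour of known length scales DE exactly per the formula:
  # down alley 4 for d metres and back, then trace the ideal path
  L <- m$config$alley_length
  d <- 50
  q <- m$vertices[4, ] + d * m$dirs[4, ]
  pts <- rbind(m$alley_ends[1, ], m$vertices[1, ], c(0, 0),
               m$vertices[4, ], q, m$vertices[4, ], c(0, 0),
               m$vertices[3, ], m$alley_ends[3, ])
  tr2 <- traj_from_polyline(pts)
  de <- distance_error(tr2, spec, m)
  extra <- 2 * (m$config$circumradius + d)
  expect_equal(de, 100 * extra / 246, tolerance = 1e-6)
})

test_that("distance error is non-negative and increases with path jitter", {
  m <- default_maze
  p <- default_proto
  spec <- protocol_row(p, 1)
  de_at <- function(sd, seed) {
    ag <- agent_config("allocentric", initial_error_prob = 0,
                       path_jitter_sd = sd, speed_sd = 0)
    withr::with_seed(seed, {
      res <- simulate_trial(ag, spec, m)
      distance_error(res$trajectory, spec, m)
    })
  }
  des <- vapply(c(0, 0.3, 1, 2.5), de_at, numeric(1), seed = 5)
  expect_true(all(des >= -1e-9))
  expect_lt(des[1], 1e-6)
  expect_true(all(diff(des) > 0))
})

test_that("rotation angle: ideal trace, added loop, zig-zag oracle", {
  m <- default_maze
  spec <- protocol_row(default_proto, 1)
  tr <- ideal_trajectory(m, 1, 3)
  expect_lt(abs(rotation_angle(tr, spec, m)), 1)

  # inserting a square loop adds one full 360 degree rotation
  L <- m$config$alley_length
  mid <- m$vertices[3, ] + 0.4 * L * m$dirs[3, ]
  u <- m$dirs[3, ]
  v <- c(-u[2], u[1])
  side <- 5
  loop <- rbind(mid, mid + side * v, mid + side * v + side * u,
                mid + side * u, mid)
  pts <- rbind(m$alley_ends[1, ], m$vertices[1, ], c(0, 0), m$vertices[3, ],
               loop, m$alley_ends[3, ])
  ra_loop <- rotation_angle(traj_from_polyline(pts), spec, m)
  expect_equal(ra_loop, 360, tolerance = 1)

  # staircase with k alternating 90-degree corners, never captured:
  # participant rotation = 90 k, minus the 36 degree ideal minimum
  k <- 6
  start <- m$alley_ends[1, ]
  pts <- start
  pos <- start
  for (i in seq_len(k + 1)) {
    step <- if (i %% 2 == 1) c(0, -20) else c(-20, 0)
    pos <- pos + step
    pts <- rbind(pts, pos)
  }
  ra_zig <- rotation_angle(traj_from_polyline(pts), spec, m)
  expect_equal(ra_zig, 90 * k - 36, tolerance = 1e-6)

  # stationary trajectory errors
  still <- trajectory(0:5, rep(0, 6), rep(0, 6))
  expect_error(rotation_angle(still, spec, m), "stationary")
})

test_that("compute_trial_metrics matches the theoretical ideal values", {
  m <- default_maze
  spec <- protocol_row(default_proto, 1)
  mm <- compute_trial_metrics(ideal_trajectory(m, 1, 3), spec, m)
  expect_true(mm$success)
  expect_equal(mm$visited_n, 2L)
  expect_equal(mm$tpl_m, 246, tolerance = 1e-9)
  expect_equal(mm$de_pct, 0, tolerance = 1e-9)
  expect_lt(abs(mm$ra_deg), 1)
  expect_equal(mm$mean_speed_ms, mm$tpl_m / mm$duration_s)
  expect_false(mm$ra_error)
})

test_that("compute_trial_metrics flags stationary trajectories", {
  m <- default_maze
  spec <- protocol_row(default_proto, 1)
  still <- trajectory(seq(0, 119, length.out = 60),
                      rep(0, 60) + 1e-4 * sin(1:60), rep(123, 60))
  mm <- compute_trial_metrics(still, spec, m)
  expect_false(mm$success)
  expect_equal(mm$visited_n, 1L)
  expect_true(mm$ra_error)
  expect_true(is.na(mm$ra_deg))
})

test_that("TPL truncates at capture and closes the residual gap", {
  m <- default_maze
  p <- default_proto
  ag <- noiseless_agent("allocentric")
  res <- withr::with_seed(2, simulate_trial(ag, protocol_row(p, 1), m))
  mm <- compute_trial_metrics(res$trajectory, protocol_row(p, 1), m)
  expect_equal(mm$tpl_m, 246, tolerance = 1e-9)

  # samples recorded after capture are ignored: append a post-capture tail
  tr <- res$trajectory
  tail_t <- max(tr$time_s) + (1:10) / 120
  tr2 <- trajectory(c(tr$time_s, tail_t),
                    c(tr$x_m, tr$x_m[nrow(tr)] + 1:10),
                    c(tr$y_m, rep(tr$y_m[nrow(tr)], 10)))
  mm2 <- compute_trial_metrics(tr2, protocol_row(p, 1), m)
  expect_equal(mm2$tpl_m, mm$tpl_m, tolerance = 1e-9)
})
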