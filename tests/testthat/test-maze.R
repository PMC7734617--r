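test_that("default geometry is calibrated to the 246 m ideal path", {
  ip <- ideal_path(default_maze, 1, 3)
  expect_equal(ip$length, 246)
  expect_equal(ip$length,
               2 * (default_maze$config$alley_length +
                      default_maze$config$circumradius))
})

test_that("alley ends sit 72 degrees apart as seen from the origin", {
  ang <- atan2(default_maze$rewards[, 2], default_maze$rewards[, 1]) * 180 / pi
  gaps <- sort((diff(c(ang, ang[1] + 360)) + 360) %% 360)
  expect_equal(unname(gaps), rep(72, 5))
  # alley 1 along +y
  expect_equal(unname(default_maze$rewards[1, ]), c(0, 123), tolerance = 1e-12)
})

test_that("invalid geometry is rejected", {
  expect_error(maze_config(alley_width = 20), "pentagon edge")
  expect_error(maze_config(alley_length = -1), "positive")
  expect_error(maze_config(circumradius = 0), "positive")
  expect_error(maze_config(capture_radius = 500), "capture_radius")
})

test_that("ideal path lengths are symmetric and handle the turn-around case", {
  for (a in 1:5) {
    for (b in 1:5) {
      expect_equal(ideal_path(default_maze, a, b)$length,
                   ideal_path(default_maze, b, a)$length)
    }
  }
  ip <- ideal_path(default_maze, 1, 1)
  expect_equal(ip$length, 2 * default_maze$config$alley_length)
  expect_equal(ip$min_rotation, 180)
  expect_error(ideal_path(default_maze, 0, 3), "alley id")
  expect_error(ideal_path(default_maze, 1, 6), "alley id")
})

test_that("minimum rotation matches dense numerical integration of heading", {
  for (pair in list(c(1, 3), c(4, 1), c(4, 3), c(2, 5))) {
    ip <- ideal_path(default_maze, pair[1], pair[2])
    traj <- traj_from_polyline(ip$polyline, speed = 2, rate = 500)
    h <- atan2(diff(traj$y_m), diff(traj$x_m)) * 180 / pi
    dh <- (diff(h) + 180) %% 360 - 180
    expect_equal(sum(abs(dh)), ip$min_rotation, tolerance = 1e-6)
  }
})

test_that("ideal path is the shortest path routed through the centroid", {
  # brute-force grid of via-points a (leaving alley 1) and b (entering
  # alley 3): end1 -> a -> centroid -> b -> end3
  ip <- ideal_path(default_maze, 1, 3)
  e1 <- default_maze$alley_ends[1, ]
  e3 <- default_maze$alley_ends[3, ]
  g <- as.matrix(expand.grid(x = seq(-10, 10, by = 1), y = seq(-10, 10, by = 1)))
  d <- function(p, q) sqrt(sum((p - q)^2))
  lens <- apply(g, 1, function(a) {
    min(apply(g, 1, function(b) {
      d(e1, a) + d(a, c(0, 0)) + d(c(0, 0), b) + d(b, e3)
    }))
  })
  expect_gte(min(lens), ip$length - 1e-9)
})

test_that("locate_points labels the canonical regions", {
  m <- default_maze
  expect_identical(locate_points(m, 0, 0), "center")
  expect_identical(locate_points(m, m$rewards[3, 1], m$rewards[3, 2]),
                   "alley_end_3")
  expect_identical(locate_points(m, 10 * m$config$circumradius,
                                 10 * m$config$circumradius), "outside")
  # a point halfway down alley 1 (on axis)
  mid <- m$vertices[1, ] + 0.5 * m$config$alley_length * m$dirs[1, ]
  expect_identical(locate_points(m, mid[1], mid[2]), "alley_1")
  # just beside the corridor
  off <- mid + c(m$config$alley_width, 0)
  expect_identical(locate_points(m, off[1], off[2]), "outside")
  # every point gets exactly one label (vectorised call, one label each)
  xs <- seq(-130, 130, length.out = 40)
  labs <- locate_points(m, xs, xs)
  expect_length(labs, 40)
  expect_true(all(labs %in% c("center", "outside", paste0("alley_", 1:5),
                              paste0("alley_end_", 1:5))))
})

test_that("the canonical protocol matches the trial schedule", {
  p <- default_protocol(1)
  expect_equal(nrow(p), 28)
  expect_equal(sum(p$trial_type == "training"), 16)
  expect_equal(sum(p$trial_type == "test"), 5)
  expect_equal(p$trial_index[p$trial_type == "test"], c(6, 10, 14, 17, 21))
  expect_equal(sum(p$trial_type == "compelled_AS"), 4)
  expect_equal(sum(p$trial_type == "compelled_ES"), 3)
  expect_setequal(p$start_alley[p$trial_type == "compelled_AS"], c(2, 5))
  expect_equal(sort(p$start_alley[p$trial_type == "compelled_AS"]),
               c(2, 2, 5, 5))
  expect_true(all(p$cue_visibility[p$trial_type == "compelled_ES"] == "bare"))
  expect_true(all(p$time_limit == 120))
  # training/test invariants
  expect_true(all(p$start_alley[p$trial_type == "training"] == 1))
  expect_true(all(p$start_alley[p$trial_type == "test"] == 4))
})

test_that("protocol generation is a pure function of the seed", {
  expect_identical(default_protocol(7), default_protocol(7))
  orders <- vapply(1:20, function(s) {
    paste(default_protocol(s)$trial_type[22:28], collapse = ",")
  }, character(1))
  expect_gt(length(unique(orders)), 1)
})

test_that("trial_spec enforces the protocol invariants", {
  expect_error(trial_spec(1, "task1", "training", 2, 3), "invariants")
  expect_error(trial_spec(1, "task1", "test", 4, 3), "invariants")
  expect_error(trial_spec(1, "task2", "compelled_AS", 3, 3), "invariants")
  expect_error(trial_spec(1, "task2", "compelled_ES", 1, 3,
                          cue_visibility = "cued"), "invariants")
})
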