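#' Configure the five-alley star maze
#'
#' The maze is a regular pentagon with one alley radiating outward from each
#' vertex. Coordinates are planar metres with the origin at the pentagon
#' centroid; alley 1 points along +y and alley `i` is centred at heading
#' `(i - 1) * 72` degrees counter-clockwise from alley 1. The reward of an
#' alley sits at its far end and is captured (it is invisible until reached)
#' when the participant comes within `capture_radius` of it.
#'
#' The default dimensions are calibrated so that the ideal path from the end
#' of alley 1 to the reward at the end of alley 3 — out of the alley, through
#' the pentagon centroid, and down the goal alley — measures
#' `2 * (alley_length + circumradius) = 246` m.
#'
#' @param circumradius Pentagon circumradius (m).
#' @param alley_length Length of each alley corridor, vertex to far end (m).
#' @param alley_width Corridor width (m); must be smaller than the pentagon
#'   edge so corridors do not overlap at the vertices.
#' @param capture_radius Radius around a reward point within which the reward
#'   is considered found (m).
#' @param landmark_labels Optional character vector of five labels for the
#'   landmarks placed between adjacent alley ends (gap i = between alleys i
#'   and i + 1).
#' @param cue_visibility `"cued"` (landmarks visible) or `"bare"` (landmarks
#'   stripped, as in compelled egocentric trials).
#' @return A `maze_config` object (list).
#' @export
#' @examples
#' cfg <- maze_config()
#' maze <- build_maze(cfg)
#' ideal_path(maze, 1, 3)$length  # 246
maze_config <- function(circumradius = 8,
                        alley_length = 115,
                        alley_width = 4,
                        capture_radius = 2,
                        landmark_labels = NULL,
                        cue_visibility = c("cued", "bare")) {
  cue_visibility <- match.arg(cue_visibility)
  for (nm in c("circumradius", "alley_length", "alley_width", "capture_radius")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("maze configuration error: `", nm, "` must be a single positive number",
           call. = FALSE)
    }
  }
  edge <- 2 * circumradius * sin(pi / 5)
  if (alley_width >= edge) {
    stop("maze configuration error: alley_width (", alley_width,
         " m) must be smaller than the pentagon edge (", signif(edge, 4), " m)",
         call. = FALSE)
  }
  if (capture_radius > alley_length) {
    stop("maze configuration error: capture_radius exceeds alley_length",
         call. = FALSE)
  }
  if (is.null(landmark_labels)) {
    landmark_labels <- paste0("landmark_", 1:5, "_", c(2:5, 1))
  }
  if (length(landmark_labels) != 5L) {
    stop("maze configuration error: landmark_labels must have length 5",
         call. = FALSE)
  }
  structure(
    list(
      circumradius = circumradius,
      alley_length = alley_length,
      alley_width = alley_width,
      n_alleys = 5L,
      capture_radius = capture_radius,
      landmark_labels = as.character(landmark_labels),
      cue_visibility = cue_visibility
    ),
    class = "maze_config"
  )
}

#' Build the maze geometry from a configuration
#'
#' Resolves the configuration into explicit coordinates: pentagon vertices,
#' unit alley directions, alley-end/reward points, and landmark positions
#' (midway between adjacent alley ends).
#'
#' @param config A [maze_config()] object, or a named list of arguments for it.
#' @return A `star_maze` object with elements `config`, `headings_deg`,
#'   `dirs` (5 x 2 unit vectors), `vertices` (5 x 2), `alley_ends` (5 x 2),
#'   `rewards` (alias of `alley_ends`), `landmarks` (5 x 2 with labels), and
#'   `edge_length`.
#' @export
build_maze <- function(config = maze_config()) {
  if (!inherits(config, "maze_config")) {
    if (is.list(config)) {
      config <- do.call(maze_config, config)
    } else {
      stop("maze configuration error: `config` must be a maze_config or list",
           call. = FALSE)
    }
  }
  headings <- (90 + (0:4) * 72) %% 360
  rad <- headings * pi / 180
  dirs <- cbind(cos(rad), sin(rad))
  vertices <- config$circumradius * dirs
  ends <- (config$circumradius + config$alley_length) * dirs
  landmarks <- (ends + ends[c(2:5, 1), , drop = FALSE]) / 2
  rownames(landmarks) <- config$landmark_labels
  colnames(vertices) <- colnames(ends) <- colnames(dirs) <-
    colnames(landmarks) <- c("x", "y")
  structure(
    list(
      config = config,
      headings_deg = headings,
      dirs = dirs,
      vertices = vertices,
      alley_ends = ends,
      rewards = ends,
      landmarks = landmarks,
      edge_length = 2 * config$circumradius * sin(pi / 5)
    ),
    class = "star_maze"
  )
}

#' @export
print.star_maze <- function(x, ...) {
  cfg <- x$config
  cat("<star_maze> regular pentagon, 5 alleys\n")
  cat(sprintf("  circumradius %.3g m, alley %0.4g x %.3g m, capture radius %.3g m\n",
              cfg$circumradius, cfg$alley_length, cfg$alley_width,
              cfg$capture_radius))
  ip <- ideal_path(x, 1L, 3L)
  cat(sprintf("  ideal path alley 1 -> 3: %.4g m, %.3g deg minimum rotation\n",
              ip$length, ip$min_rotation))
  invisible(x)
}

.check_alley_id <- function(alley, maze) {
  if (!is.numeric(alley) || length(alley) != 1L || is.na(alley) ||
      alley != as.integer(alley) || alley < 1L || alley > maze$config$n_alleys) {
    stop("input error: alley id must be an integer in 1..",
         maze$config$n_alleys, call. = FALSE)
  }
  as.integer(alley)
}

# Signed angle wrap into (-180, 180].
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

# Sum of absolute heading changes (deg) along a polyline, zero-length
# segments dropped.
polyline_rotation <- function(pts) {
  dx <- diff(pts[, 1])
  dy <- diff(pts[, 2])
  len <- sqrt(dx^2 + dy^2)
  keep <- len > .Machine$double.eps
  if (sum(keep) < 2L) return(0)
  h <- atan2(dy[keep], dx[keep]) * 180 / pi
  sum(abs(wrap_angle(diff(h))))
}

polyline_length <- function(pts) {
  sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
}

#' Ideal path between two alley ends
#'
#' The ideal (minimum) pathway from the end of the start alley to the reward
#' at the end of the goal alley: down the start alley to its pentagon vertex,
#' through the pentagon centroid, and out to the goal alley end. Its length is
#' the "ideal distance traveled" of the distance-error metric and its total
#' absolute heading change is the "minimum rotations" of the rotation-angle
#' metric. For `start == goal` (turning around, needed when a test trial
#' returns to the start alley's reward) the path is out-and-back to the
#' pentagon vertex with a 180 degree turn.
#'
#' @param maze A [build_maze()] object.
#' @param start_alley,goal_alley Alley ids in 1..5.
#' @return An `ideal_path` list: `polyline` (matrix of x,y waypoints),
#'   `length` (m) and `min_rotation` (deg).
#' @export
ideal_path <- function(maze, start_alley, goal_alley) {
  stopifnot(inherits(maze, "star_maze"))
  s <- .check_alley_id(start_alley, maze)
  g <- .check_alley_id(goal_alley, maze)
  if (s == g) {
    pts <- rbind(maze$alley_ends[s, ], maze$vertices[s, ], maze$alley_ends[s, ])
    len <- 2 * maze$config$alley_length
    rot <- 180
  } else {
    pts <- rbind(
      maze$alley_ends[s, ],
      maze$vertices[s, ],
      c(0, 0),
      maze$vertices[g, ],
      maze$alley_ends[g, ]
    )
    len <- polyline_length(pts)
    rot <- polyline_rotation(pts)
  }
  rownames(pts) <- NULL
  colnames(pts) <- c("x", "y")
  structure(list(polyline = pts, length = len, min_rotation = rot),
            class = "ideal_path")
}

#' Classify points into maze regions
#'
#' Every planar point maps to exactly one label: `"center"` (inside the
#' pentagon), `"alley_i"` (inside corridor i), `"alley_end_i"` (the distal
#' part of corridor i, within twice the capture radius of the far end) or
#' `"outside"`. Where regions touch, the more specific label wins
#' (alley end > alley > center).
#'
#' @param maze A [build_maze()] object.
#' @param x,y Numeric vectors of coordinates (m), recycled to equal length.
#' @return Character vector of region labels.
#' @export
#' @examples
#' maze <- build_maze()
#' locate_points(maze, 0, 0)                     # "center"
#' locate_points(maze, maze$rewards[3, 1], maze$rewards[3, 2])  # "alley_end_3"
locate_points <- function(maze, x, y) {
  stopifnot(inherits(maze, "star_maze"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  cfg <- maze$config
  labels <- rep("outside", n)

  # center: inside the convex pentagon (vertices counter-clockwise)
  inside <- rep(TRUE, n)
  v <- maze$vertices
  for (i in 1:5) {
    j <- if (i == 5) 1L else i + 1L
    ex <- v[j, 1] - v[i, 1]
    ey <- v[j, 2] - v[i, 2]
    cross <- ex * (y - v[i, 2]) - ey * (x - v[i, 1])
    inside <- inside & cross >= 0
  }
  labels[inside] <- "center"

  # corridors, distal end zone takes precedence over plain corridor
  half_w <- cfg$alley_width / 2
  end_zone <- cfg$alley_length - 2 * cfg$capture_radius
  for (i in 1:5) {
    dx <- x - v[i, 1]
    dy <- y - v[i, 2]
    ux <- maze$dirs[i, 1]
    uy <- maze$dirs[i, 2]
    t <- dx * ux + dy * uy           # depth into the alley from its entry
    s <- abs(ux * dy - uy * dx)      # cross-track distance from the axis
    in_corridor <- t >= 0 & t <= cfg$alley_length & s <= half_w
    labels[in_corridor] <- paste0("alley_", i)
    labels[in_corridor & t >= end_zone] <- paste0("alley_end_", i)
  }
  labels
}

# Per-alley depth t (m from the alley entry) and cross-track distance s for
# all samples; used by the visited-alley counter. Returns list(t, s) of
# n x 5 matrices.
.alley_coords <- function(maze, x, y) {
  n <- length(x)
  t <- s <- matrix(NA_real_, n, 5)
  v <- maze$vertices
  for (i in 1:5) {
    dx <- x - v[i, 1]
    dy <- y - v[i, 2]
    t[, i] <- dx * maze$dirs[i, 1] + dy * maze$dirs[i, 2]
    s[, i] <- abs(maze$dirs[i, 1] * dy - maze$dirs[i, 2] * dx)
  }
  list(t = t, s = s)
}

#' Sample a trajectory that exactly traces the ideal path
#'
#' Samples the ideal polyline at a nominal rate and constant speed. The
#' polyline breakpoints are inserted as additional samples so the sampled
#' trajectory preserves the exact ideal length and rotation (a pure grid
#' would cut the corner at the centroid).
#'
#' @inheritParams ideal_path
#' @param sampling_rate Samples per second (Hz).
#' @param speed Walking speed (m/s).
#' @return A [trajectory()] object.
#' @export
ideal_trajectory <- function(maze, start_alley, goal_alley,
                             sampling_rate = 120, speed = 8) {
  stopifnot(speed > 0, sampling_rate > 0)
  ip <- ideal_path(maze, start_alley, goal_alley)
  pts <- ip$polyline
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  t_total <- total / speed
  t_grid <- seq(0, t_total, by = 1 / sampling_rate)
  t_all <- sort(unique(c(t_grid, cum / speed, t_total)))
  s_all <- t_all * speed
  x <- stats::approx(cum, pts[, 1], xout = s_all, rule = 2)$y
  y <- stats::approx(cum, pts[, 2], xout = s_all, rule = 2)$y
  trajectory(t_all, x, y, sampling_rate = sampling_rate)
}
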