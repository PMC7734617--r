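#' Construct a sampled planar trajectory
#'
#' A trajectory is the recorded position time series of one navigation trial:
#' strictly increasing times (s) and planar coordinates (m) in the maze frame.
#'
#' @param time_s,x_m,y_m Equal-length numeric vectors.
#' @param sampling_rate Nominal sampling rate (Hz), kept as metadata.
#' @param trial_index Optional protocol trial index this trajectory belongs to.
#' @return A tibble of class `maze_trajectory` with columns
#'   `time_s`, `x_m`, `y_m`.
#' @export
trajectory <- function(time_s, x_m, y_m, sampling_rate = 120,
                       trial_index = NA_integer_) {
  time_s <- as.numeric(time_s)
  x_m <- as.numeric(x_m)
  y_m <- as.numeric(y_m)
  n <- length(time_s)
  if (length(x_m) != n || length(y_m) != n) {
    stop("trajectory validation error: time_s, x_m, y_m must have equal length",
         call. = FALSE)
  }
  if (n < 2L) {
    stop("trajectory validation error: at least 2 samples are required",
         call. = FALSE)
  }
  if (anyNA(time_s) || anyNA(x_m) || anyNA(y_m) ||
      any(!is.finite(time_s)) || any(!is.finite(x_m)) || any(!is.finite(y_m))) {
    stop("trajectory validation error: non-numeric or non-finite samples",
         call. = FALSE)
  }
  if (any(diff(time_s) <= 0)) {
    stop("trajectory validation error: time must be strictly increasing",
         call. = FALSE)
  }
  out <- tibble::tibble(time_s = time_s, x_m = x_m, y_m = y_m)
  class(out) <- c("maze_trajectory", class(out))
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "trial_index") <- as.integer(trial_index)
  out
}

#' Read a trajectory from CSV
#'
#' The canonical dialect is a comma-separated file with header
#' `time_s,x_m,y_m`. Other layouts (e.g. deposited datasets with different
#' column names or units) can be adapted with `col_map` and the unit scale
#' factors. The reader is strict: missing columns are a format error;
#' non-numeric rows, fewer than 2 rows, or non-monotone time are validation
#' errors.
#'
#' @param path Path to a CSV file.
#' @param col_map Named character vector mapping canonical names to source
#'   column names, e.g. `c(time_s = "t", x_m = "posx", y_m = "posy")`.
#' @param time_scale,length_scale Multipliers applied to the source values to
#'   convert to seconds and metres.
#' @inheritParams trajectory
#' @return A [trajectory()] object.
#' @export
read_trajectory <- function(path,
                            col_map = c(time_s = "time_s", x_m = "x_m", y_m = "y_m"),
                            time_scale = 1, length_scale = 1,
                            sampling_rate = 120,
                            trial_index = NA_integer_) {
  if (!file.exists(path)) {
    stop("I/O error: trajectory file not found: ", path, call. = FALSE)
  }
  needed <- c("time_s", "x_m", "y_m")
  if (!all(needed %in% names(col_map))) {
    stop("format error: col_map must name time_s, x_m and y_m", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(col_map[needed]), names(df))
  if (length(missing)) {
    stop("format error: ", path, " lacks column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- lapply(needed, function(nm) {
    v <- df[[col_map[[nm]]]]
    suppressWarnings(as.numeric(v))
  })
  if (anyNA(num[[1]]) || anyNA(num[[2]]) || anyNA(num[[3]])) {
    stop("trajectory validation error: non-numeric rows in ", path,
         call. = FALSE)
  }
  trajectory(num[[1]] * time_scale, num[[2]] * length_scale,
             num[[3]] * length_scale,
             sampling_rate = sampling_rate, trial_index = trial_index)
}

#' Write a trajectory as canonical CSV
#'
#' Fixed six-decimal formatting with a `.` decimal point regardless of
#' locale, so that write -> read -> write round-trips byte-identically.
#'
#' @param traj A [trajectory()] object (or data frame with the canonical
#'   columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (is.null(traj) || !is.data.frame(traj) || nrow(traj) == 0L) {
    stop("trajectory validation error: empty trajectory cannot be written",
         call. = FALSE)
  }
  if (!all(c("time_s", "x_m", "y_m") %in% names(traj))) {
    stop("format error: trajectory lacks canonical columns", call. = FALSE)
  }
  lines <- c(
    "time_s,x_m,y_m",
    sprintf("%.6f,%.6f,%.6f", traj$time_s, traj$x_m, traj$y_m)
  )
  writeLines(lines, path)
  invisible(path)
}
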