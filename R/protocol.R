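#' Build one trial specification
#'
#' A trial is defined by its task, type, start alley, reward alleys, cue
#' visibility and time limit. Invariants of the canonical protocol are
#' enforced: training trials start in alley 1 with the reward in alley 3;
#' test trials start in alley 4 with rewards in alleys 1 and 3; compelled
#' allocentric trials start in alley 2 or 5 (cued) with the reward in
#' alley 3; compelled egocentric trials start in alley 1 with the reward in
#' alley 3 in the bare maze.
#'
#' @param trial_index 1-based position in the session.
#' @param task `"task1"` or `"task2"`.
#' @param trial_type One of `"training"`, `"test"`, `"compelled_AS"`,
#'   `"compelled_ES"`.
#' @param start_alley Alley id 1..5.
#' @param reward_alleys Integer vector of 1 or 2 alley ids.
#' @param cue_visibility `"cued"` or `"bare"`.
#' @param time_limit Seconds allowed per navigation (default 120).
#' @param training_index,test_index Optional 1-based counters within the
#'   training / test subsequences.
#' @return A one-row tibble.
#' @export
trial_spec <- function(trial_index, task, trial_type, start_alley,
                       reward_alleys, cue_visibility = "cued",
                       time_limit = 120,
                       training_index = NA_integer_,
                       test_index = NA_integer_) {
  task <- match.arg(task, c("task1", "task2"))
  trial_type <- match.arg(trial_type,
                          c("training", "test", "compelled_AS", "compelled_ES"))
  cue_visibility <- match.arg(cue_visibility, c("cued", "bare"))
  start_alley <- as.integer(start_alley)
  reward_alleys <- sort(unique(as.integer(reward_alleys)))
  if (!length(reward_alleys) %in% 1:2 || any(reward_alleys < 1 | reward_alleys > 5)) {
    stop("protocol error: reward_alleys must be 1 or 2 alley ids in 1..5",
         call. = FALSE)
  }
  ok <- switch(trial_type,
    training = start_alley == 1L && identical(reward_alleys, 3L),
    test = start_alley == 4L && identical(reward_alleys, c(1L, 3L)),
    compelled_AS = start_alley %in% c(2L, 5L) && identical(reward_alleys, 3L) &&
      cue_visibility == "cued",
    compelled_ES = start_alley == 1L && identical(reward_alleys, 3L) &&
      cue_visibility == "bare"
  )
  if (!ok) {
    stop("protocol error: trial ", trial_index, " (", trial_type,
         ") violates the canonical start/reward/cue invariants", call. = FALSE)
  }
  tibble::tibble(
    trial_index = as.integer(trial_index),
    task = task,
    trial_type = trial_type,
    start_alley = start_alley,
    reward_alleys = list(reward_alleys),
    cue_visibility = cue_visibility,
    time_limit = as.numeric(time_limit),
    training_index = as.integer(training_index),
    test_index = as.integer(test_index)
  )
}

#' The canonical two-task trial schedule
#'
#' Task 1 ("free navigation") is 21 trials: 16 training trials (start alley 1,
#' reward alley 3) with 5 interposed test trials (start alley 4, rewards in
#' alleys 1 and 3) at positions 6, 10, 14, 17 and 21. Task 2 ("compelled
#' strategies") is 7 trials — four compelled allocentric trials starting from
#' alleys 2 and 5 (twice each, cued) and three compelled egocentric trials
#' (start alley 1, bare maze) — in a counterbalanced order that is a pure
#' function of `counterbalance_seed`.
#'
#' @param counterbalance_seed Integer seed determining the Task 2 item order.
#' @return A `maze_protocol` tibble of 28 trial specifications.
#' @export
#' @examples
#' p <- default_protocol(1)
#' table(p$trial_type)
default_protocol <- function(counterbalance_seed = 1L) {
  test_positions <- c(6L, 10L, 14L, 17L, 21L)
  rows <- vector("list", 28L)
  tr <- 0L
  te <- 0L
  for (i in 1:21) {
    if (i %in% test_positions) {
      te <- te + 1L
      rows[[i]] <- trial_spec(i, "task1", "test", 4L, c(1L, 3L),
                              test_index = te)
    } else {
      tr <- tr + 1L
      rows[[i]] <- trial_spec(i, "task1", "training", 1L, 3L,
                              training_index = tr)
    }
  }
  items <- c(rep("compelled_AS", 4L), rep("compelled_ES", 3L))
  order <- withr::with_seed(as.integer(counterbalance_seed),
                            sample(seq_along(items)))
  items <- items[order]
  as_starts <- c(2L, 5L, 2L, 5L)
  as_k <- 0L
  for (j in seq_along(items)) {
    idx <- 21L + j
    if (items[j] == "compelled_AS") {
      as_k <- as_k + 1L
      rows[[idx]] <- trial_spec(idx, "task2", "compelled_AS",
                                as_starts[as_k], 3L)
    } else {
      rows[[idx]] <- trial_spec(idx, "task2", "compelled_ES", 1L, 3L,
                                cue_visibility = "bare")
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("maze_protocol", class(out))
  attr(out, "counterbalance_seed") <- as.integer(counterbalance_seed)
  out
}

# Fetch the spec row for a trial index; errors on unknown indices.
protocol_row <- function(protocol, trial_index) {
  row <- protocol[protocol$trial_index == trial_index, ]
  if (nrow(row) != 1L) {
    stop("protocol error: unknown trial index ", trial_index, call. = FALSE)
  }
  row
}

# Reward alleys of a (one-row) spec, as an integer vector.
spec_rewards <- function(spec) {
  r <- spec$reward_alleys
  if (is.list(r)) r <- r[[1]]
  as.integer(r)
}
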