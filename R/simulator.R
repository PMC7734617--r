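#' Configure a simulated navigating agent
#'
#' Agents emulate the behaviours the task elicits. An `egocentric` agent
#' replays the trained start-relative motor sequence (alley offset +2 mod 5,
#' so from the test start in alley 4 it lands in alley 1); an `allocentric`
#' agent steers to the landmark-defined goal (alley 3) from any cued start,
#' and degrades to searching behaviour in the bare maze; a `shifter`
#' alternates between the two on test trials; a `lost` agent wanders,
#' peering partway into alleys and only occasionally walking one to its end.
#'
#' Errors decay over training: on training trial `t` the agent errs with
#' probability `initial_error_prob * (1 - learning_rate)^(t - 1)`; an error
#' either derails the whole trial (probability `error_fail_prob`: the agent
#' wanders until the time limit) or inserts one or two wrong-alley
#' excursions before the reward.
#'
#' @param strategy `"egocentric"`, `"allocentric"`, `"shifter"` or `"lost"`.
#' @param learning_rate Per-trial decay of the error probability, in (0, 1].
#' @param initial_error_prob Error probability on the first training trial.
#' @param error_fail_prob Probability that an error derails the trial
#'   entirely rather than adding a detour.
#' @param path_jitter_sd Cross-track jitter amplitude (m); smooth lateral
#'   wobble around the planned path.
#' @param speed_mean,speed_sd Mean and SD of the lognormal per-trial walking
#'   speed (m/s).
#' @param switch_prob Shifter only: probability of switching strategy after
#'   each test trial (1 = strict alternation).
#' @param walk_prob Lost only: probability that a wandering move commits to
#'   an alley end instead of a partial peek.
#' @return An `agent_config` object.
#' @export
agent_config <- function(strategy = c("egocentric", "allocentric",
                                      "shifter", "lost"),
                         learning_rate = 0.5,
                         initial_error_prob = 0.6,
                         error_fail_prob = 0.5,
                         path_jitter_sd = 0.5,
                         speed_mean = 8,
                         speed_sd = 1.5,
                         switch_prob = 1,
                         walk_prob = 0.3) {
  strategy <- match.arg(strategy)
  for (p in c("learning_rate", "initial_error_prob", "error_fail_prob",
              "switch_prob", "walk_prob")) {
    v <- get(p)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop("agent configuration error: `", p, "` must lie in [0, 1]",
           call. = FALSE)
    }
  }
  if (learning_rate == 0) {
    stop("agent configuration error: learning_rate must be in (0, 1]",
         call. = FALSE)
  }
  if (speed_mean <= 0 || speed_sd < 0) {
    stop("agent configuration error: speeds must be positive", call. = FALSE)
  }
  structure(
    list(strategy = strategy, learning_rate = learning_rate,
         initial_error_prob = initial_error_prob,
         error_fail_prob = error_fail_prob,
         path_jitter_sd = path_jitter_sd,
         speed_mean = speed_mean, speed_sd = speed_sd,
         switch_prob = switch_prob, walk_prob = walk_prob,
         learned_offset = 2L,   # trained alley-1 -> alley-3 sequence
         learned_goal = 3L),    # landmark-defined goal alley
    class = "agent_config"
  )
}

# Waypoint polyline for a sequence of alley visits. `visits` is a list of
# c(alley, frac); each visit routes current position -> own vertex ->
# centroid -> new vertex -> point at frac * alley_length into the new alley.
.plan_waypoints <- function(maze, start_alley, visits) {
  L <- maze$config$alley_length
  pt_at <- function(a, frac) maze$vertices[a, ] + frac * L * maze$dirs[a, ]
  pts <- list(pt_at(start_alley, 1))
  current <- start_alley
  for (v in visits) {
    a <- v[1]
    frac <- v[2]
    pts[[length(pts) + 1L]] <- maze$vertices[current, ]
    pts[[length(pts) + 1L]] <- c(0, 0)
    pts[[length(pts) + 1L]] <- maze$vertices[a, ]
    pts[[length(pts) + 1L]] <- pt_at(a, frac)
    current <- a
  }
  do.call(rbind, pts)
}

# Wandering visit sequence: partial peeks into random alleys with, after at
# least `min_peeks` peeks, occasional full walks to an alley end, until the
# planned length exceeds the budget. A wanderer peers around before
# committing, and commits to alleys it has not explored yet, so its trials
# always show inefficient multi-alley exploration.
.wander_visits <- function(start_alley, budget_len, maze, walk_prob = 0,
                           min_peeks = 2L) {
  L <- maze$config$alley_length
  R <- maze$config$circumradius
  visits <- list()
  current <- start_alley
  cur_frac <- 1
  total <- 0
  explored <- start_alley
  n_moves <- 0L
  while (total < budget_len) {
    walk <- n_moves >= min_peeks && stats::runif(1) < walk_prob
    if (walk) {
      pool <- setdiff(1:5, explored)
      if (!length(pool)) pool <- setdiff(1:5, current)
      a <- if (length(pool) == 1L) pool else sample(pool, 1L)
      frac <- 1
    } else {
      a <- sample(setdiff(1:5, current), 1L)
      frac <- stats::runif(1, 0.2, 0.6)
    }
    visits[[length(visits) + 1L]] <- c(a, frac)
    total <- total + cur_frac * L + 2 * R + frac * L
    current <- a
    explored <- union(explored, a)
    n_moves <- n_moves + 1L
  }
  visits
}

# Smooth cross-track jitter profile along arc length: a sum of three random
# sinusoids with RMS amplitude `sd` (bounded by ~2.45 * sd).
.jitter_profile <- function(s, sd) {
  if (sd <= 0) return(rep(0, length(s)))
  w <- stats::runif(3, 0.5, 1)
  w <- w / sqrt(sum(w^2))
  lambda <- stats::runif(3, 25, 60)
  phase <- stats::runif(3, 0, 2 * pi)
  e <- rep(0, length(s))
  for (j in 1:3) {
    e <- e + w[j] * sin(2 * pi * s / lambda[j] + phase[j])
  }
  sd * sqrt(2) * e
}

# Sample a planned waypoint polyline at constant speed, add cross-track
# jitter, truncate at the time limit and at reward capture.
.sample_plan <- function(pts, speed, time_limit, sampling_rate, jitter_sd,
                         rewards_xy, capture_radius) {
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  keep <- seg > .Machine$double.eps
  if (any(!keep)) {
    pts <- pts[c(TRUE, keep), , drop = FALSE]
    seg <- seg[keep]
  }
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  t_end <- min(total / speed, time_limit)
  times <- seq(0, t_end, by = 1 / sampling_rate)
  if (length(times) < 2L) times <- c(0, 1 / sampling_rate)
  s <- pmin(times * speed, total)
  x <- stats::approx(cum, pts[, 1], xout = s, rule = 2)$y
  y <- stats::approx(cum, pts[, 2], xout = s, rule = 2)$y
  if (jitter_sd > 0) {
    e <- .jitter_profile(s, jitter_sd)
    # unit tangent by one-sided differences (repeating the last step)
    dx <- diff(x)
    dy <- diff(y)
    dx <- c(dx, dx[length(dx)])
    dy <- c(dy, dy[length(dy)])
    nrm <- sqrt(dx^2 + dy^2)
    nrm[nrm == 0] <- 1
    x <- x - e * dy / nrm
    y <- y + e * dx / nrm
  }
  # capture: first sample within the capture radius of any reward
  cap_idx <- NA_integer_
  if (nrow(rewards_xy) > 0) {
    cap2 <- capture_radius^2
    for (r in seq_len(nrow(rewards_xy))) {
      d2 <- (x - rewards_xy[r, 1])^2 + (y - rewards_xy[r, 2])^2
      hit <- which(d2 <= cap2)
      if (length(hit) && (is.na(cap_idx) || hit[1] < cap_idx)) {
        cap_idx <- hit[1]
      }
    }
  }
  if (!is.na(cap_idx)) {
    n <- max(cap_idx, 2L)
    times <- times[seq_len(n)]
    x <- x[seq_len(n)]
    y <- y[seq_len(n)]
  }
  list(times = times, x = x, y = y, captured = !is.na(cap_idx))
}

# Target alley implied by the agent's strategy for this trial; NA means the
# agent has no usable target (lost, or allocentric in the bare maze).
.agent_target <- function(agent, spec, state) {
  replay <- function(start) ((start - 1L + agent$learned_offset) %% 5L) + 1L
  switch(agent$strategy,
    egocentric = replay(spec$start_alley),
    allocentric = if (identical(spec$cue_visibility, "cued"))
      agent$learned_goal else NA_integer_,
    shifter = {
      if (identical(spec$trial_type, "test")) {
        if (state$shifter_side == "AS") agent$learned_goal
        else replay(spec$start_alley)
      } else if (identical(spec$cue_visibility, "cued")) {
        agent$learned_goal
      } else {
        replay(spec$start_alley)
      }
    },
    lost = NA_integer_
  )
}

#' Simulate one trial of an agent
#'
#' Draws from the current RNG stream; wrap in [withr::with_seed()] (or let
#' [simulate_cohort()] do so) for reproducibility.
#'
#' @param agent An [agent_config()].
#' @param spec A one-row trial specification.
#' @param maze A [build_maze()] object.
#' @param state Agent state list (`n_training_done`, `shifter_side`); use
#'   `NULL` to start fresh.
#' @param sampling_rate Trajectory sampling rate (Hz).
#' @return List with `trajectory`, updated `state`, and `truth` (planned
#'   target, whether an error was planted, realized success).
#' @export
simulate_trial <- function(agent, spec, maze, state = NULL,
                           sampling_rate = 120) {
  if (is.null(state)) {
    state <- list(n_training_done = 0L,
                  shifter_side = sample(c("AS", "ES"), 1L))
  }
  cfg <- maze$config
  training_no <- if (identical(spec$trial_type, "training")) {
    state$n_training_done + 1L
  } else {
    16L + 1L  # post-training residual error level
  }
  p_err <- agent$initial_error_prob *
    (1 - agent$learning_rate)^(training_no - 1L)
  target <- .agent_target(agent, spec, state)
  speed <- if (agent$speed_sd > 0) {
    m <- agent$speed_mean
    s <- agent$speed_sd
    stats::rlnorm(1, meanlog = log(m^2 / sqrt(m^2 + s^2)),
                  sdlog = sqrt(log(1 + s^2 / m^2)))
  } else {
    agent$speed_mean
  }
  budget <- speed * spec$time_limit * 1.1
  error <- FALSE
  derailed <- FALSE
  if (is.na(target)) {
    # no usable target: lost agents may commit to alley ends, a degraded
    # allocentric agent only searches
    walk_p <- if (agent$strategy == "lost") agent$walk_prob else 0
    visits <- .wander_visits(spec$start_alley, budget, maze, walk_p)
  } else {
    error <- stats::runif(1) < p_err
    if (error && stats::runif(1) < agent$error_fail_prob) {
      derailed <- TRUE
      visits <- .wander_visits(spec$start_alley, budget, maze, 0)
    } else if (error) {
      k <- sample(1:2, 1L)
      pool <- setdiff(1:5, c(spec$start_alley, target))
      wrong <- sample(pool, k)
      visits <- lapply(wrong, function(a) c(a, stats::runif(1, 0.5, 0.9)))
      visits[[length(visits) + 1L]] <- c(target, 1)
    } else {
      visits <- list(c(target, 1))
    }
  }
  pts <- .plan_waypoints(maze, spec$start_alley, visits)
  rewards_xy <- maze$rewards[spec_rewards(spec), , drop = FALSE]
  samp <- .sample_plan(pts, speed, spec$time_limit, sampling_rate,
                       agent$path_jitter_sd, rewards_xy, cfg$capture_radius)
  traj <- trajectory(samp$times, samp$x, samp$y,
                     sampling_rate = sampling_rate,
                     trial_index = spec$trial_index)
  if (identical(spec$trial_type, "training")) {
    state$n_training_done <- state$n_training_done + 1L
  }
  if (identical(spec$trial_type, "test")) {
    if (stats::runif(1) < agent$switch_prob) {
      state$shifter_side <- if (state$shifter_side == "AS") "ES" else "AS"
    }
  }
  list(
    trajectory = traj,
    state = state,
    truth = tibble::tibble(
      trial_index = spec$trial_index,
      trial_type = spec$trial_type,
      target = target,
      error = error,
      derailed = derailed,
      success = samp$captured,
      speed = speed
    )
  )
}

#' Simulate one participant's full session
#'
#' Runs the agent through every trial of the protocol, recording the
#' trajectory and the generating ground truth (true strategy, planted
#' errors, realized successes and the resulting true learning onset).
#'
#' @inheritParams simulate_trial
#' @param protocol A [default_protocol()] tibble.
#' @param participant_id,group Metadata for the session.
#' @param meta Optional named list of extra metadata fields
#'   (`sex`, `age_years`, z-scores, ...) passed to [participant_session()].
#' @return A [participant_session()] with a `truth` element.
#' @export
simulate_session <- function(agent, protocol, maze,
                             participant_id = "P1", group = "TD",
                             meta = list(), sampling_rate = 120) {
  state <- NULL
  trials <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(protocol))) {
    spec <- protocol[i, ]
    res <- simulate_trial(agent, spec, maze, state, sampling_rate)
    state <- res$state
    trials[[as.character(spec$trial_index)]] <- res$trajectory
    truth_rows[[i]] <- res$truth
  }
  truth <- dplyr::bind_rows(truth_rows)
  train_succ <- truth$success[truth$trial_type == "training"]
  onset <- learning_onset(train_succ)$onset
  args <- c(
    list(participant_id = participant_id, group = group, trials = trials,
         truth = list(strategy = agent$strategy, trials = truth,
                      onset = onset, agent = agent)),
    meta
  )
  do.call(participant_session, args)
}

#' Configure a synthetic cohort
#'
#' Group-level mixtures of agent strategies (defaults mirror the strategy
#' shares observed in the study cohort), group-level learning parameters
#' with per-agent heterogeneity, and a z-score generation model that plants
#' a monotone link between an agent's error level and its visuospatial
#' scores: `z = intercept + slope * initial_error_prob + N(0, sd)`.
#'
#' @param n_td,n_cp Group sizes.
#' @param mixture_td,mixture_cp Named strategy mixture weights (must sum
#'   to 1).
#' @param td_agent,cp_agent Named lists of [agent_config()] overrides per
#'   group (learning rate, error level, jitter, speeds...).
#' @param error_sd Per-agent SD of `initial_error_prob` around the group
#'   level (truncated to \[0.02, 0.95\]).
#' @param zscore_model Named list with `corsi`, `labyrinth`, `raven`
#'   components, each `c(intercept, slope, sd)`.
#' @param sex_p_m Named probabilities of male sex per group.
#' @param age_mean,age_sd Age distribution (years).
#' @param counterbalance_seed Protocol seed.
#' @param sampling_rate Trajectory sampling rate (Hz).
#' @param seed Master seed; the whole cohort is a pure function of it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_td = 13L, n_cp = 15L,
                          mixture_td = c(allocentric = 0.54,
                                         egocentric = 0.31,
                                         shifter = 0.15, lost = 0),
                          mixture_cp = c(allocentric = 0.27,
                                         egocentric = 0.53,
                                         shifter = 0.07, lost = 0.13),
                          td_agent = list(initial_error_prob = 0.3,
                                          learning_rate = 0.6),
                          cp_agent = list(initial_error_prob = 0.6,
                                          learning_rate = 0.35),
                          error_sd = 0.15,
                          zscore_model = list(
                            corsi = c(intercept = 1.2, slope = -2.5, sd = 0.4),
                            labyrinth = c(intercept = 1.0, slope = -2.0, sd = 0.5),
                            raven = c(intercept = 1.8, slope = -1.5, sd = 1.0)
                          ),
                          sex_p_m = c(CP = 11 / 15, TD = 5 / 13),
                          age_mean = 10.4, age_sd = 2.2,
                          counterbalance_seed = 1L,
                          sampling_rate = 120,
                          seed = 1L) {
  for (mx in list(mixture_td, mixture_cp)) {
    if (is.null(names(mx)) ||
        !all(names(mx) %in% c("allocentric", "egocentric", "shifter", "lost")) ||
        abs(sum(mx) - 1) > 1e-8 || any(mx < 0)) {
      stop("cohort configuration error: mixtures must be named non-negative ",
           "weights over the four strategies summing to 1", call. = FALSE)
    }
  }
  structure(
    list(n_td = n_td, n_cp = n_cp,
         mixture_td = mixture_td, mixture_cp = mixture_cp,
         td_agent = td_agent, cp_agent = cp_agent, error_sd = error_sd,
         zscore_model = zscore_model, sex_p_m = sex_p_m,
         age_mean = age_mean, age_sd = age_sd,
         counterbalance_seed = as.integer(counterbalance_seed),
         sampling_rate = sampling_rate, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Draw one participant's agent + metadata under the group settings.
.draw_participant <- function(config, group, id) {
  mix <- if (group == "TD") config$mixture_td else config$mixture_cp
  base <- if (group == "TD") config$td_agent else config$cp_agent
  strategy <- sample(names(mix), 1L, prob = mix)
  args <- utils::modifyList(list(strategy = strategy), base)
  err <- min(0.95, max(0.02, stats::rnorm(1, args$initial_error_prob %||% 0.6,
                                          config$error_sd)))
  args$initial_error_prob <- err
  agent <- do.call(agent_config, args)
  zm <- config$zscore_model
  draw_z <- function(coef) {
    coef[["intercept"]] + coef[["slope"]] * err + stats::rnorm(1, 0, coef[["sd"]])
  }
  meta <- list(
    sex = sample(c("M", "F"), 1L,
                 prob = c(config$sex_p_m[[group]], 1 - config$sex_p_m[[group]])),
    age_years = round(stats::rnorm(1, config$age_mean, config$age_sd), 1),
    corsi_z = round(draw_z(zm$corsi), 2),
    labyrinth_z = round(draw_z(zm$labyrinth), 2),
    raven_z = round(draw_z(zm$raven), 2)
  )
  list(agent = agent, meta = meta)
}

#' Simulate a full synthetic cohort
#'
#' Fully reproducible from `config$seed`: agents are drawn from the group
#' mixtures, run through the complete protocol, and returned as a
#' [maze_cohort()] whose sessions carry the generating ground truth. Use
#' [write_cohort()] to emit the manifest + trajectory CSVs.
#'
#' @param config A [cohort_config()].
#' @param maze Optional prebuilt maze.
#' @return A [maze_cohort()].
#' @export
simulate_cohort <- function(config = cohort_config(), maze = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(maze)) maze <- build_maze()
  protocol <- default_protocol(config$counterbalance_seed)
  withr::with_seed(config$seed, {
    sessions <- list()
    for (group in c("TD", "CP")) {
      n <- if (group == "TD") config$n_td else config$n_cp
      for (i in seq_len(n)) {
        id <- sprintf("%s%02d", group, i)
        drawn <- .draw_participant(config, group, id)
        sessions[[id]] <- simulate_session(
          drawn$agent, protocol, maze,
          participant_id = id, group = group, meta = drawn$meta,
          sampling_rate = config$sampling_rate
        )
      }
    }
    maze_cohort(sessions, protocol = protocol, maze_config = maze$config)
  })
}

#' Ground-truth table of a simulated cohort
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @return Tibble with `participant_id`, `group`, `true_strategy`,
#'   `true_label` (the participant-classification label the generating
#'   strategy corresponds to) and `true_onset`.
#' @export
cohort_truth <- function(cohort) {
  label_map <- c(egocentric = "Egocentric", allocentric = "Allocentric",
                 shifter = "Shifter", lost = "Lacking")
  rows <- lapply(cohort$sessions, function(s) {
    strat <- if (!is.null(s$truth)) s$truth$strategy else NA_character_
    tibble::tibble(
      participant_id = s$participant_id,
      group = s$group,
      true_strategy = strat,
      true_label = if (!is.na(strat)) unname(label_map[strat]) else NA_character_,
      true_onset = if (!is.null(s$truth)) s$truth$onset else NA_integer_
    )
  })
  dplyr::bind_rows(rows)
}
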