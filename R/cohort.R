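#' Construct one participant's session
#'
#' Bundles a participant's metadata (group, motor-severity levels, test
#' z-scores) with their per-trial trajectories. The visuospatial and
#' cognitive z-scores (Corsi block, Labyrinth, Raven) are inputs measured
#' outside the maze task.
#'
#' @param participant_id Character id.
#' @param group `"CP"` or `"TD"`.
#' @param sex Optional `"M"`/`"F"`.
#' @param age_years Optional age.
#' @param gmfcs,macs Optional severity levels (`"I"`, `"II"`, `"III"`).
#' @param raven_z,corsi_z,labyrinth_z Optional z-scores.
#' @param trials Named list of [trajectory()] objects; names are protocol
#'   trial indices.
#' @param truth Optional list of simulator ground truth (kept alongside for
#'   parameter-recovery studies).
#' @return A `participant_session` object.
#' @export
participant_session <- function(participant_id, group,
                                sex = NA_character_, age_years = NA_real_,
                                gmfcs = NA_character_, macs = NA_character_,
                                raven_z = NA_real_, corsi_z = NA_real_,
                                labyrinth_z = NA_real_,
                                trials = list(), truth = NULL) {
  if (!is.character(group) || length(group) != 1L || !group %in% c("CP", "TD")) {
    stop("cohort validation error: group must be \"CP\" or \"TD\" (participant ",
         participant_id, ")", call. = FALSE)
  }
  if (length(trials) && is.null(names(trials))) {
    stop("cohort validation error: trials must be named by trial index",
         call. = FALSE)
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      group = group,
      sex = sex,
      age_years = as.numeric(age_years),
      gmfcs = gmfcs,
      macs = macs,
      raven_z = as.numeric(raven_z),
      corsi_z = as.numeric(corsi_z),
      labyrinth_z = as.numeric(labyrinth_z),
      trials = trials,
      truth = truth
    ),
    class = "participant_session"
  )
}

#' Assemble sessions into a cohort
#'
#' @param sessions List of [participant_session()] objects.
#' @param protocol A [default_protocol()] tibble shared by all sessions.
#' @param maze_config The [maze_config()] the trajectories live in.
#' @return A `maze_cohort` object.
#' @export
maze_cohort <- function(sessions, protocol = default_protocol(),
                        maze_config = starmaze::maze_config()) {
  ids <- vapply(sessions, function(s) s$participant_id, character(1))
  if (anyDuplicated(ids)) {
    stop("cohort validation error: duplicated participant ids", call. = FALSE)
  }
  names(sessions) <- ids
  ok_idx <- as.character(protocol$trial_index)
  for (s in sessions) {
    bad <- setdiff(names(s$trials), ok_idx)
    if (length(bad)) {
      stop("cohort validation error: participant ", s$participant_id,
           " has trials outside the protocol: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(sessions = sessions, protocol = protocol, maze_config = maze_config),
    class = "maze_cohort"
  )
}

#' @export
print.maze_cohort <- function(x, ...) {
  groups <- vapply(x$sessions, function(s) s$group, character(1))
  cat("<maze_cohort> ", length(x$sessions), " participants (",
      sum(groups == "CP"), " CP, ", sum(groups == "TD"), " TD), ",
      nrow(x$protocol), "-trial protocol\n", sep = "")
  invisible(x)
}

#' Read a cohort from a manifest file
#'
#' The manifest (JSON or YAML by extension) lists the maze configuration,
#' the protocol counterbalance seed and, per participant, metadata and the
#' trajectory file of each recorded trial (paths relative to the manifest).
#' Trials listed in the protocol but absent from the manifest are recorded as
#' missing with a warning, not an error; a listed file that does not exist is
#' an I/O error naming the participant and trial.
#'
#' @param manifest_path Path to `manifest.json` / `manifest.yaml`.
#' @return A [maze_cohort()] object.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("I/O error: manifest not found: ", manifest_path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(manifest_path))
  man <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(manifest_path)
  } else {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  }
  base <- dirname(manifest_path)
  cfg_args <- man$maze %||% list()
  config <- do.call(maze_config, cfg_args)
  seed <- man$protocol$counterbalance_seed %||% 1L
  protocol <- default_protocol(seed)
  rate <- man$sampling_rate %||% 120

  if (is.null(man$participants) || !length(man$participants)) {
    stop("cohort validation error: manifest lists no participants",
         call. = FALSE)
  }
  n_missing <- 0L
  sessions <- lapply(man$participants, function(p) {
    trials <- list()
    for (tr in p$trials %||% list()) {
      idx <- as.integer(tr$trial_index)
      fp <- file.path(base, tr$file)
      if (!file.exists(fp)) {
        stop("I/O error: trajectory file for participant ", p$id,
             ", trial ", idx, " not found: ", fp, call. = FALSE)
      }
      trials[[as.character(idx)]] <-
        read_trajectory(fp, sampling_rate = rate, trial_index = idx)
    }
    absent <- setdiff(protocol$trial_index, as.integer(names(trials)))
    n_missing <<- n_missing + length(absent)
    participant_session(
      participant_id = p$id, group = p$group %||% NA_character_,
      sex = p$sex %||% NA_character_,
      age_years = p$age_years %||% NA_real_,
      gmfcs = p$gmfcs %||% NA_character_, macs = p$macs %||% NA_character_,
      raven_z = p$raven_z %||% NA_real_, corsi_z = p$corsi_z %||% NA_real_,
      labyrinth_z = p$labyrinth_z %||% NA_real_,
      trials = trials
    )
  })
  if (n_missing > 0L) {
    warning(n_missing, " protocol trial(s) have no recorded trajectory; ",
            "they are treated as missing", call. = FALSE)
  }
  maze_cohort(sessions, protocol = protocol, maze_config = config)
}

#' Write a cohort as a manifest plus canonical trajectory CSVs
#'
#' Inverse of [read_cohort()]: one sub-directory per participant holding
#' `trial_XX.csv` files, plus a `manifest.json` at the top. Output is
#' deterministic, so identical cohorts write byte-identical directories.
#'
#' @param cohort A [maze_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "maze_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  participants <- lapply(cohort$sessions, function(s) {
    pdir <- file.path(dir, s$participant_id)
    dir.create(pdir, showWarnings = FALSE)
    trials <- lapply(names(s$trials), function(idx) {
      fn <- file.path(s$participant_id, sprintf("trial_%02d.csv", as.integer(idx)))
      write_trajectory(s$trials[[idx]], file.path(dir, fn))
      list(trial_index = as.integer(idx), file = fn)
    })
    list(
      id = s$participant_id, group = s$group, sex = s$sex,
      age_years = s$age_years, gmfcs = s$gmfcs, macs = s$macs,
      raven_z = s$raven_z, corsi_z = s$corsi_z, labyrinth_z = s$labyrinth_z,
      trials = trials
    )
  })
  man <- list(
    maze = cohort$maze_config[c("circumradius", "alley_length", "alley_width",
                                "capture_radius")],
    protocol = list(
      counterbalance_seed = attr(cohort$protocol, "counterbalance_seed") %||% 1L
    ),
    participants = unname(participants)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
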