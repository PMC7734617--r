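#' Participant-by-training-trial value matrix for one metric
#'
#' Rows are participants of the requested group, columns the 16 training
#' trials (training order); missing trials are `NA`.
#'
#' @param metrics_tbl Output of [cohort_metrics()].
#' @param group `"CP"` or `"TD"`, or `NULL` for everyone.
#' @param metric Column of `metrics_tbl` (`"visited_n"`, `"tpl_m"`,
#'   `"de_pct"`, `"ra_deg"`, ...).
#' @param n_training Number of training trials (16 in the canonical
#'   protocol).
#' @return Numeric matrix with participant ids as row names.
#' @export
training_matrix <- function(metrics_tbl, group = NULL, metric = "de_pct",
                            n_training = 16L) {
  m <- metrics_tbl[metrics_tbl$trial_type == "training", , drop = FALSE]
  if (!is.null(group)) m <- m[m$group == group, , drop = FALSE]
  if (nrow(m) == 0L) {
    stop("input error: no training trials for the requested group",
         call. = FALSE)
  }
  if (!metric %in% names(m)) {
    stop("input error: unknown metric column `", metric, "`", call. = FALSE)
  }
  ids <- unique(m$participant_id)
  out <- matrix(NA_real_, length(ids), n_training,
                dimnames = list(ids, seq_len(n_training)))
  for (i in seq_len(nrow(m))) {
    out[m$participant_id[i], m$training_index[i]] <- as.numeric(m[[metric]][i])
  }
  out
}

#' Group learning curve for one metric
#'
#' Median and interquartile range of a metric across a group's participants,
#' per training trial; missing values are excluded cell-wise.
#'
#' @inheritParams training_matrix
#' @return Tibble with `training_index`, `median`, `q1`, `q3`, `iqr`, `n`.
#' @export
group_learning_curves <- function(metrics_tbl, group, metric = "de_pct",
                                  n_training = 16L) {
  mat <- training_matrix(metrics_tbl, group, metric, n_training)
  tibble::tibble(
    group = group,
    metric = metric,
    training_index = seq_len(ncol(mat)),
    median = unname(apply(mat, 2, stats::median, na.rm = TRUE)),
    q1 = unname(apply(mat, 2, stats::quantile, probs = 0.25, na.rm = TRUE,
                      names = FALSE)),
    q3 = unname(apply(mat, 2, stats::quantile, probs = 0.75, na.rm = TRUE,
                      names = FALSE)),
    iqr = q3 - q1,
    n = unname(apply(mat, 2, function(v) sum(!is.na(v))))
  )
}

# Friedman p over columns k..K of a matrix (complete cases); NaN (e.g.
# constant data) is read as "no detectable change" -> p = 1.
.friedman_p <- function(mat, k) {
  sub <- mat[, k:ncol(mat), drop = FALSE]
  sub <- sub[stats::complete.cases(sub), , drop = FALSE]
  if (nrow(sub) < 2L) return(NA_real_)
  p <- tryCatch(stats::friedman.test(as.matrix(sub))$p.value,
                error = function(e) NaN)
  if (is.nan(p)) 1 else p
}

# Paired Wilcoxon p between columns k-1 and k; all-zero differences -> no
# change -> p = 1.
.wilcoxon_pair_p <- function(mat, k) {
  x <- mat[, k - 1L]
  y <- mat[, k]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2L || all(x == y)) return(1)
  tryCatch(
    suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value),
    error = function(e) 1
  )
}

#' Detect the learning-curve stabilization trial ("knee")
#'
#' The knee is where the group learning curves bend from high to low slope.
#' The search makes the original visual identification explicit: the knee is
#' the smallest candidate trial `k` such that, for all four metrics
#' (visited alleys, TPL, DE, RA), performance is statistically stable from
#' `k` onwards (Friedman test over trials `k..16`, p > `alpha_stable`) while
#' still changing into `k` (paired Wilcoxon between trials `k - 1` and `k`,
#' p < `alpha_change`).
#'
#' @param value_matrices Named list of four participant x 16 matrices from
#'   [training_matrix()] (one per metric).
#' @param alpha_stable Friedman significance level above which trials
#'   `k..16` count as stable.
#' @param alpha_change Wilcoxon significance level below which the step into
#'   `k` counts as a real change.
#' @param candidates Candidate knee trials (default 2..15).
#' @param min_participants Minimum participants required (paired tests need
#'   replicates).
#' @return A `knee_result` list: `knee` (integer or `NA`), `friedman_p` and
#'   `wilcoxon_p` (per metric, at the knee), and `diagnostics` (a tibble of
#'   every candidate evaluation).
#' @export
detect_knee <- function(value_matrices, alpha_stable = 0.05,
                        alpha_change = 0.05, candidates = 2:15,
                        min_participants = 5L) {
  if (is.null(names(value_matrices)) || length(value_matrices) < 1L) {
    stop("input error: value_matrices must be a named list of matrices",
         call. = FALSE)
  }
  n_trials <- unique(vapply(value_matrices, ncol, integer(1)))
  if (length(n_trials) != 1L) {
    stop("input error: all matrices must have the same number of trials",
         call. = FALSE)
  }
  n_part <- vapply(value_matrices, nrow, integer(1))
  if (any(n_part < min_participants)) {
    stop("input error: at least ", min_participants,
         " participants are required per metric", call. = FALSE)
  }
  diag_rows <- list()
  knee <- NA_integer_
  for (k in candidates) {
    fp <- vapply(value_matrices, .friedman_p, numeric(1), k = k)
    wp <- vapply(value_matrices, .wilcoxon_pair_p, numeric(1), k = k)
    diag_rows[[length(diag_rows) + 1L]] <- tibble::tibble(
      candidate = k,
      metric = names(value_matrices),
      friedman_p = unname(fp),
      wilcoxon_p = unname(wp)
    )
    ok <- all(!is.na(fp)) && all(fp > alpha_stable) &&
      all(!is.na(wp)) && all(wp < alpha_change)
    if (ok && is.na(knee)) knee <- as.integer(k)
  }
  diagnostics <- dplyr::bind_rows(diag_rows)
  at_knee <- if (!is.na(knee)) {
    diagnostics[diagnostics$candidate == knee, ]
  } else NULL
  structure(
    list(
      knee = knee,
      friedman_p = if (!is.na(knee)) stats::setNames(at_knee$friedman_p, at_knee$metric),
      wilcoxon_p = if (!is.na(knee)) stats::setNames(at_knee$wilcoxon_p, at_knee$metric),
      alpha_stable = alpha_stable,
      alpha_change = alpha_change,
      diagnostics = diagnostics
    ),
    class = "knee_result"
  )
}

#' @export
print.knee_result <- function(x, ...) {
  if (is.na(x$knee)) {
    cat("<knee_result> no stabilization trial found\n")
  } else {
    cat("<knee_result> knee at training trial", x$knee, "\n")
    cat("  Friedman p (stability after knee): ",
        paste(sprintf("%s=%.3f", names(x$friedman_p), x$friedman_p),
              collapse = ", "), "\n", sep = "")
    cat("  Wilcoxon p (change into knee):     ",
        paste(sprintf("%s=%.3f", names(x$wilcoxon_p), x$wilcoxon_p),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Knee detection for both cohort groups
#'
#' Convenience wrapper building the four metric matrices per group and
#' running [detect_knee()] on each.
#'
#' @param metrics_tbl Output of [cohort_metrics()].
#' @param metrics The four learning-curve metric columns.
#' @inheritParams detect_knee
#' @return Named list of `knee_result`s (`CP`, `TD`), keeping only groups
#'   present.
#' @export
detect_knee_by_group <- function(metrics_tbl,
                                 metrics = c("visited_n", "tpl_m",
                                             "de_pct", "ra_deg"),
                                 alpha_stable = 0.05, alpha_change = 0.05,
                                 min_participants = 5L) {
  groups <- intersect(c("CP", "TD"), unique(metrics_tbl$group))
  out <- lapply(groups, function(g) {
    mats <- lapply(metrics, function(m) training_matrix(metrics_tbl, g, m))
    names(mats) <- metrics
    detect_knee(mats, alpha_stable, alpha_change,
                min_participants = min_participants)
  })
  stats::setNames(out, groups)
}

#' Stable-trial performance summary
#'
#' Per metric, the group median (IQR) at each group's stabilization trial,
#' the theoretical value for an ideal navigation (2 visited alleys, the
#' ideal path length, 0 % DE, 0 deg RA), and the between-group Mann-Whitney
#' p-value.
#'
#' @param metrics_tbl Output of [cohort_metrics()].
#' @param knee_per_group Named list/vector of knee trials, e.g.
#'   `c(CP = 7, TD = 5)`.
#' @param maze The maze (for the theoretical path length).
#' @return A tibble, one row per metric.
#' @export
stable_performance_table <- function(metrics_tbl, knee_per_group,
                                     maze = build_maze()) {
  ideal_len <- ideal_path(maze, 1L, 3L)$length
  th <- c(visited_n = 2, tpl_m = ideal_len, de_pct = 0, ra_deg = 0,
          mean_speed_ms = NA_real_, duration_s = NA_real_)
  vals_at_knee <- function(group, metric) {
    k <- knee_per_group[[group]]
    m <- metrics_tbl[metrics_tbl$trial_type == "training" &
                       metrics_tbl$group == group &
                       metrics_tbl$training_index == k, , drop = FALSE]
    as.numeric(m[[metric]])
  }
  rows <- lapply(names(th), function(metric) {
    cp <- vals_at_knee("CP", metric)
    td <- vals_at_knee("TD", metric)
    mw <- if (length(cp) && length(td)) mann_whitney(cp, td) else
      list(p.value = NA_real_)
    tibble::tibble(
      metric = metric,
      cp_median = stats::median(cp, na.rm = TRUE),
      cp_iqr = stats::IQR(cp, na.rm = TRUE),
      td_median = stats::median(td, na.rm = TRUE),
      td_iqr = stats::IQR(td, na.rm = TRUE),
      th_value = unname(th[metric]),
      p = mw$p.value
    )
  })
  dplyr::bind_rows(rows)
}
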