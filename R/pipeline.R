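#' Run the full analysis pipeline
#'
#' Orchestrates every stage over a cohort: per-trial metrics, strategy
#' classification, group learning curves, knee detection, the stable-trial
#' summary, group statistics (demographics, correlations, navigation
#' comparisons, post-hoc power) and figures. Artifacts are written under
#' `out_dir` (tidy CSVs, a knee/stats JSON, PNG figures); re-running with the
#' same inputs reproduces the CSV/JSON outputs exactly.
#'
#' @param cohort A [maze_cohort()] (from [read_cohort()] or
#'   [simulate_cohort()]).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param options A [metric_options()] list.
#' @param alpha_stable,alpha_change Knee-detection levels (see
#'   [detect_knee()]).
#' @param knee_per_group Optional named override of the knee trials (e.g.
#'   `c(CP = 7, TD = 5)`); when `NULL` the knees are detected from the data.
#' @param figures Write PNG figures?
#' @return A `maze_report_bundle` list with all stage outputs, invisibly
#'   printable via [make_report()].
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         options = metric_options(),
                         alpha_stable = 0.05, alpha_change = 0.05,
                         knee_per_group = NULL, figures = TRUE) {
  stopifnot(inherits(cohort, "maze_cohort"))
  maze <- build_maze(cohort$maze_config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  metrics <- stage("metrics", cohort_metrics(cohort, maze, options))
  classification <- stage("classify",
                          classify_cohort(metrics, cohort$protocol))
  groups <- intersect(c("CP", "TD"), unique(metrics$group))
  curves <- stage("learning_curves", dplyr::bind_rows(lapply(groups, function(g) {
    dplyr::bind_rows(lapply(c("visited_n", "tpl_m", "de_pct", "ra_deg"),
                            function(m) group_learning_curves(metrics, g, m)))
  })))
  knees <- if (is.null(knee_per_group)) {
    kr <- stage("knee", tryCatch(
      detect_knee_by_group(metrics, alpha_stable = alpha_stable,
                           alpha_change = alpha_change),
      error = function(e) list()
    ))
    knee_vals <- vapply(kr, function(r) r$knee, integer(1))
    list(results = kr, per_group = knee_vals)
  } else {
    list(results = NULL, per_group = unlist(knee_per_group))
  }
  have_knees <- length(knees$per_group) == 2L && !anyNA(knees$per_group)
  stable_tbl <- if (have_knees && length(groups) == 2L) {
    stage("stable_table",
          stable_performance_table(metrics, as.list(knees$per_group), maze))
  }
  navigation <- if (have_knees && length(groups) == 2L) {
    stage("compare_navigation",
          compare_navigation(metrics, as.list(knees$per_group),
                             classification = classification))
  }
  correlations <- if (have_knees) {
    stage("correlations",
          learning_phase_correlations(metrics, cohort,
                                      as.list(knees$per_group)))
  }
  demographics <- if (length(groups) == 2L) {
    stage("demographics", tryCatch(compare_demographics(cohort),
                                   error = function(e) NULL))
  }
  n_by_group <- table(vapply(cohort$sessions, function(s) s$group, character(1)))
  power <- if (length(groups) == 2L) {
    posthoc_power(n_by_group[["TD"]], n_by_group[["CP"]], d = 1,
                  alpha = 0.05, tails = 1)
  } else NA_real_

  bundle <- structure(
    list(metrics = metrics, classification = classification, curves = curves,
         knees = knees, stable_table = stable_tbl, navigation = navigation,
         correlations = correlations, demographics = demographics,
         power = power, out_dir = out_dir),
    class = "maze_report_bundle"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "trial_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(classification,
                     file.path(out_dir, "classification.csv"),
                     row.names = FALSE)
    utils::write.csv(curves, file.path(out_dir, "learning_curves.csv"),
                     row.names = FALSE)
    report <- list(
      knee_per_group = as.list(knees$per_group),
      knee_diagnostics = lapply(knees$results, function(r) r$diagnostics),
      stable_table = stable_tbl,
      navigation = navigation,
      correlations = correlations,
      demographics = demographics,
      posthoc_power = power
    )
    jsonlite::write_json(report, file.path(out_dir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    if (figures) {
      .write_figures(bundle, out_dir)
    }
  }
  invisible(bundle)
}

.write_figures <- function(bundle, out_dir) {
  save_plot <- function(p, name, width = 8, height = 6) {
    grDevices::png(file.path(out_dir, name), width = width * 96,
                   height = height * 96, res = 96)
    print(p)
    grDevices::dev.off()
  }
  save_plot(plot_learning_curves(bundle$curves), "learning_curves.png", 9, 7)
  save_plot(plot_strategy_shares(bundle$classification), "strategy_shares.png")
  save_plot(plot_compelled_success(bundle$classification),
            "compelled_success.png")
  invisible(NULL)
}

#' Learning-curve figure
#'
#' Median and IQR ribbon per group across the 16 training trials, one panel
#' per metric.
#'
#' @param curves Output of [group_learning_curves()] (possibly row-bound over
#'   groups and metrics).
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$training_index,
                                       y = .data$median,
                                       colour = .data$group,
                                       fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "training trial", y = "group median (IQR)",
                  title = "Learning curves over the 16 training trials") +
    ggplot2::theme_minimal()
}

#' Strategy-share figure
#'
#' @param classification Output of [classify_cohort()].
#' @return A ggplot object (stacked shares per group).
#' @export
plot_strategy_shares <- function(classification) {
  shares <- classification |>
    dplyr::count(.data$group, .data$strategy) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(shares, ggplot2::aes(x = .data$group, y = .data$pct,
                                       fill = .data$strategy)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "participants (%)",
                  title = "Freely adopted navigation strategies") +
    ggplot2::theme_minimal()
}

#' Compelled-success figure
#'
#' @param classification Output of [classify_cohort()].
#' @return A ggplot object (box plots of the compelled AS/ES success rates
#'   per group).
#' @export
plot_compelled_success <- function(classification) {
  long <- tidyr::pivot_longer(
    classification[, c("participant_id", "group",
                       "compelled_AS_pct", "compelled_ES_pct")],
    cols = c("compelled_AS_pct", "compelled_ES_pct"),
    names_to = "compelled", values_to = "pct"
  )
  long$compelled <- ifelse(long$compelled == "compelled_AS_pct",
                           "compelled AS", "compelled ES")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$pct,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~compelled) +
    ggplot2::labs(x = NULL, y = "success (%)",
                  title = "Success under compelled strategies") +
    ggplot2::theme_minimal()
}

#' Render a human-readable report
#'
#' Formats the bundle's summaries (demographics, stable-trial table,
#' correlations, strategy shares, compelled success, power) as aligned text
#' tables with deterministic formatting.
#'
#' @param bundle Output of [run_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
make_report <- function(bundle) {
  if (!inherits(bundle, "maze_report_bundle")) {
    stop("usage error: make_report expects a run_pipeline() bundle",
         call. = FALSE)
  }
  missing <- c()
  if (is.null(bundle$metrics)) missing <- c(missing, "metrics")
  if (is.null(bundle$classification)) missing <- c(missing, "classification")
  if (length(missing)) {
    stop("incomplete bundle: missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fmt_tbl <- function(df) {
    utils::capture.output(print(as.data.frame(df), digits = 4,
                                row.names = FALSE))
  }
  lines <- c("=== Star-maze navigation report ===", "")
  if (!is.null(bundle$demographics)) {
    lines <- c(lines, "-- Demographics and test scores --",
               fmt_tbl(bundle$demographics), "")
  }
  kv <- bundle$knees$per_group
  if (length(kv)) {
    lines <- c(lines, "-- Stabilization trial (knee) --",
               paste0("  ", names(kv), ": ",
                      ifelse(is.na(kv), "none", kv), collapse = "\n"), "")
  }
  if (!is.null(bundle$stable_table)) {
    lines <- c(lines, "-- Performance at the stable trial --",
               fmt_tbl(bundle$stable_table), "")
  }
  shares <- bundle$classification |>
    dplyr::count(.data$group, .data$strategy) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::ungroup()
  lines <- c(lines, "-- Strategy shares --", fmt_tbl(shares), "")
  if (!is.null(bundle$correlations)) {
    lines <- c(lines, "-- Learning-phase correlations (Spearman) --",
               fmt_tbl(bundle$correlations), "")
  }
  if (!is.null(bundle$navigation)) {
    lines <- c(lines, "-- Between-group comparisons --",
               fmt_tbl(bundle$navigation), "")
  }
  if (!is.na(bundle$power)) {
    lines <- c(lines, sprintf(
      "Post-hoc power (two-sample t, d = 1, alpha = 0.05, one-tailed): %.2f",
      bundle$power))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
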