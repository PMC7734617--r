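#' Mann-Whitney U test with a pinned convention
#'
#' Wraps [stats::wilcox.test()] with an explicit convention: the exact null
#' distribution when there are no ties and the smaller sample has at most
#' `exact_max` observations, otherwise the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest min(n1, n2) for which the exact distribution is
#'   used (given no ties).
#' @param alternative Passed to [stats::wilcox.test()].
#' @return List with `statistic` (U for the first sample), `p.value` and
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney <- function(x, y, exact_max = 8L, alternative = "two.sided") {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L) {
    stop("input error: both samples must be non-empty", call. = FALSE)
  }
  if (length(unique(c(x, y))) == 1L) {
    # fully tied samples carry no ordering information
    return(list(statistic = length(x) * length(y) / 2, p.value = 1,
                method = "degenerate"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && min(length(x), length(y)) <= exact_max
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                       alternative = alternative)
  )
  p <- res$p.value
  if (is.na(p) || is.nan(p)) p <- 1
  list(statistic = unname(res$statistic), p.value = p,
       method = if (use_exact) "exact" else "normal_approx")
}

#' Pearson chi-square test of a 2 x 2 contingency table
#'
#' Without continuity correction (this is the "chi-square test for
#' uniformity" convention that reproduces the gender comparison of the
#' original cohort).
#'
#' @param tab 2 x 2 matrix of counts (rows = groups, columns = categories).
#' @return List with `statistic`, `df` and `p.value`.
#' @export
#' @examples
#' chisq_uniformity(rbind(CP = c(11, 4), TD = c(5, 8)))
chisq_uniformity <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0)) {
    stop("input error: a 2 x 2 table of non-negative counts is required",
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value)
}

# Lilliefors normality p; NA when the sample is too small for the test.
.lilliefors_p <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4L || length(unique(x)) < 3L) return(NA_real_)
  nortest::lillie.test(x)$p.value
}

# Normality-gated two-group comparison of a continuous variable: unpaired
# t-test when both groups pass Lilliefors at alpha, Mann-Whitney otherwise.
.gated_comparison <- function(x_cp, x_td, alpha = 0.05) {
  p_cp <- .lilliefors_p(x_cp)
  p_td <- .lilliefors_p(x_td)
  normal <- !is.na(p_cp) && !is.na(p_td) && p_cp > alpha && p_td > alpha
  if (normal) {
    res <- stats::t.test(x_cp, x_td, var.equal = TRUE)
    list(test = "t_test", statistic = unname(res$statistic),
         p.value = res$p.value, normal_cp_p = p_cp, normal_td_p = p_td)
  } else {
    res <- mann_whitney(x_cp, x_td)
    list(test = "mann_whitney", statistic = res$statistic,
         p.value = res$p.value, normal_cp_p = p_cp, normal_td_p = p_td)
  }
}

# Session metadata as a tibble.
cohort_meta <- function(cohort) {
  rows <- lapply(cohort$sessions, function(s) {
    tibble::tibble(
      participant_id = s$participant_id, group = s$group, sex = s$sex,
      age_years = s$age_years, raven_z = s$raven_z, corsi_z = s$corsi_z,
      labyrinth_z = s$labyrinth_z
    )
  })
  dplyr::bind_rows(rows)
}

#' Demographic and test-score comparisons between groups
#'
#' Gender via the 2 x 2 Pearson chi-square without continuity correction;
#' age and the Raven/Corsi/Labyrinth z-scores via the normality-gated rule
#' (unpaired t-test when both groups pass a Lilliefors test at `alpha`,
#' Mann-Whitney U otherwise). Descriptives are mean (SD) for normal
#' variables, median (IQR) otherwise.
#'
#' @param cohort A [maze_cohort()] whose sessions carry the metadata.
#' @param alpha Normality-gate level.
#' @return A tibble, one row per compared variable.
#' @export
compare_demographics <- function(cohort, alpha = 0.05) {
  meta <- cohort_meta(cohort)
  for (g in c("CP", "TD")) {
    if (!any(meta$group == g)) {
      stop("input error: group ", g, " is empty", call. = FALSE)
    }
  }
  rows <- list()
  sex_known <- meta[!is.na(meta$sex), ]
  if (nrow(sex_known) && length(unique(sex_known$sex)) == 2L) {
    tab <- table(sex_known$group, sex_known$sex)
    cs <- chisq_uniformity(as.matrix(tab))
    desc <- function(g) paste(tab[g, c("M", "F")], collapse = "/")
    rows$gender <- tibble::tibble(
      variable = "gender_MF", test = "chi_square",
      statistic = cs$statistic, p = cs$p.value,
      desc_cp = desc("CP"), desc_td = desc("TD"),
      normal_cp_p = NA_real_, normal_td_p = NA_real_
    )
  }
  cont <- c(age = "age_years", raven_z = "raven_z", corsi_z = "corsi_z",
            labyrinth_z = "labyrinth_z")
  for (nm in names(cont)) {
    v <- cont[[nm]]
    x_cp <- meta[[v]][meta$group == "CP"]
    x_td <- meta[[v]][meta$group == "TD"]
    if (all(is.na(x_cp)) || all(is.na(x_td))) next
    g <- .gated_comparison(x_cp, x_td, alpha)
    fmt <- function(x) {
      if (g$test == "t_test") {
        sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE))
      } else {
        sprintf("%.2f (%.2f)", stats::median(x, na.rm = TRUE),
                stats::IQR(x, na.rm = TRUE))
      }
    }
    rows[[nm]] <- tibble::tibble(
      variable = nm, test = g$test, statistic = g$statistic, p = g$p.value,
      desc_cp = fmt(x_cp), desc_td = fmt(x_td),
      normal_cp_p = g$normal_cp_p, normal_td_p = g$normal_td_p
    )
  }
  dplyr::bind_rows(rows)
}

#' Post-hoc power of the two-sample t-test
#'
#' Closed form via the noncentral t distribution: noncentrality
#' `ncp = d * sqrt(n1 * n2 / (n1 + n2))` on `n1 + n2 - 2` degrees of freedom.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param d Cohen's d effect size (>= 0).
#' @param alpha Significance level in (0, 1).
#' @param tails 1 (one-tailed, the default) or 2.
#' @return Power in \[0, 1\].
#' @export
#' @examples
#' posthoc_power(13, 15, d = 1, alpha = 0.05, tails = 1)  # ~0.82
posthoc_power <- function(n1, n2, d, alpha = 0.05, tails = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("input error: alpha must lie in (0, 1)", call. = FALSE)
  }
  if (n1 < 2 || n2 < 2) stop("input error: n1, n2 must be >= 2", call. = FALSE)
  if (d < 0) stop("input error: d must be >= 0", call. = FALSE)
  if (!tails %in% c(1, 2)) stop("input error: tails must be 1 or 2", call. = FALSE)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (tails == 1) {
    crit <- stats::qt(1 - alpha, df)
    1 - stats::pt(crit, df, ncp = ncp)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    (1 - stats::pt(crit, df, ncp = ncp)) + stats::pt(-crit, df, ncp = ncp)
  }
}

#' Spearman correlations between learning-phase performance and z-scores
#'
#' For every participant, the median of each learning-curve metric over the
#' pre-knee training trials of their group (trials `1..knee - 1`), pooled
#' across groups and correlated (Spearman) with the Corsi, Labyrinth and
#' Raven z-scores — 12 metric x score pairs. Participants missing a score
#' are dropped pairwise; a pair with fewer than 3 complete observations
#' yields `NA`.
#'
#' @param metrics_tbl Output of [cohort_metrics()].
#' @param cohort The cohort (for the z-scores).
#' @param knee_per_group Named knee trials, e.g. `c(CP = 7, TD = 5)`.
#' @param metrics Learning-curve metric columns.
#' @return Tibble with `metric`, `score`, `rho`, `p`, `n`.
#' @export
learning_phase_correlations <- function(metrics_tbl, cohort, knee_per_group,
                                        metrics = c("visited_n", "tpl_m",
                                                    "de_pct", "ra_deg")) {
  meta <- cohort_meta(cohort)
  pre <- metrics_tbl[metrics_tbl$trial_type == "training", , drop = FALSE]
  pre <- pre[!is.na(pre$training_index), , drop = FALSE]
  keep <- vapply(seq_len(nrow(pre)), function(i) {
    k <- knee_per_group[[pre$group[i]]]
    !is.null(k) && !is.na(k) && pre$training_index[i] < k
  }, logical(1))
  pre <- pre[keep, , drop = FALSE]
  med <- stats::aggregate(pre[metrics], by = list(participant_id = pre$participant_id),
                          FUN = stats::median, na.rm = TRUE)
  df <- merge(med, meta, by = "participant_id")
  scores <- c("corsi_z", "labyrinth_z", "raven_z")
  rows <- list()
  for (m in metrics) {
    for (s in scores) {
      ok <- !is.na(df[[m]]) & !is.na(df[[s]])
      n <- sum(ok)
      if (n >= 3L) {
        ct <- suppressWarnings(
          stats::cor.test(df[[m]][ok], df[[s]][ok], method = "spearman")
        )
        rho <- unname(ct$estimate)
        p <- ct$p.value
      } else {
        rho <- NA_real_
        p <- NA_real_
      }
      rows[[paste(m, s)]] <- tibble::tibble(metric = m, score = s,
                                            rho = rho, p = p, n = n)
    }
  }
  dplyr::bind_rows(rows)
}

#' Between-group comparison of navigation performance
#'
#' Mann-Whitney U tests comparing CP and TD at the stabilization trial for
#' each navigation metric, plus the compelled allocentric / egocentric
#' success percentages.
#'
#' @param metrics_tbl Output of [cohort_metrics()].
#' @param classification Output of [classify_cohort()] (for the compelled
#'   rates); optional.
#' @param knee_per_group Named knee trials, e.g. `c(CP = 7, TD = 5)`.
#' @param metrics Stable-trial metric columns to compare.
#' @return Tibble with one row per compared variable: medians, IQRs, U and p.
#' @export
compare_navigation <- function(metrics_tbl, knee_per_group,
                               classification = NULL,
                               metrics = c("visited_n", "tpl_m", "de_pct",
                                           "ra_deg", "mean_speed_ms",
                                           "duration_s")) {
  get_vals <- function(group, metric) {
    k <- knee_per_group[[group]]
    m <- metrics_tbl[metrics_tbl$trial_type == "training" &
                       metrics_tbl$group == group &
                       metrics_tbl$training_index == k, , drop = FALSE]
    as.numeric(m[[metric]])
  }
  one_row <- function(variable, cp, td) {
    cp <- cp[!is.na(cp)]
    td <- td[!is.na(td)]
    mw <- if (length(cp) && length(td)) mann_whitney(cp, td) else
      list(statistic = NA_real_, p.value = NA_real_)
    tibble::tibble(
      variable = variable,
      cp_median = stats::median(cp), cp_iqr = stats::IQR(cp),
      td_median = stats::median(td), td_iqr = stats::IQR(td),
      U = mw$statistic, p = mw$p.value
    )
  }
  rows <- lapply(metrics, function(m) {
    one_row(paste0("stable_", m), get_vals("CP", m), get_vals("TD", m))
  })
  if (!is.null(classification)) {
    for (v in c("compelled_AS_pct", "compelled_ES_pct")) {
      rows[[length(rows) + 1L]] <- one_row(
        v,
        classification[[v]][classification$group == "CP"],
        classification[[v]][classification$group == "TD"]
      )
    }
  }
  dplyr::bind_rows(rows)
}
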