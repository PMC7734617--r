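#' Classify the strategy revealed by one test trial
#'
#' Test trials start from alley 4 with rewards in both alley 1 and alley 3,
#' so the alley reached reveals the strategy: reaching alley 3 by entering
#' only two alleys is allocentric (`"AS"`, steering by landmarks), reaching
#' alley 1 with only two alleys is egocentric (`"ES"`, replaying the trained
#' body turns), and anything else — failure, or more than two alleys
#' visited — is `"NoEfficient"`.
#'
#' @param metrics A one-row tibble from [compute_trial_metrics()].
#' @param spec The matching trial specification; must be a test trial.
#' @return `"AS"`, `"ES"` or `"NoEfficient"`.
#' @export
classify_test_trial <- function(metrics, spec) {
  if (!identical(spec$trial_type, "test")) {
    stop("usage error: classify_test_trial applies only to test trials",
         call. = FALSE)
  }
  if (isTRUE(metrics$success) && metrics$visited_n == 2L) {
    if (metrics$reached_alley == 3L) return("AS")
    if (metrics$reached_alley == 1L) return("ES")
  }
  "NoEfficient"
}

#' Classify a participant from their five test-trial labels
#'
#' Precedence: `"Allocentric"` if at least `run_threshold` consecutive
#' `"AS"` labels and no `"ES"` at all (the remainder being `"NoEfficient"`);
#' `"Egocentric"` symmetrically; `"Shifter"` if both `"AS"` and `"ES"`
#' appear; `"Lacking"` if at least `noeff_threshold` labels are
#' `"NoEfficient"`. Residual patterns matching no rule fall back to
#' `"Lacking"`. The default thresholds read the protocol's "more than three"
#' as >= 4 of the 5 trials; both are configurable.
#'
#' @param trial_labels Character vector of exactly 5 labels in protocol
#'   order, from [classify_test_trial()].
#' @param run_threshold Minimum consecutive-run length for
#'   Allocentric/Egocentric.
#' @param noeff_threshold Minimum count of `"NoEfficient"` for Lacking.
#' @return One of `"Allocentric"`, `"Egocentric"`, `"Shifter"`, `"Lacking"`.
#' @export
#' @examples
#' classify_participant(c("AS", "AS", "AS", "AS", "AS"))     # Allocentric
#' classify_participant(c("ES", "ES", "AS", "ES", "ES"))     # Shifter
classify_participant <- function(trial_labels, run_threshold = 4L,
                                 noeff_threshold = 4L) {
  if (length(trial_labels) != 5L ||
      !all(trial_labels %in% c("AS", "ES", "NoEfficient"))) {
    stop("usage error: exactly 5 labels in {AS, ES, NoEfficient} required",
         call. = FALSE)
  }
  longest_run <- function(lab) {
    r <- rle(trial_labels)
    runs <- r$lengths[r$values == lab]
    if (length(runs)) max(runs) else 0L
  }
  has_as <- any(trial_labels == "AS")
  has_es <- any(trial_labels == "ES")
  if (has_as && !has_es && longest_run("AS") >= run_threshold) {
    return("Allocentric")
  }
  if (has_es && !has_as && longest_run("ES") >= run_threshold) {
    return("Egocentric")
  }
  if (has_as && has_es) return("Shifter")
  if (sum(trial_labels == "NoEfficient") >= noeff_threshold) return("Lacking")
  "Lacking"  # documented fallback for residual patterns
}

#' Success of a compelled trial
#'
#' A compelled (forced-strategy) trial counts as successful only when the
#' reward is reached by a direct route — success with exactly two visited
#' alleys, i.e. no wandering.
#'
#' @inheritParams classify_test_trial
#' @return Logical.
#' @export
compelled_success <- function(metrics, spec) {
  if (!spec$trial_type %in% c("compelled_AS", "compelled_ES")) {
    stop("usage error: compelled_success applies only to compelled trials",
         call. = FALSE)
  }
  isTRUE(metrics$success) && metrics$visited_n == 2L
}

#' Per-participant compelled success rates
#'
#' Percentage of successful compelled trials, separately for the forced
#' allocentric and forced egocentric navigations. Missing trials are excluded
#' from the denominator with a warning; a type with zero recorded trials
#' yields `NA`.
#'
#' @param metrics_tbl Rows of [cohort_metrics()] for one participant.
#' @return Tibble with `compelled_AS_pct`, `compelled_ES_pct` and the
#'   trial counts used.
#' @export
compelled_success_rate <- function(metrics_tbl) {
  rate_for <- function(type, expected) {
    m <- metrics_tbl[metrics_tbl$trial_type == type, , drop = FALSE]
    n <- nrow(m)
    if (n < expected) {
      warning("participant has ", n, "/", expected, " recorded ", type,
              " trials; rate computed over recorded trials", call. = FALSE)
    }
    if (n == 0L) return(list(pct = NA_real_, n = 0L))
    ok <- vapply(seq_len(n), function(i) {
      compelled_success(m[i, ], m[i, ])
    }, logical(1))
    list(pct = 100 * sum(ok) / n, n = n)
  }
  as_r <- rate_for("compelled_AS", 4L)
  es_r <- rate_for("compelled_ES", 3L)
  tibble::tibble(
    compelled_AS_pct = as_r$pct, compelled_AS_n = as_r$n,
    compelled_ES_pct = es_r$pct, compelled_ES_n = es_r$n
  )
}

#' Learning onset over the 16 training trials
#'
#' The onset is the smallest training trial from which the participant
#' succeeded at every remaining training trial ("never failed subsequently");
#' `NA` if no stable success was ever obtained. A lone success on the final
#' training trial does not count as stability (the terminal run must span at
#' least two trials), so strictly alternating success is "never stable".
#' Missing trials count as failures. The onset is also binned into the protocol's categories; the
#' default bin edges are configurable because the original description of the
#' middle bins is ambiguous.
#'
#' @param success Logical vector of length 16 (training-trial successes, in
#'   training order; `NA` = missing = failure).
#' @param bins Named list of inclusive `c(lo, hi)` onset ranges defining the
#'   bins, in order of evaluation.
#' @return List with `onset` (integer or `NA`) and `bin` (character).
#' @export
#' @examples
#' learning_onset(rep(TRUE, 16))$onset   # 1
#' learning_onset(c(FALSE, FALSE, rep(TRUE, 14)))$onset   # 3
learning_onset <- function(success,
                           bins = list(first_trial = c(1, 1),
                                       trial_2_3 = c(2, 3),
                                       trial_4_7 = c(4, 7),
                                       late = c(8, 16))) {
  if (length(success) != 16L) {
    stop("usage error: 16 training-trial success flags required", call. = FALSE)
  }
  success <- !is.na(success) & success
  stable <- rev(cumprod(rev(success))) == 1
  onset <- if (any(stable[1:15])) which(stable)[1] else NA_integer_
  bin <- "never"
  if (!is.na(onset)) {
    for (nm in names(bins)) {
      rg <- bins[[nm]]
      if (onset >= rg[1] && onset <= rg[2]) {
        bin <- nm
        break
      }
    }
  }
  list(onset = onset, bin = bin)
}

#' Classify every participant in a cohort
#'
#' Combines the per-test-trial labels, the overall participant strategy, the
#' learning onset and the compelled success rates into one row per
#' participant.
#'
#' @param metrics_tbl Output of [cohort_metrics()].
#' @param protocol The cohort's protocol (used to identify trial roles).
#' @param run_threshold,noeff_threshold See [classify_participant()].
#' @param bins See [learning_onset()].
#' @return A tibble, one row per participant.
#' @export
classify_cohort <- function(metrics_tbl, protocol,
                            run_threshold = 4L, noeff_threshold = 4L,
                            bins = NULL) {
  if (is.null(bins)) bins <- formals(learning_onset)$bins
  if (is.language(bins)) bins <- eval(bins)
  ids <- unique(metrics_tbl$participant_id)
  rows <- lapply(ids, function(id) {
    m <- metrics_tbl[metrics_tbl$participant_id == id, , drop = FALSE]
    # five test-trial labels in protocol order; missing trials -> NoEfficient
    test_specs <- protocol[protocol$trial_type == "test", ]
    labels <- vapply(test_specs$trial_index, function(ti) {
      row <- m[m$trial_index == ti, , drop = FALSE]
      if (nrow(row) == 0L) return("NoEfficient")
      classify_test_trial(row, protocol_row(protocol, ti))
    }, character(1))
    train_specs <- protocol[protocol$trial_type == "training", ]
    succ <- vapply(train_specs$trial_index, function(ti) {
      row <- m[m$trial_index == ti, , drop = FALSE]
      if (nrow(row) == 0L) NA else row$success
    }, logical(1))
    ons <- learning_onset(succ, bins = bins)
    rates <- suppressWarnings(compelled_success_rate(m))
    tibble::tibble(
      participant_id = id,
      group = m$group[1],
      trial_1 = labels[1], trial_2 = labels[2], trial_3 = labels[3],
      trial_4 = labels[4], trial_5 = labels[5],
      strategy = classify_participant(labels, run_threshold, noeff_threshold),
      onset = ons$onset,
      onset_bin = ons$bin,
      compelled_AS_pct = rates$compelled_AS_pct,
      compelled_ES_pct = rates$compelled_ES_pct
    )
  })
  dplyr::bind_rows(rows)
}
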