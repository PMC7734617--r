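mk_metrics <- function(success, reached = NA_integer_, visited = 1L) {
  tibble::tibble(success = success, reached_alley = reached,
                 visited_n = visited)
}
test_spec <- default_proto[default_proto$trial_type == "test", ][1, ]
as_spec <- default_proto[default_proto$trial_type == "compelled_AS", ][1, ]

test_that("test-trial strategy labels follow the reached alley and visits", {
  expect_equal(classify_test_trial(mk_metrics(TRUE, 3L, 2L), test_spec), "AS")
  expect_equal(classify_test_trial(mk_metrics(TRUE, 1L, 2L), test_spec), "ES")
  expect_equal(classify_test_trial(mk_metrics(TRUE, 3L, 3L), test_spec),
               "NoEfficient")
  expect_equal(classify_test_trial(mk_metrics(FALSE), test_spec),
               "NoEfficient")
  expect_error(classify_test_trial(mk_metrics(TRUE, 3L, 2L),
                                   protocol_row(default_proto, 1)),
               "usage error")
})

test_that("participant classification applies the precedence rules", {
  expect_equal(classify_participant(rep("AS", 5)), "Allocentric")
  expect_equal(classify_participant(rep("ES", 5)), "Egocentric")
  expect_equal(classify_participant(c("AS", "AS", "AS", "AS", "NoEfficient")),
               "Allocentric")
  expect_equal(classify_participant(c("NoEfficient", "ES", "ES", "ES", "ES")),
               "Egocentric")
  expect_equal(classify_participant(c("ES", "ES", "AS", "ES", "ES")),
               "Shifter")
  expect_equal(classify_participant(c("AS", "ES", "AS", "ES", "AS")),
               "Shifter")
  expect_equal(classify_participant(c(rep("NoEfficient", 4), "AS")),
               "Lacking")
  expect_equal(classify_participant(rep("NoEfficient", 5)), "Lacking")
  # residual pattern (run of 3, no second strategy, < 4 inefficient)
  expect_equal(classify_participant(c("AS", "AS", "AS", "NoEfficient",
                                      "NoEfficient")), "Lacking")
  # the consecutive-run threshold is configurable
  expect_equal(classify_participant(c("AS", "AS", "AS", "NoEfficient",
                                      "NoEfficient"), run_threshold = 3),
               "Allocentric")
  expect_error(classify_participant(c("AS", "ES")), "usage error")
  expect_error(classify_participant(rep("XX", 5)), "usage error")
})

test_that("compelled success demands a direct two-alley route", {
  expect_true(compelled_success(mk_metrics(TRUE, 3L, 2L), as_spec))
  expect_false(compelled_success(mk_metrics(TRUE, 3L, 3L), as_spec))
  expect_false(compelled_success(mk_metrics(FALSE, NA, 4L), as_spec))
  expect_error(compelled_success(mk_metrics(TRUE, 3L, 2L), test_spec),
               "usage error")
})

test_that("compelled success rates are percentages over recorded trials", {
  mk_rows <- function(type, n, ok_n) {
    tibble::tibble(
      trial_type = type,
      success = c(rep(TRUE, ok_n), rep(FALSE, n - ok_n)),
      visited_n = 2L
    )
  }
  full <- dplyr::bind_rows(mk_rows("compelled_AS", 4, 4),
                           mk_rows("compelled_ES", 3, 0))
  r <- compelled_success_rate(full)
  expect_equal(r$compelled_AS_pct, 100)
  expect_equal(r$compelled_ES_pct, 0)

  r2 <- compelled_success_rate(dplyr::bind_rows(mk_rows("compelled_AS", 4, 2),
                                                mk_rows("compelled_ES", 3, 2)))
  expect_equal(r2$compelled_AS_pct, 50)
  expect_equal(r2$compelled_ES_pct, 100 * 2 / 3)

  # missing trials shrink the denominator with a warning; none -> NA
  expect_warning(
    expect_warning(r3 <- compelled_success_rate(mk_rows("compelled_AS", 2, 1)),
                   "compelled_AS"),
    "compelled_ES"
  )
  expect_equal(r3$compelled_AS_pct, 50)
  expect_true(is.na(r3$compelled_ES_pct))
})

test_that("learning onset is the start of the terminal success run", {
  expect_equal(learning_onset(rep(TRUE, 16))$onset, 1)
  expect_equal(learning_onset(rep(TRUE, 16))$bin, "first_trial")
  expect_equal(learning_onset(c(FALSE, FALSE, rep(TRUE, 14)))$onset, 3)
  expect_equal(learning_onset(c(FALSE, FALSE, rep(TRUE, 14)))$bin, "trial_2_3")
  expect_equal(learning_onset(c(rep(FALSE, 5), rep(TRUE, 11)))$bin, "trial_4_7")
  # success only on even trials is never stable
  alt <- rep(c(FALSE, TRUE), 8)
  expect_true(is.na(learning_onset(alt)$onset))
  expect_equal(learning_onset(alt)$bin, "never")
  # missing = failure
  flags <- rep(TRUE, 16)
  flags[2] <- NA
  expect_equal(learning_onset(flags)$onset, 3)
  expect_error(learning_onset(rep(TRUE, 5)), "usage error")
  # configurable bins
  alt_bins <- list(first = c(1, 1), upto7 = c(2, 7), late = c(8, 16))
  expect_equal(learning_onset(c(rep(FALSE, 7), rep(TRUE, 9)),
                              bins = alt_bins)$bin, "late")
})

test_that("cohort classification is a pure function of the metrics", {
  co <- withr::with_seed(31, {
    maze <- build_maze()
    p <- default_protocol(1)
    sessions <- list(
      simulate_session(noiseless_agent("egocentric"), p, maze, "E1", "TD"),
      simulate_session(noiseless_agent("allocentric"), p, maze, "A1", "CP")
    )
    maze_cohort(sessions, p, maze$config)
  })
  mt <- cohort_metrics(co)
  cl1 <- classify_cohort(mt, co$protocol)
  cl2 <- classify_cohort(mt[sample(nrow(mt)), ], co$protocol)
  expect_equal(cl1[order(cl1$participant_id), ]$strategy,
               cl2[order(cl2$participant_id), ]$strategy)
  expect_setequal(cl1$strategy, c("Egocentric", "Allocentric"))
  expect_true(all(cl1$onset == 1))
})
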