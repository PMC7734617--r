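test_that("noiseless agents honour the behavioural contracts", {
  m <- default_maze
  p <- default_proto
  test_sp <- p[p$trial_type == "test", ][1, ]
  as_sp2 <- p[p$trial_type == "compelled_AS" & p$start_alley == 2, ][1, ]
  as_sp5 <- p[p$trial_type == "compelled_AS" & p$start_alley == 5, ][1, ]
  es_sp <- p[p$trial_type == "compelled_ES", ][1, ]

  run <- function(strategy, spec, seed = 3) {
    withr::with_seed(seed, {
      res <- simulate_trial(noiseless_agent(strategy), spec, m,
                            state = list(n_training_done = 16L,
                                         shifter_side = "AS"))
      mm <- compute_trial_metrics(res$trajectory, spec, m)
      list(metrics = mm, truth = res$truth)
    })
  }

  # egocentric replay from the test start lands in alley 1
  ego_test <- run("egocentric", test_sp)
  expect_true(ego_test$metrics$success)
  expect_equal(ego_test$metrics$reached_alley, 1L)
  expect_equal(ego_test$metrics$visited_seq, "4>1")

  # egocentric replay from a compelled-AS start misses the reward
  # (offset +2 from alley 2 ends in alley 4)
  ego_as <- run("egocentric", as_sp2)
  expect_false(ego_as$metrics$success)
  expect_equal(ego_as$truth$target, 4L)

  # allocentric agent succeeds from any cued start
  for (sp in list(as_sp2, as_sp5, test_sp)) {
    allo <- run("allocentric", sp)
    expect_true(allo$metrics$success)
    expect_equal(allo$metrics$reached_alley, 3L)
    expect_equal(allo$metrics$visited_n, 2L)
  }

  # allocentric agent fails in the bare maze
  allo_bare <- run("allocentric", es_sp)
  expect_false(allo_bare$metrics$success)

  # egocentric agent succeeds in the bare maze (body-based replay)
  ego_bare <- run("egocentric", es_sp)
  expect_true(ego_bare$metrics$success)
  expect_equal(ego_bare$metrics$reached_alley, 3L)
})

test_that("simulated cohorts are byte-identical under the same seed", {
  cfg <- cohort_config(n_td = 2, n_cp = 2, seed = 12)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_equal(co1$sessions$TD01$trials[["1"]], co2$sessions$TD01$trials[["1"]])
  expect_equal(cohort_truth(co1), cohort_truth(co2))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co1, d1)
  write_cohort(co2, d2)
  f1 <- file.path(d1, "manifest.json")
  f2 <- file.path(d2, "manifest.json")
  expect_identical(readLines(f1), readLines(f2))
  c1 <- file.path(d1, "CP01", "trial_05.csv")
  c2 <- file.path(d2, "CP01", "trial_05.csv")
  expect_identical(readBin(c1, "raw", file.size(c1)),
                   readBin(c2, "raw", file.size(c2)))
})

test_that("noiseless cohorts are recovered perfectly by the classifier", {
  m <- default_maze
  p <- default_proto
  co <- withr::with_seed(8, {
    sessions <- list()
    k <- 0
    for (st in c("egocentric", "allocentric", "shifter", "lost")) {
      for (r in 1:2) {
        k <- k + 1
        id <- sprintf("P%02d", k)
        sessions[[id]] <- simulate_session(noiseless_agent(st), p, m, id,
                                           if (r == 1) "TD" else "CP")
      }
    }
    maze_cohort(sessions, p, m$config)
  })
  mt <- cohort_metrics(co)
  cl <- classify_cohort(mt, p)
  j <- merge(cl, cohort_truth(co), by = "participant_id")
  expect_equal(j$strategy, j$true_label)
  # measured onset equals the generating onset
  expect_equal(j$onset, j$true_onset)
})

test_that("median DE learning curve decays for a learning cohort", {
  cfg <- cohort_config(
    n_td = 8, n_cp = 0,
    mixture_td = c(allocentric = 0.5, egocentric = 0.5, shifter = 0, lost = 0),
    td_agent = list(initial_error_prob = 0.9, learning_rate = 0.5),
    error_sd = 0, seed = 21
  )
  co <- simulate_cohort(cfg)
  mt <- cohort_metrics(co)
  curve <- group_learning_curves(mt, "TD", "de_pct")
  expect_gt(curve$median[1], 50)
  # non-increasing within sampling error (small late-phase wobble allowed)
  expect_true(all(diff(curve$median) <= 5))
  # late trials are essentially clean
  expect_lt(stats::median(curve$median[12:16]), 5)
})

test_that("a slower-learning group stabilizes at a later knee", {
  mk <- function(lr_td, lr_cp) cohort_config(
    n_td = 25, n_cp = 25,
    td_agent = list(initial_error_prob = 1.0, learning_rate = lr_td),
    cp_agent = list(initial_error_prob = 1.0, learning_rate = lr_cp),
    mixture_td = c(allocentric = 0.5, egocentric = 0.5, shifter = 0, lost = 0),
    mixture_cp = c(allocentric = 0.5, egocentric = 0.5, shifter = 0, lost = 0),
    error_sd = 0, seed = 2
  )
  co <- simulate_cohort(mk(0.97, 0.75))
  mt <- cohort_metrics(co)
  kk <- detect_knee_by_group(mt)
  expect_false(is.na(kk$TD$knee))
  expect_false(is.na(kk$CP$knee))
  expect_lt(kk$TD$knee, kk$CP$knee)
})

test_that("planted z-score links surface as negative learning-phase correlations", {
  cfg <- cohort_config(n_td = 14, n_cp = 14, error_sd = 0.25, seed = 6)
  co <- simulate_cohort(cfg)
  mt <- cohort_metrics(co)
  res <- learning_phase_correlations(mt, co, list(CP = 7, TD = 5))
  corsi_tpl <- res[res$metric == "tpl_m" & res$score == "corsi_z", ]
  expect_lt(corsi_tpl$rho, 0)
})

test_that("identically configured groups are exchangeable", {
  cfg <- cohort_config(
    n_td = 10, n_cp = 10,
    mixture_td = c(allocentric = 0.5, egocentric = 0.5, shifter = 0, lost = 0),
    mixture_cp = c(allocentric = 0.5, egocentric = 0.5, shifter = 0, lost = 0),
    td_agent = list(initial_error_prob = 0.4, learning_rate = 0.5),
    cp_agent = list(initial_error_prob = 0.4, learning_rate = 0.5),
    seed = 14
  )
  co <- simulate_cohort(cfg)
  mt <- cohort_metrics(co)
  stable <- mt[mt$trial_type == "training" & mt$training_index >= 10, ]
  med <- tapply(stable$de_pct, stable$group, stats::median)
  expect_lt(abs(med[["CP"]] - med[["TD"]]), 2)
})
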