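test_that("the default schedule realizes the published design exactly", {
  sc <- schedule_config(seed = 3)
  sch <- build_schedule(sc)
  expect_equal(nrow(sch), 480)
  expect_equal(sum(sch$feedback_type == "deceptive"), 120)
  expect_equal(sum(sch$feedback_type == "informative"), 360)
  expect_equal(sum(sch$report_requested & sch$feedback_type == "informative"),
               120)
  expect_true(all(sch$report_requested[sch$feedback_type == "deceptive"]))
  # balanced within each block of 160
  for (b in 1:3) {
    blk <- sch[sch$block == b, ]
    expect_equal(nrow(blk), 160)
    expect_equal(sum(blk$feedback_type == "deceptive"), 40)
    expect_equal(sum(blk$report_requested), 80)
  }
  ctl <- build_control_schedule(sc)
  expect_equal(nrow(ctl), 160)
  expect_equal(sum(ctl$report_requested), 80)
  expect_true(all(ctl$feedback_type == "none"))
})

test_that("schedule randomization is seed-deterministic and count-exact", {
  sc <- schedule_config(seed = 11)
  expect_identical(build_schedule(sc), build_schedule(sc))
  sc2 <- schedule_config(seed = 12)
  expect_false(identical(build_schedule(sc)$feedback_type,
                         build_schedule(sc2)$feedback_type))
  # p_deceptive = 0: all informative, reports on a third (160 of 480)
  sch0 <- build_schedule(schedule_config(p_deceptive = 0, n_blocks = 1,
                                         seed = 1))
  expect_true(all(sch0$feedback_type == "informative"))
  expect_equal(sum(sch0$report_requested), 160)
  # fractions that do not yield whole per-block counts are rejected
  expect_error(build_schedule(schedule_config(p_deceptive = 0.13, seed = 1)),
               class = "cbl_error")
  expect_error(schedule_config(p_deceptive = 1.4), class = "cbl_error")
})

test_that("sessions satisfy the trial-record invariants across seeds", {
  st <- small_trained()
  obs <- observer_params()
  for (seed in c(21, 22, 23)) {
    sch <- build_schedule(tiny_schedule(seed = seed))
    rec <- quietly_cbl(run_session(sch, st$model, st$gen, obs,
                                   small_templates(), seed = seed,
                                   n_boot = 50))
    expect_equal(nrow(rec), 24)
    dec <- rec$feedback_type == "deceptive"
    inf <- rec$feedback_type == "informative"
    expect_true(all(rec$feedback_shown[dec] != rec$decoded[dec]))
    expect_true(all(rec$feedback_shown[inf] == rec$decoded[inf]))
    expect_true(all(rec$report_requested[dec]))
    expect_true(all(is.na(rec$report) == !rec$report_requested))
    rep_dec <- dec & rec$report_requested
    expect_true(all(rec$introspection[rep_dec] %in%
                      c("genuine", "confabulation")))
    expect_true(all(rec$introspection[!dec & rec$report_requested] == "n/a"))
    expect_true(all(rec$ie >= 0))
    expect_true(all(is.finite(rec$consistency)))
    expect_equal(rec$ie, abs(rec$signed_ie))
    # accuracy label consistency
    ok <- !is.na(rec$report)
    expect_equal(rec$accuracy[ok],
                 label_accuracy(rec$report[ok], rec$decoded[ok]))
  }
})

test_that("sessions are reproducible and feedback assignment is pre-determined", {
  st <- small_trained()
  obs <- observer_params()
  sch <- build_schedule(tiny_schedule(seed = 31))
  r1 <- quietly_cbl(run_session(sch, st$model, st$gen, obs, small_templates(),
                                seed = 77, n_boot = 50))
  r2 <- quietly_cbl(run_session(sch, st$model, st$gen, obs, small_templates(),
                                seed = 77, n_boot = 50))
  expect_identical(r1, r2)
  # the deceptive trial indices come from the schedule alone, not decoding
  expect_identical(which(sch$feedback_type == "deceptive"),
                   which(r1$feedback_type == "deceptive"))
})

test_that("blind cue-following limits produce the degenerate accuracies", {
  st <- small_trained()
  tmpl <- small_templates()
  follower <- observer_params(w_int = 0, w_cue = 1, sigma_obs = 1e-9,
                              cue_weighting = "fixed")
  # all-informative: following the cue is always correct
  sc_inf <- schedule_config(n_main_trials = 12, p_deceptive = 0,
                            report_fraction_informative = 1, n_blocks = 1,
                            seed = 2)
  rec <- quietly_cbl(run_session(build_schedule(sc_inf), st$model, st$gen,
                                 follower, tmpl, seed = 5, n_boot = 50))
  expect_true(all(rec$accuracy == "correct"))
  # all-deceptive: following the cue is always wrong
  sc_dec <- schedule_config(n_main_trials = 12, p_deceptive = 1, n_blocks = 1,
                            seed = 2)
  rec2 <- quietly_cbl(run_session(build_schedule(sc_dec), st$model, st$gen,
                                  follower, tmpl, seed = 5, n_boot = 50))
  expect_true(all(rec2$accuracy == "incorrect"))
  expect_true(all(rec2$introspection == "confabulation"))
})

test_that("control sessions carry no feedback and ignore the cue weight", {
  st <- small_trained()
  tmpl <- small_templates()
  sc <- tiny_schedule(seed = 41)
  ctl <- build_control_schedule(sc)
  a <- quietly_cbl(run_control_session(ctl, st$model, st$gen,
                                       observer_params(w_cue = 0.11), tmpl,
                                       seed = 9, n_boot = 50))
  b <- quietly_cbl(run_control_session(ctl, st$model, st$gen,
                                       observer_params(w_cue = 3), tmpl,
                                       seed = 9, n_boot = 50))
  expect_equal(nrow(a), 8)
  expect_equal(sum(!is.na(a$report)), 4)
  expect_true(all(a$feedback_shown == "none"))
  # with cue = 0 the cue weight is irrelevant given identical seeds
  expect_identical(a$report, b$report)
  expect_identical(a$confidence, b$confidence)
  # a main schedule is rejected
  expect_error(run_control_session(build_schedule(sc), st$model, st$gen,
                                   observer_params(), tmpl, seed = 9),
               class = "cbl_error")
})
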