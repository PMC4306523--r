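test_that("percept timeline alternates exclusive percepts with gamma durations", {
  prof <- behavioral_profile()
  tl <- simulate_percept_timeline(prof, duration = 1e4, seed = 3)
  excl <- tl$epochs[tl$epochs$percept != "mixed", ]
  # strict alternation of the two exclusive percepts
  expect_true(all(excl$percept[-1] != excl$percept[-nrow(excl)]))
  # configured mean dominance 4.50 s recovered over a long timeline
  full <- excl$duration[-nrow(excl)]  # last epoch is truncated
  expect_gt(mean(full), 4.35)
  expect_lt(mean(full), 4.65)
  expect_lt(abs(sd(full) - 0.99), 0.15)
  # mixed-percept fraction near the configured 2.23%
  mixed_frac <- sum(tl$epochs$duration[tl$epochs$percept == "mixed"]) / 1e4
  expect_lt(abs(mixed_frac - 0.0223), 0.01)
})

test_that("degenerate timelines behave sensibly", {
  prof <- behavioral_profile()
  short <- simulate_percept_timeline(prof, duration = 0.5, seed = 1)
  expect_identical(nrow(short$epochs), 1L)
  expect_length(short$switch_times, 0)
  nomix <- simulate_percept_timeline(
    behavioral_profile(mixed_fraction = 0), duration = 500, seed = 2)
  expect_false(any(nomix$epochs$percept == "mixed"))
})

test_that("reaction times reproduce the configured distribution", {
  prof <- behavioral_profile()
  tl <- simulate_percept_timeline(prof, duration = 2e4, seed = 5)
  rts <- tl$presses$time - tl$epochs$onset
  expect_lt(abs(mean(rts) - 0.90), 0.03)
  expect_lt(abs(sd(rts) - 0.43), 0.04)
})

test_that("subject simulation is deterministic and structurally correct", {
  cfg <- reduced_cohort_config(seed = 11, n_subjects = 5, trials = 4,
                               n_rivalry = 2)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$subjects[[2]]$runs[[1]]$bold$y,
                   co2$subjects[[2]]$runs[[1]]$bold$y)
  expect_identical(co1$subjects[[2]]$runs[[1]]$events,
                   co2$subjects[[2]]$runs[[1]]$events)
  expect_identical(co1$truth, co2$truth)
  ev <- co1$subjects[[1]]$runs[[1]]$events
  # rivalry-first ordering: first stimulation trial is rivalry
  stim <- ev[startsWith(ev$trial_type, "stimulation"), ]
  expect_identical(stim$trial_type[1], "stimulation_rivalry")
  expect_identical(sum(stim$trial_type == "stimulation_rivalry"), 2L)
  # replay presses carry response times, rivalry presses do not
  for (i in seq_len(nrow(stim))) {
    pr <- ev[ev$trial_type %in% c("press_toward", "press_away") &
               ev$onset >= stim$onset[i] &
               ev$onset <= stim$onset[i] + stim$duration[i] + 2, ]
    if (stim$trial_type[i] == "stimulation_replay")
      expect_true(all(!is.na(pr$response_time)))
    else expect_true(all(is.na(pr$response_time)))
  }
})

test_that("replay trials re-present the recorded rivalry report sequence", {
  cfg <- reduced_cohort_config(seed = 12, n_subjects = 5, trials = 2)
  co <- simulate_cohort(cfg)
  run <- co$subjects[[1]]$runs[[1]]
  ev <- run$events
  stim <- ev[startsWith(ev$trial_type, "stimulation"), ]
  riv <- stim[stim$trial_type == "stimulation_rivalry", ][1, ]
  rep_ <- stim[stim$trial_type == "stimulation_replay", ][1, ]
  # replay stimulus-change times (run frame) = recorded rivalry press times
  # shifted into the replay trial
  riv_press <- ev[ev$trial_type %in% c("press_toward", "press_away") &
                    ev$onset >= riv$onset & ev$onset <= riv$onset + 33.5, ]
  expected_changes <- riv_press$onset - riv$onset
  expected_changes <- expected_changes[expected_changes <= 31]
  got <- run$true_replay_switches - rep_$onset
  expect_equal(sort(got),
               sort(expected_changes[-1][diff(match(
                 riv_press$trial_type[riv_press$onset - riv$onset <= 31],
                 c("press_toward", "press_away"))) != 0]),
               tolerance = 1e-9)
})

test_that("a silent model yields flat baseline BOLD", {
  cfg <- reduced_cohort_config(seed = 13, n_subjects = 5, trials = 2,
                               noise_sd = 0, neural_sd = 0,
                               b_replay_mean = 0, b_replay_sd = 0,
                               delta_b_mean = c("rV5->rpSPL" = 0),
                               delta_b_sd = 0,
                               c_stimulation = 0, c_switch = 0)
  co <- simulate_cohort(cfg)
  expect_true(all(co$subjects[[1]]$runs[[1]]$bold$y == 0))
})

test_that("driving input to V5 concentrates variance at V5", {
  cfg <- reduced_cohort_config(seed = 14, n_subjects = 5, trials = 2,
                               noise_sd = 0, neural_sd = 0,
                               a = c("rV5->rpSPL" = 0),
                               b_replay_mean = 0, b_replay_sd = 0,
                               delta_b_mean = c("rV5->rpSPL" = 0),
                               delta_b_sd = 0,
                               c_stimulation = 0.6, c_switch = 0.3)
  co <- simulate_cohort(cfg)
  y <- co$subjects[[1]]$runs[[1]]$bold$y
  expect_gt(var(y[, "rV5"]), var(y[, "raSPL"]))
})

test_that("the linking rule ties mean dominance duration to delta-B", {
  cfg <- reduced_cohort_config(seed = 15, n_subjects = 12, trials = 6,
                               n_rivalry = 3, linking_sd = 0)
  co <- simulate_cohort(cfg)
  tr <- co$truth
  pred <- cfg$gamma0 +
    as.matrix(tr[paste0("delta_b.", co$cfg$model$b_connections)]) %*%
    cfg$gamma_c[co$cfg$model$b_connections]
  expect_equal(tr$linked_mean_duration, drop(pred), tolerance = 1e-9)
  # realized behavior tracks the linked mean
  # the subject profiles carry exactly the linked means
  prof_means <- vapply(co$subjects, function(s) s$truth$profile$mean_duration, 0)
  expect_equal(prof_means, tr$linked_mean_duration, tolerance = 1e-12)
  realized <- vapply(co$subjects, function(s)
    mean_dominance_from_events(do.call(rbind, lapply(s$runs, `[[`, "events"))),
    0)
  expect_gt(cor(realized, tr$linked_mean_duration), 0.3)
})

test_that("cohort files round-trip and load_run trims the lead-in", {
  cfg <- reduced_cohort_config(seed = 16, n_subjects = 5, trials = 2)
  co <- simulate_cohort(cfg)
  d <- withr::local_tempdir()
  write_subject(co$subjects[[1]], d, 1)
  run <- load_run(file.path(d, "sub-01_run-01_bold.tsv"),
                  file.path(d, "sub-01_run-01_events.tsv"), discard_vols = 5)
  raw <- co$subjects[[1]]$runs[[1]]
  expect_identical(nrow(run$bold$y), nrow(raw$bold$y) - 5L)
  expect_equal(run$bold$y, raw$bold$y[-(1:5), ], tolerance = 1e-8,
               ignore_attr = TRUE)
  # event clock shifted by the discarded duration
  first_stim <- run$events[run$events$trial_type == "stimulation_rivalry", ][1, ]
  expect_equal(first_stim$onset,
               raw$events$onset[raw$events$trial_type == "stimulation_rivalry"][1] -
                 5 * 2.1, tolerance = 1e-9)
})
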