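test_that("reaction-time correction shifts presses and clips at zero", {
  ev <- tiny_events()
  expect_identical(correct_event_times(ev, 0), ev[order(ev$onset), ])
  ev2 <- correct_event_times(ev, 0.9)
  expect_equal(ev2$onset[ev2$trial_type == "press_away"][1], 16 - 0.9)
  # boxcars untouched
  expect_equal(ev2$onset[ev2$trial_type == "stimulation_rivalry"], 10.5)
  ev3 <- rbind(ev, data.frame(onset = 0.5, duration = 0,
                              trial_type = "press_toward",
                              response_time = NA))
  expect_equal(min(correct_event_times(ev3, 0.9)$onset[
    correct_event_times(ev3, 0.9)$trial_type == "press_toward"]), 0)
})

test_that("mean reaction time is estimated from replay response times", {
  ev <- tiny_events()
  expect_equal(estimate_mean_rt(ev), 0.9)
  ev$response_time <- NA_real_
  expect_warning(rt0 <- estimate_mean_rt(ev), "no response times")
  expect_identical(rt0, 0)
})

test_that("switch events are percept changes after the first report", {
  sw <- derive_switch_events(tiny_events())
  # rivalry trial: presses toward/away/toward -> 2 switches; replay likewise
  expect_identical(nrow(sw), 4L)
  expect_identical(sw$condition, c("rivalry", "rivalry", "replay", "replay"))
  expect_equal(sw$onset, c(16, 20, 57.9, 61.9))
  # mixed reports never produce switches and do not break the chain
  ev <- tiny_events()
  ev <- rbind(ev, data.frame(onset = 17.5, duration = 0,
                             trial_type = "press_mixed", response_time = NA))
  expect_identical(nrow(derive_switch_events(ev)), 4L)
})

test_that("canonical HRF has the analytic gamma mode and a stable integral", {
  k <- canonical_hrf(hrf_spec(), dt = 0.01)
  tt <- seq(0, 32, by = 0.01)
  # mode of the response gamma (shape 6, scale 1) is at (6-1)*1 = 5 s
  expect_lt(abs(tt[which.max(k)] - 5), 0.011)
  # positive peak followed by a negative undershoot
  expect_gt(max(k), 0)
  expect_lt(min(k[tt > 10 & tt < 20]), 0)
  # discrete integral stable under refinement
  i1 <- sum(canonical_hrf(hrf_spec(), 0.02)) * 0.02
  i2 <- sum(canonical_hrf(hrf_spec(), 0.01)) * 0.01
  expect_lt(abs(i1 - i2) / abs(i2), 0.01)
  expect_error(hrf_spec(response_dispersion = 0), "dispersions")
})

test_that("design matrix columns are HRF convolutions of the stimuli", {
  hrf <- hrf_spec()
  # no events at all: all task columns zero, intercept present
  empty <- data.frame(onset = numeric(0), duration = numeric(0),
                      trial_type = character(0), response_time = numeric(0))
  X0 <- build_design_matrix(empty, hrf, n_vols = 20, TR = 2.1)
  expect_true(all(X0$X[, 1:4] == 0))
  expect_true(all(X0$X[, "intercept"] == 1))
  # a single switch at t = 0 reproduces the kernel at the TR grid
  ev <- data.frame(
    onset = c(0, 0, 1e-9),
    duration = c(42, 0, 0),
    trial_type = c("stimulation_rivalry", "press_toward", "press_away"),
    response_time = NA)
  X <- build_design_matrix(ev, hrf, n_vols = 20, TR = 2.1)
  kern <- canonical_hrf(hrf, 2.1 / hrf$microtime_bins)
  at_tr <- kern[(seq_len(20) - 1) * hrf$microtime_bins + 1]
  at_tr[is.na(at_tr)] <- 0
  expect_equal(X$X[, "rivalry_switch"], at_tr,
               tolerance = 1e-9, ignore_attr = TRUE)
  # events beyond the run end are refused with their onsets listed
  late <- data.frame(onset = 100, duration = 0,
                     trial_type = "press_toward", response_time = NA)
  expect_error(build_design_matrix(rbind(ev, late), hrf, 20, 2.1), "100")
})

test_that("a boxcar column equals the sum of its shifted impulse responses", {
  hrf <- hrf_spec(microtime_bins = 8)
  dtm <- 2.1 / 8
  ev_box <- data.frame(onset = 4.2, duration = 6.3,
                       trial_type = "fixation", response_time = NA)
  Xb <- build_design_matrix(ev_box, hrf, n_vols = 15, TR = 2.1)
  # superposition oracle: one unit impulse per microtime bin of the boxcar
  kern <- canonical_hrf(hrf, dtm)
  nT <- 15 * 8
  u <- numeric(nT)
  on <- round(4.2 / dtm); len <- round(6.3 / dtm)
  acc <- numeric(nT + length(kern))
  for (j in seq_len(len)) {
    i0 <- on + j
    acc[i0:(i0 + length(kern) - 1)] <- acc[i0:(i0 + length(kern) - 1)] + kern
  }
  oracle <- acc[(seq_len(15) - 1) * 8 + 1]
  expect_equal(Xb$X[, "fixation"], oracle, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("OLS recovers noiseless coefficients and is permutation invariant", {
  cfg <- reduced_cohort_config(seed = 31, n_subjects = 5, trials = 2)
  co <- simulate_cohort(cfg)
  run <- co$subjects[[1]]$runs[[1]]
  ev <- correct_event_times(run$events, estimate_mean_rt(run$events))
  X <- build_design_matrix(ev, hrf_spec(), n_vols = nrow(run$bold$y), TR = 2.1)
  beta_true <- matrix(c(0.5, -1, 2, 0.3, 1, 0, 0.2, 0.1, -0.5, 4), 5, 2)
  y <- bold_series(X$X %*% beta_true, 2.1)
  fit <- fit_glm(y, X)
  expect_equal(unname(fit$beta), beta_true, tolerance = 1e-8)
  # joint row permutation leaves the estimate unchanged
  perm <- sample(nrow(X$X))
  Xp <- X; Xp$X <- X$X[perm, ]
  fit_p <- fit_glm(bold_series(y$y[perm, , drop = FALSE], 2.1), Xp)
  expect_equal(fit_p$beta, fit$beta, tolerance = 1e-8)
  # residuals orthogonal to the design (normal equations)
  noisy <- bold_series(y$y + with_seed(1, matrix(rnorm(length(y$y)), nrow(y$y))), 2.1)
  fit_n <- fit_glm(noisy, X)
  expect_lt(max(abs(crossprod(X$X, fit_n$residuals))), 1e-6)
  # rank deficiency is reported with the offending column
  Xbad <- X; Xbad$X <- cbind(X$X, dup = X$X[, "stimulation"])
  expect_error(fit_glm(noisy, Xbad), "collinear")
})

test_that("the rivalry > replay contrast is linear in the true amplitudes", {
  cfg <- reduced_cohort_config(seed = 32, n_subjects = 5, trials = 2)
  co <- simulate_cohort(cfg)
  run <- co$subjects[[1]]$runs[[1]]
  ev <- correct_event_times(run$events, estimate_mean_rt(run$events))
  X <- build_design_matrix(ev, hrf_spec(), n_vols = nrow(run$bold$y), TR = 2.1)
  amp <- function(ar, ap) {
    b <- matrix(0, 5, 1)
    rownames(b) <- colnames(X$X)
    b["rivalry_switch", 1] <- ar; b["replay_switch", 1] <- ap
    fit_glm(bold_series(X$X %*% b, 2.1), X)
  }
  expect_equal(contrast_rivalry_gt_replay(amp(1, 0.5))$estimate, 0.5,
               tolerance = 1e-8)
  expect_equal(contrast_rivalry_gt_replay(amp(0.7, 0.7))$estimate, 0,
               tolerance = 1e-8)
  expect_error(contrast_rivalry_gt_replay(
    structure(list(beta = matrix(0, 2, 1, dimnames = list(c("a", "b"), "r")),
                   design = list(X = matrix(0, 1, 2))), class = "glm_fit")),
    "lacks")
})

test_that("GLM t statistics are t-distributed under the null", {
  # fixed representative design, 1000 white-noise runs
  cfg <- reduced_cohort_config(seed = 33, n_subjects = 5, trials = 2)
  co <- simulate_cohort(cfg)
  run <- co$subjects[[1]]$runs[[1]]
  ev <- correct_event_times(run$events, estimate_mean_rt(run$events))
  X <- build_design_matrix(ev, hrf_spec(), n_vols = nrow(run$bold$y), TR = 2.1)
  n <- nrow(X$X)
  tvals <- with_seed(101, vapply(seq_len(1000), function(i) {
    y <- bold_series(matrix(rnorm(n), n, 1), 2.1)
    contrast_rivalry_gt_replay(fit_glm(y, X))$t
  }, 0))
  df <- n - ncol(X$X)
  # type-I error at the two-sided 5% level within 5% +/- 1.5%
  rate <- mean(abs(tvals) > qt(0.975, df))
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
  # distributional check (KS at alpha = 0.01)
  ks <- stats::ks.test(pt(tvals, df), "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("group-level one-sample t-test summarizes subject contrasts", {
  set.seed(4)
  cmat <- matrix(rnorm(30, mean = c(0.5, 0, 0)), 10, 3, byrow = TRUE,
                 dimnames = list(NULL, c("rV5", "rpSPL", "raSPL")))
  g <- group_contrast_ttest(cmat)
  ref <- t.test(cmat[, 1])
  expect_equal(g$t[1], unname(ref$statistic), tolerance = 1e-9)
  expect_equal(g$p[1], ref$p.value, tolerance = 1e-9)
  expect_equal(g$df[1], 9)
})
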