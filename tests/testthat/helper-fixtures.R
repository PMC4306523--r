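# Shared fixtures: all synthetic, built in code at test time.

# the reduced study configuration used by the recovery suites: 1 run of
# 2 trials (1 rivalry / 1 replay), coarse integration grid, 10.5 s fixation
# so the grid divides every phase
reduced_cohort_config <- function(seed, n_subjects = 18, trials = 2,
                                  n_rivalry = 1, ...) {
  cohort_config(n_subjects = n_subjects, n_runs = 1,
                trials_per_run = trials, n_rivalry = n_rivalry,
                fixation_duration = 10.5, dt = 0.7, seed = seed, ...)
}

# single-modulated-connection ground truth (V5 -> pSPL, rivalry +0.3,
# replay 0) used by the parameter-recovery checks
single_b_config <- function(seed, trials = 4) {
  ms <- enumerate_model_space()
  m32 <- ms[[which(vapply(ms, `[[`, 0L, "model_id") == 32L)]]
  cohort_config(n_subjects = 5, n_runs = 1, trials_per_run = trials,
                n_rivalry = trials %/% 2, fixation_duration = 10.5,
                dt = 0.7, seed = seed, model = m32,
                b_replay_mean = 0, b_replay_sd = 0,
                delta_b_mean = c("rV5->rpSPL" = 0.3), delta_b_sd = 0)
}

# tiny deterministic events table: one rivalry and one replay trial
tiny_events <- function() {
  data.frame(
    onset = c(0, 10.5, 12, 16, 20, 42, 52.5, 54.4, 57.9, 61.9, 84, 94.5),
    duration = c(10.5, 31.5, 0, 0, 0, 10.5, 31.5, 0, 0, 0, 10.5, 0),
    trial_type = c("fixation", "stimulation_rivalry", "press_toward",
                   "press_away", "press_toward", "fixation",
                   "stimulation_replay", "press_toward", "press_away",
                   "press_toward", "fixation", "fixation"),
    response_time = c(NA, NA, NA, NA, NA, NA, NA, 0.9, 0.9, 0.9, NA, NA)
  )[-12, ]
}

# simple 1-run forward simulation on a known model
tiny_simulation <- function(noise_sd = 0, seed = 1, dt = 0.35) {
  ms <- enumerate_model_space()
  m <- ms[[which(vapply(ms, `[[`, 0L, "model_id") == 60L)]]
  p <- dcm_parameters(
    m, a = c("rV5->rpSPL" = 0.25, "rpSPL->raSPL" = 0.25,
             "rpSPL->rV5" = 0.10, "raSPL->rpSPL" = 0.10),
    b_rivalry = setNames(c(0.3, 0.1, 0.3, 0.3), m$b_connections),
    b_replay = setNames(rep(0.15, 4), m$b_connections),
    c_stimulation = 0.6,
    c_rivalry_switch = c(rV5 = 0.3), c_replay_switch = c(rV5 = 0.3))
  tl <- input_timeline(
    94.5, dt = dt,
    fixation = data.frame(onset = c(0, 42, 84), duration = c(10.5, 10.5, 10.5)),
    stimulation = data.frame(onset = c(10.5, 52.5), duration = c(31.5, 31.5)),
    rivalry_switch_times = c(15, 19.5, 26, 33),
    replay_switch_times = c(57, 61.5, 68, 75),
    pulse_width = 2.1)
  bold <- simulate_bold(p, tl)
  if (noise_sd > 0)
    bold$y <- bold$y + with_seed(seed, matrix(
      rnorm(length(bold$y), 0, noise_sd), nrow(bold$y), ncol(bold$y)))
  list(model = m, params = p, inputs = tl, bold = bold)
}

with_seed <- bistableDCM:::with_seed
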