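# Synthetic cohort generator: percept timelines with gamma-distributed
# dominance durations, button events with reaction-time delays, replay trials
# that re-present a recorded rivalry sequence, and ROI BOLD generated from
# known ground-truth coupling parameters.

#' Behavioral profile of one subject
#'
#' Dominance durations of the two exclusive percepts are gamma distributed;
#' shape and scale are solved from the target mean and SD (shape =
#' (mean/sd)^2, scale = sd^2/mean). A small fraction of stimulus time is
#' spent in mixed percepts, inserted at transitions. Button-press reaction
#' times are truncated-normal. Defaults reproduce mean dominance 4.50 s
#' (SD 0.99 s), 2.23% mixed time, and RT 0.90 +/- 0.43 s.
#'
#' @param mean_duration,sd_duration Mean / SD of exclusive dominance
#'   durations (s).
#' @param mixed_fraction Fraction of stimulus time in mixed percepts
#'   (in `[0, 0.1]`).
#' @param mixed_mean_duration Mean duration of a mixed epoch (s).
#' @param rt_mean,rt_sd Reaction-time mean and SD (s); draws are truncated
#'   below at `rt_min`.
#' @param rt_min Lower truncation for reaction times (s).
#' @return A `behavioral_profile` object (includes derived gamma
#'   `shape`/`scale` and per-transition mixed-epoch probability).
#' @export
behavioral_profile <- function(mean_duration = 4.50, sd_duration = 0.99,
                               mixed_fraction = 0.0223,
                               mixed_mean_duration = 0.5,
                               rt_mean = 0.90, rt_sd = 0.43, rt_min = 0.15) {
  stopifnot(mean_duration > 0, sd_duration > 0)
  if (mixed_fraction < 0 || mixed_fraction > 0.1)
    stop("mixed_fraction must lie in [0, 0.1]")
  shape <- (mean_duration / sd_duration)^2
  scale <- sd_duration^2 / mean_duration
  # per-transition probability of a mixed epoch giving the target fraction:
  # f = p*mm / (me + p*mm)  =>  p = f*me / ((1-f)*mm)
  p_mixed <- if (mixed_fraction > 0)
    mixed_fraction * mean_duration /
      ((1 - mixed_fraction) * mixed_mean_duration) else 0
  structure(list(mean_duration = mean_duration, sd_duration = sd_duration,
                 shape = shape, scale = scale,
                 mixed_fraction = mixed_fraction,
                 mixed_mean_duration = mixed_mean_duration,
                 p_mixed = min(1, p_mixed),
                 rt_mean = rt_mean, rt_sd = rt_sd, rt_min = rt_min),
            class = "behavioral_profile")
}

draw_rt <- function(n, profile) {
  pmax(profile$rt_min, rnorm(n, profile$rt_mean, profile$rt_sd))
}

#' Simulate a percept timeline for one stimulation period
#'
#' Alternating exclusive percepts ("toward"/"away") with gamma-distributed
#' durations; with probability `p_mixed` a short mixed epoch is inserted at
#' each transition. The timeline is truncated at `duration`. Switches are
#' the onsets of exclusive epochs whose percept differs from the previous
#' exclusive percept; each epoch onset is reported by a button press one
#' reaction time later.
#'
#' @param profile A [behavioral_profile()].
#' @param duration Stimulation duration (s).
#' @param seed Optional integer seed (local RNG).
#' @param initial Optional initial percept (\"toward\" or \"away\";
#'   random when NULL).
#' @return A `percept_timeline`: `epochs` (onset, duration, percept),
#'   `switch_times` (true exclusive switch onsets), `presses` (time,
#'   percept, rt, is_switch).
#' @export
simulate_percept_timeline <- function(profile, duration, seed = NULL,
                                      initial = NULL) {
  stopifnot(duration > 0)
  with_seed(seed, {
    percepts <- c("toward", "away")
    cur <- if (is.null(initial)) sample(percepts, 1) else initial
    onset <- 0
    rows <- list()
    while (onset < duration) {
      len <- rgamma(1, shape = profile$shape, scale = profile$scale)
      rows[[length(rows) + 1]] <-
        data.frame(onset = onset, duration = len, percept = cur)
      onset <- onset + len
      if (onset >= duration) break
      if (profile$p_mixed > 0 && runif(1) < profile$p_mixed) {
        mlen <- rgamma(1, shape = 2, scale = profile$mixed_mean_duration / 2)
        rows[[length(rows) + 1]] <-
          data.frame(onset = onset, duration = mlen, percept = "mixed")
        onset <- onset + mlen
      }
      cur <- setdiff(percepts, cur)
    }
    epochs <- do.call(rbind, rows)
    over <- epochs$onset + epochs$duration > duration
    epochs$duration[over] <- duration - epochs$onset[over]
    epochs <- epochs[epochs$duration > 1e-9, , drop = FALSE]
    excl <- epochs[epochs$percept != "mixed", , drop = FALSE]
    switch_times <- excl$onset[-1][excl$percept[-1] !=
                                     excl$percept[-nrow(excl)]]
    presses <- data.frame(
      time = epochs$onset + draw_rt(nrow(epochs), profile),
      percept = epochs$percept,
      rt = NA_real_,
      is_switch = epochs$onset %in% switch_times
    )
    structure(list(epochs = epochs, switch_times = switch_times,
                   presses = presses, duration = duration),
              class = "percept_timeline")
  })
}

#' Ground truth for one simulated subject
#'
#' @param model The generating `dcm_model_spec`.
#' @param params A [dcm_parameters()] object holding A, C and both
#'   conditions' B (rivalry B on the rivalry-switch input, replay B on the
#'   replay-switch input) -- the two conditions share A and C by
#'   construction.
#' @param profile The subject's [behavioral_profile()].
#' @param delta_b Named vector, rivalry minus replay modulation per
#'   modulated connection.
#' @return A `subject_ground_truth` object.
#' @export
subject_ground_truth <- function(model, params, profile, delta_b) {
  structure(list(model = model, params = params, profile = profile,
                 delta_b = delta_b),
            class = "subject_ground_truth")
}

#' Cohort configuration
#'
#' Defaults encode the study design being emulated: 18 subjects, 6 runs of
#' 10 trials (5 rivalry / 5 replay, rivalry first, pseudo-random order),
#' 31.5 s stimulation followed by 11 s fixation per trial, TR 2.1 s with 5
#' lead-in volumes, and a linear rule linking each subject's mean dominance
#' duration to their rivalry-minus-replay modulation differences:
#' `mean_i = gamma0 + sum_c gamma_c * deltaB_{i,c} + eps_i` (floored at 1 s).
#'
#' @param n_subjects,n_runs,trials_per_run,n_rivalry Cohort / design sizes.
#' @param stim_duration,fixation_duration Trial phase durations (s).
#' @param TR Repetition time (s).
#' @param lead_in_vols Scanner equilibration volumes of fixation prepended
#'   to each run (discarded at load time).
#' @param dt Integration step for BOLD generation (s); must divide TR and
#'   all phase durations.
#' @param pulse_width Width of the switch driving pulses (s).
#' @param noise_sd BOLD observation noise SD (percent signal change).
#' @param neural_sd SD of endogenous white neural fluctuations per region
#'   (activity units per sqrt(s)); these spontaneous fluctuations
#'   decorrelate the regions, as resting-state activity does in real
#'   recordings.
#' @param a,self,c_stimulation,c_switch Ground-truth endogenous coupling
#'   (named by connection), self-coupling, and driving gains (switch gain
#'   applies to V5 for both switch inputs).
#' @param model The generating model (default: the fully bidirectional
#'   model with switch input to V5 only).
#' @param b_replay_mean,b_replay_sd Population mean/SD of replay-condition
#'   modulation per modulated connection.
#' @param delta_b_mean,delta_b_sd Population mean/SD of the
#'   rivalry-minus-replay modulation difference per modulated connection.
#' @param gamma0,gamma_c,linking_sd Linking-rule intercept (s), slopes
#'   (s per unit modulation difference, named by connection), and noise SD
#'   (default calibrated so the population R-squared of the linking rule is
#'   0.75 at the default slopes and delta-B spread).
#' @param stability_margin Largest admissible real part of any eigenvalue
#'   of `A + B` under full modulation; ground-truth draws violating it are
#'   resampled, so every simulated brain has bounded dynamics.
#' @param profile Template [behavioral_profile()]; per-subject mean
#'   durations from the linking rule replace its mean (constant shape, so
#'   the duration CV is preserved).
#' @param hemo Hemodynamic parameters.
#' @param seed Master seed; every random stream of the cohort derives from
#'   it.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_subjects = 18, n_runs = 6, trials_per_run = 10,
                          n_rivalry = 5,
                          stim_duration = 31.5, fixation_duration = 11,
                          TR = 2.1, lead_in_vols = 5, dt = 0.05,
                          pulse_width = 2.1, noise_sd = 0.3,
                          neural_sd = 0.15,
                          a = c("rV5->rpSPL" = 0.25, "rpSPL->raSPL" = 0.25,
                                "rpSPL->rV5" = 0.10, "raSPL->rpSPL" = 0.10),
                          self = -0.5,
                          c_stimulation = 0.6, c_switch = 0.3,
                          model = NULL,
                          b_replay_mean = 0.15, b_replay_sd = 0.05,
                          delta_b_mean = c("raSPL->rpSPL" = 0.15,
                                           "rpSPL->raSPL" = -0.15,
                                           "rpSPL->rV5" = 0.15,
                                           "rV5->rpSPL" = 0.15),
                          delta_b_sd = 0.10,
                          gamma0 = 4.5,
                          gamma_c = c("raSPL->rpSPL" = 0,
                                      "rpSPL->raSPL" = -2,
                                      "rpSPL->rV5" = 0,
                                      "rV5->rpSPL" = 2),
                          linking_sd = 0.163,
                          stability_margin = 0.10,
                          profile = behavioral_profile(),
                          hemo = hemodynamic_params(),
                          seed = 1L) {
  if (n_subjects < 5) stop("need at least 5 subjects")
  stopifnot(n_rivalry >= 1, n_rivalry < trials_per_run || trials_per_run == 1)
  if (is.null(model)) {
    space <- enumerate_model_space()
    full_b <- vapply(space, function(m) length(m$b_connections) == 4L &&
                       length(m$c_switch_regions) == 0L, NA)
    model <- space[[which(full_b)]]
  }
  structure(list(
    n_subjects = n_subjects, n_runs = n_runs,
    trials_per_run = trials_per_run, n_rivalry = n_rivalry,
    stim_duration = stim_duration, fixation_duration = fixation_duration,
    TR = TR, lead_in_vols = lead_in_vols, dt = dt,
    pulse_width = pulse_width, noise_sd = noise_sd, neural_sd = neural_sd,
    a = a, self = self, c_stimulation = c_stimulation, c_switch = c_switch,
    model = model,
    b_replay_mean = b_replay_mean, b_replay_sd = b_replay_sd,
    delta_b_mean = delta_b_mean, delta_b_sd = delta_b_sd,
    gamma0 = gamma0, gamma_c = gamma_c, linking_sd = linking_sd,
    stability_margin = stability_margin,
    profile = profile, hemo = hemo, seed = as.integer(seed)),
    class = "cohort_config")
}

# rivalry-first trial order where replay trial k never precedes rivalry
# trial k (a replay can only replay an already-recorded sequence)
trial_order <- function(n_rivalry, n_replay) {
  n <- n_rivalry + n_replay
  if (n == 1) return("rivalry")
  repeat {
    ord <- sample(c(rep("rivalry", n_rivalry), rep("replay", n_replay)))
    cr <- cumsum(ord == "rivalry"); cp <- cumsum(ord == "replay")
    if (ord[1] == "rivalry" && all(cp <= cr)) return(ord)
  }
}

#' Simulate one subject's runs
#'
#' Generates every run of one subject: trial schedule, rivalry percept
#' timelines, replay trials re-presenting the percept sequence reported in
#' the paired rivalry trial of the same run (stimulus changes at the
#' recorded report times, fresh reaction times for the new reports), events
#' tables, and ROI BOLD from the subject's ground-truth parameters (rivalry
#' B drives the rivalry-switch input, replay B the replay-switch input).
#'
#' @param truth A [subject_ground_truth()].
#' @param cfg A [cohort_config()].
#' @param seed Integer seed for this subject.
#' @return A `subject_data` object: `runs` (each with `events`, `bold`,
#'   `true_rivalry_switches`, `true_replay_switches`), `truth`, `cfg`
#'   timing fields.
#' @export
simulate_subject <- function(truth, cfg, seed) {
  trial_len <- cfg$stim_duration + cfg$fixation_duration
  lead_in <- cfg$lead_in_vols * cfg$TR
  run_len <- lead_in + cfg$trials_per_run * trial_len
  n_vols <- floor(run_len / cfg$TR + 1e-9)
  if (run_len > n_vols * cfg$TR + 1e-6) {
    # run ends mid-volume; integrate the full run, sample n_vols volumes
  }
  n_replay <- cfg$trials_per_run - cfg$n_rivalry
  runs <- with_seed(seed, lapply(seq_len(cfg$n_runs), function(run) {
    ord <- trial_order(cfg$n_rivalry, n_replay)
    onsets <- lead_in + (seq_along(ord) - 1) * trial_len
    ev <- list(data.frame(onset = 0, duration = lead_in,
                          trial_type = "fixation", response_time = NA_real_))
    riv_sw <- numeric(0); rep_sw <- numeric(0)
    recorded <- list()  # rivalry timelines available for replay
    for (k in seq_along(ord)) {
      t0 <- onsets[k]
      if (ord[k] == "rivalry") {
        tl <- simulate_percept_timeline(truth$profile, cfg$stim_duration)
        recorded[[length(recorded) + 1]] <- tl
        riv_sw <- c(riv_sw, t0 + tl$switch_times)
        pr <- tl$presses
        keep <- pr$time <= cfg$stim_duration + 2
        ev[[length(ev) + 1]] <- data.frame(
          onset = t0, duration = cfg$stim_duration,
          trial_type = "stimulation_rivalry", response_time = NA_real_)
        if (any(keep))
          ev[[length(ev) + 1]] <- data.frame(
            onset = t0 + pr$time[keep], duration = 0,
            trial_type = paste0("press_", pr$percept[keep]),
            response_time = NA_real_)
      } else {
        src <- recorded[[1]]; recorded <- recorded[-1]
        # stimulus changes at the recorded exclusive report times
        excl <- src$presses[src$presses$percept != "mixed", , drop = FALSE]
        changes <- excl$time[excl$time <= cfg$stim_duration - 0.5]
        percepts <- excl$percept[excl$time <= cfg$stim_duration - 0.5]
        rep_sw <- c(rep_sw, t0 + changes[-1][percepts[-1] !=
                                               percepts[-length(percepts)]])
        rts <- draw_rt(length(changes), truth$profile)
        press_t <- changes + rts
        keep <- press_t <= cfg$stim_duration + 2
        ev[[length(ev) + 1]] <- data.frame(
          onset = t0, duration = cfg$stim_duration,
          trial_type = "stimulation_replay", response_time = NA_real_)
        if (any(keep))
          ev[[length(ev) + 1]] <- data.frame(
            onset = t0 + press_t[keep], duration = 0,
            trial_type = paste0("press_", percepts[keep]),
            response_time = rts[keep])
      }
      ev[[length(ev) + 1]] <- data.frame(
        onset = t0 + cfg$stim_duration, duration = cfg$fixation_duration,
        trial_type = "fixation", response_time = NA_real_)
    }
    events <- do.call(rbind, ev)
    events <- events[order(events$onset), , drop = FALSE]
    rownames(events) <- NULL
    stim <- events[startsWith(events$trial_type, "stimulation"),
                   c("onset", "duration")]
    fix <- events[events$trial_type == "fixation", c("onset", "duration")]
    inputs <- input_timeline(run_len, dt = cfg$dt,
                             fixation = fix, stimulation = stim,
                             rivalry_switch_times = riv_sw,
                             replay_switch_times = rep_sw,
                             pulse_width = cfg$pulse_width)
    clean <- simulate_bold_state_noise(truth$params, inputs, cfg$hemo,
                                       cfg$TR, n_vols,
                                       neural_sd = cfg$neural_sd)
    y <- clean$y
    if (cfg$noise_sd > 0)
      y <- y + matrix(rnorm(length(y), 0, cfg$noise_sd), nrow(y), ncol(y))
    list(events = events, bold = bold_series(y, cfg$TR),
         true_rivalry_switches = riv_sw, true_replay_switches = rep_sw)
  }))
  structure(list(runs = runs, truth = truth,
                 lead_in_vols = cfg$lead_in_vols, TR = cfg$TR),
            class = "subject_data")
}

#' Simulate a full cohort with known ground truth
#'
#' Draws per-subject modulation parameters (replay-condition B plus a
#' rivalry-minus-replay difference), sets each subject's mean dominance
#' duration via the linear linking rule, and simulates every subject's
#' runs. Per-subject seeds derive deterministically from the master seed,
#' so the cohort is a pure function of its configuration.
#'
#' @param cfg A [cohort_config()].
#' @return A `cohort` object: `subjects` (list of `subject_data`), `truth`
#'   (data.frame: subject, delta-B per connection, linked mean duration),
#'   `cfg`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  con_labels <- cfg$model$b_connections
  nb <- length(con_labels)
  gamma_c <- cfg$gamma_c
  regions <- cfg$model$regions
  con <- modulable_connections(regions)
  n <- length(regions$labels)
  Amat <- diag(rep(cfg$self, n)); dimnames(Amat) <- list(regions$labels,
                                                         regions$labels)
  for (j in seq_len(nrow(con))) {
    val <- if (con$label[j] %in% names(cfg$a)) cfg$a[[con$label[j]]] else 0
    Amat[con$target[j], con$source[j]] <- val
  }
  bmat <- function(vals) {
    M <- matrix(0, n, n)
    for (lab in names(vals)) {
      j <- match(lab, con$label)
      M[match(con$target[j], regions$labels),
        match(con$source[j], regions$labels)] <- vals[[lab]]
    }
    M
  }
  max_re <- function(M) max(Re(eigen(M, only.values = TRUE)$values))
  subjects <- vector("list", cfg$n_subjects)
  truth_rows <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    par_seed <- cfg$seed + 7919L * i
    draw <- with_seed(par_seed, {
      for (attempt in 1:100) {
        b_rep <- setNames(rnorm(nb, rep(cfg$b_replay_mean, length.out = nb),
                                cfg$b_replay_sd), con_labels)
        db_mu <- if (nb) rep_len(cfg$delta_b_mean[con_labels], nb) else numeric(0)
        db_mu[is.na(db_mu)] <- 0
        delta_b <- setNames(rnorm(nb, db_mu, cfg$delta_b_sd), con_labels)
        link <- cfg$gamma0 +
          sum(ifelse(is.na(gamma_c[con_labels]), 0,
                     gamma_c[con_labels]) * delta_b) +
          rnorm(1, 0, cfg$linking_sd)
        stable <- max_re(Amat + bmat(b_rep + delta_b)) <=
          cfg$stability_margin &&
          max_re(Amat + bmat(b_rep)) <= cfg$stability_margin
        if (link > 0 && stable) break
        if (link <= 0)
          warning("non-positive linked dominance duration; resampling subject ",
                  i)
      }
      list(b_rep = b_rep, delta_b = delta_b, link = max(1, link))
    })
    profile <- behavioral_profile(
      mean_duration = draw$link,
      sd_duration = cfg$profile$sd_duration * draw$link /
        cfg$profile$mean_duration,
      mixed_fraction = cfg$profile$mixed_fraction,
      mixed_mean_duration = cfg$profile$mixed_mean_duration,
      rt_mean = cfg$profile$rt_mean, rt_sd = cfg$profile$rt_sd,
      rt_min = cfg$profile$rt_min)
    driven <- cfg$model$c_switch_regions
    v5 <- cfg$model$regions$labels[1]
    c_sw <- setNames(rep(cfg$c_switch, 1 + length(driven)), c(v5, driven))
    params <- dcm_parameters(
      cfg$model, a = cfg$a, self = cfg$self,
      b_rivalry = draw$b_rep + draw$delta_b, b_replay = draw$b_rep,
      c_stimulation = cfg$c_stimulation,
      c_rivalry_switch = c_sw, c_replay_switch = c_sw)
    truth <- subject_ground_truth(cfg$model, params, profile, draw$delta_b)
    subjects[[i]] <- simulate_subject(truth, cfg,
                                      seed = cfg$seed + 104729L * i)
    row <- data.frame(subject = i, linked_mean_duration = draw$link)
    for (lab in con_labels) row[[paste0("delta_b.", lab)]] <- draw$delta_b[[lab]]
    truth_rows[[i]] <- row
  }
  structure(list(subjects = subjects,
                 truth = do.call(rbind, truth_rows), cfg = cfg),
            class = "cohort")
}

#' Write a subject's runs to disk
#'
#' One events TSV and one BOLD TSV per run
#' (`sub-XX_run-YY_events.tsv` / `sub-XX_run-YY_bold.tsv`).
#'
#' @param subject A `subject_data`.
#' @param dir Output directory (created if needed).
#' @param subject_id Integer id used in file names.
#' @return Invisibly, the written file paths.
#' @export
write_subject <- function(subject, dir, subject_id = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- unlist(lapply(seq_along(subject$runs), function(r) {
    base <- file.path(dir, sprintf("sub-%02d_run-%02d", subject_id, r))
    write_events(subject$runs[[r]]$events, paste0(base, "_events.tsv"))
    write_bold(subject$runs[[r]]$bold, paste0(base, "_bold.tsv"))
    paste0(base, c("_events.tsv", "_bold.tsv"))
  }))
  invisible(paths)
}

#' Mean dominance duration from recorded events
#'
#' Mean duration of exclusive-percept epochs across all rivalry trials:
#' epochs are delimited by consecutive button presses within a trial (the
#' final epoch ends at stimulation offset); epochs initiated by a
#' mixed-percept report are excluded.
#'
#' @param events Events table of one or more runs (uncorrected press
#'   times).
#' @return Mean exclusive dominance duration (s).
#' @export
mean_dominance_from_events <- function(events) {
  stim <- events[events$trial_type == "stimulation_rivalry", , drop = FALSE]
  durs <- numeric(0)
  for (i in seq_len(nrow(stim))) {
    lo <- stim$onset[i]; hi <- lo + stim$duration[i]
    pr <- events[events$trial_type %in% PRESS_TYPES &
                   events$onset >= lo & events$onset <= hi + 2, , drop = FALSE]
    if (!nrow(pr)) next
    bounds <- c(pr$onset, hi)
    d <- diff(bounds)
    keep <- pr$trial_type != "press_mixed" & d > 0
    durs <- c(durs, d[keep])
  }
  mean(durs)
}
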