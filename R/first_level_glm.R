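# First-level GLM: four task regressors (fixation boxcar, stimulation boxcar,
# rivalry-switch impulses, replay-switch impulses) convolved with a canonical
# double-gamma HRF at microtime resolution, OLS per region, and the
# rivalry-switch > replay-switch contrast.

PRESS_TYPES <- c("press_toward", "press_away", "press_mixed")

#' Read / write a BIDS-events-style table
#'
#' Tab-separated columns `onset` (s), `duration` (s), `trial_type`,
#' `response_time` (s, `n/a` where not applicable).
#'
#' @param events Data.frame with those columns.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  ev <- events
  ev$response_time <- ifelse(is.na(ev$response_time), "n/a",
                             format(ev$response_time, digits = 10))
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = c("n/a", "NA"))
  ev$response_time <- as.numeric(ev$response_time)
  validate_events(ev)
}

validate_events <- function(events) {
  need <- c("onset", "duration", "trial_type", "response_time")
  if (!all(need %in% names(events)))
    stop("events need columns: ", paste(need, collapse = ", "))
  if (is.unsorted(events$onset)) events <- events[order(events$onset), ]
  if (any(events$duration < 0)) stop("negative event duration")
  events
}

#' Load one synthetic run, discarding initial volumes
#'
#' Reads the BOLD series and events of a run and removes the first
#' `discard_vols` volumes (scanner equilibration), shifting the event time
#' origin accordingly. Events that end before the new origin are dropped;
#' partially overlapping boxcars are clipped.
#'
#' @param bold_path,events_path Paths to the run's BOLD and events files.
#' @param discard_vols Number of leading volumes to drop (default 5).
#' @return List with elements `bold` (`bold_series`) and `events`.
#' @export
load_run <- function(bold_path, events_path, discard_vols = 5) {
  bold <- read_bold(bold_path)
  events <- read_events(events_path)
  shift <- discard_vols * bold$TR
  if (discard_vols > 0) {
    bold <- bold_series(bold$y[-seq_len(discard_vols), , drop = FALSE], bold$TR)
    events$onset <- events$onset - shift
    ends <- events$onset + events$duration
    events <- events[ends > 1e-9, , drop = FALSE]
    clip <- events$onset < 0
    events$duration[clip] <- events$duration[clip] + events$onset[clip]
    events$onset[clip] <- 0
  }
  list(bold = bold, events = events)
}

#' Estimate the mean manual reaction time from replay trials
#'
#' In replay trials the stimulus change time is known, so the reaction time
#' is observable as the interval between the stimulus change and the button
#' press; it is carried in the events table's `response_time` column of
#' press rows inside replay trials. The mean over those presses estimates
#' the subject's reporting latency.
#'
#' @param events An events table for one or more runs.
#' @return Mean reaction time (s); 0 with a warning when no replay press
#'   carries a response time.
#' @export
estimate_mean_rt <- function(events) {
  press <- events$trial_type %in% PRESS_TYPES & !is.na(events$response_time)
  if (!any(press)) {
    warning("no response times recorded; assuming mean RT 0")
    return(0)
  }
  mean(events$response_time[press])
}

#' Shift button presses back by the mean reaction time
#'
#' Subtracts the estimated mean reaction time from every press onset to
#' approximate the true time of the perceptual event being reported; onsets
#' are clipped at 0. All other rows are unchanged.
#'
#' @param events Events table.
#' @param mean_rt Mean reaction time (s), e.g. from [estimate_mean_rt()].
#' @return Corrected events table.
#' @export
correct_event_times <- function(events, mean_rt) {
  stopifnot(mean_rt >= 0)
  press <- events$trial_type %in% PRESS_TYPES
  events$onset[press] <- pmax(0, events$onset[press] - mean_rt)
  events[order(events$onset), , drop = FALSE]
}

#' Derive perceptual switch events from button presses
#'
#' A switch is a press whose reported exclusive percept (toward/away)
#' differs from the previous exclusive percept reported within the same
#' stimulation trial. The first press of a trial reports the initial percept
#' and is not a switch; mixed-percept presses never generate switch events.
#'
#' @param events Events table (RT-corrected or not).
#' @return Data.frame with columns `onset` (s) and `condition`
#'   (`"rivalry"` or `"replay"`).
#' @export
derive_switch_events <- function(events) {
  stim <- events[events$trial_type %in%
                   c("stimulation_rivalry", "stimulation_replay"), ,
                 drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(stim))) {
    lo <- stim$onset[i]
    hi <- lo + stim$duration[i] + 2  # presses may trail the stimulus by an RT
    cond <- sub("stimulation_", "", stim$trial_type[i])
    pr <- events[events$trial_type %in% c("press_toward", "press_away") &
                   events$onset >= lo - 2 & events$onset < hi, , drop = FALSE]
    if (nrow(pr) < 2) next
    percept <- sub("press_", "", pr$trial_type)
    sw <- which(percept[-1] != percept[-length(percept)]) + 1
    if (length(sw))
      out[[length(out) + 1]] <- data.frame(onset = pr$onset[sw],
                                           condition = cond)
  }
  if (!length(out))
    return(data.frame(onset = numeric(0), condition = character(0)))
  res <- do.call(rbind, out)
  res[order(res$onset), , drop = FALSE]
}

#' Canonical double-gamma HRF specification
#'
#' Defaults follow the standard canonical parameterization: response peak
#' delay 6 s, undershoot delay 16 s, unit dispersions, undershoot ratio 6,
#' 32 s kernel, 16 microtime bins per TR.
#'
#' @param response_delay,undershoot_delay Delays of the response and
#'   undershoot gamma components (s).
#' @param response_dispersion,undershoot_dispersion Dispersions (scale
#'   parameters, s) of the two components.
#' @param undershoot_ratio Response-to-undershoot amplitude ratio.
#' @param length Kernel length (s).
#' @param microtime_bins Bins per TR used to build stimulus functions.
#' @return An `hrf_spec` object.
#' @export
hrf_spec <- function(response_delay = 6, undershoot_delay = 16,
                     response_dispersion = 1, undershoot_dispersion = 1,
                     undershoot_ratio = 6, length = 32, microtime_bins = 16) {
  if (response_dispersion <= 0 || undershoot_dispersion <= 0)
    stop("dispersions must be positive")
  if (length < max(response_delay, undershoot_delay))
    stop("kernel length must cover both gamma components")
  structure(list(response_delay = response_delay,
                 undershoot_delay = undershoot_delay,
                 response_dispersion = response_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio,
                 length = length, microtime_bins = microtime_bins),
            class = "hrf_spec")
}

#' Sample the canonical HRF kernel
#'
#' Difference of two gamma densities: response minus undershoot scaled by
#' `1/undershoot_ratio`. With delay `d` and dispersion `s` the gamma
#' component has shape `d/s` and scale `s`, so its mode is at `d - s`.
#'
#' @param spec An [hrf_spec()].
#' @param dt Sampling step (s).
#' @return Numeric vector of kernel samples at `0, dt, ..., length`.
#' @export
canonical_hrf <- function(spec = hrf_spec(), dt = 0.1) {
  stopifnot(dt > 0)
  tt <- seq(0, spec$length, by = dt)
  dgamma(tt, shape = spec$response_delay / spec$response_dispersion,
         scale = spec$response_dispersion) -
    dgamma(tt, shape = spec$undershoot_delay / spec$undershoot_dispersion,
           scale = spec$undershoot_dispersion) / spec$undershoot_ratio
}

#' Build the first-level design matrix
#'
#' Stimulus functions are built at microtime resolution (`TR /
#' microtime_bins`): boxcars for fixation and visual stimulation (rivalry
#' and replay stimulation share one regressor), unit impulses at the
#' (RT-corrected) switch times, separately for rivalry-switch and
#' replay-switch. Each is convolved with the canonical HRF and sampled at
#' the volume times `0, TR, ...`. An intercept column is appended, plus any
#' supplied nuisance regressors.
#'
#' @param events RT-corrected events table.
#' @param hrf An [hrf_spec()].
#' @param n_vols Number of volumes in the run.
#' @param TR Repetition time (s).
#' @param nuisance Optional numeric matrix of nuisance columns
#'   (`n_vols` rows), e.g. head-motion parameters.
#' @return A `design_matrix` object: `X` (n_vols x columns), `TR`, `hrf`.
#' @export
build_design_matrix <- function(events, hrf = hrf_spec(), n_vols, TR = 2.1,
                                nuisance = NULL) {
  run_len <- n_vols * TR
  late <- events$onset > run_len + 1e-9
  if (any(late))
    stop("events beyond run end: onsets ",
         paste(round(events$onset[late], 2), collapse = ", "))
  dtm <- TR / hrf$microtime_bins
  nT <- n_vols * hrf$microtime_bins
  tgrid <- (seq_len(nT) - 1) * dtm

  boxcar <- function(types) {
    u <- numeric(nT)
    rows <- events[events$trial_type %in% types, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      sel <- tgrid >= rows$onset[i] - 1e-9 &
             tgrid < rows$onset[i] + rows$duration[i] - 1e-9
      u[sel] <- 1
    }
    u
  }
  impulses <- function(times) {
    u <- numeric(nT)
    idx <- round(times / dtm) + 1
    idx <- idx[idx >= 1 & idx <= nT]
    u[idx] <- u[idx] + 1
    u
  }
  sw <- derive_switch_events(events)
  stimfun <- cbind(
    fixation = boxcar("fixation"),
    stimulation = boxcar(c("stimulation_rivalry", "stimulation_replay")),
    rivalry_switch = impulses(sw$onset[sw$condition == "rivalry"]),
    replay_switch = impulses(sw$onset[sw$condition == "replay"])
  )
  kern <- canonical_hrf(hrf, dtm)
  conv_cols <- apply(stimfun, 2, function(u) {
    v <- convolve(u, rev(kern), type = "open")[seq_len(nT)]
    v
  })
  vol_idx <- (seq_len(n_vols) - 1) * hrf$microtime_bins + 1
  X <- conv_cols[vol_idx, , drop = FALSE]
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_vols)
    colnames(nuisance) <- colnames(nuisance) %||%
      paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  X <- cbind(X, intercept = 1)
  structure(list(X = X, TR = TR, hrf = hrf), class = "design_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the GLM by ordinary least squares
#'
#' @param bold A `bold_series` (volumes x regions).
#' @param design A `design_matrix` with the same number of rows.
#' @return A `glm_fit`: `beta` (coefficients x regions), `se`, `t`,
#'   `sigma2` (residual variance per region), `df`, `XtXinv`, `design`.
#' @export
fit_glm <- function(bold, design) {
  X <- design$X
  Y <- bold$y
  if (nrow(X) != nrow(Y))
    stop("design has ", nrow(X), " rows but BOLD has ", nrow(Y), " volumes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  df <- nrow(X) - qrX$rank
  sigma2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  se <- sqrt(outer(diag(XtXinv), sigma2))
  structure(list(beta = beta, se = se, t = beta / se, sigma2 = sigma2,
                 df = df, XtXinv = XtXinv, design = design,
                 residuals = resid),
            class = "glm_fit")
}

#' Rivalry-switch > replay-switch contrast
#'
#' Applies the contrast vector (+1 on the rivalry-switch column, -1 on the
#' replay-switch column, 0 elsewhere) to a GLM fit.
#'
#' @param fit A `glm_fit`.
#' @return Data.frame per region: `estimate`, `se`, `t`, `df`, `p`
#'   (two-sided).
#' @export
contrast_rivalry_gt_replay <- function(fit) {
  regions <- colnames(fit$beta) %||% paste0("region", seq_len(ncol(fit$beta)))
  cols <- rownames(fit$beta)
  if (!all(c("rivalry_switch", "replay_switch") %in% cols))
    stop("design lacks rivalry_switch / replay_switch columns")
  cvec <- setNames(numeric(length(cols)), cols)
  cvec[c("rivalry_switch", "replay_switch")] <- c(1, -1)
  est <- drop(cvec %*% fit$beta)
  cv <- drop(t(cvec) %*% fit$XtXinv %*% cvec)
  se <- sqrt(cv * fit$sigma2)
  tval <- est / se
  data.frame(region = regions, estimate = est, se = se,
             t = tval, df = fit$df,
             p = 2 * pt(-abs(tval), fit$df), row.names = NULL)
}

#' Group-level one-sample t-test on subject contrasts
#'
#' @param contrasts Matrix subjects x regions of per-subject contrast
#'   estimates.
#' @return Data.frame per region: mean, t, df, two-sided p.
#' @export
group_contrast_ttest <- function(contrasts) {
  contrasts <- as.matrix(contrasts)
  n <- nrow(contrasts)
  m <- colMeans(contrasts)
  se <- apply(contrasts, 2, sd) / sqrt(n)
  tval <- m / se
  data.frame(region = colnames(contrasts), mean = m, t = tval, df = n - 1,
             p = 2 * pt(-abs(tval), n - 1), row.names = NULL)
}
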