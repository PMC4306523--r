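# Model inversion: penalized nonlinear least squares on the forward model
# (Levenberg-Marquardt with Gaussian shrinkage priors) plus a Laplace
# approximation to the log model evidence (accuracy minus complexity).
# Deterministic given its inputs; numerical equality with any particular
# neuroimaging toolbox is not claimed.

#' Shrinkage priors for the free coupling parameters
#'
#' Zero-mean Gaussian priors per parameter class (A off-diagonal, B, C).
#' Hemodynamic parameters are fixed at their canonical values. The
#' observation-noise variance is estimated by maximum likelihood with a
#' lower floor.
#'
#' @param a_var,b_var,c_var Prior variances of the endogenous, modulatory
#'   and driving parameters (default 0.25 each).
#' @param a_mean,b_mean,c_mean Prior means (default 0).
#' @param noise_floor Lower bound on the estimated noise variance.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(a_var = 0.25, b_var = 0.25, c_var = 0.25,
                       a_mean = 0, b_mean = 0, c_mean = 0,
                       noise_floor = 1e-6) {
  if (min(a_var, b_var, c_var) <= 0) stop("prior variances must be positive")
  structure(list(a_var = a_var, b_var = b_var, c_var = c_var,
                 a_mean = a_mean, b_mean = b_mean, c_mean = c_mean,
                 noise_floor = noise_floor),
            class = "prior_spec")
}

# free-parameter bookkeeping for one model: one row per parameter with its
# class and matrix position
theta_map <- function(model) {
  labs <- model$regions$labels
  con <- modulable_connections(model$regions)
  rows <- list()
  for (i in seq_len(nrow(con)))
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("A:", con$label[i]), kind = "a",
      row = match(con$target[i], labs), col = match(con$source[i], labs),
      input = NA_integer_)
  for (inp in c("rivalry_switch", "replay_switch")) {
    short <- sub("_switch", "", inp)
    for (lab in model$b_connections) {
      i <- match(lab, con$label)
      rows[[length(rows) + 1]] <- data.frame(
        name = paste0("B:", short, ":", lab), kind = "b",
        row = match(con$target[i], labs), col = match(con$source[i], labs),
        input = match(inp, DCM_INPUTS))
    }
  }
  c_entries <- rbind(
    data.frame(region = labs[1], input = "stimulation"),
    data.frame(region = labs[1], input = c("rivalry_switch", "replay_switch")))
  for (reg in model$c_switch_regions)
    c_entries <- rbind(c_entries,
                       data.frame(region = reg,
                                  input = c("rivalry_switch", "replay_switch")))
  for (i in seq_len(nrow(c_entries)))
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("C:", sub("_switch", "", c_entries$input[i]), ":",
                    c_entries$region[i]),
      kind = "c", row = match(c_entries$region[i], labs), col = NA_integer_,
      input = match(c_entries$input[i], DCM_INPUTS))
  do.call(rbind, rows)
}

theta_matrices <- function(theta, map, model, self = -0.5) {
  n <- length(model$regions$labels)
  ti <- theta_indices(map, n)
  A <- diag(rep(self, n))
  B <- numeric(n * n * length(DCM_INPUTS))
  C <- matrix(0, n, length(DCM_INPUTS))
  A[ti$a_pos] <- theta[ti$a_par]
  B[ti$b_pos] <- theta[ti$b_par]
  C[ti$c_pos] <- theta[ti$c_par]
  list(A = A, B = array(B, c(n, n, length(DCM_INPUTS))), C = C)
}

# flat-index view of the parameter map, so packing theta into (A, B, C) is a
# handful of vectorized assignments in the inversion hot loop
theta_indices <- function(map, n) {
  a <- map$kind == "a"; b <- map$kind == "b"; cc <- map$kind == "c"
  list(a_pos = map$row[a] + (map$col[a] - 1L) * n,
       a_par = which(a),
       b_pos = map$row[b] + (map$col[b] - 1L) * n +
         (map$input[b] - 1L) * n * n,
       b_par = which(b),
       c_pos = map$row[cc] + (map$input[cc] - 1L) * n,
       c_par = which(cc))
}

prior_variances <- function(map, priors) {
  v <- c(a = priors$a_var, b = priors$b_var, c = priors$c_var)
  m <- c(a = priors$a_mean, b = priors$b_mean, c = priors$c_mean)
  list(var = unname(v[map$kind]), mean = unname(m[map$kind]))
}

#' Invert a DCM for one subject
#'
#' Estimates the free A/B/C parameters of one model from ROI BOLD by
#' Levenberg-Marquardt minimization of the penalized least-squares
#' objective (Gaussian likelihood with ML noise variance, Gaussian
#' shrinkage priors), starting from the prior mean, and returns a
#' Laplace-approximate log evidence
#' `accuracy - complexity`. Runs are inverted jointly with independent
#' state resets at each run boundary. The scheme is deterministic.
#'
#' @param bold A `bold_series` or list of them (one per run).
#' @param inputs Matching [input_timeline()] or list, on the grid the data
#'   were sampled from (`TR` must be a multiple of `dt`).
#' @param model A `dcm_model_spec`.
#' @param priors A [prior_spec()].
#' @param hemo Hemodynamic parameters (fixed during inversion).
#' @param self Fixed self-coupling (1/s).
#' @param max_iter Maximum accepted Levenberg-Marquardt steps.
#' @param tol Relative decrease of the penalized objective below which the
#'   scheme is declared converged.
#' @param fd_step Relative finite-difference step for the Jacobian.
#' @return A `posterior_fit`: `theta` (posterior mode, named), `Sigma`
#'   (posterior covariance), `logev`, `accuracy`, `complexity`, `sigma2`,
#'   `pve` (percent variance explained), `converged`, `iterations`,
#'   `model_id`.
#' @export
invert_dcm <- function(bold, inputs, model, priors = prior_spec(),
                       hemo = hemodynamic_params(), self = -0.5,
                       max_iter = 32, tol = 1e-6, fd_step = 1e-4) {
  if (inherits(bold, "bold_series")) bold <- list(bold)
  if (inherits(inputs, "input_timeline")) inputs <- list(inputs)
  stopifnot(length(bold) == length(inputs))
  hv <- hemo_vector(hemo)
  runs <- lapply(seq_along(bold), function(r) {
    b <- bold[[r]]; u <- inputs[[r]]
    step <- b$TR / u$dt
    if (abs(step - round(step)) > 1e-8)
      stop("TR must be a multiple of the input timeline step")
    idx <- as.integer((seq_len(nrow(b$y)) - 1) * round(step) + 1)
    if (max(idx) > nrow(u$U) + 1)
      stop("input timeline shorter than the BOLD run")
    list(U = u$U, dt = u$dt, idx = idx)
  })
  y <- unlist(lapply(bold, function(b) as.numeric(b$y)))
  N <- length(y)
  map <- theta_map(model)
  p <- nrow(map)
  pv <- prior_variances(map, priors)
  mu <- pv$mean
  Pinv <- diag(1 / pv$var, p)

  dts <- vapply(runs, `[[`, 0, "dt")
  if (max(dts) - min(dts) > 1e-12)
    stop("all runs must share one integration step")
  dt <- dts[1]
  runsU <- lapply(runs, `[[`, "U")
  runsIdx <- lapply(runs, `[[`, "idx")
  nreg <- length(model$regions$labels)
  ti <- theta_indices(map, nreg)
  A0 <- diag(rep(self, nreg))
  B0 <- numeric(nreg * nreg * length(DCM_INPUTS))
  C0 <- matrix(0, nreg, length(DCM_INPUTS))
  # 0-based flat positions and kind codes for the C++ Jacobian kernel
  kind_code <- c(a = 0L, b = 1L, c = 2L)[map$kind]
  pos0 <- integer(nrow(map))
  pos0[ti$a_par] <- ti$a_pos - 1L
  pos0[ti$b_par] <- ti$b_pos - 1L
  pos0[ti$c_par] <- ti$c_pos - 1L
  pack <- function(theta) {
    A <- A0; A[ti$a_pos] <- theta[ti$a_par]
    Bv <- B0; Bv[ti$b_pos] <- theta[ti$b_par]
    Cm <- C0; Cm[ti$c_pos] <- theta[ti$c_par]
    list(A = A, Bv = Bv, Cm = Cm)
  }
  predict_y <- function(theta) {
    mt <- pack(theta)
    out <- vector("list", length(runs))
    for (r in seq_along(runs)) {
      res <- .dcm_forward_cpp(mt$A, mt$Bv, mt$Cm, runsU[[r]], dt, hv,
                              runsIdx[[r]])
      if (!res$ok) return(NULL)
      out[[r]] <- res$y
    }
    unlist(out)
  }

  theta <- mu
  g <- predict_y(theta)
  if (is.null(g)) stop("forward model diverges at the prior mean")
  r_vec <- y - g
  rss <- sum(r_vec^2)
  sigma2 <- max(rss / N, priors$noise_floor)
  qf <- function(th) drop(t(th - mu) %*% Pinv %*% (th - mu))
  obj <- rss / (2 * sigma2) + 0.5 * qf(theta)

  lambda <- 1
  iterations <- 0L
  converged <- FALSE
  J <- NULL
  jac <- function(theta) {
    mt <- pack(theta)
    steps <- fd_step * pmax(1, abs(theta))
    res <- .dcm_jac_cpp(mt$A, mt$Bv, mt$Cm, runsU, runsIdx, dt, hv,
                        kind_code, pos0, steps)
    if (!res$ok) return(NULL)
    res$J
  }

  for (it in seq_len(max_iter)) {
    J <- jac(theta)
    if (is.null(J)) break
    grad <- drop(t(J) %*% r_vec) / sigma2 - drop(Pinv %*% (theta - mu))
    H <- crossprod(J) / sigma2 + Pinv
    accepted <- FALSE
    for (trial in 1:12) {
      Hl <- H + lambda * diag(diag(H), p)
      delta <- tryCatch(solve(Hl, grad), error = function(e) NULL)
      if (!is.null(delta)) {
        th_new <- theta + delta
        g_new <- predict_y(th_new)
        if (!is.null(g_new)) {
          r_new <- y - g_new
          rss_new <- sum(r_new^2)
          obj_new <- rss_new / (2 * sigma2) + 0.5 * qf(th_new)
          if (obj_new < obj) {
            theta <- th_new; g <- g_new; r_vec <- r_new; rss <- rss_new
            sigma2 <- max(rss / N, priors$noise_floor)
            obj_prev <- obj
            obj <- rss / (2 * sigma2) + 0.5 * qf(theta)
            lambda <- max(lambda / 3, 1e-8)
            accepted <- TRUE
            iterations <- it
            # relative objective decrease under the previous noise level
            if (abs(obj_prev - obj_new) < tol * (1 + abs(obj_prev)))
              converged <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e9) break
    }
    if (!accepted) { converged <- TRUE; break }
    if (converged) break
  }

  Jf <- jac(theta)
  if (!is.null(Jf)) J <- Jf
  # unbiased plug-in noise level: correct the ML estimate by the effective
  # number of parameters the data actually constrain, so models with many
  # weakly identified parameters cannot buy accuracy from overfitted noise
  H <- crossprod(J) / sigma2 + Pinv
  Sig0 <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (!is.null(Sig0)) {
    p_eff <- sum(diag(Sig0 %*% crossprod(J))) / sigma2
    sigma2 <- max(rss / max(N - p_eff, 1), priors$noise_floor)
    H <- crossprod(J) / sigma2 + Pinv
  }
  Sigma <- NULL
  jitter <- 0
  for (k in 0:8) {
    Sigma <- tryCatch(chol2inv(chol(H + jitter * diag(p))),
                      error = function(e) NULL)
    if (!is.null(Sigma)) break
    jitter <- max(jitter * 100, 1e-10 * max(diag(H)))
  }
  if (is.null(Sigma)) stop("posterior covariance could not be computed")
  names(theta) <- map$name
  dimnames(Sigma) <- list(map$name, map$name)
  accuracy <- -N / 2 * (log(2 * pi * sigma2) + rss / (N * sigma2))
  ld_prior <- sum(log(pv$var))
  ld_post <- determinant(Sigma, logarithm = TRUE)$modulus
  complexity <- 0.5 * (qf(theta) + ld_prior - as.numeric(ld_post))
  tss <- sum((y - mean(y))^2)
  structure(list(theta = theta, Sigma = Sigma,
                 logev = accuracy - complexity,
                 accuracy = accuracy, complexity = complexity,
                 sigma2 = sigma2, pve = 100 * (1 - rss / tss),
                 converged = converged, iterations = iterations,
                 model_id = model$model_id, map = map),
            class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf(
    "DCM fit, model %d: logev = %.2f (accuracy %.2f, complexity %.2f), %.1f%% var, %s in %d steps\n",
    x$model_id, x$logev, x$accuracy, x$complexity, x$pve,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Extract modulation estimates per condition
#'
#' @param fit A `posterior_fit`.
#' @param condition `"rivalry"` or `"replay"`.
#' @return Named vector of B estimates over the model's modulated
#'   connections.
#' @export
b_estimates <- function(fit, condition = c("rivalry", "replay")) {
  condition <- match.arg(condition)
  pre <- paste0("B:", condition, ":")
  sel <- startsWith(names(fit$theta), pre)
  setNames(fit$theta[sel], sub(pre, "", names(fit$theta)[sel]))
}

#' Prepare inversion inputs from a simulated cohort
#'
#' For each subject: estimates the mean reaction time from the replay
#' presses, shifts press times back by it, derives the switch events, and
#' builds the four-input timeline of every run on the requested integration
#' grid. This is the analysis-side view of the data (it uses only what the
#' events tables record, not the generator's hidden switch times).
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dt Integration step for inversion (default: the generator's).
#' @param pulse_width Switch pulse width (default: the generator's).
#' @return List (one element per subject) of `list(bold = <list>, inputs =
#'   <list>, events = <list>, mean_rt)`.
#' @export
inversion_data_from_cohort <- function(cohort, dt = NULL, pulse_width = NULL) {
  cfg <- cohort$cfg
  if (is.null(dt)) dt <- cfg$dt
  if (is.null(pulse_width)) pulse_width <- cfg$pulse_width
  lapply(cohort$subjects, function(sub) {
    all_ev <- do.call(rbind, lapply(sub$runs, `[[`, "events"))
    mean_rt <- estimate_mean_rt(all_ev)
    runs <- lapply(sub$runs, function(run) {
      ev <- correct_event_times(run$events, mean_rt)
      sw <- derive_switch_events(ev)
      n_vols <- nrow(run$bold$y)
      run_len <- n_vols * run$bold$TR
      stim <- ev[startsWith(ev$trial_type, "stimulation"),
                 c("onset", "duration")]
      fix <- ev[ev$trial_type == "fixation", c("onset", "duration")]
      tl <- input_timeline(run_len, dt = dt, fixation = fix,
                           stimulation = stim,
                           rivalry_switch_times =
                             sw$onset[sw$condition == "rivalry"],
                           replay_switch_times =
                             sw$onset[sw$condition == "replay"],
                           pulse_width = pulse_width)
      list(bold = run$bold, inputs = tl, events = ev)
    })
    list(bold = lapply(runs, `[[`, "bold"),
         inputs = lapply(runs, `[[`, "inputs"),
         events = lapply(runs, `[[`, "events"),
         mean_rt = mean_rt)
  })
}

#' Approximate log evidence for every subject under every model
#'
#' Inverts each model for each subject and collects the Laplace evidence
#' into a subjects x models matrix. Non-converged fits are listed in the
#' `"nonconverged"` attribute rather than silently dropped.
#'
#' @param data Per-subject data as from [inversion_data_from_cohort()].
#' @param models List of `dcm_model_spec` (e.g. the full 64-model space).
#' @param priors A [prior_spec()].
#' @param keep_fits Retain all posterior fits (attribute `"fits"`)?
#' @param progress Print one line per subject.
#' @param ... Passed to [invert_dcm()].
#' @return Numeric matrix, rownames subjects, colnames model ids, class
#'   `evidence_matrix`.
#' @export
evidence_table <- function(data, models, priors = prior_spec(),
                           keep_fits = TRUE, progress = FALSE, ...) {
  S <- length(data); K <- length(models)
  E <- matrix(NA_real_, S, K,
              dimnames = list(paste0("sub", seq_len(S)),
                              vapply(models, `[[`, 0L, "model_id")))
  fits <- if (keep_fits) vector("list", S) else NULL
  bad <- list()
  for (s in seq_len(S)) {
    if (keep_fits) fits[[s]] <- vector("list", K)
    for (k in seq_len(K)) {
      fit <- invert_dcm(data[[s]]$bold, data[[s]]$inputs, models[[k]],
                        priors = priors, ...)
      E[s, k] <- fit$logev
      if (!fit$converged)
        bad[[length(bad) + 1]] <- data.frame(subject = s,
                                             model_id = fit$model_id)
      if (keep_fits) fits[[s]][[k]] <- fit
    }
    if (progress)
      message(sprintf("subject %d/%d done (best model %s)", s, S,
                      colnames(E)[which.max(E[s, ])]))
  }
  structure(E, class = c("evidence_matrix", "matrix"),
            nonconverged = if (length(bad)) do.call(rbind, bad) else NULL,
            fits = fits)
}
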