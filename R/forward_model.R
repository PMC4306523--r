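# Forward (generative) model: bilinear neural dynamics
#   dx/dt = (A + sum_j u_j B^j) x + C u
# followed by a balloon-Windkessel hemodynamic observation model giving ROI
# BOLD in percent signal change about a 0 baseline.

#' Balloon-Windkessel hemodynamic parameters
#'
#' Canonical constants for the hemodynamic observation model: neuronal
#' efficacy `epsilon` (gain from neural activity to the vasodilatory
#' signal), signal decay `kappa` (1/s), autoregulation `gamma` (1/s), mean
#' transit time `tau` (s), vessel stiffness `alpha`, resting oxygen
#' extraction `E0`, resting venous volume fraction `V0`, and the BOLD
#' observation coefficients `k1..k3` (defaults `7*E0`, `2`, `2*E0 - 0.2`).
#' The efficacy default (0.25) maps sustained neural activity of order 1 to
#' a few percent signal change.
#'
#' @param epsilon,kappa,gamma,tau,alpha,E0,V0,k1,k2,k3 Numeric scalars, see
#'   above.
#' @return A `hemodynamic_params` object.
#' @export
hemodynamic_params <- function(epsilon = 0.25, kappa = 0.64, gamma = 0.32,
                               tau = 2.0, alpha = 0.32, E0 = 0.4, V0 = 0.04,
                               k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2) {
  vals <- c(epsilon = epsilon, kappa = kappa, gamma = gamma, tau = tau,
            alpha = alpha, E0 = E0, V0 = V0, k1 = k1, k2 = k2, k3 = k3)
  if (any(vals[c("epsilon", "kappa", "gamma", "tau", "V0")] <= 0))
    stop("epsilon, kappa, gamma, tau and V0 must be strictly positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (E0 <= 0 || E0 >= 1) stop("E0 must lie in (0, 1)")
  structure(as.list(vals), class = "hemodynamic_params")
}

hemo_vector <- function(h) {
  unlist(h[c("epsilon", "kappa", "gamma", "tau", "alpha", "E0", "V0",
             "k1", "k2", "k3")])
}

#' Numeric coupling parameters for one model
#'
#' Assembles the A (endogenous), B (modulatory, one matrix per input) and C
#' (driving) coupling matrices on the support of a model's masks. Modulation
#' acts only through the two switch inputs; values are supplied per modulated
#' connection, separately for the rivalry-switch and replay-switch input.
#' All rates are in 1/s.
#'
#' @param model A `dcm_model_spec`.
#' @param a Named vector of endogenous off-diagonal coupling, names
#'   `"source->target"` over [modulable_connections()]. Missing names
#'   default to 0.
#' @param self Self-coupling placed on the diagonal of A (must be negative;
#'   default -0.5/s, the standard identifiability convention).
#' @param b_rivalry,b_replay Named vectors over `model$b_connections`:
#'   modulation of those connections by the rivalry-switch / replay-switch
#'   input. Missing names default to 0.
#' @param c_stimulation Driving gain of visual stimulation into V5.
#' @param c_rivalry_switch,c_replay_switch Named vectors of driving gains of
#'   the switch inputs, names over the driven regions (V5 plus the model's
#'   free switch-input regions). Missing names default to 0.
#' @return A `dcm_parameters` object with fields `A` (n x n), `B`
#'   (n x n x 4 array over inputs), `C` (n x 4), `model`.
#' @export
dcm_parameters <- function(model, a = NULL, self = -0.5,
                           b_rivalry = NULL, b_replay = NULL,
                           c_stimulation = 0,
                           c_rivalry_switch = NULL, c_replay_switch = NULL) {
  labs <- model$regions$labels
  n <- length(labs)
  if (self >= 0) stop("self-coupling must be strictly negative for stability")
  con <- modulable_connections(model$regions)

  A <- diag(rep(self, n)); dimnames(A) <- list(labs, labs)
  for (i in seq_len(nrow(con))) {
    val <- if (!is.null(a) && con$label[i] %in% names(a)) a[[con$label[i]]] else 0
    if (val != 0 && !model$a_mask[con$target[i], con$source[i]])
      stop("endogenous coupling outside the a-mask: ", con$label[i])
    A[con$target[i], con$source[i]] <- val
  }

  B <- array(0, dim = c(n, n, length(DCM_INPUTS)),
             dimnames = list(labs, labs, DCM_INPUTS))
  fill_b <- function(input, vals) {
    if (is.null(vals)) return()
    bad <- setdiff(names(vals), model$b_connections)
    if (length(bad))
      stop("modulation outside the model's b-mask: ", paste(bad, collapse = ", "))
    for (lab in names(vals)) {
      i <- match(lab, con$label)
      B[con$target[i], con$source[i], input] <<- vals[[lab]]
    }
  }
  fill_b("rivalry_switch", b_rivalry)
  fill_b("replay_switch", b_replay)

  C <- matrix(0, n, length(DCM_INPUTS), dimnames = list(labs, DCM_INPUTS))
  C[labs[1], "stimulation"] <- c_stimulation
  fill_c <- function(input, vals) {
    if (is.null(vals)) return()
    driven <- labs[model$c_mask[, input]]
    bad <- setdiff(names(vals), driven)
    if (length(bad))
      stop("driving input outside the model's c-mask: ", paste(bad, collapse = ", "))
    for (r in names(vals)) C[r, input] <<- vals[[r]]
  }
  fill_c("rivalry_switch", c_rivalry_switch)
  fill_c("replay_switch", c_replay_switch)

  structure(list(A = A, B = B, C = C, model = model, m = length(DCM_INPUTS)),
            class = "dcm_parameters")
}

#' Experimental input timeline on a fine grid
#'
#' Builds the four DCM inputs (fixation, visual stimulation, rivalry-switch,
#' replay-switch) as step functions on an integration grid. Boxcar windows
#' are half-open `[onset, onset + duration)`; switch events are rectangular
#' pulses of height 1 centred on the event time. Inputs are piecewise
#' constant over each integration step.
#'
#' @param duration Total timeline length (s).
#' @param dt Integration step (s); default 0.05.
#' @param fixation,stimulation Data.frames (or matrices) with columns
#'   `onset`, `duration` (s) giving the boxcar windows per condition.
#' @param rivalry_switch_times,replay_switch_times Numeric vectors of event
#'   times (s).
#' @param pulse_width Width of the switch pulses (s); default one
#'   integration step.
#' @return An `input_timeline` object: `U` (steps x 4 matrix, columns in
#'   fixation/stimulation/rivalry-switch/replay-switch order; row k
#'   applies on `[(k-1) dt, k dt)`), `dt`,
#'   `duration`.
#' @export
input_timeline <- function(duration, dt = 0.05,
                           fixation = NULL, stimulation = NULL,
                           rivalry_switch_times = numeric(0),
                           replay_switch_times = numeric(0),
                           pulse_width = dt) {
  stopifnot(duration > 0, dt > 0, pulse_width > 0)
  nT <- round(duration / dt)
  if (abs(nT * dt - duration) > 1e-9)
    stop("dt must divide the timeline duration")
  tstart <- (seq_len(nT) - 1) * dt
  U <- matrix(0, nT, length(DCM_INPUTS),
              dimnames = list(NULL, DCM_INPUTS))
  add_box <- function(col, wins) {
    if (is.null(wins) || nrow(wins) == 0) return()
    for (i in seq_len(nrow(wins))) {
      sel <- tstart >= wins$onset[i] - 1e-9 &
             tstart < wins$onset[i] + wins$duration[i] - 1e-9
      U[sel, col] <<- 1
    }
  }
  # pulses are snapped to the step grid and always span the same number of
  # steps, so every event injects the same input energy (~ pulse_width)
  add_pulse <- function(col, times) {
    nsteps <- max(1L, round(pulse_width / dt))
    for (tt in times) {
      i0 <- round(tt / dt - nsteps / 2) + 1
      sel <- seq(max(1, i0), min(nT, i0 + nsteps - 1))
      U[sel, col] <<- 1
    }
  }
  add_box("fixation", fixation)
  add_box("stimulation", stimulation)
  add_pulse("rivalry_switch", rivalry_switch_times)
  add_pulse("replay_switch", replay_switch_times)
  structure(list(U = U, dt = dt, duration = nT * dt), class = "input_timeline")
}

#' Integrate the bilinear neural dynamics
#'
#' Solves `dx/dt = (A + sum_j u_j B^j) x + C u` with a classical 4th-order
#' Runge-Kutta scheme, treating inputs as piecewise constant over each step.
#'
#' @param params A [dcm_parameters()] object.
#' @param inputs An [input_timeline()].
#' @param x0 Initial state (defaults to rest, all zeros).
#' @return A `neural_trajectory`: `x` ((steps+1) x regions matrix of neural
#'   states at grid times starting at 0), `time`, `dt`.
#' @export
integrate_neural <- function(params, inputs, x0 = NULL) {
  n <- nrow(params$A)
  if (is.null(x0)) x0 <- rep(0, n)
  stopifnot(length(x0) == n)
  res <- .neural_rk4_cpp(params$A, as.numeric(params$B), params$C,
                         inputs$U, as.numeric(x0), inputs$dt)
  if (!res$ok)
    stop(sprintf("neural integration diverged at t = %.3f s (unstable parameters?)",
                 res$bad_time))
  x <- res$x
  colnames(x) <- rownames(params$A)
  structure(list(x = x, dt = inputs$dt,
                 time = (seq_len(nrow(x)) - 1) * inputs$dt),
            class = "neural_trajectory")
}

#' Hemodynamic (balloon-Windkessel) observation model
#'
#' Transforms a neural trajectory into fine-grid BOLD percent signal change
#' per region. Resting input yields a constant 0 baseline.
#'
#' @param traj A `neural_trajectory`.
#' @param h A [hemodynamic_params()] object.
#' @param keep_states If TRUE also return the hemodynamic state trajectories
#'   (signal s, inflow f, volume v, deoxyhemoglobin q per region).
#' @return A `bold_fine` object: `y` (same grid as `traj`, percent signal
#'   change), `time`, `dt`, optionally `states`.
#' @export
balloon_transform <- function(traj, h = hemodynamic_params(),
                              keep_states = FALSE) {
  stopifnot(inherits(h, "hemodynamic_params"))
  res <- .balloon_rk4_cpp(traj$x, traj$dt, h$epsilon,
                          h$kappa, h$gamma, h$tau, h$alpha, h$E0, h$V0,
                          h$k1, h$k2, h$k3, keep_states)
  if (!res$ok)
    stop(sprintf("hemodynamic integration diverged at t = %.3f s", res$bad_time))
  y <- res$y
  colnames(y) <- colnames(traj$x)
  out <- list(y = y, time = traj$time, dt = traj$dt)
  if (keep_states) out$states <- res$states
  structure(out, class = "bold_fine")
}

#' Decimate fine-grid BOLD to the scanner TR grid and add noise
#'
#' Samples the fine-grid signal at volume times 0, TR, 2*TR, ... and adds
#' i.i.d. Gaussian observation noise.
#'
#' @param y_fine A `bold_fine` object (or plain matrix on a `dt` grid, in
#'   which case `dt` must be given).
#' @param TR Sampling interval (s); must be a multiple of the fine step.
#' @param noise_sd Noise standard deviation in percent-signal-change units.
#' @param seed Optional integer seed; sampling is then reproducible and does
#'   not disturb the caller's RNG stream.
#' @param dt Fine grid step, only needed when `y_fine` is a bare matrix.
#' @return A `bold_series`: `y` (volumes x regions), `TR`, `time`.
#' @export
sample_and_noise <- function(y_fine, TR = 2.1, noise_sd = 0, seed = NULL,
                             dt = NULL) {
  if (inherits(y_fine, "bold_fine")) {
    dt <- y_fine$dt
    ym <- y_fine$y
  } else ym <- as.matrix(y_fine)
  if (is.null(dt)) stop("dt required for bare-matrix input")
  step <- TR / dt
  if (abs(step - round(step)) > 1e-8)
    stop("TR must be an integer multiple of the fine integration step")
  n_keep <- floor((nrow(ym) - 1) * dt / TR + 1e-9)  # = floor(duration / TR)
  idx <- (seq_len(n_keep) - 1) * round(step) + 1
  y <- ym[idx, , drop = FALSE]
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(rnorm(length(y), 0, noise_sd),
                                    nrow(y), ncol(y)))
    y <- y + noise
  }
  bold_series(y, TR)
}

#' Construct a BOLD series object
#'
#' @param y Matrix, volumes x regions (percent signal change); column names
#'   are region labels.
#' @param TR Repetition time (s).
#' @return A `bold_series` object.
#' @export
bold_series <- function(y, TR) {
  y <- as.matrix(y)
  structure(list(y = y, TR = TR, time = (seq_len(nrow(y)) - 1) * TR),
            class = "bold_series")
}

#' Full forward simulation at scanner resolution
#'
#' Fused neural + hemodynamic integration sampled directly at the TR grid
#' (volume times 0, TR, ...). Numerically identical to
#' `integrate_neural() |> balloon_transform() |> sample_and_noise()` but
#' avoids materialising the fine grid; this is the path the model inversion
#' calls.
#'
#' @inheritParams integrate_neural
#' @param h Hemodynamic parameters.
#' @param TR Repetition time (s); must be a multiple of `inputs$dt`.
#' @param n_vols Number of volumes; default `floor(duration / TR)`.
#' @return A `bold_series` (noise-free).
#' @export
simulate_bold <- function(params, inputs, h = hemodynamic_params(),
                          TR = 2.1, n_vols = NULL) {
  step <- TR / inputs$dt
  if (abs(step - round(step)) > 1e-8)
    stop("TR must be an integer multiple of the integration step")
  if (is.null(n_vols)) n_vols <- floor(inputs$duration / TR + 1e-9)
  idx <- as.integer((seq_len(n_vols) - 1) * round(step) + 1)
  res <- .dcm_forward_cpp(params$A, as.numeric(params$B), params$C,
                          inputs$U, inputs$dt, hemo_vector(h), idx)
  if (!res$ok)
    stop(sprintf("forward simulation diverged at t = %.3f s", res$bad_time))
  y <- res$y
  colnames(y) <- rownames(params$A)
  bold_series(y, TR)
}

# Forward simulation with endogenous neural fluctuations: white state noise
# of SD `neural_sd` (activity units, per sqrt(s)) enters each region's
# dx/dt alongside the experimental inputs. Implemented by augmenting the
# input set with one unit-gain noise input per region, piecewise constant
# at the integration step (scaled 1/sqrt(dt) so the injected variance per
# unit time is neural_sd^2). Used by the cohort generator; the caller
# manages the RNG stream.
simulate_bold_state_noise <- function(params, inputs, h = hemodynamic_params(),
                                      TR = 2.1, n_vols = NULL,
                                      neural_sd = 0) {
  if (neural_sd <= 0) return(simulate_bold(params, inputs, h, TR, n_vols))
  step <- TR / inputs$dt
  if (abs(step - round(step)) > 1e-8)
    stop("TR must be an integer multiple of the integration step")
  if (is.null(n_vols)) n_vols <- floor(inputs$duration / TR + 1e-9)
  idx <- as.integer((seq_len(n_vols) - 1) * round(step) + 1)
  n <- nrow(params$A)
  nT <- nrow(inputs$U)
  W <- matrix(rnorm(nT * n, 0, neural_sd / sqrt(inputs$dt)), nT, n)
  U <- cbind(inputs$U, W)
  m <- ncol(inputs$U)
  B <- array(0, dim = c(n, n, m + n))
  B[, , seq_len(m)] <- params$B
  C <- cbind(params$C, diag(n))
  res <- .dcm_forward_cpp(params$A, as.numeric(B), C, U, inputs$dt,
                          hemo_vector(h), idx)
  if (!res$ok)
    stop(sprintf("forward simulation diverged at t = %.3f s", res$bad_time))
  y <- res$y
  colnames(y) <- rownames(params$A)
  bold_series(y, TR)
}

#' Write / read ROI BOLD series as tab-separated text
#'
#' Column `time_s` plus one column per region.
#'
#' @param bold A `bold_series`.
#' @param path File path.
#' @export
write_bold <- function(bold, path) {
  df <- data.frame(time_s = bold$time, bold$y, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  tt <- df$time_s
  y <- as.matrix(df[setdiff(names(df), "time_s")])
  TR <- if (length(tt) > 1) tt[2] - tt[1] else NA_real_
  bold_series(y, TR)
}

# evaluate expr under a temporary RNG state when seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
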