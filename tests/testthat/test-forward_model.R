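one_region_params <- function(a = -0.3) {
  # minimal hand-built parameter object for the integrator (bypasses the
  # 3-region constructor on purpose)
  structure(list(A = matrix(a, 1, 1, dimnames = list("x", "x")),
                 B = array(0, c(1, 1, 4)),
                 C = matrix(0, 1, 4), m = 4),
            class = "dcm_parameters")
}

flat_inputs <- function(duration, dt) {
  structure(list(U = matrix(0, round(duration / dt), 4,
                            dimnames = list(NULL, bistableDCM:::DCM_INPUTS)),
                 dt = dt, duration = duration),
            class = "input_timeline")
}

test_that("zero input from rest stays exactly at rest", {
  sim <- tiny_simulation()
  tl <- flat_inputs(20, 0.1)
  tr <- integrate_neural(sim$params, tl)
  expect_true(all(tr$x == 0))
  y <- balloon_transform(tr)
  expect_true(all(y$y == 0))
})

test_that("one-region decay matches the closed form to 1e-6 relative", {
  a <- -0.3; x0 <- 2
  tl <- flat_inputs(5, 1e-3)
  tr <- integrate_neural(one_region_params(a), tl, x0 = x0)
  exact <- x0 * exp(a * tr$time)
  expect_lt(max(abs(tr$x[, 1] - exact) / exact), 1e-6)
})

test_that("three-region integration agrees with a 10x finer grid and deSolve", {
  skip_if_not_installed("deSolve")
  sim <- tiny_simulation(dt = 0.1)
  tr <- integrate_neural(sim$params, sim$inputs)
  # 10x finer RK4 with the same piecewise-constant inputs
  U10 <- sim$inputs$U[rep(seq_len(nrow(sim$inputs$U)), each = 10), ]
  tl10 <- structure(list(U = U10, dt = 0.01, duration = sim$inputs$duration),
                    class = "input_timeline")
  tr10 <- integrate_neural(sim$params, tl10)
  x10 <- tr10$x[seq(1, nrow(tr10$x), by = 10), ]
  scale <- max(abs(x10))
  expect_lt(max(abs(tr$x - x10)) / scale, 1e-4)
  # independent oracle: deSolve::lsoda on the same right-hand side
  Umat <- sim$inputs$U
  rhs <- function(t, x, parms) {
    k <- min(nrow(Umat), floor(t / 0.1 + 1e-9) + 1)
    u <- Umat[k, ]
    Aeff <- sim$params$A
    for (j in 1:4) Aeff <- Aeff + u[j] * sim$params$B[, , j]
    list(drop(Aeff %*% x + sim$params$C %*% u))
  }
  ode <- deSolve::lsoda(c(0, 0, 0), times = tr$time, func = rhs,
                        rtol = 1e-9, atol = 1e-11, hmax = 0.1)
  expect_lt(max(abs(tr$x - ode[, 2:4])) / scale, 1e-4)
})

test_that("divergence is reported with the first bad time", {
  p <- one_region_params(a = +2)  # unstable growth
  tl <- flat_inputs(40, 0.1)
  expect_error(integrate_neural(p, tl, x0 = 1), "diverged at t")
})

test_that("neural dynamics are linear in the driving input when B = 0", {
  p <- one_region_params(-0.4)
  p$C[1, 2] <- 1
  tl <- flat_inputs(30, 0.1)
  tl$U[50:150, "stimulation"] <- 0.5
  tl2 <- tl; tl2$U <- tl$U * 2
  x1 <- integrate_neural(p, tl)$x
  x2 <- integrate_neural(p, tl2)$x
  expect_equal(2 * x1, x2, tolerance = 1e-12)
})

test_that("positive modulation accelerates the target given active source", {
  sim <- tiny_simulation()
  p0 <- sim$params
  p0$B[] <- 0
  tr_mod <- integrate_neural(sim$params, sim$inputs)
  tr_ref <- integrate_neural(p0, sim$inputs)
  # during rivalry-switch pulses the modulated system moves its targets more
  pulse_rows <- which(sim$inputs$U[, "rivalry_switch"] == 1)
  expect_gt(mean(abs(diff(tr_mod$x[pulse_rows, "rpSPL"]))),
            mean(abs(diff(tr_ref$x[pulse_rows, "rpSPL"]))))
})

test_that("stable defaults stay bounded over a full run", {
  sim <- tiny_simulation()
  tr <- integrate_neural(sim$params, sim$inputs)
  expect_true(all(abs(tr$x) < 10))
})

test_that("hemodynamic impulse response is single-peaked and transient", {
  p <- one_region_params(-0.5)
  p$C[1, 2] <- 1
  mk <- function(dt) {
    tl <- flat_inputs(40, dt)
    tl$U[round(1 / dt):(round(1.1 / dt) - 1), "stimulation"] <- 1  # 0.1 s kick
    balloon_transform(integrate_neural(p, tl))$y[, 1]
  }
  y <- mk(0.01)
  peak <- which.max(y)
  expect_gt(y[peak], 0)
  # single positive peak: rises monotonically from the event to the peak
  expect_true(all(diff(y[101:peak]) >= -1e-12))
  # returns to within 1% of baseline (relative to peak) by t = 32 s post-event
  t32 <- 101 + round(32 / 0.01)
  expect_lt(abs(y[t32]) / y[peak], 0.01)
  # fine-step oracle: halving the integration step changes nothing material
  y2 <- mk(0.005)
  expect_lt(max(abs(y2[seq(1, length(y2), by = 2)] - y)) / y[peak], 5e-3)
})

test_that("doubling V0 doubles the BOLD output pointwise", {
  sim <- tiny_simulation(dt = 0.1)
  tr <- integrate_neural(sim$params, sim$inputs)
  y1 <- balloon_transform(tr, hemodynamic_params())$y
  y2 <- balloon_transform(tr, hemodynamic_params(V0 = 0.08))$y
  expect_equal(y2, 2 * y1, tolerance = 1e-12)
})

test_that("hemodynamic parameter validation rejects out-of-range values", {
  expect_error(hemodynamic_params(alpha = 1.2), "alpha")
  expect_error(hemodynamic_params(E0 = 0), "E0")
  expect_error(hemodynamic_params(tau = -1), "positive")
})

test_that("decimation and noise behave as specified", {
  sim <- tiny_simulation(dt = 0.35)
  yf <- balloon_transform(integrate_neural(sim$params, sim$inputs))
  b0 <- sample_and_noise(yf, TR = 2.1, noise_sd = 0)
  expect_identical(nrow(b0$y), 45L)  # floor(duration / TR)
  idx <- seq(1, by = 6, length.out = nrow(b0$y))
  expect_identical(b0$y, yf$y[idx, ])          # exact decimation
  b1 <- sample_and_noise(yf, TR = 2.1, noise_sd = 0.5, seed = 42)
  b2 <- sample_and_noise(yf, TR = 2.1, noise_sd = 0.5, seed = 42)
  expect_identical(b1$y, b2$y)                 # determinism contract
  expect_error(sample_and_noise(yf, TR = 1.0), "multiple")
  # Monte-Carlo: realized noise SD within 5% of nominal over 1e4 samples
  big <- matrix(0, 10001, 1)
  bn <- sample_and_noise(big, TR = 0.1, noise_sd = 0.7, seed = 9, dt = 0.1)
  expect_lt(abs(sd(bn$y) - 0.7) / 0.7, 0.05)
})

test_that("fused forward path equals the modular neural/balloon/decimate path", {
  sim <- tiny_simulation(dt = 0.35)
  y_mod <- sample_and_noise(
    balloon_transform(integrate_neural(sim$params, sim$inputs)), TR = 2.1)
  y_fused <- simulate_bold(sim$params, sim$inputs, TR = 2.1)
  expect_equal(y_fused$y, y_mod$y, tolerance = 1e-12)
})

test_that("BOLD series round-trips through its text format", {
  sim <- tiny_simulation(dt = 0.35)
  b <- simulate_bold(sim$params, sim$inputs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bold(b, path)
  b2 <- read_bold(path)
  expect_equal(b2$y, b$y, tolerance = 1e-8)
  expect_equal(b2$TR, b$TR, tolerance = 1e-8)
})
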