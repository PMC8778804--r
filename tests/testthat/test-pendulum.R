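test_that("analytic block MoI matches closed forms and the voxel pipeline", {
  # cube: (m/6) s^2 about any principal axis
  for (ax in 1:3)
    expect_equal(analytic_block_moi(c(0.2, 0.2, 0.2), 3, ax), 3 / 6 * 0.04)
  expect_equal(analytic_block_moi(c(0.1, 0.2, 0.3), 1, 3),
               (0.01 + 0.04) / 12)

  # cross-module oracle: voxelized cuboid agrees within discretization error
  pr <- primitive_model("cuboid", c(50, 38, 26), h = 1)
  I <- diag(inertia_tensor(pr$model))
  mass <- pr$truth$total_mass
  for (ax in 1:3)
    expect_equal(I[ax], analytic_block_moi(c(0.050, 0.038, 0.026), mass, ax),
                 tolerance = 1e-2)
})

test_that("noiseless damped-oscillator traces are recovered to 1e-6", {
  w_d <- 2.0; zeta <- 0.01; X <- 0.03; phi <- 0.4
  t <- seq(0, 70, by = 1 / 70)
  tr <- oscillation_trace(t, damped_omega(t, X, phi, zeta, w_d))
  fit <- fit_damped_oscillator(tr, fit_window = 60)
  expect_equal(fit$omega_d, w_d, tolerance = 1e-6)
  expect_equal(fit$zeta, zeta, tolerance = 1e-6)
  expect_equal(fit$tau, 2 * pi / w_d, tolerance = 1e-6)
  # amplitude/phase are reported relative to the window start (t0 = 10 s)
  w_n <- w_d / sqrt(1 - zeta^2)
  expect_equal(fit$X, X * exp(-zeta * w_n * 10), tolerance = 1e-6)
  phase_diff <- (fit$phi - (phi + w_d * 10)) %% (2 * pi)
  expect_lt(min(phase_diff, 2 * pi - phase_diff), 1e-6)
  expect_lt(fit$residual_rms, 1e-10)

  # invariant: omega_d = omega_n sqrt(1 - zeta^2)
  expect_equal(fit$omega_d, fit$omega_n * sqrt(1 - fit$zeta^2),
               tolerance = 1e-12)
})

test_that("an undamped trace yields omega_n equal to omega_d", {
  t <- seq(0, 70, by = 1 / 70)
  tr <- oscillation_trace(t, damped_omega(t, 0.05, 0, 0, 1.7))
  fit <- fit_damped_oscillator(tr, fit_window = 60)
  expect_equal(fit$zeta, 0, tolerance = 1e-8)
  expect_equal(fit$omega_n, fit$omega_d, tolerance = 1e-8)
})

test_that("omega_d is recovered within 0.1% under 2% amplitude noise", {
  w_d <- 2.0; zeta <- 0.005; X <- 0.03
  t <- seq(0, 70, by = 1 / 70)
  clean <- damped_omega(t, X, 0.4, zeta, w_d)
  for (seed in 1:3) {
    set.seed(seed)
    tr <- oscillation_trace(t, clean + rnorm(length(t), 0, 0.02 * X * w_d))
    fit <- fit_damped_oscillator(tr, fit_window = 60)
    expect_equal(fit$omega_d, w_d, tolerance = 1e-3)
  }
})

test_that("period aggregation averages repeats and validates input", {
  t <- seq(0, 70, by = 1 / 70)
  f1 <- fit_damped_oscillator(
    oscillation_trace(t, damped_omega(t, 0.05, 0, 0.01, 2)), 60)
  est <- period_estimate(list(f1, f1, f1))
  expect_equal(as.numeric(est), f1$tau)
  expect_equal(attr(est, "sd"), 0)

  fits <- lapply(c(1.0, 1.1, 1.2), function(tau) {
    f <- f1; f$tau <- tau; f
  })
  expect_equal(as.numeric(period_estimate(fits)), 1.1)
  expect_error(period_estimate(list()), "insufficient")
})

test_that("trifilar formula scaling and domain checks hold", {
  base <- rig_moi(1, 9.81, 0.2, 1, 1)
  expect_equal(rig_moi(1, 9.81, 0.2, 2, 1), 4 * base)   # tau^2 scaling
  expect_error(rig_moi(-1, 9.81, 0.2, 1, 1), "positive")
  expect_error(rig_moi(1, 9.81, 0, 1, 1), "positive")
})

test_that("the ODE oracle round trip recovers a known MoI within 0.1%", {
  rig <- default_rig()
  I_true <- 0.02
  tr <- simulate_pendulum_trace(I_true, rig, zeta = 0.01,
                                amplitude = 2 * pi / 180, duration = 120)
  fit <- fit_damped_oscillator(tr, 60)
  I_est <- rig_moi(rig$m_p, rig$g, rig$R, fit$tau, rig$L)
  expect_equal(I_est, I_true, tolerance = 1e-3)

  # additivity: (rig + centered block) minus rig isolates the block MoI
  block_I <- analytic_block_moi(c(0.1, 0.2, 0.05), 0.35, 3)
  tr2 <- simulate_pendulum_trace(I_true + block_I, rig, zeta = 0.01,
                                 amplitude = 2 * pi / 180, duration = 120,
                                 m_total = rig$m_p + 0.35)
  fit2 <- fit_damped_oscillator(tr2, 60)
  I_both <- rig_moi(rig$m_p + 0.35, rig$g, rig$R, fit2$tau, rig$L)
  expect_equal(I_both - I_est, block_I, tolerance = 1e-3)
})

test_that("small-angle error grows with oscillation amplitude", {
  rig <- default_rig()
  I_true <- 0.02
  errs <- vapply(c(2, 25) * pi / 180, function(amp) {
    tr <- simulate_pendulum_trace(I_true, rig, zeta = 0.005, amplitude = amp,
                                  duration = 80)
    fit <- fit_damped_oscillator(tr, 60)
    abs(rig_moi(rig$m_p, rig$g, rig$R, fit$tau, rig$L) - I_true) / I_true
  }, 0)
  expect_lt(errs[1], 5e-3)
  expect_gt(errs[2], errs[1])
})

test_that("CoM-offset correction reduces to the plain difference at D = 0", {
  rig <- default_rig()
  m_b <- 0.35; tau <- 1.1
  uncorrected <- rig_moi(m_b + rig$m_p, rig$g, rig$R, tau, rig$L) - rig$I_p
  expect_identical(specimen_moi_corrected(m_b, tau_with = tau, rig = rig,
                                          D = 0), uncorrected)
  # correction magnitude grows monotonically with D at fixed tau
  Ds <- seq(0, 0.031, by = 0.005)
  est <- vapply(Ds, function(D)
    specimen_moi_corrected(m_b, tau_with = tau, rig = rig, D = D), 0)
  expect_true(all(diff(uncorrected - est) > 0))
  expect_error(specimen_moi_corrected(m_b, tau_with = tau, rig = rig, D = -1),
               "non-negative")
})

test_that("offset composites are corrected back to the block CoM MoI", {
  rig <- default_rig()
  m_b <- 0.35
  block_I <- analytic_block_moi(c(0.1, 0.2, 0.05), m_b, 3)
  D <- 0.031
  I_tot <- rig$I_p + block_I + m_b * D^2
  tr <- simulate_pendulum_trace(I_tot, rig, zeta = 0.01,
                                amplitude = 2 * pi / 180, duration = 120,
                                m_total = rig$m_p + m_b)
  tau <- fit_damped_oscillator(tr, 60)$tau
  corrected <- specimen_moi_corrected(m_b, tau_with = tau, rig = rig, D = D)
  uncorrected <- specimen_moi_corrected(m_b, tau_with = tau, rig = rig, D = 0)
  expect_equal(corrected, block_I, tolerance = 1e-2)
  # the uncorrected estimate is biased high by about m_b D^2
  expect_equal(uncorrected - block_I, m_b * D^2,
               tolerance = 0.02 * block_I / (m_b * D^2) + 0.02)
})

test_that("traces without an oscillatory component are rejected", {
  set.seed(13)
  t <- seq(0, 70, by = 1 / 70)
  expect_error(fit_damped_oscillator(
    oscillation_trace(t, rnorm(length(t), 0, 0.01)), 60),
    "no oscillation")
  tr <- oscillation_trace(t, damped_omega(t, 0.05, 0, 0.01, 2))
  expect_error(fit_damped_oscillator(tr, fit_window = 200), "shorter")
})

test_that("gyroscope CSV logs are read across header variants", {
  dir <- withr::local_tempdir()
  t <- seq(0, 1, by = 0.1); w <- sin(t)
  p1 <- file.path(dir, "a.csv")
  utils::write.csv(data.frame(time_s = t, omega_rad_s = w), p1,
                   row.names = FALSE)
  tr1 <- read_trace_csv(p1)
  expect_equal(tr1$omega, w)
  expect_equal(tr1$rate, 10, tolerance = 1e-9)

  p2 <- file.path(dir, "b.csv")
  utils::write.csv(data.frame(Time = t, gyro_z = w), p2, row.names = FALSE)
  expect_equal(read_trace_csv(p2)$omega, w)

  p3 <- file.path(dir, "c.csv")
  utils::write.csv(data.frame(foo = t, bar = w), p3, row.names = FALSE)
  expect_error(read_trace_csv(p3), "could not identify")
})
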