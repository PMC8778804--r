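# Shared fixtures, memoized so the heavy synthetic volumes are rasterized
# once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# default bird-like scene (noisy) plus its rasterization
bird_scene <- function(seed = 11L) {
  fixture(paste0("bird_", seed), function() {
    spec <- make_bird_like_scene(seed = seed)
    c(list(spec = spec), rasterize_scene(spec))
  })
}

# noiseless bird-like scene for exact-bookkeeping checks
bird_scene_noiseless <- function() {
  fixture("bird0", function() {
    spec <- make_bird_like_scene(noise_sigma = 0)
    c(list(spec = spec), rasterize_scene(spec))
  })
}

# an exact calibration for a known grey -> density line (two samples on it)
line_cal <- function(slope = 1, intercept = 0) {
  fit_calibration(list(
    phantom_sample("lo", 0, (0 - intercept) / slope, 1),
    phantom_sample("hi", 1000, (1000 - intercept) / slope, 1)))
}

# mass model of one rasterized primitive at given voxel pitch (mm), noiseless
primitive_model <- function(primitive, dims, h, offset = c(0.37, 0.71, 0.13),
                            rotation = NULL, extent = 64) {
  spec <- scene_spec(
    list(scene_shape(primitive, center = rep(extent / 2, 3) + offset,
                     dims = dims, density = 1000, rotation = rotation)),
    spacing = rep(h, 3), volume_shape = rep(round(extent / h), 3),
    noise_sigma = 0)
  sc <- rasterize_scene(spec)
  list(model = build_mass_model(apply_calibration(sc$grid, line_cal()),
                                sc$labels$labels > 0),
       truth = sc$truth)
}

# small rotation matrices
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

# uniformly random proper rotation
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

default_rig <- function() pendulum_rig(m_p = 1.2, R = 0.3, L = 1.2, I_p = 0.02)

# closed-form damped-oscillator angular velocity
damped_omega <- function(t, X, phi, zeta, w_d) {
  w_n <- w_d / sqrt(1 - zeta^2)
  X * exp(-zeta * w_n * t) *
    (w_d * cos(w_d * t + phi) - zeta * w_n * sin(w_d * t + phi))
}
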