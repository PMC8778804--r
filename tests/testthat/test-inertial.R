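test_that("mass models convert density and geometry to SI point masses", {
  g1 <- voxel_grid(array(1000, c(1, 1, 1)), c(1, 1, 1))
  m1 <- build_mass_model(g1, array(TRUE, c(1, 1, 1)))
  expect_equal(m1$total_mass, 1e-6)                 # 1 mm^3 at 1000 kg m^-3

  g2 <- voxel_grid(array(1000, c(10, 10, 10)), c(1, 1, 1))
  m2 <- build_mass_model(g2, array(TRUE, c(10, 10, 10)))
  expect_equal(m2$total_mass, 1e-3, tolerance = 1e-14)

  expect_error(build_mass_model(g2, array(FALSE, c(10, 10, 10))), "empty")
})

test_that("centre of mass follows the lever rule and symmetry", {
  m <- mass_model(c(1, 3), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(centre_of_mass(m), c(0.75, 0, 0))

  g <- voxel_grid(array(500, c(6, 8, 10)), c(1, 1, 1), origin = c(5, -3, 2))
  mm <- build_mass_model(g, array(TRUE, c(6, 8, 10)))
  expect_equal(centre_of_mass(mm) * 1e3, c(5 + 3, -3 + 4, 2 + 5),
               tolerance = 1e-12)

  expect_error(centre_of_mass(mass_model(0, c(0, 0, 0))), "degenerate")
})

test_that("the inertia tensor matches point-mass and cuboid closed forms", {
  # single point mass m at distance d along x
  m <- 2.5; d <- 0.3
  pm <- mass_model(m, c(d, 0, 0))
  I <- inertia_tensor(pm, origin = c(0, 0, 0))
  expect_equal(I, diag(c(0, m * d^2, m * d^2)), tolerance = 1e-15)

  # voxelized uniform cuboid about its CoM vs (m/12)(b^2+c^2, ...)
  pr <- primitive_model("cuboid", c(50, 38, 26), h = 1)
  I_vox <- inertia_tensor(pr$model)
  mass <- pr$truth$total_mass
  I_true <- mass / 12 * diag(c(0.038^2 + 0.026^2,
                               0.050^2 + 0.026^2,
                               0.050^2 + 0.038^2))
  expect_equal(diag(I_vox), diag(I_true), tolerance = 1e-2)
  expect_lt(max(abs(I_vox - t(I_vox))), 1e-25)
})

test_that("parallel-axis translation is exact and invertible", {
  set.seed(7)
  model <- mass_model(runif(200, 0.01, 1), matrix(rnorm(600, 0, 0.2), 200, 3))
  com <- centre_of_mass(model)
  I_com <- inertia_tensor(model, com)
  for (rep in 1:25) {
    dvec <- rnorm(3, 0, 0.5)
    direct <- inertia_tensor(model, com + dvec)
    translated <- translate_tensor(I_com, model$total_mass, dvec)
    expect_equal(translated, direct, tolerance = 1e-12)
    # scalar classic form along an axis perpendicular to d
    perp <- c(-dvec[2], dvec[1], 0); perp <- perp / sqrt(sum(perp^2))
    expect_equal(as.numeric(t(perp) %*% translated %*% perp),
                 as.numeric(t(perp) %*% I_com %*% perp) +
                   model$total_mass * sum(dvec^2) *
                   (1 - sum(perp * dvec / sqrt(sum(dvec^2)))^2),
                 tolerance = 1e-12)
  }
  # d = 0 leaves the tensor unchanged; round trip returns the original
  expect_identical(translate_tensor(I_com, model$total_mass, c(0, 0, 0)), I_com)
  shifted <- translate_tensor(I_com, model$total_mass, c(0.1, -0.2, 0.05))
  back <- shifted - model$total_mass *
    (sum(c(0.1, -0.2, 0.05)^2) * diag(3) - tcrossprod(c(0.1, -0.2, 0.05)))
  expect_equal(back, I_com, tolerance = 1e-12)
})

test_that("principal decomposition respects ordering and handedness", {
  pd <- principal_decomposition(diag(c(1, 2, 3)))
  expect_equal(pd$principal_moments, c(1, 2, 3))
  expect_equal(pd$principal_axes, diag(3))

  set.seed(8)
  for (rep in 1:20) {
    rot <- random_rotation()
    tensor <- rot %*% diag(c(1, 2, 3)) %*% t(rot)
    pd <- principal_decomposition(tensor)
    expect_equal(pd$principal_moments, c(1, 2, 3), tolerance = 1e-10)
    # axes equal the applied rotation columns up to sign
    for (k in 1:3)
      expect_equal(abs(sum(pd$principal_axes[, k] * rot[, k])), 1,
                   tolerance = 1e-10)
    expect_equal(det(pd$principal_axes), 1, tolerance = 1e-10)
    expect_equal(crossprod(pd$principal_axes), diag(3), tolerance = 1e-10)
  }

  # degenerate: only the moments are contractual
  pdg <- principal_decomposition(diag(c(2, 2, 5)))
  expect_equal(pdg$principal_moments, c(2, 2, 5))

  bad <- diag(3); bad[1, 2] <- 0.1
  expect_error(principal_decomposition(bad), "symmetric")
})

test_that("principal moments are invariant under rigid rotation", {
  set.seed(9)
  model <- mass_model(runif(300, 0.01, 1), matrix(rnorm(900, 0, 0.3), 300, 3))
  ref <- principal_decomposition(inertia_tensor(model))$principal_moments
  for (rep in 1:10) {
    rot <- random_rotation()
    rotated <- mass_model(model$masses, model$coords %*% t(rot))
    pm <- principal_decomposition(inertia_tensor(rotated))$principal_moments
    expect_equal(pm, ref, tolerance = 1e-8)
  }
})

test_that("MoI about an axis equals the tensor contraction and closed forms", {
  m <- mass_model(c(1, 2), rbind(c(0, 0.3, 0), c(0, -0.15, 0.2)))
  ax <- axis_spec(c(0, 0, 0), c(1, 0, 0))
  expect_equal(moi_about_axis(m, ax),
               1 * 0.3^2 + 2 * (0.15^2 + 0.2^2), tolerance = 1e-14)

  set.seed(10)
  model <- mass_model(runif(200, 0.01, 1), matrix(rnorm(600, 0, 0.2), 200, 3))
  com <- centre_of_mass(model)
  I_com <- inertia_tensor(model, com)
  for (rep in 1:10) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    expect_equal(moi_about_axis(model, axis_spec(com, n)),
                 as.numeric(t(n) %*% I_com %*% n), tolerance = 1e-12)
  }

  # voxelized cylinder about its longitudinal axis -> m r^2 / 2
  pr <- primitive_model("cylinder", c(20, 50), h = 1)
  mass <- pr$truth$total_mass
  axis <- axis_spec(pr$truth$com, c(0, 0, 1))
  expect_equal(moi_about_axis(pr$model, axis), mass * 0.020^2 / 2,
               tolerance = 5e-3)
})

test_that("the CoM tensor trace identity holds exactly", {
  set.seed(11)
  model <- mass_model(runif(100, 0.01, 1), matrix(rnorm(300, 0, 0.2), 100, 3))
  com <- centre_of_mass(model)
  I_com <- inertia_tensor(model, com)
  r2 <- rowSums(sweep(model$coords, 2, com)^2)
  expect_equal(sum(diag(I_com)), 2 * sum(model$masses * r2),
               tolerance = 1e-13)
  # physical tensors are PSD and satisfy the triangle inequality
  pm <- principal_decomposition(I_com)$principal_moments
  expect_true(all(pm >= 0))
  expect_gte(pm[1] + pm[2], pm[3] * (1 - 1e-12))
})

test_that("board-plane fitting recovers normals from exact and noisy points", {
  # exact horizontal plane z = 5, oriented toward a CoM above it
  pts <- cbind(runif(20, 0, 0.1), runif(20, 0, 0.1), 5e-3)
  fit <- fit_board_plane(pts, com_hint = c(0.05, 0.05, 0.05))
  expect_equal(abs(fit$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_gt(fit$normal[3], 0)
  expect_lt(fit$rms, 1e-15)

  # three points define an exact interpolating plane
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1))
  f3 <- fit_board_plane(tri)
  expect_lt(max(abs(tri %*% f3$normal - sum(f3$point * f3$normal))), 1e-12)

  # Gaussian noise sigma = 0.1 mm over a 100 mm board: normal within 0.2 deg
  set.seed(12)
  base <- cbind(runif(400, 0, 0.1), runif(400, 0, 0.1), 0)
  noisy <- base; noisy[, 3] <- rnorm(400, 0, 1e-4)
  fn <- fit_board_plane(noisy, com_hint = c(0, 0, 1))
  angle <- acos(min(1, abs(fn$normal[3]))) * 180 / pi
  expect_lt(angle, 0.2)

  expect_error(fit_board_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))), "collinear")
})

test_that("uniform-density models preserve mass and bias MoI as expected", {
  # truly uniform object: uniform assumption reproduces the calibrated result
  g <- voxel_grid(array(800, c(8, 8, 8)), c(1, 1, 1))
  mask <- array(TRUE, c(8, 8, 8))
  cal_model <- build_mass_model(g, mask)
  uni <- uniform_density_comparison(mask, cal_model$total_mass, g)
  expect_equal(uni$mass, cal_model$total_mass)
  cal_props <- inertial_properties(cal_model)
  expect_equal(uni$tensor, cal_props$tensor, tolerance = 1e-10)

  # dense core, light periphery: uniform density pushes mass outward and
  # overestimates MoI about the central axis; total mass preserved exactly
  vals <- array(100, c(16, 16, 16)); vals[5:12, 5:12, 5:12] <- 2000
  g2 <- voxel_grid(vals, c(1, 1, 1))
  mask2 <- array(TRUE, c(16, 16, 16))
  cal2 <- build_mass_model(g2, mask2)
  uni2 <- uniform_density_comparison(mask2, cal2$total_mass, g2)
  expect_identical(uni2$mass, cal2$total_mass)
  axis <- axis_spec(centre_of_mass(cal2), c(0, 0, 1))
  expect_gt(moi_about_axis(attr(uni2, "model"), axis),
            moi_about_axis(cal2, axis))
})
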