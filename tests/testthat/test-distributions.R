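test_that("projection maps conserve their parent totals", {
  # single element lands in a single cell with its full mass
  m1 <- mass_model(0.5, c(0.01, 0.02, 0.03))
  p1 <- project_quantity(m1, 3, cell_size = 0.005, "mass")
  expect_equal(sum(p1$grid > 0), 1L)
  expect_equal(sum(p1$grid), 0.5)

  set.seed(14)
  model <- mass_model(runif(500, 1e-4, 1e-2),
                      matrix(runif(1500, 0, 0.3), 500, 3))
  for (ax in 1:3) {
    pm <- project_quantity(model, ax, 0.01, "mass")
    expect_equal(sum(pm$grid), model$total_mass, tolerance = 1e-10)
  }
  ref <- axis_spec(centre_of_mass(model), c(0, 0, 1))
  pmoi <- project_quantity(model, 3, 0.01, "moi", reference_axis = ref)
  expect_equal(sum(pmoi$grid), moi_about_axis(model, ref), tolerance = 1e-10)
  expect_error(project_quantity(model, 3, 0.01, "moi"), "reference_axis")

  # refining the cell size changes resolution, never totals
  fine <- project_quantity(model, 3, 0.002, "mass")
  expect_equal(sum(fine$grid), model$total_mass, tolerance = 1e-10)
  expect_gt(length(fine$grid), length(pm$grid))
})

test_that("distal mass concentrations show up stronger in MoI than mass maps", {
  # dumbbell: a heavy proximal cluster and a light distal cluster
  model <- mass_model(c(0.8, 0.2),
                      rbind(c(0, 0.02, 0), c(0, 0.40, 0)))
  ref <- axis_spec(c(0, 0, 0), c(1, 0, 0))
  mass_map <- project_quantity(model, 3, 0.01, "mass")
  moi_map <- project_quantity(model, 3, 0.01, "moi", reference_axis = ref)
  # distal cluster: small mass share, dominant MoI share
  distal_mass_share <- 0.2 / 1.0
  distal_moi_share <- (0.2 * 0.40^2) / (0.8 * 0.02^2 + 0.2 * 0.40^2)
  expect_gt(distal_moi_share, distal_mass_share)
  expect_equal(max(moi_map$grid) / sum(moi_map$grid), distal_moi_share,
               tolerance = 1e-12)
})

test_that("segment fraction columns sum to one and rank wings correctly", {
  sc <- bird_scene_noiseless()
  cal <- line_cal(sc$spec$calibration_truth$slope,
                  sc$spec$calibration_truth$intercept)
  model <- build_mass_model(apply_calibration(sc$grid, cal),
                            sc$labels$labels > 0)
  com <- centre_of_mass(model)
  axes <- list(roll = axis_spec(com, c(1, 0, 0)),
               pitch = axis_spec(com, c(0, 1, 0)),
               yaw = axis_spec(com, c(0, 0, 1)))
  tab <- segment_fraction_table(model, sc$labels, axes)
  for (col in c("mass_fraction", "I_roll_fraction", "I_pitch_fraction",
                "I_yaw_fraction"))
    expect_equal(sum(tab[[col]]), 1, tolerance = 1e-12)

  wings <- tab$segment %in% c("wing_left", "wing_right")
  expect_gt(sum(tab$I_roll_fraction[wings]), sum(tab$mass_fraction[wings]))

  # fractions are invariant under uniform rescaling of all masses
  scaled <- model; scaled$masses <- model$masses * 3.7
  scaled$total_mass <- model$total_mass * 3.7
  tab2 <- segment_fraction_table(scaled, sc$labels, axes)
  expect_equal(tab2$mass_fraction, tab$mass_fraction, tolerance = 1e-12)
  expect_equal(tab2$I_roll_fraction, tab$I_roll_fraction, tolerance = 1e-12)

  # a single exhaustive segment gets fraction 1 everywhere
  lab1 <- label_volume(array(1L, model$grid_dim), c("1" = "all"))
  tab1 <- segment_fraction_table(model, lab1, axes)
  expect_equal(unlist(tab1[1, c("mass_fraction", "I_roll_fraction",
                                "I_pitch_fraction", "I_yaw_fraction")]),
               c(mass_fraction = 1, I_roll_fraction = 1,
                 I_pitch_fraction = 1, I_yaw_fraction = 1))
})

test_that("spanwise profiles conserve, mirror and resolve density gaps", {
  sc <- bird_scene_noiseless()
  cal <- line_cal(sc$spec$calibration_truth$slope,
                  sc$spec$calibration_truth$intercept)
  model <- build_mass_model(apply_calibration(sc$grid, cal),
                            sc$labels$labels > 0)
  com <- centre_of_mass(model)
  span <- axis_spec(com, c(0, 1, 0)); roll <- axis_spec(com, c(1, 0, 0))
  prof <- spanwise_profile(model, span, roll, n_bins = 40)
  total <- prof$profile[prof$profile$group == "total", "value"]
  expect_equal(sum(total), moi_about_axis(model, roll), tolerance = 1e-10)

  # mirror-symmetric scene: profile symmetric about 0 within one bin
  expect_equal(total, rev(total), tolerance = 0.08)

  # refining bins never changes the total
  prof2 <- spanwise_profile(model, span, roll, n_bins = 13)
  expect_equal(sum(prof2$profile$value), sum(total), tolerance = 1e-10)

  # grouped curves sum to the total curve
  lab <- as.integer(sc$labels$labels)[model$index]
  grp <- ifelse(lab %in% c(3L, 4L), "wings", "body")
  pg <- spanwise_profile(model, span, roll, n_bins = 40, group_labels = grp)
  by_bin <- tapply(pg$profile$value[pg$profile$group != "total"],
                   pg$profile$bin_center[pg$profile$group != "total"], sum)
  expect_equal(as.numeric(by_bin), total, tolerance = 1e-10)
})

test_that("a low-density gap between dense strips yields a double bell", {
  # wing analogue: dense strips flank a light gap near +/-0.5 span
  shapes <- list(
    scene_shape("cuboid", c(32, 32, 32), c(20, 60, 6), 1000, 1L),   # body
    scene_shape("cuboid", c(32, 10, 32), c(20, 8, 6), 1200, 2L),    # outer strip
    scene_shape("cuboid", c(32, 18, 32), c(20, 8, 6), 150, 3L),     # gap
    scene_shape("cuboid", c(32, 26, 32), c(20, 8, 6), 1200, 4L),    # inner strip
    scene_shape("cuboid", c(32, 54, 32), c(20, 8, 6), 1200, 5L),
    scene_shape("cuboid", c(32, 46, 32), c(20, 8, 6), 150, 6L),
    scene_shape("cuboid", c(32, 38, 32), c(20, 8, 6), 1200, 7L))
  spec <- scene_spec(shapes, spacing = c(1, 1, 1),
                     volume_shape = c(64, 64, 64), noise_sigma = 0)
  sc <- rasterize_scene(spec)
  model <- build_mass_model(apply_calibration(sc$grid, line_cal()),
                            sc$labels$labels > 0)
  com <- centre_of_mass(model)
  prof <- spanwise_profile(model, axis_spec(com, c(0, 1, 0)),
                           axis_spec(com, c(1, 0, 0)), n_bins = 16)
  v <- prof$profile$value
  ctr <- prof$profile$bin_center
  # on the positive half: local minimum at the gap flanked by two maxima
  # (strips at ~0.2-0.33 and 0.6-0.87 of semispan, gap between)
  gap_bin <- which.min(abs(ctr - 0.44))
  inner <- which.min(abs(ctr - 0.31)); outer <- which.min(abs(ctr - 0.81))
  expect_lt(v[gap_bin], v[inner])
  expect_lt(v[gap_bin], v[outer])

  # a flat object on the centreline has no usable semispan
  flat <- mass_model(rep(1, 4), cbind(runif(4), 0, runif(4)))
  expect_error(spanwise_profile(flat, axis_spec(c(0, 0, 0), c(0, 1, 0)),
                                axis_spec(c(0, 0, 0), c(1, 0, 0))),
               "degenerate")
})
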