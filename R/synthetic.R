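#' Scene primitives for synthetic CT volumes
#'
#' A scene is a list of density-defined solids rasterized into a voxel grid
#' by center sampling.  Dimensions and centers are in mm (scene/world
#' units); densities in kg m^-3.  `rotation` is a 3x3 rotation matrix from
#' body to world axes (identity if omitted).
#'
#' Primitives and their `dims`:
#' * `cuboid` / `plate`: full edge lengths (a, b, c);
#' * `sphere`: radius;
#' * `cylinder`: (radius, height), axis along body axis 3;
#' * `ellipsoid`: semi-axes (a, b, c).
#'
#' @param primitive one of `"cuboid"`, `"plate"`, `"sphere"`, `"cylinder"`,
#'   `"ellipsoid"`.
#' @param center length-3, mm.
#' @param dims primitive dimensions, mm (see above), all > 0.
#' @param density kg m^-3, >= 0.
#' @param label integer segment label (> 0).
#' @param rotation optional 3x3 rotation matrix.
#' @return a `scene_shape`.
#' @export
scene_shape <- function(primitive = c("cuboid", "plate", "sphere",
                                      "cylinder", "ellipsoid"),
                        center, dims, density, label = 1L, rotation = NULL) {
  primitive <- match.arg(primitive)
  if (primitive == "plate") primitive <- "cuboid"
  dims <- as.numeric(dims)
  needed <- switch(primitive, cuboid = 3L, sphere = 1L, cylinder = 2L,
                   ellipsoid = 3L)
  stopifnot(length(center) == 3L, length(dims) == needed, all(dims > 0),
            density >= 0, label > 0)
  if (is.null(rotation)) rotation <- diag(3)
  stopifnot(max(abs(crossprod(rotation) - diag(3))) < 1e-9)
  structure(list(primitive = primitive, center = as.numeric(center),
                 dims = dims, density = as.numeric(density),
                 label = as.integer(label), rotation = rotation),
            class = "scene_shape")
}

# rotation taking body axis 3 onto world axis `axis` (for cylinders)
rot_cyl_axis <- function(axis) {
  switch(axis,
         cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
         cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)),
         diag(3))
}

shape_volume_mm3 <- function(sh) {
  switch(sh$primitive,
         cuboid = prod(sh$dims),
         sphere = 4 / 3 * pi * sh$dims[1L]^3,
         cylinder = pi * sh$dims[1L]^2 * sh$dims[2L],
         ellipsoid = 4 / 3 * pi * prod(sh$dims))
}

# body-frame CoM inertia tensor (SI) for unit handling: dims mm -> m
shape_body_tensor <- function(sh, mass) {
  d <- sh$dims * 1e-3
  switch(sh$primitive,
         cuboid = mass / 12 * diag(c(d[2L]^2 + d[3L]^2,
                                     d[1L]^2 + d[3L]^2,
                                     d[1L]^2 + d[2L]^2)),
         sphere = 2 / 5 * mass * d[1L]^2 * diag(3),
         cylinder = {
           r <- d[1L]; h <- d[2L]
           diag(c(mass * (3 * r^2 + h^2) / 12,
                  mass * (3 * r^2 + h^2) / 12,
                  mass * r^2 / 2))
         },
         ellipsoid = mass / 5 * diag(c(d[2L]^2 + d[3L]^2,
                                       d[1L]^2 + d[3L]^2,
                                       d[1L]^2 + d[2L]^2)))
}

# axis-aligned bounding half-extents in world frame, mm
shape_half_extent <- function(sh) {
  body_half <- switch(sh$primitive,
                      cuboid = sh$dims / 2,
                      sphere = rep(sh$dims[1L], 3),
                      cylinder = c(sh$dims[1L], sh$dims[1L], sh$dims[2L] / 2),
                      ellipsoid = sh$dims)
  as.numeric(abs(sh$rotation) %*% body_half)
}

# logical containment of world points (n x 3 mm) in a shape (center sampling)
shape_contains <- function(sh, pts) {
  rel <- sweep(pts, 2, sh$center)
  body <- rel %*% sh$rotation  # = t(R) applied row-wise
  switch(sh$primitive,
         cuboid = abs(body[, 1L]) <= sh$dims[1L] / 2 &
                  abs(body[, 2L]) <= sh$dims[2L] / 2 &
                  abs(body[, 3L]) <= sh$dims[3L] / 2,
         sphere = rowSums(body^2) <= sh$dims[1L]^2,
         cylinder = abs(body[, 3L]) <= sh$dims[2L] / 2 &
                    body[, 1L]^2 + body[, 2L]^2 <= sh$dims[1L]^2,
         ellipsoid = (body[, 1L] / sh$dims[1L])^2 +
                     (body[, 2L] / sh$dims[2L])^2 +
                     (body[, 3L] / sh$dims[3L])^2 <= 1)
}

#' Synthetic scene specification
#'
#' @param shapes list of [scene_shape()]s; later-listed shapes win overlaps.
#' @param calibration_truth named list/vector `slope`, `intercept`: the true
#'   grey -> density line (`rho = slope * grey + intercept`); the rasterizer
#'   inverts it to produce grey-values.
#' @param noise_sigma additive Gaussian grey noise, grey units.
#' @param spacing voxel spacing, mm (length 3).
#' @param volume_shape voxel counts (length 3).
#' @param seed RNG seed making the rasterization deterministic.
#' @param segment_names named map label -> name (defaults to
#'   `segment_<label>`).
#' @param air_density background density, kg m^-3 (default 1.2).
#' @return a `scene_spec`.
#' @export
scene_spec <- function(shapes, calibration_truth = c(slope = 1, intercept = 0),
                       noise_sigma = 0, spacing = c(1.25, 0.98, 0.98),
                       volume_shape = c(64, 64, 64), seed = 1L,
                       segment_names = NULL, air_density = 1.2) {
  ct <- as.list(calibration_truth)
  stopifnot(length(spacing) == 3L, all(spacing > 0),
            length(volume_shape) == 3L, all(volume_shape >= 1),
            ct$slope > 0, noise_sigma >= 0)
  if (is.null(segment_names)) {
    labs <- unique(vapply(shapes, `[[`, 0L, "label"))
    segment_names <- stats::setNames(paste0("segment_", labs), labs)
  }
  structure(list(shapes = shapes,
                 calibration_truth = ct,
                 noise_sigma = noise_sigma, spacing = as.numeric(spacing),
                 volume_shape = as.integer(volume_shape),
                 seed = as.integer(seed), segment_names = segment_names,
                 air_density = air_density),
            class = "scene_spec")
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Analytic ground truth of a scene
#'
#' Closed-form masses, centres of mass and CoM inertia tensors per shape,
#' composed per label and for the whole scene by rotation and the
#' parallel-axis theorem — computed from the primitives, never from voxels.
#' Assumes shapes do not overlap (overlap resolution is a rasterization
#' rule; analytic truth for overlapping solids is not attempted).
#'
#' @param spec a [scene_spec()].
#' @return list: `total_mass` (kg), `com` (m), `tensor_about_com` (kg m^2),
#'   `principal_moments`, `per_label` (data.frame of label, name, mass) and
#'   `label_tensors` (list of per-label CoM tensors), all SI.
#' @export
scene_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!length(spec$shapes))
    return(list(total_mass = 0, com = c(NA, NA, NA),
                tensor_about_com = matrix(0, 3, 3),
                principal_moments = c(0, 0, 0),
                per_label = data.frame(), label_tensors = list()))
  masses <- vapply(spec$shapes, function(sh)
    sh$density * shape_volume_mm3(sh) * 1e-9, 0)
  coms <- t(vapply(spec$shapes, function(sh) sh$center * 1e-3, numeric(3)))
  tensors <- lapply(seq_along(spec$shapes), function(i) {
    sh <- spec$shapes[[i]]
    sh$rotation %*% shape_body_tensor(sh, masses[i]) %*% t(sh$rotation)
  })
  total <- sum(masses)
  com <- colSums(coms * masses) / total
  about <- function(idx, origin) {
    out <- matrix(0, 3, 3)
    for (i in idx)
      out <- out + translate_tensor(tensors[[i]], masses[i], origin - coms[i, ])
    out
  }
  tensor_com <- about(seq_along(spec$shapes), com)

  labs <- vapply(spec$shapes, `[[`, 0L, "label")
  ids <- sort(unique(labs))
  lab_mass <- vapply(ids, function(l) sum(masses[labs == l]), 0)
  lab_com <- t(vapply(ids, function(l) {
    i <- labs == l
    colSums(coms[i, , drop = FALSE] * masses[i]) / sum(masses[i])
  }, numeric(3)))
  label_tensors <- lapply(seq_along(ids), function(k)
    about(which(labs == ids[k]), lab_com[k, ]))
  names(label_tensors) <- unname(spec$segment_names[as.character(ids)])
  list(total_mass = total, com = com, tensor_about_com = tensor_com,
       principal_moments = principal_decomposition(tensor_com)$principal_moments,
       per_label = data.frame(
         label = ids,
         segment = unname(spec$segment_names[as.character(ids)]),
         mass_kg = lab_mass,
         com_x = lab_com[, 1L], com_y = lab_com[, 2L], com_z = lab_com[, 3L],
         stringsAsFactors = FALSE),
       label_tensors = label_tensors)
}

#' Rasterize a scene into a CT-like volume
#'
#' Center sampling: each voxel takes the density of the shape containing its
#' center (later-listed shapes win overlaps; air elsewhere), converted to a
#' grey-value by inverting the true calibration line, with seeded additive
#' Gaussian noise.  Partial-volume effects are deliberately not modelled.
#'
#' @param spec a [scene_spec()].
#' @param origin world position of the volume corner, mm.
#' @return list: `grid` (noisy grey [voxel_grid()]), `labels`
#'   ([label_volume()]), `truth` ([scene_ground_truth()] result), and
#'   `voxelised` (center-sampled bookkeeping: total and per-label mass of
#'   the labelled voxels from the noiseless densities — the discretized
#'   truth the calibrated pipeline can match exactly).
#' @export
rasterize_scene <- function(spec, origin = c(0, 0, 0)) {
  stopifnot(inherits(spec, "scene_spec"))
  d <- spec$volume_shape
  lo <- origin; hi <- origin + d * spec$spacing
  for (sh in spec$shapes) {
    he <- shape_half_extent(sh)
    if (any(sh$center - he < lo - 1e-9) || any(sh$center + he > hi + 1e-9))
      stop("shape with label ", sh$label, " extends outside the volume",
           call. = FALSE)
  }
  template <- voxel_grid(array(0, dim = d), spacing = spec$spacing,
                         origin = origin)
  n <- prod(d)
  pts <- linear_index_world(template, seq_len(n))
  density <- rep(spec$air_density, n)
  labels <- integer(n)
  for (sh in spec$shapes) {
    inside <- shape_contains(sh, pts)
    density[inside] <- sh$density
    labels[inside] <- sh$label
  }
  grey_true <- (density - spec$calibration_truth$intercept) /
    spec$calibration_truth$slope
  grey <- if (spec$noise_sigma > 0)
    with_preserved_seed(spec$seed,
                        grey_true + stats::rnorm(n, 0, spec$noise_sigma))
  else grey_true

  vox_vol <- prod(spec$spacing) * 1e-9
  ids <- sort(unique(labels[labels != 0L]))
  per_label <- vapply(ids, function(l)
    compensated_sum(density[labels == l]) * vox_vol, 0)
  voxelised <- list(
    total_mass = compensated_sum(density[labels != 0L]) * vox_vol,
    per_label = stats::setNames(per_label,
                                unname(spec$segment_names[as.character(ids)])))

  list(grid = voxel_grid(array(grey, dim = d), spacing = spec$spacing,
                         origin = origin),
       labels = label_volume(array(labels, dim = d), spec$segment_names),
       truth = scene_ground_truth(spec),
       voxelised = voxelised)
}

#' Phantom rod layout for calibration tests
#'
#' Parallel cylindrical rods running the full depth of the volume along
#' axis 1, laid out on a ring in the in-plane axes, with matching ellipse
#' ROIs (well inside each rod) at the 25/50/75% planes, ready for
#' [sample_phantom()].
#'
#' @param densities rod densities, kg m^-3 (>= 2; the laboratory set spans
#'   450-1820).
#' @param spacing voxel spacing mm, `volume_shape` voxel counts.
#' @param volume_shape length-3 voxel counts.
#' @param rod_radius mm.
#' @param calibration_truth,noise_sigma,seed passed to [scene_spec()].
#' @return a [scene_spec()] with an extra element `rois`: per-rod list of
#'   three [roi_ellipse()]s, named by rod.
#' @export
make_phantom_rods <- function(densities,
                              spacing = c(1.25, 0.98, 0.98),
                              volume_shape = c(16, 128, 128),
                              rod_radius = 8,
                              calibration_truth = c(slope = 1, intercept = 0),
                              noise_sigma = 0, seed = 1L) {
  stopifnot(length(densities) >= 2L)
  k <- length(densities)
  extent <- spacing[2:3] * volume_shape[2:3]
  ring_r <- min(extent) / 2 - rod_radius - 2 * max(spacing[2:3])
  ang <- 2 * pi * (seq_len(k) - 1) / k
  centers <- cbind(extent[1L] / 2 + ring_r * cos(ang),
                   extent[2L] / 2 + ring_r * sin(ang))
  gap <- sqrt(sum((centers[1, ] - centers[2, ])^2)) - 2 * rod_radius
  if (k > 1 && gap <= 0)
    stop("rod layout error: rods overlap; reduce rod_radius or rod count",
         call. = FALSE)
  depth <- spacing[1L] * volume_shape[1L]
  shapes <- lapply(seq_len(k), function(i)
    scene_shape("cylinder",
                center = c(depth / 2, centers[i, 1L], centers[i, 2L]),
                dims = c(rod_radius, depth), density = densities[i],
                label = i, rotation = rot_cyl_axis(1L)))
  rois <- lapply(seq_len(k), function(i)
    lapply(c(0.25, 0.5, 0.75), function(f)
      roi_ellipse(f, center = centers[i, ],
                  semi_axes = rep(0.6 * rod_radius, 2))))
  names(rois) <- paste0("rod_", seq_len(k))
  spec <- scene_spec(shapes, calibration_truth = calibration_truth,
                     noise_sigma = noise_sigma, spacing = spacing,
                     volume_shape = volume_shape, seed = seed,
                     segment_names = stats::setNames(names(rois), seq_len(k)))
  spec$rois <- rois
  spec$densities <- densities
  spec
}

#' Bird-like multi-segment test scene
#'
#' A labelled analogue of a pinned, wings-outstretched raptor on the
#' scanner: ellipsoid torso, sphere head, thin distal wing plates, leg
#' cylinders and a tail plate, mirror-symmetric about the mid-sagittal
#' plane.  Wing plates are thin and distal so their MoI fraction far
#' exceeds their mass fraction, reproducing the defining feature of avian
#' mass distribution.  World axes: 1 = anteroposterior (x, roll axis),
#' 2 = mediolateral/span (y, pitch axis), 3 = dorsoventral (z, yaw axis).
#'
#' Densities default to soft tissue ~1000, bone-weighted head/legs
#' 1050/1100, feathered wings 350 and tail 250 kg m^-3.
#'
#' @param wings `"extended"` (default) or `"retracted"` (plates folded
#'   inboard alongside the torso, same mass).
#' @param spacing voxel spacing mm (default 1 mm isotropic: the scanner
#'   scale of sub-mm pixels / 1.25 mm slices, and commensurate with the
#'   scene's shape boundaries so center-sampling error stays well below the
#'   analytic-comparison tolerances).
#' @param calibration_truth true grey -> density line.
#' @param noise_sigma grey noise s.d.
#' @param seed RNG seed.
#' @param densities named numeric overriding any of `torso`, `head`,
#'   `wing`, `leg`, `tail`.
#' @return a [scene_spec()]; segments named torso, head, wing_left,
#'   wing_right, leg_left, leg_right, tail.  Element `groups` maps each
#'   label to `"wings"` or `"body"` for spanwise profiles.
#' @export
make_bird_like_scene <- function(wings = c("extended", "retracted"),
                                 spacing = c(1, 1, 1),
                                 calibration_truth = c(slope = 1.5,
                                                       intercept = -80),
                                 noise_sigma = 5, seed = 1L,
                                 densities = NULL) {
  wings <- match.arg(wings)
  rho <- c(torso = 1000, head = 1050, wing = 350, leg = 1100, tail = 250)
  if (!is.null(densities)) rho[names(densities)] <- densities
  wing_dims <- c(90, 170, 8)
  wing_centers <- if (wings == "extended")
    list(c(121, 93, 40), c(121, 327, 40))
  else list(c(121, 133, 40), c(121, 287, 40))
  if (wings == "retracted") wing_dims <- c(170, 90, 8)
  shapes <- list(
    scene_shape("ellipsoid", c(130, 210, 40), c(55, 32, 28), rho["torso"], 1L),
    scene_shape("sphere", c(56, 210, 46), 18, rho["head"], 2L),
    scene_shape("plate", wing_centers[[1L]], wing_dims, rho["wing"], 3L),
    scene_shape("plate", wing_centers[[2L]], wing_dims, rho["wing"], 4L),
    scene_shape("cylinder", c(199, 190, 56), c(6, 36), rho["leg"], 5L,
                rotation = rot_cyl_axis(1L)),
    scene_shape("cylinder", c(199, 230, 56), c(6, 36), rho["leg"], 6L,
                rotation = rot_cyl_axis(1L)),
    scene_shape("plate", c(202, 210, 42), c(32, 40, 8), rho["tail"], 7L))
  segment_names <- stats::setNames(
    c("torso", "head", "wing_left", "wing_right", "leg_left", "leg_right",
      "tail"), 1:7)
  volume_shape <- round(c(220, 420, 80) / spacing)
  spec <- scene_spec(shapes, calibration_truth = calibration_truth,
                     noise_sigma = noise_sigma, spacing = spacing,
                     volume_shape = volume_shape, seed = seed,
                     segment_names = segment_names)
  spec$groups <- stats::setNames(
    c("body", "body", "wings", "wings", "body", "body", "body"), 1:7)
  spec
}

#' Simulate a trifilar-pendulum angular-velocity trace
#'
#' Integrates the exact (large-angle) trifilar equation of motion — the
#' geometric restoring torque
#' \eqn{-M g R^2 \sin\theta / \sqrt{L^2 - 2R^2(1 - \cos\theta)}}
#' with linear viscous damping — rather than the small-angle approximation,
#' so the small-angle error of the measurement model is measurable.
#' Sampled at `rate` Hz with seeded additive Gaussian noise on the angular
#' velocity.
#'
#' @param I_total MoI of everything oscillating, about the rotation axis,
#'   kg m^2.
#' @param rig a [pendulum_rig()].
#' @param zeta damping ratio (relative to the small-angle natural
#'   frequency).
#' @param amplitude initial angular displacement, rad (released from rest).
#' @param duration s.
#' @param rate sampling rate, Hz (default 70).
#' @param noise_sigma angular-velocity noise s.d., rad s^-1.
#' @param seed RNG seed.
#' @param m_total oscillating mass, kg; defaults to the rig mass alone.
#' @return an [oscillation_trace()].
#' @export
simulate_pendulum_trace <- function(I_total, rig, zeta = 0, amplitude,
                                    duration, rate = 70, noise_sigma = 0,
                                    seed = 1L, m_total = rig$m_p) {
  stopifnot(inherits(rig, "pendulum_rig"), I_total > 0, zeta >= 0,
            duration > 0, rate > 0, m_total > 0)
  # geometric limit: the threads must stay longer than the chord they span
  if (rig$L^2 - 2 * rig$R^2 * (1 - cos(amplitude)) <= 0)
    stop("amplitude ", amplitude, " rad exceeds the geometric limit of the ",
         "suspension", call. = FALSE)
  k <- m_total * rig$g * rig$R^2 / rig$L  # small-angle stiffness
  cc <- 2 * zeta * sqrt(k * I_total)
  deriv <- function(t, y, parms) {
    theta <- y[1L]; omega <- y[2L]
    torque <- -m_total * rig$g * rig$R^2 * sin(theta) /
      sqrt(rig$L^2 - 2 * rig$R^2 * (1 - cos(theta))) - cc * omega
    list(c(omega, torque / I_total))
  }
  times <- seq(0, duration, by = 1 / rate)
  sol <- deSolve::ode(y = c(theta = amplitude, omega = 0), times = times,
                      func = deriv, parms = NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-12)
  omega <- sol[, "omega"]
  if (noise_sigma > 0)
    omega <- with_preserved_seed(seed,
                                 omega + stats::rnorm(length(omega), 0,
                                                      noise_sigma))
  oscillation_trace(times, omega)
}
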