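#' Build a per-voxel mass model
#'
#' Converts a calibrated density volume plus specimen mask into the mass
#' model the analytics consume: one mass (kg) and one world-center
#' coordinate (m) per retained voxel.  All analytics are in SI; millimetres
#' exist only at the I/O boundary.  Negative calibrated densities are
#' clamped to zero mass (noise below the air line must not contribute
#' negative mass).
#'
#' @param density_volume a [voxel_grid()] whose values are densities in
#'   kg m^-3 (see [apply_calibration()]).
#' @param specimen_mask logical array from [apply_threshold()] (or a
#'   `threshold_result`).
#' @return object of class `mass_model`: `masses` (kg), `coords` (n x 3, m),
#'   `voxel_volume` (m^3), `total_mass` (kg), plus the linear `index` of each
#'   retained voxel and `grid_dim` for label alignment.
#' @export
build_mass_model <- function(density_volume, specimen_mask) {
  stopifnot(inherits(density_volume, "voxel_grid"))
  if (inherits(specimen_mask, "threshold_result"))
    specimen_mask <- specimen_mask$mask
  if (!identical(dim(specimen_mask), dim(density_volume$values)))
    stop("mask shape does not match the volume", call. = FALSE)
  idx <- which(specimen_mask)
  if (!length(idx))
    stop("empty specimen: the mask retains no voxels", call. = FALSE)
  vol <- voxel_volume_m3(density_volume)
  rho <- as.numeric(density_volume$values[idx])
  rho[rho < 0] <- 0
  masses <- rho * vol
  coords <- linear_index_world(density_volume, idx) * 1e-3  # mm -> m
  structure(list(masses = masses, coords = coords, voxel_volume = vol,
                 total_mass = compensated_sum(masses),
                 index = idx, grid_dim = dim(density_volume$values)),
            class = "mass_model")
}

#' Construct a mass model directly from point masses
#'
#' Mostly for testing and for composite rigid bodies: the analytics treat a
#' mass model as a weighted point cloud, so any set of point masses is valid.
#'
#' @param masses numeric vector, kg (>= 0).
#' @param coords n x 3 matrix, m.
#' @param voxel_volume nominal element volume, m^3 (default `NA`).
#' @export
mass_model <- function(masses, coords, voxel_volume = NA_real_) {
  coords <- rbind_index(coords)
  stopifnot(length(masses) == nrow(coords), all(masses >= 0))
  structure(list(masses = as.numeric(masses), coords = coords,
                 voxel_volume = voxel_volume,
                 total_mass = compensated_sum(as.numeric(masses)),
                 index = NULL, grid_dim = NULL),
            class = "mass_model")
}

#' @export
print.mass_model <- function(x, ...) {
  cat("<mass_model> ", length(x$masses), " mass elements, total ",
      signif(x$total_mass, 6), " kg\n", sep = "")
  invisible(x)
}

#' Centre of mass
#'
#' Mass-weighted mean of the element positions:
#' each component is `sum(m_i x_i) / sum(m_i)`.
#'
#' @param model a [mass_model()] / [build_mass_model()] result.
#' @return length-3 numeric, m.
#' @export
centre_of_mass <- function(model) {
  stopifnot(inherits(model, "mass_model"))
  if (model$total_mass <= 0)
    stop("degenerate model: total mass is zero", call. = FALSE)
  c(compensated_dot(model$masses, model$coords[, 1L]),
    compensated_dot(model$masses, model$coords[, 2L]),
    compensated_dot(model$masses, model$coords[, 3L])) / model$total_mass
}

#' Inertia tensor about an arbitrary origin
#'
#' Standard rigid-body tensor with coordinates relative to `origin`:
#' `I_xx = sum m (y^2 + z^2)` (and cyclic) on the diagonal and products of
#' inertia stored as tensor entries `I_xy = -sum m x y` (and cyclic) off the
#' diagonal.  This is the sign convention for which `L = I w`; some
#' biomechanics tables list the positive products `+sum m x y` instead.
#'
#' @param model a [mass_model()].
#' @param origin length-3 numeric, m.  Default: the model's centre of mass.
#' @return symmetric 3 x 3 matrix, kg m^2.
#' @export
inertia_tensor <- function(model, origin = centre_of_mass(model)) {
  stopifnot(inherits(model, "mass_model"), length(origin) == 3L)
  m <- model$masses
  x <- model$coords[, 1L] - origin[1L]
  y <- model$coords[, 2L] - origin[2L]
  z <- model$coords[, 3L] - origin[3L]
  ixx <- compensated_dot(m, y * y + z * z)
  iyy <- compensated_dot(m, x * x + z * z)
  izz <- compensated_dot(m, x * x + y * y)
  ixy <- -compensated_dot(m, x * y)
  ixz <- -compensated_dot(m, x * z)
  iyz <- -compensated_dot(m, y * z)
  matrix(c(ixx, ixy, ixz,
           ixy, iyy, iyz,
           ixz, iyz, izz), 3L, 3L)
}

#' Principal moments and axes of an inertia tensor
#'
#' Eigendecomposition of a symmetric inertia tensor.  Moments are returned
#' ascending; axes are the corresponding columns, orthonormal and
#' right-handed (determinant +1, the third axis flipped if necessary), with
#' each axis sign-fixed so that its largest-magnitude component is positive.
#' For degenerate moments the axes within the degenerate eigenspace are an
#' arbitrary orthonormal choice.
#'
#' @param tensor symmetric 3 x 3 matrix, kg m^2.
#' @return list with `principal_moments` (ascending) and `principal_axes`
#'   (3 x 3 rotation matrix, columns = axes).
#' @export
principal_decomposition <- function(tensor) {
  tensor <- as.matrix(tensor)
  asym <- max(abs(tensor - t(tensor)))
  if (asym > 1e-9 * max(1, max(abs(tensor))))
    stop("tensor is not symmetric (relative asymmetry ",
         signif(asym / max(abs(tensor)), 3), ")", call. = FALSE)
  e <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  axes <- e$vectors[, ord, drop = FALSE]
  for (k in 1:3) {
    j <- which.max(abs(axes[, k]))
    if (axes[j, k] < 0) axes[, k] <- -axes[, k]
  }
  if (det(axes) < 0) axes[, 3L] <- -axes[, 3L]
  list(principal_moments = vals, principal_axes = axes)
}

#' Full inertial summary of a mass model
#'
#' Convenience wrapper computing mass, centre of mass, the inertia tensor
#' about the CoM (or a supplied origin), and the principal decomposition.
#'
#' @param model a [mass_model()].
#' @param origin tensor origin, m; default the centre of mass.
#' @return object of class `inertial_properties`.
#' @export
inertial_properties <- function(model, origin = NULL) {
  com <- centre_of_mass(model)
  if (is.null(origin)) origin <- com
  tensor <- inertia_tensor(model, origin)
  pd <- principal_decomposition(tensor)
  structure(list(mass = model$total_mass, com = com, origin = origin,
                 tensor = tensor,
                 principal_moments = pd$principal_moments,
                 principal_axes = pd$principal_axes),
            class = "inertial_properties")
}

#' @export
print.inertial_properties <- function(x, ...) {
  cat("<inertial_properties>\n")
  cat(sprintf("  mass  %.6g kg\n", x$mass))
  cat(sprintf("  CoM   (%.6g, %.6g, %.6g) m\n", x$com[1], x$com[2], x$com[3]))
  cat("  inertia tensor about (",
      paste(signif(x$origin, 6), collapse = ", "), ") m  [kg m^2]:\n", sep = "")
  print(signif(x$tensor, 6))
  cat("  principal moments: ",
      paste(signif(x$principal_moments, 6), collapse = ", "), " kg m^2\n", sep = "")
  invisible(x)
}

#' @export
summary.inertial_properties <- function(object, ...) {
  print(object)
  cat("  principal axes (columns):\n")
  print(signif(object$principal_axes, 6))
  invisible(object)
}

#' Axis specification
#' @param point length-3 numeric, m: a point on the axis.
#' @param direction length-3 numeric; normalised internally, must be nonzero.
#' @return object of class `axis_spec` with a unit `direction`.
#' @export
axis_spec <- function(point, direction) {
  stopifnot(length(point) == 3L, length(direction) == 3L)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("axis direction must be nonzero", call. = FALSE)
  structure(list(point = as.numeric(point),
                 direction = as.numeric(direction) / nrm),
            class = "axis_spec")
}

#' Moment of inertia about an arbitrary axis
#'
#' `sum m_i d_i^2` with `d_i` the perpendicular distance of element `i` from
#' the axis line.  Equals `n' I n` for the tensor about any point on the
#' axis, with `n` the unit direction.
#'
#' @param model a [mass_model()].
#' @param axis an [axis_spec()].
#' @return scalar, kg m^2.
#' @export
moi_about_axis <- function(model, axis) {
  stopifnot(inherits(model, "mass_model"), inherits(axis, "axis_spec"))
  compensated_dot(model$masses, perp_dist2(model$coords, axis))
}

# squared perpendicular distances of points from an axis line
perp_dist2 <- function(coords, axis) {
  r <- sweep(coords, 2, axis$point)
  proj <- as.numeric(r %*% axis$direction)
  rowSums(r * r) - proj * proj
}

#' Total-least-squares plane fit to board points
#'
#' Fits the plane minimising orthogonal distances (smallest singular
#' direction of the centered points), used to recover the dorsoventral axis
#' as the normal of the scanned mounting board.  The normal is oriented to
#' point toward the side of the plane containing `com_hint` when given.
#'
#' @param board_points n x 3 matrix (n >= 3, non-collinear), m.
#' @param com_hint optional length-3 point (e.g. the specimen CoM) fixing
#'   the normal's sign.
#' @return list with unit `normal`, `point` (the centroid) and `rms`
#'   orthogonal residual.
#' @export
fit_board_plane <- function(board_points, com_hint = NULL) {
  pts <- rbind_index(board_points)
  if (nrow(pts) < 3L) stop("at least 3 points are required", call. = FALSE)
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr)
  sv <- svd(centered)
  if (sv$d[2L] <= 1e-12 * max(sv$d[1L], 1))
    stop("degenerate point set: points are collinear", call. = FALSE)
  normal <- sv$v[, 3L]
  if (!is.null(com_hint) && sum(normal * (com_hint - ctr)) < 0)
    normal <- -normal
  list(normal = normal, point = ctr,
       rms = sqrt(mean((centered %*% normal)^2)))
}

#' Parallel-axis translation of a CoM tensor
#'
#' `I' = I + m (|d|^2 Id - d d')` for a displacement `d` of the origin away
#' from the centre of mass; exact, no discretization involved.
#'
#' @param tensor 3 x 3 inertia tensor about the CoM, kg m^2.
#' @param mass total mass, kg.
#' @param displacement length-3, m: new origin minus CoM.
#' @return 3 x 3 tensor about the displaced origin.
#' @export
translate_tensor <- function(tensor, mass, displacement) {
  d <- as.numeric(displacement)
  stopifnot(length(d) == 3L)
  tensor + mass * (sum(d * d) * diag(3) - tcrossprod(d))
}

#' Uniform-density comparison model
#'
#' Re-runs the inertial pipeline under the uniform-density assumption
#' (density = specimen mass / specimen volume, i.e. every retained voxel is
#' assigned `total_mass / n_voxels`), for side-by-side comparison with the
#' calibrated result.  Total mass is preserved exactly by construction.
#'
#' @param specimen_mask logical array (or `threshold_result`).
#' @param total_mass measured specimen mass, kg.
#' @param geometry a [voxel_grid()] supplying spacing/origin (its values are
#'   ignored).
#' @param origin tensor origin passed to [inertial_properties()].
#' @return an `inertial_properties` object, with the underlying uniform
#'   [mass_model()] attached as attribute `"model"`.
#' @export
uniform_density_comparison <- function(specimen_mask, total_mass, geometry,
                                       origin = NULL) {
  stopifnot(inherits(geometry, "voxel_grid"))
  if (inherits(specimen_mask, "threshold_result"))
    specimen_mask <- specimen_mask$mask
  idx <- which(specimen_mask)
  if (!length(idx)) stop("empty specimen: the mask retains no voxels", call. = FALSE)
  n <- length(idx)
  coords <- linear_index_world(geometry, idx) * 1e-3
  model <- mass_model(rep(total_mass / n, n), coords,
                      voxel_volume = voxel_volume_m3(geometry))
  # keep exact preservation of the stated total
  model$total_mass <- total_mass
  props <- inertial_properties(model, origin = origin)
  attr(props, "model") <- model
  props
}
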