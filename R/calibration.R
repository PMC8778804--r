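#' Elliptical region-of-interest specification
#'
#' Describes one ellipse drawn on one plane of a volume, used to sample a
#' calibration phantom rod.  The plane is selected as a fraction of the way
#' along a designated array axis (e.g. 0.25, 0.5, 0.75 along the rod);
#' the ellipse lives in the world (mm) coordinates of the two remaining
#' axes, in their array order.
#'
#' @param plane_fraction position of the sampling plane in (0, 1) along
#'   `plane_axis`.
#' @param center length-2 ellipse center, mm, in-plane world coordinates.
#' @param semi_axes length-2 strictly positive semi-axes, mm.
#' @param rotation ellipse rotation, radians (default 0).
#' @param plane_axis which array axis the plane is orthogonal to (default 1,
#'   the slice axis).
#' @return an object of class `roi_spec`.
#' @export
roi_ellipse <- function(plane_fraction, center, semi_axes, rotation = 0,
                        plane_axis = 1L) {
  stopifnot(plane_fraction > 0, plane_fraction < 1,
            length(center) == 2L, length(semi_axes) == 2L,
            all(semi_axes > 0), plane_axis %in% 1:3)
  structure(list(plane_fraction = plane_fraction, center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes), rotation = rotation,
                 plane_axis = as.integer(plane_axis)),
            class = "roi_spec")
}

#' Sample a calibration phantom through elliptical ROIs
#'
#' Pools every voxel whose center falls strictly inside any of the supplied
#' ellipses (partial-coverage voxels are excluded, avoiding partial-volume
#' contamination of the phantom mean) and records the pooled mean grey-value.
#'
#' @param grid a [voxel_grid()].
#' @param rois list of [roi_ellipse()] specs (typically the 25/50/75% planes).
#' @param known_density the phantom's certified density, kg m^-3.
#' @param name phantom name.
#' @return an object of class `phantom_sample` with fields `name`,
#'   `known_density`, `mean_grey`, `n_voxels`.
#' @export
sample_phantom <- function(grid, rois, known_density, name = "phantom") {
  stopifnot(inherits(grid, "voxel_grid"), known_density >= 0)
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  if (!length(rois)) stop("at least one ROI is required", call. = FALSE)
  vals <- unlist(lapply(seq_along(rois), function(i) {
    v <- roi_voxels(grid, rois[[i]])
    if (!length(v))
      stop("ROI ", i, " (plane fraction ", rois[[i]]$plane_fraction,
           ") contains no voxel centers", call. = FALSE)
    v
  }))
  phantom_sample(name, known_density, mean(vals), length(vals))
}

#' Construct a phantom sample from known values
#' @param name phantom name.
#' @param known_density kg m^-3, >= 0.
#' @param mean_grey mean grey-value, scanner units.
#' @param n_voxels pooled voxel count, >= 1.
#' @export
phantom_sample <- function(name, known_density, mean_grey, n_voxels) {
  stopifnot(known_density >= 0, n_voxels >= 1)
  structure(list(name = name, known_density = as.numeric(known_density),
                 mean_grey = as.numeric(mean_grey),
                 n_voxels = as.integer(n_voxels)),
            class = "phantom_sample")
}

#' Air sample at standard room conditions
#'
#' Air is treated as a true calibration point at 1.2 kg m^-3 (room
#' temperature and pressure) rather than zero.
#' @inheritParams phantom_sample
#' @export
air_sample <- function(mean_grey, n_voxels = 1L)
  phantom_sample("air", 1.2, mean_grey, n_voxels)

# grey-values of voxels whose centers fall strictly inside one ROI ellipse
roi_voxels <- function(grid, roi) {
  d <- dim(grid$values)
  ax <- roi$plane_axis
  n <- d[ax]
  slice_idx <- floor(roi$plane_fraction * n) + 1L
  slice_idx <- min(max(slice_idx, 1L), n)
  inplane <- setdiff(1:3, ax)
  u <- axis_centers(grid, inplane[1L])
  v <- axis_centers(grid, inplane[2L])
  uu <- rep(u, times = length(v)) - roi$center[1L]
  vv <- rep(v, each = length(u)) - roi$center[2L]
  cr <- cos(roi$rotation); sr <- sin(roi$rotation)
  a <- (cr * uu + sr * vv) / roi$semi_axes[1L]
  b <- (-sr * uu + cr * vv) / roi$semi_axes[2L]
  inside <- a * a + b * b < 1
  plane <- switch(ax,
                  grid$values[slice_idx, , ],
                  grid$values[, slice_idx, ],
                  grid$values[, , slice_idx])
  as.numeric(plane)[inside]
}

#' Fit a per-scan linear density calibration
#'
#' Ordinary least squares of known density on mean grey-value across the
#' phantom samples (unweighted), optionally including an air sample as a
#' data point at 1.2 kg m^-3.  Each scan needs its own calibration:
#' calibration curves differ between scans, so reuse across scans is not
#' supported by the workflow.
#'
#' @param samples list of [phantom_sample()] objects (>= 2, distinct grey).
#' @param air_sample optional [air_sample()]; appended when `include_air`.
#' @param include_air include the air point (default: whenever supplied).
#' @return object of class `density_calibration` with `slope`
#'   (kg m^-3 per grey unit), `intercept` (kg m^-3), `r_squared`, `samples`.
#' @export
fit_calibration <- function(samples, air_sample = NULL,
                            include_air = !is.null(air_sample)) {
  if (inherits(samples, "phantom_sample")) samples <- list(samples)
  if (include_air) {
    if (is.null(air_sample)) stop("include_air = TRUE but no air sample given",
                                  call. = FALSE)
    samples <- c(samples, list(air_sample))
  }
  if (length(samples) < 2L)
    stop("insufficient data: at least 2 phantom samples are required",
         call. = FALSE)
  grey <- vapply(samples, `[[`, 0, "mean_grey")
  dens <- vapply(samples, `[[`, 0, "known_density")
  if (diff(range(grey)) == 0)
    stop("degenerate fit: all samples share one grey-value", call. = FALSE)
  fit <- stats::lm(dens ~ grey)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((dens - mean(dens))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 samples = samples, fit = fit),
            class = "density_calibration")
}

#' @export
print.density_calibration <- function(x, ...) {
  cat("<density_calibration>  rho = ", signif(x$slope, 6), " * grey ",
      ifelse(x$intercept < 0, "- ", "+ "), signif(abs(x$intercept), 6),
      "  [kg m^-3]\n", sep = "")
  cat("  ", length(x$samples), " samples, R^2 = ",
      formatC(x$r_squared, digits = 6, format = "f"), "\n", sep = "")
  invisible(x)
}

#' @export
coef.density_calibration <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
summary.density_calibration <- function(object, ...) {
  df <- data.frame(
    name = vapply(object$samples, `[[`, "", "name"),
    known_density = vapply(object$samples, `[[`, 0, "known_density"),
    mean_grey = vapply(object$samples, `[[`, 0, "mean_grey"),
    n_voxels = vapply(object$samples, `[[`, 0L, "n_voxels"))
  df$fitted <- object$slope * df$mean_grey + object$intercept
  df$residual <- df$known_density - df$fitted
  structure(list(table = df, slope = object$slope,
                 intercept = object$intercept, r_squared = object$r_squared),
            class = "summary.density_calibration")
}

#' @export
print.summary.density_calibration <- function(x, ...) {
  cat("Linear density calibration (kg m^-3 vs grey-value)\n")
  cat("  slope     ", signif(x$slope, 8), "\n")
  cat("  intercept ", signif(x$intercept, 8), "\n")
  cat("  R^2       ", formatC(x$r_squared, digits = 6, format = "f"), "\n\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
predict.density_calibration <- function(object, newdata, ...) {
  grey <- if (missing(newdata))
    vapply(object$samples, `[[`, 0, "mean_grey")
  else if (is.list(newdata)) newdata$grey %||% newdata$mean_grey
  else newdata
  object$slope * as.numeric(grey) + object$intercept
}

#' @export
plot.density_calibration <- function(x, ...) {
  grey <- vapply(x$samples, `[[`, 0, "mean_grey")
  dens <- vapply(x$samples, `[[`, 0, "known_density")
  plot(grey, dens, xlab = "mean grey-value (scanner units)",
       ylab = expression(density ~ (kg ~ m^-3)),
       main = sprintf("Density calibration (R² = %.4f)", x$r_squared), ...)
  graphics::abline(x$intercept, x$slope, col = "grey40")
  invisible(x)
}

#' Export / import a calibration as JSON
#' @param cal a `density_calibration`.
#' @param path JSON file path.
#' @export
write_calibration <- function(cal, path) {
  jsonlite::write_json(list(
    slope = cal$slope, intercept = cal$intercept, r_squared = cal$r_squared,
    samples = lapply(cal$samples, function(s)
      s[c("name", "known_density", "mean_grey", "n_voxels")])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path)
  samples <- lapply(j$samples, function(s)
    phantom_sample(s$name, s$known_density, s$mean_grey, s$n_voxels))
  cal <- fit_calibration(samples)
  # refitting from the embedded samples must reproduce the stored line
  if (abs(cal$slope - j$slope) > 1e-9 * max(1, abs(j$slope)) ||
      abs(cal$intercept - j$intercept) > 1e-9 * max(1, abs(j$intercept)))
    warning("stored calibration coefficients disagree with refit of the ",
            "embedded samples; using the refit")
  cal
}

#' Hounsfield units from attenuation coefficients
#'
#' `HU = 1000 (mu_voxel - mu_water) / mu_water`: water defines 0 HU and
#' vanishing attenuation (air) maps to -1000 HU.
#'
#' @param mu_voxel attenuation coefficient(s) of the voxel material.
#' @param mu_water attenuation coefficient of distilled water, > 0.
#' @return Hounsfield units.
#' @export
hounsfield_from_attenuation <- function(mu_voxel, mu_water) {
  if (!is.numeric(mu_water) || mu_water <= 0)
    stop("mu_water must be strictly positive", call. = FALSE)
  1000 * (mu_voxel - mu_water) / mu_water
}

#' Basic (uncalibrated) HU to density map for biological material
#'
#' The approximate linear relation anchored at water (0 HU -> 1000 kg m^-3)
#' and air (-1000 HU -> 0 kg m^-3), i.e. `rho = HU + 1000`.  Adequate near
#' water density; the phantom calibration supersedes it for quantitative
#' work.
#'
#' @param hu Hounsfield units.
#' @return density, kg m^-3.
#' @export
density_from_hu <- function(hu) hu + 1000

#' Apply a fitted calibration to a volume
#'
#' Per-voxel `rho = slope * grey + intercept`; geometry metadata is carried
#' through unchanged, so the result is a [voxel_grid()] whose values are
#' densities in kg m^-3.
#'
#' @param grid a [voxel_grid()] of grey-values.
#' @param cal a `density_calibration`.
#' @return a [voxel_grid()] of densities.
#' @export
apply_calibration <- function(grid, cal) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(cal, "density_calibration"))
  voxel_grid(cal$slope * grid$values + cal$intercept,
             spacing = grid$spacing, origin = grid$origin,
             axis_labels = grid$axis_labels)
}
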