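#' Voxel grids
#'
#' A `voxel_grid` is the single in-memory representation of a CT volume used
#' throughout the package: a rank-3 array of scanner grey-values together with
#' the voxel spacing (mm) and the world position (mm) of the corner of voxel
#' (1,1,1).  Array axes are ordered (slice, row, col); anatomical meaning is
#' recorded in `axis_labels` and never assumed from scan orientation.
#'
#' Voxel centers carry the mass: the world coordinate of the center of voxel
#' index (i,j,k) is `origin + (index - 1/2) * spacing` (1-based indices), a
#' bijective affine map.
#'
#' @param values rank-3 numeric/integer array of grey-values.
#' @param spacing numeric length-3, mm per voxel along each array axis; all
#'   components strictly positive.
#' @param origin numeric length-3, mm, world position of the corner of the
#'   first voxel. Default `c(0, 0, 0)`.
#' @param axis_labels character length-3 names for the array axes.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0),
                       axis_labels = c("slice", "row", "col")) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a rank-3 array", call. = FALSE)
  if (any(dim(values) < 1L))
    stop("all three dimensions must be >= 1", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin,
                 axis_labels = as.character(axis_labels)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("<voxel_grid> ", paste(d, collapse = " x "),
      " voxels (", paste(x$axis_labels, collapse = ", "), ")\n", sep = "")
  cat("  spacing: ", paste(signif(x$spacing, 4), collapse = " x "), " mm",
      "   voxel volume: ", signif(prod(x$spacing), 6), " mm^3\n", sep = "")
  cat("  origin:  (", paste(signif(x$origin, 6), collapse = ", "), ") mm\n", sep = "")
  cat("  grey-values in [", min(x$values), ", ", max(x$values), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' Voxel volume in cubic metres
#' @param grid a [voxel_grid()].
#' @return scalar, m^3.
#' @export
voxel_volume_m3 <- function(grid) prod(grid$spacing) * 1e-9

#' Map voxel indices to world coordinates (mm)
#'
#' Returns the world coordinates of voxel centers.  Indices are 1-based;
#' center of voxel (i,j,k) = origin + (index - 1/2) * spacing.
#'
#' @param grid a [voxel_grid()].
#' @param index integer matrix (n x 3) or length-3 vector of 1-based indices.
#' @return n x 3 matrix of world coordinates, mm.
#' @export
index_to_world <- function(grid, index) {
  index <- rbind_index(index)
  sweep(sweep(index - 0.5, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' Map world coordinates (mm) to voxel indices
#'
#' Inverse of [index_to_world()]: the voxel whose cell contains each point.
#' For points exactly at a voxel center this recovers the index exactly.
#'
#' @param grid a [voxel_grid()].
#' @param world numeric matrix (n x 3) or length-3 vector, mm.
#' @return n x 3 integer matrix of 1-based voxel indices.
#' @export
world_to_index <- function(grid, world) {
  world <- rbind_index(world)
  idx <- sweep(sweep(world, 2, grid$origin, "-"), 2, grid$spacing, "/") + 0.5
  storage.mode(idx) <- "double"
  round(idx)
}

rbind_index <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  if (ncol(x) != 3L) stop("index/coordinate input must have 3 columns", call. = FALSE)
  x
}

# world coordinates (mm) of every voxel center along one array axis
axis_centers <- function(grid, axis) {
  n <- dim(grid$values)[axis]
  grid$origin[axis] + (seq_len(n) - 0.5) * grid$spacing[axis]
}

# n x 3 matrix of world centers (mm) for linear indices into the value array
linear_index_world <- function(grid, lin) {
  d <- dim(grid$values)
  lin0 <- lin - 1L
  i <- lin0 %% d[1L]
  j <- (lin0 %/% d[1L]) %% d[2L]
  k <- lin0 %/% (d[1L] * d[2L])
  cbind(grid$origin[1L] + (i + 0.5) * grid$spacing[1L],
        grid$origin[2L] + (j + 0.5) * grid$spacing[2L],
        grid$origin[3L] + (k + 0.5) * grid$spacing[3L])
}

#' Label volumes for virtual dissection
#'
#' Integer segment labels aligned voxel-for-voxel with a companion
#' [voxel_grid()].  Label 0 is reserved for background/unassigned; every
#' nonzero label must be named.
#'
#' @param labels rank-3 integer array.
#' @param segment_names named character or integer-named vector/list mapping
#'   label value to anatomical name, e.g. `c("1" = "torso", "2" = "head")`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, segment_names) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a rank-3 array", call. = FALSE)
  storage.mode(labels) <- "integer"
  segment_names <- unlist(segment_names)
  present <- sort(unique(as.integer(labels)))
  present <- present[present != 0L]
  missing <- setdiff(present, as.integer(names(segment_names)))
  if (length(missing))
    stop("labels without a segment name: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(labels = labels, segment_names = segment_names),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "), " voxels, ",
      length(x$segment_names), " named segments\n", sep = "")
  invisible(x)
}
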