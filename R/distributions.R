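#' Project mass or MoI onto a planar grid
#'
#' Collapses one world axis and accumulates each element's mass (or its
#' MoI contribution `m_i d_i^2` about `reference_axis`) into the planar cell
#' containing its projected center.  Voxel-center binning (no kernel
#' spreading) keeps conservation exact: the grid sums to the parent total.
#'
#' @param model a [mass_model()].
#' @param axis world axis to collapse (1, 2 or 3).
#' @param cell_size cell edge, m (> 0).
#' @param quantity `"mass"` or `"moi"`.
#' @param reference_axis an [axis_spec()]; required when `quantity = "moi"`.
#' @return object of class `projection_map`: `grid` (2D matrix of summed
#'   kg or kg m^2), `normalised` (grid / max for display), `cell_size`,
#'   `projection_axis`, `quantity`, `u`/`v` cell-center coordinates (m,
#'   remaining world axes in array order).
#' @export
project_quantity <- function(model, axis, cell_size,
                             quantity = c("mass", "moi"),
                             reference_axis = NULL) {
  stopifnot(inherits(model, "mass_model"), axis %in% 1:3, cell_size > 0)
  quantity <- match.arg(quantity)
  vals <- if (quantity == "mass") model$masses else {
    if (is.null(reference_axis))
      stop("a reference_axis is required for MoI projections", call. = FALSE)
    model$masses * perp_dist2(model$coords, reference_axis)
  }
  inplane <- setdiff(1:3, axis)
  u <- model$coords[, inplane[1L]]
  v <- model$coords[, inplane[2L]]
  u0 <- min(u); v0 <- min(v)
  iu <- floor((u - u0) / cell_size) + 1L
  iv <- floor((v - v0) / cell_size) + 1L
  nu <- max(iu); nv <- max(iv)
  grid <- matrix(compensated_group_sum(vals, as.integer((iv - 1L) * nu + iu),
                                       as.integer(nu * nv)),
                 nrow = nu, ncol = nv)
  structure(list(grid = grid,
                 normalised = if (max(grid) > 0) grid / max(grid) else grid,
                 cell_size = cell_size, projection_axis = axis,
                 quantity = quantity, reference_axis = reference_axis,
                 u = u0 + (seq_len(nu) - 0.5) * cell_size,
                 v = v0 + (seq_len(nv) - 0.5) * cell_size),
            class = "projection_map")
}

#' @export
print.projection_map <- function(x, ...) {
  cat("<projection_map> ", x$quantity, " collapsed along world axis ",
      x$projection_axis, "\n  ", nrow(x$grid), " x ", ncol(x$grid),
      " cells of ", x$cell_size * 1e3, " mm; total = ",
      signif(sum(x$grid), 8), if (x$quantity == "mass") " kg" else " kg m^2",
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.projection_map <- function(x, normalised = TRUE, ...) {
  z <- if (normalised) x$normalised else x$grid
  graphics::image(x$u, x$v, z, asp = 1, useRaster = TRUE,
                  xlab = "m", ylab = "m",
                  main = paste0("projected ", x$quantity,
                                if (normalised) " (normalised)"), ...)
  invisible(x)
}

#' Export a projection map as a CSV matrix
#' @param map a `projection_map`.
#' @param path output CSV path.
#' @export
write_projection_csv <- function(map, path) {
  utils::write.table(map$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Segment-wise mass and MoI fraction table
#'
#' For each anatomical segment, the fraction of total mass and of total MoI
#' about the shared whole-body roll/pitch/yaw axes (not per-segment CoM
#' axes).  Every column sums to 1.
#'
#' @param model a [mass_model()] built from the full specimen.
#' @param labels a [label_volume()] aligned with the model's source grid.
#' @param axes named list of three [axis_spec()]s: `roll`, `pitch`, `yaw`
#'   (typically through the whole-body CoM).
#' @return data.frame with columns `segment`, `mass_fraction`,
#'   `I_roll_fraction`, `I_pitch_fraction`, `I_yaw_fraction` plus the
#'   absolute values (`mass_kg`, `I_*_kg_m2`).
#' @export
segment_fraction_table <- function(model, labels, axes) {
  stopifnot(inherits(model, "mass_model"), inherits(labels, "label_volume"))
  if (!all(c("roll", "pitch", "yaw") %in% names(axes)))
    stop("`axes` must name roll, pitch and yaw axis_specs", call. = FALSE)
  if (is.null(model$index))
    stop("model carries no voxel indices; build it with build_mass_model()",
         call. = FALSE)
  lab <- as.integer(labels$labels)[model$index]
  ids <- sort(unique(lab))
  grp <- match(lab, ids)
  nm <- ifelse(ids == 0L, "unassigned",
               unname(labels$segment_names[as.character(ids)]))
  out <- data.frame(segment = nm, label = ids,
                    mass_kg = compensated_group_sum(model$masses, grp, length(ids)),
                    stringsAsFactors = FALSE)
  for (ax in c("roll", "pitch", "yaw")) {
    contrib <- model$masses * perp_dist2(model$coords, axes[[ax]])
    out[[paste0("I_", ax, "_kg_m2")]] <-
      compensated_group_sum(contrib, grp, length(ids))
  }
  out$mass_fraction <- out$mass_kg / sum(out$mass_kg)
  for (ax in c("roll", "pitch", "yaw")) {
    col <- paste0("I_", ax, "_kg_m2")
    out[[paste0("I_", ax, "_fraction")]] <- out[[col]] / sum(out[[col]])
  }
  out[order(-out$mass_kg), , drop = FALSE]
}

#' Spanwise roll-MoI profile
#'
#' Bins each element's roll-MoI contribution `m_i d_i^2` by its signed
#' position along the span axis, normalised by the semispan (the maximum
#' absolute span coordinate of retained material, so bins cover [-1, 1]
#' referred to the body centreline through `span_axis`).  Optional group
#' labels (e.g. wings vs body) yield one curve per group plus the total.
#'
#' @param model a [mass_model()].
#' @param span_axis an [axis_spec()] through the body centreline, pointing
#'   spanwise.
#' @param roll_axis an [axis_spec()] about which MoI contributions are taken.
#' @param n_bins number of uniform bins over [-1, 1] (>= 2; default 50).
#' @param group_labels optional character/integer vector, one per element
#'   (e.g. `"wings"`/`"body"`).
#' @return object of class `spanwise_profile`: data.frame `profile` with
#'   `bin_center`, `group`, `value` (kg m^2), plus `semispan` (m).
#' @export
spanwise_profile <- function(model, span_axis, roll_axis, n_bins = 50L,
                             group_labels = NULL) {
  stopifnot(inherits(model, "mass_model"), inherits(span_axis, "axis_spec"),
            inherits(roll_axis, "axis_spec"), n_bins >= 2L)
  r <- sweep(model$coords, 2, span_axis$point)
  s <- as.numeric(r %*% span_axis$direction)
  semispan <- max(abs(s))
  if (semispan == 0)
    stop("degenerate span: all material lies on the centreline plane", call. = FALSE)
  sn <- s / semispan
  contrib <- model$masses * perp_dist2(model$coords, roll_axis)
  edges <- seq(-1, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(sn, edges, rightmost.closed = TRUE), 1L), n_bins)
  groups <- if (is.null(group_labels)) rep("total", length(bin))
            else as.character(group_labels)
  stopifnot(length(groups) == length(bin))
  gl <- sort(unique(groups))
  rows <- do.call(rbind, lapply(gl, function(g) {
    sel <- groups == g
    vals <- compensated_group_sum(contrib[sel], bin[sel], n_bins)
    data.frame(bin_center = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
               group = g, value = vals, stringsAsFactors = FALSE)
  }))
  if (!is.null(group_labels)) {
    tot <- compensated_group_sum(contrib, bin, n_bins)
    rows <- rbind(rows, data.frame(
      bin_center = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
      group = "total", value = tot, stringsAsFactors = FALSE))
  }
  structure(list(profile = rows, semispan = semispan, n_bins = n_bins),
            class = "spanwise_profile")
}

#' @export
print.spanwise_profile <- function(x, ...) {
  tot <- x$profile[x$profile$group == "total", ]
  cat("<spanwise_profile> ", x$n_bins, " bins, semispan ",
      signif(x$semispan, 6), " m, total roll MoI ",
      signif(sum(tot$value), 8), " kg m^2\n", sep = "")
  invisible(x)
}

#' @export
plot.spanwise_profile <- function(x, ...) {
  pr <- x$profile
  gl <- unique(pr$group)
  cols <- seq_along(gl)
  plot(NA, xlim = c(-1, 1), ylim = range(pr$value),
       xlab = "normalised span", ylab = expression(roll ~ MoI ~ (kg ~ m^2)), ...)
  for (i in seq_along(gl)) {
    sub <- pr[pr$group == gl[i], ]
    graphics::lines(sub$bin_center, sub$value, col = cols[i])
  }
  graphics::legend("topright", legend = gl, col = cols, lty = 1, bty = "n")
  invisible(x)
}
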