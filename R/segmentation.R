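#' Threshold a volume into a specimen mask
#'
#' A voxel is retained when its grey-value is at least `threshold` and it is
#' not excluded.  The exclusion mask models the manual removal of scanner
#' parts / mounting board that accompanies thresholding in practice.
#'
#' @param grid a [voxel_grid()] of grey-values.
#' @param threshold grey units.
#' @param exclusion_mask optional logical/integer array (or [label_volume()])
#'   of voxels to drop regardless of grey-value (nonzero = excluded).
#' @return logical array, same shape as the volume.  An all-`FALSE` mask is
#'   permitted.
#' @export
apply_threshold <- function(grid, threshold, exclusion_mask = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  mask <- grid$values >= threshold
  if (!is.null(exclusion_mask)) {
    ex <- if (inherits(exclusion_mask, "label_volume")) exclusion_mask$labels
          else exclusion_mask
    if (!identical(dim(ex), dim(grid$values)))
      stop("exclusion mask shape does not match the volume", call. = FALSE)
    mask <- mask & !(ex != 0)
  }
  mask
}

# calibrated specimen mass (kg) at a threshold; negative densities clamped
mass_at_threshold <- function(grid, cal, threshold, exclusion_mask = NULL,
                              count_clamped = FALSE) {
  mask <- apply_threshold(grid, threshold, exclusion_mask)
  rho <- cal$slope * grid$values[mask] + cal$intercept
  ncl <- sum(rho < 0)
  rho[rho < 0] <- 0
  m <- compensated_sum(rho) * voxel_volume_m3(grid)
  if (count_clamped) list(mass = m, n_voxels = sum(mask), n_clamped = ncl)
  else m
}

#' Optimise the specimen threshold against the measured mass
#'
#' Finds the grey-value threshold at which the calibrated mass estimate (sum
#' of retained voxel masses, negative calibrated densities clamped to zero)
#' matches the balance-measured specimen mass.  Because retained voxel masses
#' are non-negative, estimated mass is non-increasing in the threshold, and
#' the search is a deterministic bisection over the candidate grey levels;
#' should a non-monotone evaluation nevertheless be detected (possible only
#' with exotic calibrations), the search falls back to a full scan over the
#' candidate levels minimising `|mass error|`.
#'
#' @param grid a [voxel_grid()] of grey-values.
#' @param cal a [fit_calibration()] result.
#' @param target_mass measured specimen mass, kg (> 0).
#' @param bounds length-2 grey-value interval to search.
#' @param tolerance mass tolerance, kg.  Default 1e-4 kg (0.1 g, the
#'   resolution of the laboratory balance).
#' @param exclusion_mask as in [apply_threshold()].
#' @param integer_levels restrict candidate thresholds to integer grey
#'   levels (default) or to the distinct grey-values present in `bounds`.
#' @return object of class `threshold_result`: `threshold`,
#'   `estimated_mass`, `target_mass`, `mass_error` (estimated - target),
#'   `n_voxels_retained`, `n_clamped`, `iterations`, `mask`.
#' @export
optimise_threshold <- function(grid, cal, target_mass, bounds,
                               tolerance = 1e-4, exclusion_mask = NULL,
                               integer_levels = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(cal, "density_calibration"))
  if (!is.numeric(target_mass) || target_mass <= 0)
    stop("target_mass must be > 0", call. = FALSE)
  if (length(bounds) != 2L || bounds[1L] >= bounds[2L])
    stop("bounds must be a nonempty grey-value interval", call. = FALSE)

  levels <- if (integer_levels)
    seq(ceiling(bounds[1L]), floor(bounds[2L]))
  else sort(unique(c(bounds, as.numeric(grid$values[
    grid$values >= bounds[1L] & grid$values <= bounds[2L]]))))
  if (length(levels) < 1L)
    stop("bounds contain no candidate threshold levels", call. = FALSE)

  mass_at <- function(t) mass_at_threshold(grid, cal, t, exclusion_mask)
  m_lo <- mass_at(levels[1L]); m_hi <- mass_at(levels[length(levels)])
  if (m_lo < target_mass - tolerance || m_hi > target_mass + tolerance)
    stop(sprintf(paste0("target mass %.6g kg is outside the achievable range: ",
                        "mass at lower bound = %.6g kg, at upper bound = %.6g kg"),
                 target_mass, m_lo, m_hi), call. = FALSE)

  # Bisection probes the bracket midpoint first, so re-running the search
  # with its own solution as the bracket midpoint returns that solution.
  # Bracket endpoints enter as candidates only if the interval collapses.
  lo <- 1L; hi <- length(levels); iter <- 0L
  best_i <- NA_integer_; best_err <- Inf
  monotone_ok <- TRUE
  f_lo <- m_lo; f_hi <- m_hi
  while (hi - lo > 1L && best_err > tolerance) {
    mid <- (lo + hi) %/% 2L
    iter <- iter + 1L
    m_mid <- mass_at(levels[mid])
    if (m_mid > f_lo + 1e-15 * abs(f_lo) || m_mid < f_hi - 1e-15 * abs(f_hi))
      monotone_ok <- FALSE
    err <- abs(m_mid - target_mass)
    if (err < best_err || (err == best_err && mid < best_i)) {
      best_i <- mid; best_err <- err
    }
    if (m_mid >= target_mass) { lo <- mid; f_lo <- m_mid } else { hi <- mid; f_hi <- m_mid }
  }
  if (best_err > tolerance) {
    # interval collapsed: the bracket endpoints compete too (ties -> lower)
    for (cand in c(hi, lo)) {
      err <- abs((if (cand == lo) f_lo else f_hi) - target_mass)
      if (err < best_err || (err == best_err && cand < best_i)) {
        best_i <- cand; best_err <- err
      }
    }
  }
  if (iter == 0L) iter <- 1L

  if (!monotone_ok) {
    warning("non-monotone mass-vs-threshold curve detected; ",
            "falling back to a full scan over candidate levels")
    masses <- vapply(levels, mass_at, 0)
    best_i <- which.min(abs(masses - target_mass))
    best_err <- abs(masses[best_i] - target_mass)
    iter <- iter + length(levels)
  }

  thr <- levels[best_i]
  fin <- mass_at_threshold(grid, cal, thr, exclusion_mask, count_clamped = TRUE)
  if (fin$n_clamped > 0)
    message(fin$n_clamped,
            " retained voxel(s) had negative calibrated density; clamped to zero mass")
  structure(list(threshold = thr, estimated_mass = fin$mass,
                 target_mass = target_mass,
                 mass_error = fin$mass - target_mass,
                 n_voxels_retained = fin$n_voxels, n_clamped = fin$n_clamped,
                 iterations = iter,
                 mask = apply_threshold(grid, thr, exclusion_mask)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result>\n")
  cat(sprintf("  threshold        %.6g grey units\n", x$threshold))
  cat(sprintf("  estimated mass   %.6f kg  (target %.6f kg, error %+.3g g)\n",
              x$estimated_mass, x$target_mass, 1000 * x$mass_error))
  cat(sprintf("  voxels retained  %d   iterations %d\n",
              x$n_voxels_retained, x$iterations))
  invisible(x)
}

#' Virtual dissection: per-segment mass table
#'
#' Sums voxel masses per anatomical label.  Retained voxels with label 0 are
#' reported as segment `"unassigned"`.  Per-segment sums use compensated
#' summation with the same accumulation contract as the total, so segment
#' masses plus unassigned mass equal the model's total mass to machine
#' precision.
#'
#' @param model a [build_mass_model()] result.
#' @param labels a [label_volume()] aligned with the grid the model was
#'   built from.
#' @return data.frame with columns `segment`, `mass_kg`, `mass_fraction`,
#'   `n_voxels`, ordered by decreasing mass.
#' @export
virtual_dissect <- function(model, labels) {
  stopifnot(inherits(model, "mass_model"), inherits(labels, "label_volume"))
  if (!identical(dim(labels$labels), model$grid_dim))
    stop("label volume shape does not match the mass model's source grid",
         call. = FALSE)
  lab <- as.integer(labels$labels)[model$index]
  ids <- sort(unique(lab))
  # map labels to consecutive group ids for the compensated group sum
  grp <- match(lab, ids)
  masses <- compensated_group_sum(model$masses, grp, length(ids))
  counts <- tabulate(grp, length(ids))
  names <- ifelse(ids == 0L, "unassigned",
                  unname(labels$segment_names[as.character(ids)]))
  total <- model$total_mass
  out <- data.frame(segment = names, label = ids, mass_kg = masses,
                    mass_fraction = masses / total, n_voxels = counts,
                    stringsAsFactors = FALSE)
  out[order(-out$mass_kg), , drop = FALSE]
}
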