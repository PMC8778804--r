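#' Read a CT volume from an ordered 16-bit TIFF stack
#'
#' Slices are stacked in the order given; grey-values are preserved
#' bit-exactly (no intensity rescaling).  Spacing and origin are supplied by
#' the caller since TIFF carries no reliable 3D geometry.
#'
#' @param paths character vector of TIFF file paths, one slice each, in order.
#' @param spacing numeric length-3, mm per voxel along (slice, row, col).
#' @param origin numeric length-3, mm. Default `c(0, 0, 0)`.
#' @return a [voxel_grid()] with `dim = c(length(paths), rows, cols)`.
#' @export
read_tiff_stack <- function(paths, spacing, origin = c(0, 0, 0)) {
  if (length(paths) == 0L)
    stop("empty path list: at least one TIFF slice is required", call. = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing TIFF file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  slices <- lapply(paths, tiff::readTIFF, as.is = TRUE)
  dims <- vapply(slices, function(s) dim(s)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("dimension mismatch across slices: all slices must share identical ",
         "2D dimensions", call. = FALSE)
  vol <- array(0L, dim = c(length(slices), dims[1, 1], dims[2, 1]))
  for (s in seq_along(slices)) vol[s, , ] <- slices[[s]]
  voxel_grid(vol, spacing = spacing, origin = origin)
}

#' Write a volume as a 16-bit TIFF stack
#'
#' Companion to [read_tiff_stack()]; values must be integers in
#' `[0, 65535]`.  Also used to serialize label volumes and masks.
#'
#' @param grid a [voxel_grid()], or a rank-3 integer array.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; slices are written as
#'   `<prefix>_0001.tif`, ...
#' @return invisibly, the vector of written paths.
#' @export
write_tiff_stack <- function(grid, dir, prefix = "slice") {
  values <- if (inherits(grid, "voxel_grid")) grid$values else grid
  if (min(values) < 0 || max(values) > 65535 || any(values != round(values)))
    stop("values must be integers in [0, 65535] for 16-bit TIFF", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(values)[1L]
  paths <- file.path(dir, sprintf("%s_%04d.tif", prefix, seq_len(n)))
  for (s in seq_len(n))
    tiff::writeTIFF(matrix(values[s, , ] / 65535,
                           nrow = dim(values)[2L], ncol = dim(values)[3L]),
                    paths[s], bits.per.sample = 16L)
  invisible(paths)
}

#' Write an inertial-properties report
#'
#' Serializes an [inertial_properties()] object (and optionally a segment
#' table) to a machine-readable JSON report plus a CSV segment table.  Values
#' round-trip losslessly to 15 significant digits via [read_results()].
#'
#' @param props an `inertial_properties` object.
#' @param segments optional segment table (data.frame as returned by
#'   [virtual_dissect()]); written as `<path>_segments.csv`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_results <- function(props, segments = NULL, path) {
  stopifnot(inherits(props, "inertial_properties"))
  if (!all(is.finite(props$tensor)))
    stop("non-finite inertial properties cannot be serialized", call. = FALSE)
  rep <- list(
    mass_kg = props$mass,
    com_m = as.numeric(props$com),
    origin_m = as.numeric(props$origin),
    tensor_kg_m2 = matrix_to_rows(props$tensor),
    principal_moments_kg_m2 = as.numeric(props$principal_moments),
    principal_axes = matrix_to_rows(props$principal_axes),
    segments = if (is.null(segments)) list() else
      lapply(seq_len(nrow(segments)), function(i) as.list(segments[i, ]))
  )
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(segments) && nrow(segments))
    utils::write.csv(segments,
                     sub("\\.json$", "", path) |> paste0("_segments.csv"),
                     row.names = FALSE)
  invisible(path)
}

matrix_to_rows <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))

rows_to_matrix <- function(rows) do.call(rbind, lapply(rows, as.numeric))

#' Read back a report written by [write_results()]
#' @param path JSON path.
#' @return an `inertial_properties` object with a `segments` attribute
#'   (data.frame, possibly empty).
#' @export
read_results <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = FALSE)
  props <- structure(list(
    mass = as.numeric(rep$mass_kg),
    com = as.numeric(unlist(rep$com_m)),
    origin = as.numeric(unlist(rep$origin_m)),
    tensor = rows_to_matrix(rep$tensor_kg_m2),
    principal_moments = as.numeric(unlist(rep$principal_moments_kg_m2)),
    principal_axes = rows_to_matrix(rep$principal_axes)
  ), class = "inertial_properties")
  segs <- if (length(rep$segments))
    do.call(rbind, lapply(rep$segments, function(s) as.data.frame(s)))
  else data.frame()
  attr(props, "segments") <- segs
  props
}
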