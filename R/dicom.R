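#' Read a CT volume from a DICOM series
#'
#' Minimal reader for uncompressed single-frame CT series in explicit or
#' implicit VR little-endian transfer syntax.  Slices are sorted by their
#' position along the slice direction regardless of file-name order, the
#' rescale slope/intercept is applied so values are in the scanner's output
#' units, and spacing/origin are taken from the series metadata
#' (PixelSpacing, slice positions).
#'
#' The grid's world frame is aligned with the array axes: axis 1 is the
#' slice direction with origin at the corner of the first voxel; in-plane
#' axes start at the corner of the first pixel.  Full patient-frame
#' orientation handling (oblique acquisitions) is out of scope.
#'
#' @param directory path containing exactly one DICOM series.
#' @return a [voxel_grid()].
#' @export
read_dicom_series <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  files <- Filter(is_dicom_file, files)
  if (!length(files)) stop("no DICOM files found in ", directory, call. = FALSE)
  slices <- lapply(files, read_dicom_file)

  uids <- vapply(slices, function(s) s$series_uid %||% "", "")
  if (length(unique(uids)) > 1L)
    stop("ambiguous input: directory contains ", length(unique(uids)),
         " distinct series", call. = FALSE)

  rows <- slices[[1]]$rows; cols <- slices[[1]]$cols
  ps <- slices[[1]]$pixel_spacing
  if (is.null(rows) || is.null(cols) || is.null(ps))
    stop("missing spatial metadata (Rows/Columns/PixelSpacing)", call. = FALSE)

  pos <- vapply(slices, function(s) {
    if (!is.null(s$position)) s$position[3L]
    else if (!is.null(s$slice_location)) s$slice_location else NA_real_
  }, 0)
  if (length(slices) > 1L && anyNA(pos))
    stop("missing spatial metadata (slice positions)", call. = FALSE)
  ord <- if (anyNA(pos)) seq_along(slices) else order(pos)
  slices <- slices[ord]; pos <- pos[ord]

  dz <- if (length(slices) > 1L) {
    steps <- diff(pos)
    if (any(steps <= 0)) stop("duplicate or unsorted slice positions", call. = FALSE)
    mean(steps)
  } else slices[[1]]$spacing_between %||% slices[[1]]$slice_thickness %||% 1

  vol <- array(0, dim = c(length(slices), rows, cols))
  for (s in seq_along(slices)) {
    sl <- slices[[s]]
    px <- sl$pixel * (sl$rescale_slope %||% 1) + (sl$rescale_intercept %||% 0)
    vol[s, , ] <- matrix(px, nrow = rows, ncol = cols, byrow = TRUE)
  }
  z0 <- if (anyNA(pos)) 0 else pos[1L]
  voxel_grid(vol, spacing = c(dz, ps[1L], ps[2L]),
             origin = c(z0 - dz / 2, 0, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_dicom_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 132L)
  length(hdr) == 132L && rawToChar(hdr[129:132]) == "DICM"
}

u16 <- function(raw, at) readBin(raw[at + 0:1], "integer", size = 2,
                                 endian = "little", signed = FALSE)
u32 <- function(raw, at) {
  v <- readBin(raw[at + 0:3], "integer", size = 4, endian = "little")
  if (v < 0) v + 2^32 else v
}

# Parse one DICOM file into the handful of attributes the reader needs.
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (rawToChar(raw[129:132]) != "DICM")
    stop(path, ": not a DICOM part-10 file", call. = FALSE)
  pos <- 133L
  explicit <- TRUE
  meta_end <- Inf
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

  while (pos + 7L <= length(raw) + 1L && pos <= length(raw)) {
    group <- u16(raw, pos); elem <- u16(raw, pos + 2L)
    in_meta <- group == 0x0002
    use_explicit <- in_meta || explicit
    if (use_explicit) {
      vr <- rawToChar(raw[pos + 4:5])
      if (vr %in% long_vrs) {
        len <- u32(raw, pos + 8L); hdr <- 12L
      } else {
        len <- u16(raw, pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_; len <- u32(raw, pos + 4L); hdr <- 8L
    }
    if (len == 2^32 - 1)
      stop(path, ": undefined-length element unsupported", call. = FALSE)
    val_at <- pos + hdr
    value <- raw[val_at + seq_len(len) - 1L]
    tag <- sprintf("%04X%04X", group, elem)

    str_val <- function() trimws(rawToChar(value))
    ds_val <- function() as.numeric(strsplit(str_val(), "\\\\")[[1]])
    us_val <- function() u16(value, 1L)

    if (tag == "00020010") {
      ts <- str_val()
      explicit <- ts != "1.2.840.10008.1.2"  # implicit VR little endian
      if (!(ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")))
        stop(path, ": unsupported transfer syntax ", ts, call. = FALSE)
    } else if (tag == "0020000E") out$series_uid <- str_val()
    else if (tag == "00200032") out$position <- ds_val()
    else if (tag == "00201041") out$slice_location <- ds_val()[1L]
    else if (tag == "00280010") out$rows <- us_val()
    else if (tag == "00280011") out$cols <- us_val()
    else if (tag == "00280030") out$pixel_spacing <- ds_val()
    else if (tag == "00180050") out$slice_thickness <- ds_val()[1L]
    else if (tag == "00180088") out$spacing_between <- ds_val()[1L]
    else if (tag == "00280100") out$bits_allocated <- us_val()
    else if (tag == "00280103") out$pixel_representation <- us_val()
    else if (tag == "00281052") out$rescale_intercept <- ds_val()[1L]
    else if (tag == "00281053") out$rescale_slope <- ds_val()[1L]
    else if (tag == "7FE00010") {
      bits <- out$bits_allocated %||% 16L
      signed <- isTRUE(out$pixel_representation == 1L)
      n <- len %/% (bits %/% 8L)
      px <- readBin(value, "integer", n = n, size = bits %/% 8L,
                    endian = "little", signed = signed || bits == 32L)
      if (!signed && bits == 16L) px[px < 0] <- px[px < 0] + 65536
      out$pixel <- px
    }
    pos <- val_at + len
  }
  if (is.null(out$pixel)) stop(path, ": no PixelData element", call. = FALSE)
  out
}
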