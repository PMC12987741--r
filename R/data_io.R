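#' Read a 4D dynamic PET series from NIfTI
#'
#' NIfTI headers do not reliably carry the frame duration, so it can be
#' given explicitly; otherwise a JSON sidecar (same basename, `.json`
#' extension, field `frame_duration`) is consulted, and finally the header's
#' fourth pixdim if positive.
#'
#' @param path Path to a 4D NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param frame_duration Frame length in seconds; overrides sidecar/header.
#' @return A [dynamic_series()].
#' @export
read_dynamic_series <- function(path, frame_duration = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected 4D NIfTI, got ", length(d), "D image: ", path,
         call. = FALSE)
  pd <- RNifti::pixdim(img)
  if (is.null(frame_duration)) {
    sc <- sidecar_path(path)
    if (file.exists(sc)) {
      frame_duration <- jsonlite::read_json(sc)$frame_duration
      if (is.null(frame_duration))
        stop("sidecar ", sc, " lacks a frame_duration field", call. = FALSE)
    } else if (length(pd) >= 4L && is.finite(pd[4L]) && pd[4L] > 0) {
      frame_duration <- pd[4L]
    } else {
      stop("frame_duration not supplied and not recoverable from sidecar ",
           "or header for ", path, call. = FALSE)
    }
  }
  if (frame_duration <= 0)
    stop("frame_duration must be positive, got ", frame_duration,
         call. = FALSE)
  dynamic_series(array(as.numeric(img), dim = d), frame_duration,
                 spatial_zoom = abs(pd[1:3]), affine = RNifti::xform(img))
}

#' Write a dynamic PET series as NIfTI (double precision) plus JSON sidecar
#'
#' @param series A [dynamic_series()].
#' @param path Output path (`.nii` or `.nii.gz`). A sidecar JSON carrying
#'   the frame duration is written next to it.
#' @return `path`, invisibly.
#' @export
write_dynamic_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  img <- RNifti::asNifti(series$data, internal = FALSE)
  RNifti::pixdim(img) <- c(series$spatial_zoom, series$frame_duration)
  RNifti::writeNifti(RNifti::asNifti(img, datatype = "double"), path)
  jsonlite::write_json(list(frame_duration = series$frame_duration),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read rigid-body motion parameters from text
#'
#' Whitespace-delimited text with T rows and 6 numeric columns in the usual
#' realignment order: translations x, y, z (mm) then rotations x, y, z.
#' Rotations are radians by default; set `degrees = TRUE` to convert.
#'
#' @param path Path to the text file.
#' @param frame_duration Frame length in seconds.
#' @param degrees Logical; if `TRUE` the rotation columns are converted from
#'   degrees to radians on read.
#' @return A [motion_trace()].
#' @export
read_motion_trace <- function(path, frame_duration = 1, degrees = FALSE) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = FALSE,
                           colClasses = "character")
  if (ncol(tab) != 6L)
    stop("motion trace must have 6 columns, found ", ncol(tab), " in ",
         path, call. = FALSE)
  m <- suppressWarnings(apply(as.matrix(tab), 2, as.numeric))
  m <- matrix(m, nrow = nrow(tab))
  if (any(is.na(m)))
    stop("non-numeric token(s) in motion trace ", path, call. = FALSE)
  if (degrees) m[, 4:6] <- m[, 4:6] * pi / 180
  motion_trace(m, frame_duration)
}

#' Write a motion trace as whitespace-delimited text
#'
#' @param motion A [motion_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion_trace <- function(motion, path) {
  stopifnot(inherits(motion, "motion_trace"))
  fmt <- apply(motion$params, c(1, 2), function(v) sprintf("%.15g", v))
  utils::write.table(fmt, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a parcellation (integer NIfTI label volume + TSV region table)
#'
#' @param label_path Path to an integer-valued 3D NIfTI volume.
#' @param table_path Path to a TSV with header columns `label`, `name`,
#'   `network`.
#' @return A [parcel_map()].
#' @export
read_parcellation <- function(label_path, table_path) {
  for (p in c(label_path, table_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  img <- RNifti::readNifti(label_path)
  if (length(dim(img)) != 3L)
    stop("label volume must be 3D: ", label_path, call. = FALSE)
  vals <- array(as.numeric(img), dim = dim(img))
  if (any(vals != round(vals)))
    stop("label volume contains non-integer values: ", label_path,
         call. = FALSE)
  tab <- utils::read.delim(table_path, check.names = FALSE)
  parcel_map(vals, tab)
}

#' Write a parcellation as NIfTI + TSV
#'
#' @param parcels A [parcel_map()].
#' @param label_path Output NIfTI path for the label volume.
#' @param table_path Output TSV path for the region table.
#' @return `label_path`, invisibly.
#' @export
write_parcellation <- function(parcels, label_path, table_path) {
  stopifnot(inherits(parcels, "parcel_map"))
  img <- RNifti::asNifti(parcels$labels, datatype = "int32")
  RNifti::writeNifti(img, label_path)
  utils::write.table(parcels$region_table, table_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(label_path)
}

#' Write a connectivity matrix as TSV
#'
#' The full matrix is stored (not just a triangle) for human readability,
#' with region ids as header row and first column, at 17 significant digits
#' so a read-back reproduces values to better than 1e-12.
#'
#' @param matrix A [connectivity_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(matrix, path) {
  if (!inherits(matrix, "connectivity_matrix"))
    stop("write_connectivity expects a connectivity_matrix ",
         "(invalid matrices are rejected at construction)", call. = FALSE)
  ids <- as.character(matrix$region_ids)
  body <- apply(matrix$values, c(1, 2), function(v) sprintf("%.17g", v))
  lines <- c(paste(c("region", ids), collapse = "\t"),
             vapply(seq_along(ids), function(i)
               paste(c(ids[i], body[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectivity()]
#'
#' @param path TSV path.
#' @param method Estimator tag to record on the result.
#' @param band Optional [frequency_band()] to record.
#' @return A [connectivity_matrix()].
#' @export
read_connectivity <- function(path, method = "pearson", band = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  ids <- names(tab)[-1L]
  m <- apply(as.matrix(tab[, -1L, drop = FALSE]), c(1, 2), as.numeric)
  connectivity_matrix(m, region_ids = ids, method = method, band = band)
}
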