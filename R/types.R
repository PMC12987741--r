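#' Dynamic PET series
#'
#' Container for a 4D dynamic PET acquisition: one volume per frame at a
#' fixed frame duration. All filters in the package consume and produce this
#' type. Frame onsets mark the *start* of each frame in seconds and must be
#' evenly spaced at the frame duration.
#'
#' @param data 4D numeric array (x, y, z, frame), arbitrary activity units.
#' @param frame_duration Frame length in seconds (> 0).
#' @param frame_onsets Optional onset times in seconds (length `n_frames`,
#'   strictly increasing, spacing equal to `frame_duration`). Defaults to
#'   `(0:(n_frames-1)) * frame_duration`.
#' @param spatial_zoom Voxel size in mm along each spatial axis (length 3).
#' @param affine Opaque orientation metadata passed through unchanged (for
#'   example the xform of a source NIfTI image); never interpreted.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, frame_duration, frame_onsets = NULL,
                           spatial_zoom = c(1, 1, 1), affine = NULL) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 4L)
    stop("expected 4D data (x, y, z, frame), got ",
         length(dim(data)), " dimensions", call. = FALSE)
  if (!all(is.finite(data)))
    stop("dynamic series contains non-finite values", call. = FALSE)
  nt <- dim(data)[4L]
  if (nt < 2L)
    stop("a dynamic series needs at least 2 frames, got ", nt, call. = FALSE)
  if (!is.numeric(frame_duration) || length(frame_duration) != 1L ||
      !is.finite(frame_duration) || frame_duration <= 0)
    stop("frame_duration must be a single positive number (seconds)",
         call. = FALSE)
  if (is.null(frame_onsets))
    frame_onsets <- (seq_len(nt) - 1) * frame_duration
  if (length(frame_onsets) != nt)
    stop("frame_onsets must have one entry per frame", call. = FALSE)
  sp <- diff(frame_onsets)
  if (any(sp <= 0) || any(abs(sp - frame_duration) > 1e-6 * frame_duration))
    stop("frame_onsets must increase in steps of frame_duration",
         call. = FALSE)
  if (length(spatial_zoom) != 3L || any(!is.finite(spatial_zoom)) ||
      any(spatial_zoom <= 0))
    stop("spatial_zoom must be three positive voxel sizes (mm)",
         call. = FALSE)
  structure(list(data = data, frame_duration = frame_duration,
                 frame_onsets = as.numeric(frame_onsets),
                 spatial_zoom = as.numeric(spatial_zoom), affine = affine),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_series> %dx%dx%d voxels, %d frames of %g s (%g-%g s)\n",
              d[1], d[2], d[3], d[4], x$frame_duration,
              x$frame_onsets[1], x$frame_onsets[d[4]]))
  invisible(x)
}

n_frames <- function(series) dim(series$data)[4L]

# voxels-by-frames view of the 4D array (column-major voxel order)
series_matrix <- function(series) {
  d <- dim(series$data)
  matrix(series$data, prod(d[1:3]), d[4L])
}

#' Tissue probability map
#'
#' A 3D map of per-voxel probabilities for one tissue class (gray matter,
#' white matter or CSF), on the same grid as the dynamic series it
#' accompanies.
#'
#' @param prob 3D array with values in `[0, 1]`.
#' @param tissue_class One of `"GM"`, `"WM"`, `"CSF"`.
#' @param spatial_zoom Voxel size in mm (length 3).
#' @param affine Opaque orientation metadata, passed through.
#' @return An object of class `tissue_probability_map`.
#' @export
tissue_probability_map <- function(prob, tissue_class = c("GM", "WM", "CSF"),
                                   spatial_zoom = c(1, 1, 1), affine = NULL) {
  tissue_class <- match.arg(tissue_class)
  prob <- unclass(prob)
  attributes(prob) <- list(dim = dim(prob))
  if (length(dim(prob)) != 3L)
    stop("tissue probability map must be a 3D array", call. = FALSE)
  if (!all(is.finite(prob)) || min(prob) < 0 || max(prob) > 1)
    stop("tissue probabilities must be finite and within [0, 1]",
         call. = FALSE)
  structure(list(prob = prob, tissue_class = tissue_class,
                 spatial_zoom = as.numeric(spatial_zoom), affine = affine),
            class = "tissue_probability_map")
}

#' Rigid-body motion trace
#'
#' Realignment parameters, one row per frame: three translations in mm
#' followed by three rotations in radians.
#'
#' @param params T-by-6 numeric matrix.
#' @param frame_duration Frame length in seconds.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(params, frame_duration) {
  params <- as.matrix(params)
  if (ncol(params) != 6L)
    stop("motion trace must have 6 columns (3 translations, 3 rotations), ",
         "found ", ncol(params), call. = FALSE)
  if (!all(is.finite(params)))
    stop("motion trace contains non-finite values", call. = FALSE)
  if (!is.numeric(frame_duration) || frame_duration <= 0)
    stop("frame_duration must be positive", call. = FALSE)
  dimnames(params) <- list(NULL,
    c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z"))
  structure(list(params = params, frame_duration = frame_duration),
            class = "motion_trace")
}

#' Frequency band
#'
#' A half-open analysis band in Hz. Validity against a particular sampling
#' rate (upper edge at or below Nyquist) is checked at the point of use,
#' since the same band object may be applied to series with different frame
#' durations.
#'
#' @param low Lower edge in Hz (>= 0).
#' @param high Upper edge in Hz (> `low`).
#' @return An object of class `frequency_band`.
#' @export
frequency_band <- function(low, high) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || !is.finite(low) || !is.finite(high))
    stop("band edges must be single finite numbers (Hz)", call. = FALSE)
  if (low < 0 || high <= low)
    stop("need 0 <= low < high, got [", low, ", ", high, "] Hz",
         call. = FALSE)
  structure(list(low = low, high = high), class = "frequency_band")
}

#' @export
format.frequency_band <- function(x, ...)
  sprintf("%g-%g Hz", x$low, x$high)

# stop unless band upper edge is at or below the Nyquist frequency
check_band_nyquist <- function(band, frame_duration, strict = FALSE) {
  ny <- 1 / (2 * frame_duration)
  if (band$high > ny + 1e-12 || (strict && band$high >= ny - 1e-12))
    stop("band upper edge ", band$high, " Hz exceeds ",
         if (strict) "(or reaches) " else "",
         "the Nyquist frequency ", ny, " Hz at frame duration ",
         frame_duration, " s", call. = FALSE)
  invisible(ny)
}

#' Parcellation map
#'
#' Integer-labeled volume (0 = background) plus a region table with one row
#' per label: `label`, `name`, `network`. Labels are matched by value, never
#' by index, so the volume orientation is pass-through.
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @param region_table data.frame with columns `label`, `name`, `network`.
#' @return An object of class `parcel_map`.
#' @export
parcel_map <- function(labels, region_table) {
  labels <- unclass(labels)
  attributes(labels) <- list(dim = dim(labels))
  if (length(dim(labels)) != 3L)
    stop("label volume must be 3D", call. = FALSE)
  if (any(!is.finite(labels)) || any(labels != round(labels)) ||
      any(labels < 0))
    stop("labels must be non-negative integers", call. = FALSE)
  need <- c("label", "name", "network")
  if (!all(need %in% names(region_table)))
    stop("region table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(region_table$label))
    stop("duplicate label(s) in region table: ",
         paste(unique(region_table$label[duplicated(region_table$label)]),
               collapse = ", "), call. = FALSE)
  present <- sort(unique(labels[labels > 0]))
  if (length(present) == 0L)
    stop("no parcels: label volume contains only background", call. = FALSE)
  missing <- setdiff(present, region_table$label)
  if (length(missing))
    stop("label(s) present in volume but absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- !(region_table$label %in% present)
  if (any(extra)) {
    warning("dropping ", sum(extra),
            " table row(s) with labels absent from the volume")
    region_table <- region_table[!extra, , drop = FALSE]
  }
  region_table <- region_table[order(region_table$label), , drop = FALSE]
  rownames(region_table) <- NULL
  structure(list(labels = labels, region_table = region_table),
            class = "parcel_map")
}

#' Regional mean time series
#'
#' R-by-T matrix of parcel-mean signals, the input to all connectivity
#' estimators. Frame onsets need not be contiguous (split-half analysis
#' subsets frames), only strictly increasing.
#'
#' @param values R-by-T numeric matrix (regions by frames).
#' @param region_ids Identifiers, length R.
#' @param frame_duration Frame length in seconds.
#' @param frame_onsets Onset times, length T, strictly increasing.
#' @return An object of class `region_timeseries`.
#' @export
region_timeseries <- function(values, region_ids, frame_duration,
                              frame_onsets = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 regions and 2 frames, got ",
         nrow(values), "x", ncol(values), call. = FALSE)
  if (!all(is.finite(values)))
    stop("regional time series contain non-finite values", call. = FALSE)
  if (length(region_ids) != nrow(values))
    stop("region_ids length must match the number of rows", call. = FALSE)
  if (is.null(frame_onsets))
    frame_onsets <- (seq_len(ncol(values)) - 1) * frame_duration
  if (length(frame_onsets) != ncol(values) || any(diff(frame_onsets) <= 0))
    stop("frame_onsets must be strictly increasing, one per frame",
         call. = FALSE)
  structure(list(values = values, region_ids = region_ids,
                 frame_duration = frame_duration,
                 frame_onsets = as.numeric(frame_onsets)),
            class = "region_timeseries")
}

# frame subset preserving absolute onsets; indices must be ascending
subset_frames <- function(regions, idx) {
  region_timeseries(regions$values[, idx, drop = FALSE], regions$region_ids,
                    regions$frame_duration, regions$frame_onsets[idx])
}

#' Connectivity matrix
#'
#' Symmetric R-by-R correlation matrix with unit diagonal; the unit of
#' comparison for all network statistics. Construction enforces symmetry to
#' within 1e-12, an exactly-unit diagonal and off-diagonal values in
#' `[-1, 1]`.
#'
#' @param values R-by-R numeric matrix.
#' @param region_ids Identifiers, length R.
#' @param method Estimator that produced the matrix: `"pearson"` or
#'   `"partial"`.
#' @param band Optional [frequency_band()] the matrix refers to.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, region_ids = NULL,
                                method = c("pearson", "partial"),
                                band = NULL) {
  method <- match.arg(method)
  values <- as.matrix(values)
  r <- nrow(values)
  if (r != ncol(values) || r < 2L)
    stop("connectivity matrix must be square with at least 2 regions",
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("connectivity matrix contains non-finite values", call. = FALSE)
  asym <- max(abs(values - t(values)))
  if (asym > 1e-12)
    stop("connectivity matrix is asymmetric (max |A - t(A)| = ",
         format(asym, digits = 3), ")", call. = FALSE)
  values <- (values + t(values)) / 2
  if (max(abs(diag(values) - 1)) > 1e-8)
    stop("connectivity matrix diagonal must equal 1", call. = FALSE)
  off <- values[row(values) != col(values)]
  if (length(off) && (min(off) < -1 - 1e-12 || max(off) > 1 + 1e-12))
    stop("connectivity values must lie in [-1, 1]", call. = FALSE)
  values <- pmin(pmax(values, -1), 1)
  diag(values) <- 1
  if (is.null(region_ids))
    region_ids <- if (!is.null(rownames(values))) rownames(values)
                  else seq_len(r)
  if (length(region_ids) != r)
    stop("region_ids length must match matrix dimension", call. = FALSE)
  dimnames(values) <- NULL
  if (!is.null(band) && !inherits(band, "frequency_band"))
    stop("band must be a frequency_band or NULL", call. = FALSE)
  structure(list(values = values, region_ids = region_ids, method = method,
                 band = band),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  lt <- lower_triangle(x)
  cat(sprintf("<connectivity_matrix> %d regions, method=%s%s, edges %g..%g (median %g)\n",
              nrow(x$values), x$method,
              if (!is.null(x$band)) paste0(", band ", format(x$band)) else "",
              round(min(lt), 3), round(max(lt), 3),
              round(stats::median(lt), 3)))
  invisible(x)
}

#' Lower-triangle vectorization of a connectivity matrix
#'
#' The canonical edge vector used in all matrix comparisons: off-diagonal
#' lower-triangle entries in column-major order.
#'
#' @param x A [connectivity_matrix()] or square matrix.
#' @return Numeric vector of length `R*(R-1)/2`.
#' @export
lower_triangle <- function(x) {
  m <- if (inherits(x, "connectivity_matrix")) x$values else as.matrix(x)
  m[lower.tri(m)]
}

# run code with a private, restored RNG state; NULL seed = use current stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
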