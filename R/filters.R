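#' Remove the nuisance design from time courses in one regression
#'
#' Each time course is replaced by its least-squares residual on the full
#' design (computed by QR), so all confound classes — tissue components,
#' expanded motion, out-of-band frequencies and the cumulative uptake they
#' span — are removed in a unified step. Residuals are orthogonal to every
#' design column and have (near-)zero mean because the design carries an
#' intercept.
#'
#' @param x A [region_timeseries()], [dynamic_series()] or rows-are-series
#'   matrix.
#' @param design A [design_matrix()] with one row per frame.
#' @param ... Passed to methods.
#' @return Object of the same type with cleaned time courses and an
#'   attribute `filter_report` (a `filter_report` list: method, band,
#'   design column count and a summary of the per-series variance-removed
#'   fraction).
#' @export
compcor_residualize <- function(x, design, ...)
  UseMethod("compcor_residualize")

residualize_rows <- function(vals, design) {
  stopifnot(inherits(design, "design_matrix"))
  if (ncol(vals) != nrow(design$values))
    stop("design has ", nrow(design$values), " rows but data has ",
         ncol(vals), " frames", call. = FALSE)
  qrd <- qr(design$values)
  if (qrd$rank < ncol(design$values))
    stop("design matrix is rank deficient", call. = FALSE)
  res <- t(qr.resid(qrd, t(vals)))
  v0 <- rowSums((vals - rowMeans(vals))^2)
  v1 <- rowSums(res^2)
  removed <- ifelse(v0 > 0, pmin(pmax(1 - v1 / v0, 0), 1), 0)
  list(res = res, report = filter_report("compcor", design$band,
                                         ncol(design$values), removed))
}

filter_report <- function(method, band, n_columns, removed) {
  structure(list(method = method, band = band, n_columns = n_columns,
                 variance_removed = summary(removed)),
            class = "filter_report")
}

#' @rdname compcor_residualize
#' @export
compcor_residualize.region_timeseries <- function(x, design, ...) {
  out <- residualize_rows(x$values, design)
  structure(region_timeseries(out$res, x$region_ids, x$frame_duration,
                              x$frame_onsets),
            filter_report = out$report)
}

#' @rdname compcor_residualize
#' @param mask Logical 3D mask of voxels to clean (typically gray matter);
#'   voxels outside the mask are passed through unchanged. `NULL` cleans
#'   every voxel.
#' @export
compcor_residualize.dynamic_series <- function(x, design, mask = NULL,
                                               ...) {
  X <- series_matrix(x)
  sel <- if (is.null(mask)) seq_len(nrow(X)) else which(as.vector(mask))
  if (!length(sel)) stop("empty mask", call. = FALSE)
  out <- residualize_rows(X[sel, , drop = FALSE], design)
  X[sel, ] <- out$res
  structure(dynamic_series(array(X, dim(x$data)), x$frame_duration,
                           x$frame_onsets, x$spatial_zoom, x$affine),
            filter_report = out$report)
}

#' @rdname compcor_residualize
#' @export
compcor_residualize.matrix <- function(x, design, ...) {
  out <- residualize_rows(x, design)
  structure(out$res, filter_report = out$report)
}

#' Zero-phase Butterworth band-pass filter for regional time series
#'
#' Designs an order-`order` Butterworth band-pass (an IIR filter; `2*order`
#' poles after the band transformation) and applies it forward and backward
#' so the net phase is zero — correlation analyses are phase-sensitive.
#' Edges are padded with odd reflection of length three times the filter
#' length before filtering. The signal mean is removed.
#'
#' @param regions A [region_timeseries()].
#' @param band [frequency_band()]; the upper edge must lie strictly below
#'   Nyquist.
#' @param order Filter order of the analog prototype; default 4.
#' @param causal If `TRUE`, apply a single forward pass only.
#' @return Filtered [region_timeseries()] with a `filter_report` attribute.
#' @export
butterworth_bandpass <- function(regions, band, order = 4,
                                 causal = FALSE) {
  stopifnot(inherits(regions, "region_timeseries"),
            inherits(band, "frequency_band"))
  dt <- regions$frame_duration
  check_band_nyquist(band, dt, strict = TRUE)
  ny <- 1 / (2 * dt)
  bf <- signal::butter(order, c(band$low, band$high) / ny, type = "pass")
  pad <- 3L * max(length(bf$a), length(bf$b))
  T <- ncol(regions$values)
  if (T < 3L * pad)
    stop("series of ", T, " frames is shorter than 3x the padding length (",
         3L * pad, ")", call. = FALSE)
  vals <- regions$values
  out <- vals
  for (r in seq_len(nrow(vals))) {
    x <- vals[r, ] - mean(vals[r, ])
    xp <- c(2 * x[1] - x[(pad + 1):2], x,
            2 * x[T] - x[(T - 1):(T - pad)])
    y <- as.numeric(signal::filter(bf, xp))
    if (!causal)
      y <- rev(as.numeric(signal::filter(bf, rev(y))))
    y <- y[(pad + 1):(pad + T)]
    out[r, ] <- y - mean(y)
  }
  v0 <- rowSums((vals - rowMeans(vals))^2)
  removed <- ifelse(v0 > 0, pmin(pmax(1 - rowSums(out^2) / v0, 0), 1), 0)
  structure(region_timeseries(out, regions$region_ids, dt,
                              regions$frame_onsets),
            filter_report = filter_report("butterworth", band,
                                          2L * order, removed))
}

#' Spatial Gaussian smoothing of a dynamic series
#'
#' Per-frame separable 3D Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 log 2))` per axis, converted to voxel units
#' through the stored voxel sizes. Boundaries are reflected, which
#' preserves the frame sum, and `fwhm_mm = 0` is the identity.
#'
#' @param series A [dynamic_series()].
#' @param fwhm_mm Full width at half maximum in mm (>= 0).
#' @return Smoothed [dynamic_series()].
#' @export
gaussian_smooth <- function(series, fwhm_mm) {
  stopifnot(inherits(series, "dynamic_series"))
  if (fwhm_mm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(series)
  if (any(!is.finite(series$spatial_zoom)))
    stop("unknown voxel size", call. = FALSE)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / series$spatial_zoom
  arr <- series$data
  for (axis in 1:3)
    arr <- convolve_axis(arr, reflect_conv_matrix(dim(arr)[axis],
                                                  sigma_vox[axis]), axis)
  dynamic_series(arr, series$frame_duration, series$frame_onsets,
                 series$spatial_zoom, series$affine)
}

# n x n convolution matrix for a normalized Gaussian with mirrored edges
reflect_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in -r:r) {
      j <- i + o
      while (j < 1L || j > n) {       # half-sample mirror: ... 2 1 | 1 2 ...
        if (j < 1L) j <- 1L - j
        if (j > n) j <- 2L * n + 1L - j
      }
      K[i, j] <- K[i, j] + k[o + r + 1L]
    }
  }
  K
}

convolve_axis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  a <- array(K %*% matrix(a, d[axis]), d[perm])
  aperm(a, order(perm))
}

#' Extended dynamic non-local means (edNLM) filter
#'
#' Two sequential spatiotemporal non-local-means passes with 3x3x3-voxel
#' patches spanning three then five frames (the search window equals the
#' patch window), followed by Gaussian smoothing. Weights are
#' `w_ij = exp(-||patch_i - patch_j||^2 / h^2)` normalized to sum to one
#' over the window; patch coordinates are edge-clamped, so a constant
#' series is invariant. This is a generic re-implementation of the
#' spatiotemporal NLM idea with all parameters exposed, not a bit-exact
#' port of any particular toolbox.
#'
#' @param series A [dynamic_series()].
#' @param temporal_frames Temporal patch extents of the sequential passes;
#'   each must be odd and no longer than the series.
#' @param h Bandwidth; `"auto"` sets, per pass, a robust noise sd estimate
#'   (from temporal first differences) times the patch element count.
#' @param fwhm_mm Final Gaussian smoothing in mm; default 5, 0 disables.
#' @return Filtered [dynamic_series()].
#' @export
ednlm_filter <- function(series, temporal_frames = c(3, 5), h = "auto",
                         fwhm_mm = 5) {
  stopifnot(inherits(series, "dynamic_series"))
  if (any(temporal_frames %% 2 != 1))
    stop("temporal kernel extents must be odd", call. = FALSE)
  if (n_frames(series) < max(temporal_frames))
    stop("series (", n_frames(series), " frames) shorter than the ",
         "temporal kernel (", max(temporal_frames), ")", call. = FALSE)
  arr <- series$data
  for (tk in temporal_frames) {
    tr <- (tk - 1L) / 2L
    hh <- if (identical(h, "auto")) auto_bandwidth(arr, tk) else h
    if (!is.numeric(hh) || hh <= 0)
      stop("h must be positive or \"auto\"", call. = FALSE)
    arr <- nlm_pass(arr, tr, hh)
  }
  out <- dynamic_series(arr, series$frame_duration, series$frame_onsets,
                        series$spatial_zoom, series$affine)
  if (fwhm_mm > 0) out <- gaussian_smooth(out, fwhm_mm)
  out
}

auto_bandwidth <- function(arr, tk) {
  d <- abs(apply(arr, 1:3, diff))
  sigma <- 1.4826 * stats::median(d) / sqrt(2)
  n_patch <- 27 * tk
  max(sigma * n_patch, .Machine$double.eps)
}

# one NLM pass; search window = patch window = 3x3x3 x (2*tr+1)
nlm_pass <- function(arr, tr, h) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1,
                                dt = -tr:tr))
  num <- array(0, dim(arr))
  den <- array(0, dim(arr))
  for (i in seq_len(nrow(offs))) {
    S <- shift_clamp(arr, offs[i, ])
    D2 <- box_sum((arr - S)^2, c(1L, 1L, 1L, tr))
    w <- exp(-D2 / h^2)
    num <- num + w * S
    den <- den + w
  }
  num / den
}

shift_clamp <- function(arr, off) {
  d <- dim(arr)
  idx <- lapply(seq_along(d), function(k)
    pmin(pmax(seq_len(d[k]) + off[k], 1L), d[k]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

shift_axis <- function(arr, axis, s) {
  d <- dim(arr)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- pmin(pmax(idx[[axis]] + s, 1L), d[axis])
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

# separable moving sum over a (2*radius+1) window per axis, edge-clamped
box_sum <- function(arr, radii) {
  for (axis in seq_along(radii)) {
    r <- radii[axis]
    if (r == 0L) next
    acc <- arr
    for (s in seq_len(r)) acc <- acc + shift_axis(arr, axis, s) +
        shift_axis(arr, axis, -s)
    arr <- acc
  }
  arr
}

#' Average consecutive frames to a coarser frame duration
#'
#' Non-overlapping blocks of `factor` consecutive frames are averaged;
#' trailing remainder frames are dropped (with a message) and the frame
#' duration is multiplied by `factor`. Used to match a 1 s acquisition to a
#' 3 s one.
#'
#' @param series A [dynamic_series()].
#' @param factor Integer >= 1.
#' @return Downsampled [dynamic_series()].
#' @export
downsample_frames <- function(series, factor) {
  stopifnot(inherits(series, "dynamic_series"))
  if (factor < 1 || factor != round(factor))
    stop("factor must be an integer >= 1", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(series)
  T <- n_frames(series)
  T2 <- T %/% factor
  if (T2 < 2L) stop("too few frames after downsampling", call. = FALSE)
  if (T %% factor != 0L)
    message("dropping ", T %% factor, " trailing frame(s)")
  X <- series_matrix(series)[, seq_len(T2 * factor), drop = FALSE]
  dim(X) <- c(nrow(X), factor, T2)
  Xd <- apply(X, c(1, 3), mean)
  dynamic_series(array(Xd, c(dim(series$data)[1:3], T2)),
                 series$frame_duration * factor,
                 series$frame_onsets[seq(1, T2 * factor, by = factor)],
                 series$spatial_zoom, series$affine)
}

#' Exclude the tracer-equilibration window from the start of a scan
#'
#' Retains only frames whose onset is at or after `t_min` seconds; absolute
#' onset times are preserved so that frequency and timing bookkeeping stay
#' anchored to the acquisition clock.
#'
#' @param x A [dynamic_series()], [region_timeseries()] or [motion_trace()]
#'   (the last needs `onsets` supplied).
#' @param t_min Exclusion threshold in seconds; default 600 (10 min).
#' @param ... Passed to methods.
#' @return Object of the same type with early frames removed.
#' @export
exclude_uptake_window <- function(x, t_min = 600, ...)
  UseMethod("exclude_uptake_window")

#' @export
exclude_uptake_window.dynamic_series <- function(x, t_min = 600, ...) {
  keep <- which(x$frame_onsets >= t_min)
  if (!length(keep)) stop("no frames at or after ", t_min, " s",
                          call. = FALSE)
  if (length(keep) < 2L) stop("fewer than 2 frames retained",
                              call. = FALSE)
  dynamic_series(x$data[, , , keep, drop = FALSE], x$frame_duration,
                 x$frame_onsets[keep], x$spatial_zoom, x$affine)
}

#' @export
exclude_uptake_window.region_timeseries <- function(x, t_min = 600, ...) {
  keep <- which(x$frame_onsets >= t_min)
  if (length(keep) < 2L) stop("no frames at or after ", t_min, " s",
                              call. = FALSE)
  subset_frames(x, keep)
}

#' @rdname exclude_uptake_window
#' @param onsets Frame onsets in seconds for the motion trace.
#' @export
exclude_uptake_window.motion_trace <- function(x, t_min = 600,
                                               onsets = NULL, ...) {
  if (is.null(onsets))
    onsets <- (seq_len(nrow(x$params)) - 1) * x$frame_duration
  keep <- which(onsets >= t_min)
  if (length(keep) < 2L) stop("no frames at or after ", t_min, " s",
                              call. = FALSE)
  motion_trace(x$params[keep, , drop = FALSE], x$frame_duration)
}
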