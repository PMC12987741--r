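#' Extract parcel-mean regional time series
#'
#' Row r of the result is the per-frame mean over voxels carrying label r.
#' Labels are matched by value; regions present in the table but empty in
#' the volume are dropped with a warning.
#'
#' @param series A [dynamic_series()] on the same grid as the parcellation.
#' @param parcels A [parcel_map()].
#' @return A [region_timeseries()] with `region_ids` equal to the labels.
#' @export
extract_regional_timeseries <- function(series, parcels) {
  stopifnot(inherits(series, "dynamic_series"),
            inherits(parcels, "parcel_map"))
  if (!identical(dim(series$data)[1:3], dim(parcels$labels)))
    stop("series grid ", paste(dim(series$data)[1:3], collapse = "x"),
         " does not match parcellation grid ",
         paste(dim(parcels$labels), collapse = "x"), call. = FALSE)
  X <- series_matrix(series)
  lab <- as.vector(parcels$labels)
  ids <- parcels$region_table$label
  rows <- vector("list", length(ids))
  present <- logical(length(ids))
  for (i in seq_along(ids)) {
    vox <- which(lab == ids[i])
    if (!length(vox)) next
    present[i] <- TRUE
    rows[[i]] <- if (length(vox) == 1L) X[vox, ]
                 else colMeans(X[vox, , drop = FALSE])
  }
  if (!any(present))
    stop("no label of the region table overlaps the volume", call. = FALSE)
  if (!all(present))
    warning("dropping region(s) with no voxels: ",
            paste(ids[!present], collapse = ", "))
  region_timeseries(do.call(rbind, rows[present]), ids[present],
                    series$frame_duration, series$frame_onsets)
}

#' Pearson connectivity matrix
#'
#' @param regions A [region_timeseries()] with at least 3 frames and no
#'   constant rows (a constant row has no defined correlation and is
#'   reported by region id).
#' @param band Optional [frequency_band()] recorded on the result.
#' @return A [connectivity_matrix()] with `method = "pearson"`.
#' @export
pearson_connectivity <- function(regions, band = NULL) {
  stopifnot(inherits(regions, "region_timeseries"))
  if (ncol(regions$values) < 3L)
    stop("need at least 3 frames", call. = FALSE)
  sds <- apply(regions$values, 1, stats::sd)
  if (any(sds == 0))
    stop("constant time series for region(s): ",
         paste(regions$region_ids[sds == 0], collapse = ", "),
         call. = FALSE)
  C <- stats::cor(t(regions$values))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  connectivity_matrix(C, regions$region_ids, "pearson", band)
}

#' Partial-correlation connectivity matrix
#'
#' Entry (i, j) is the Pearson correlation of the residuals of rows i and j
#' after regression on the confounds (an intercept is always added), the
#' standard way of accounting for motion parameters in the band-pass
#' filtering path. With constant-only confounds this reduces exactly to
#' plain Pearson correlation.
#'
#' @param regions A [region_timeseries()].
#' @param confounds T-by-P numeric matrix of confound time courses.
#' @param band Optional [frequency_band()] recorded on the result.
#' @return A [connectivity_matrix()] with `method = "partial"`.
#' @export
partial_corr_connectivity <- function(regions, confounds, band = NULL) {
  stopifnot(inherits(regions, "region_timeseries"))
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != ncol(regions$values))
    stop("confounds must have one row per frame", call. = FALSE)
  X <- cbind(1, unname(confounds))
  keep <- independent_columns(X)
  if (length(keep) < ncol(X))
    X <- X[, keep, drop = FALSE]
  qrd <- qr(X)
  if (qrd$rank < ncol(X))
    stop("confound matrix is rank deficient", call. = FALSE)
  res <- qr.resid(qrd, t(regions$values))
  sds <- apply(res, 2, stats::sd)
  if (any(sds == 0))
    stop("residual time series constant for region(s): ",
         paste(regions$region_ids[sds == 0], collapse = ", "),
         call. = FALSE)
  C <- stats::cor(res)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  connectivity_matrix(C, regions$region_ids, "partial", band)
}

#' Strongest connections of a matrix
#'
#' Upper-triangle edges ranked by value, returning the top
#' `ceiling(fraction * R(R-1)/2)` plus any edges tied with the cutoff.
#'
#' @param matrix A [connectivity_matrix()].
#' @param fraction Fraction of edges in (0, 1]; default 0.05 (the strongest
#'   5% of connections).
#' @return data.frame with columns `i`, `j` (region ids) and `value`,
#'   sorted descending.
#' @export
top_edges <- function(matrix, fraction = 0.05) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  m <- matrix$values
  ut <- which(upper.tri(m), arr.ind = TRUE)
  vals <- m[ut]
  n <- ceiling(fraction * length(vals))
  ord <- order(vals, decreasing = TRUE)
  cutoff <- vals[ord[n]]
  sel <- ord[vals[ord] >= cutoff]
  data.frame(i = matrix$region_ids[ut[sel, 1]],
             j = matrix$region_ids[ut[sel, 2]],
             value = vals[sel])
}

#' Rank or linear agreement between two connectivity matrices
#'
#' Correlation over the lower-triangle off-diagonal entries of two matrices
#' on the same region set.
#'
#' @param a,b [connectivity_matrix()] objects with identical region ids.
#' @param method `"spearman"` (default, as used for comparing filtering
#'   approaches) or `"pearson"`.
#' @return List with `estimate`, `n_pairs` and `method`.
#' @export
compare_matrices <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "connectivity_matrix"),
            inherits(b, "connectivity_matrix"))
  if (!identical(as.character(a$region_ids), as.character(b$region_ids)))
    stop("matrices cover different region sets", call. = FALSE)
  la <- lower_triangle(a)
  lb <- lower_triangle(b)
  list(estimate = stats::cor(la, lb, method = method),
       n_pairs = length(la), method = method)
}

#' Element-wise mean of connectivity matrices across subjects
#'
#' Averages raw correlation values (no Fisher z by default, for fidelity to
#' reported connectivity magnitudes) and resets the diagonal to 1.
#'
#' @param matrices Non-empty list of [connectivity_matrix()] objects with
#'   identical region sets.
#' @param fisher_z If `TRUE`, average in the z-domain
#'   (`tanh(mean(atanh(r)))`).
#' @return A [connectivity_matrix()].
#' @export
group_mean_matrix <- function(matrices, fisher_z = FALSE) {
  if (!length(matrices)) stop("empty matrix list", call. = FALSE)
  ids <- matrices[[1]]$region_ids
  for (m in matrices) {
    stopifnot(inherits(m, "connectivity_matrix"))
    if (!identical(as.character(m$region_ids), as.character(ids)))
      stop("matrices cover different region sets", call. = FALSE)
  }
  vals <- lapply(matrices, `[[`, "values")
  if (fisher_z) {
    z <- Reduce(`+`, lapply(vals, function(v) {
      zz <- atanh(pmin(pmax(v, -1 + 1e-15), 1 - 1e-15)); diag(zz) <- 0; zz
    })) / length(vals)
    avg <- tanh(z)
  } else {
    avg <- Reduce(`+`, vals) / length(vals)
  }
  diag(avg) <- 1
  connectivity_matrix(avg, ids, matrices[[1]]$method, matrices[[1]]$band)
}
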