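#' Threshold a tissue probability map to its most probable voxels
#'
#' Retains the upper `fraction` of voxels with the highest tissue
#' probability among voxels with nonzero probability; ties with the cutoff
#' value are all included, so the result does not depend on voxel order.
#'
#' @param map A [tissue_probability_map()].
#' @param fraction Fraction in (0, 1]; default 0.05 (the upper 5%).
#' @return Logical 3D mask, a subset of `{prob > 0}`.
#' @export
threshold_tissue_mask <- function(map, fraction = 0.05) {
  stopifnot(inherits(map, "tissue_probability_map"))
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  p <- map$prob
  nz <- p[p > 0]
  if (!length(nz))
    stop("all-zero probability map (", map$tissue_class, ")", call. = FALSE)
  n_keep <- ceiling(fraction * length(nz))
  cutoff <- sort(nz, decreasing = TRUE)[n_keep]
  p >= cutoff & p > 0
}

#' Extract principal nuisance components from a tissue compartment
#'
#' Voxel time series inside the mask are mean-centered and
#' variance-normalized (correlation PCA, so high-activity voxels do not
#' dominate) and decomposed by SVD. The smallest number of components whose
#' cumulative explained variance reaches `variance_target` is kept, capped
#' at `max_components`. Component signs are fixed so the largest-magnitude
#' element of each time course is positive.
#'
#' @param series A [dynamic_series()], or a voxels-by-frames matrix.
#' @param mask Logical 3D mask (ignored when `series` is a matrix).
#' @param variance_target Cumulative explained-variance target in (0, 1];
#'   default 0.5 ("the majority of variance").
#' @param max_components Component cap, default 6.
#' @return T-by-C matrix of orthogonal, unit-norm, zero-mean component time
#'   courses, with attributes `explained_variance` (per component) and
#'   `n_voxels`.
#' @export
extract_tissue_components <- function(series, mask = NULL,
                                      variance_target = 0.5,
                                      max_components = 6) {
  X <- if (inherits(series, "dynamic_series")) {
    if (is.null(mask)) stop("mask is required for a dynamic series",
                            call. = FALSE)
    if (!any(mask)) stop("empty tissue mask", call. = FALSE)
    series_matrix(series)[as.vector(mask), , drop = FALSE]
  } else {
    as.matrix(series)
  }
  if (ncol(X) < 2L)
    stop("need at least 2 frames for component extraction", call. = FALSE)
  mu <- rowMeans(X)
  sds <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
  if (any(sds == 0))
    stop(sum(sds == 0), " all-constant voxel time series inside the mask",
         call. = FALSE)
  Xs <- (X - mu) / sds
  sv <- svd(t(Xs))                       # T x V: left vectors are T-courses
  ev <- sv$d^2 / sum(sv$d^2)
  C <- min(which(cumsum(ev) >= variance_target - 1e-12), max_components)
  C <- max(C, 1L)
  comp <- fix_signs(sv$u[, seq_len(C), drop = FALSE])
  structure(comp, explained_variance = ev[seq_len(C)], n_voxels = nrow(X))
}

# make the largest-magnitude element of every column positive
fix_signs <- function(u) {
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  u
}

#' Friston 24-parameter motion expansion
#'
#' Expands the six rigid-body parameters into the 24-regressor motion
#' model: the parameters, their backward-difference temporal derivatives
#' (first row zero), the squared parameters and the squared derivatives,
#' in that block order.
#'
#' @param motion A [motion_trace()].
#' @return T-by-24 matrix.
#' @export
expand_motion_friston24 <- function(motion) {
  stopifnot(inherits(motion, "motion_trace"))
  P <- motion$params
  if (nrow(P) < 2L)
    stop("need at least 2 frames to form derivatives", call. = FALSE)
  D <- rbind(0, diff(P))
  out <- cbind(P, D, P^2, D^2)
  colnames(out) <- c(colnames(P), paste0("d_", colnames(P)),
                     paste0(colnames(P), "_sq"),
                     paste0("d_", colnames(P), "_sq"))
  out
}

#' Principal components of the expanded motion model
#'
#' Zero-variance columns are dropped, the rest standardized, and the
#' smallest number of principal components reaching the cumulative
#' explained-variance target is returned (at least one).
#'
#' @param expanded T-by-K matrix, typically from
#'   [expand_motion_friston24()].
#' @param variance_target Cumulative explained-variance target; default
#'   0.99.
#' @return T-by-M matrix of orthogonal unit-norm component time courses
#'   with attribute `explained_variance`.
#' @export
motion_pca <- function(expanded, variance_target = 0.99) {
  X <- as.matrix(expanded)
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  if (ncol(X) == 0L)
    stop("all motion columns are constant", call. = FALSE)
  Xs <- scale(X)
  sv <- svd(Xs)
  pos <- sv$d > sv$d[1] * 1e-12
  ev <- sv$d[pos]^2 / sum(sv$d[pos]^2)
  M <- max(1L, min(which(cumsum(ev) >= variance_target - 1e-12)))
  structure(fix_signs(sv$u[, seq_len(M), drop = FALSE]),
            explained_variance = ev[seq_len(M)])
}

#' Sine/cosine regressors for frequencies outside an analysis band
#'
#' For every Fourier grid frequency `f_k = k/(T*dt)`, `k = 1..floor(T/2)`,
#' lying strictly outside `[low, high]`, emits the cosine and sine basis
#' functions evaluated at the frame onsets. The all-zero sine at the exact
#' Nyquist frequency (even T) is dropped and all columns are mean-centered.
#' Regressing these out confines the residual spectrum to the band.
#'
#' @param n_frames Number of frames T of the analyzed window.
#' @param frame_duration Frame length in seconds.
#' @param band [frequency_band()]; upper edge must not exceed Nyquist.
#' @return T-by-F matrix (possibly zero columns, with a message) with
#'   attribute `frequencies`.
#' @export
build_band_regressors <- function(n_frames, frame_duration, band) {
  stopifnot(inherits(band, "frequency_band"))
  check_band_nyquist(band, frame_duration)
  T <- as.integer(n_frames)
  kmax <- floor(T / 2)
  f <- (1:kmax) / (T * frame_duration)
  out_band <- which(f < band$low - 1e-15 | f > band$high + 1e-15)
  if (!length(out_band)) {
    message("band ", format(band), " covers every grid frequency; ",
            "no band regressors emitted")
    return(structure(matrix(0, T, 0), frequencies = numeric(0)))
  }
  t <- (seq_len(T) - 1) * frame_duration
  cols <- vector("list", 2 * length(out_band))
  labs <- character(2 * length(out_band))
  freqs <- numeric(0)
  j <- 0
  for (k in out_band) {
    j <- j + 1
    cols[[j]] <- cos(2 * pi * f[k] * t)
    labs[j] <- sprintf("freq_cos_%d", k)
    freqs <- c(freqs, f[k])
    drop_sine <- (T %% 2 == 0) && k == kmax  # identically zero at Nyquist
    if (!drop_sine) {
      j <- j + 1
      cols[[j]] <- sin(2 * pi * f[k] * t)
      labs[j] <- sprintf("freq_sin_%d", k)
      freqs <- c(freqs, f[k])
    }
  }
  m <- do.call(cbind, cols[seq_len(j)])
  colnames(m) <- labs[seq_len(j)]
  m <- scale(m, center = TRUE, scale = FALSE)
  attr(m, "scaled:center") <- NULL
  structure(m, frequencies = freqs)
}

#' Assemble the unified nuisance design matrix
#'
#' Prepends an intercept and column-binds the tissue-component, motion and
#' out-of-band frequency blocks, all of which are removed in a single
#' multiple regression. Rank-deficient assemblies are repaired by dropping
#' later columns that add no rank (with a warning), preserving the
#' provenance label of every retained column.
#'
#' @param wm_pcs,csf_pcs T-by-C tissue component blocks (or `NULL`).
#' @param motion_pcs T-by-M motion component block (or `NULL`).
#' @param band_regressors T-by-F frequency block (or `NULL`).
#' @param n_frames Number of frames T; all blocks must match.
#' @param band Optional [frequency_band()] recorded on the design.
#' @return An object of class `design_matrix` with elements `values`
#'   (T-by-K), `column_labels` and `band`.
#' @export
assemble_design <- function(wm_pcs = NULL, csf_pcs = NULL,
                            motion_pcs = NULL, band_regressors = NULL,
                            n_frames, band = NULL) {
  blocks <- list(intercept = matrix(1, n_frames, 1),
                 wm_pc = wm_pcs, csf_pc = csf_pcs,
                 motion_pc = motion_pcs, freq = band_regressors)
  values <- NULL
  labels <- character(0)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (is.null(b) || NCOL(b) == 0L) next
    b <- as.matrix(b)
    if (nrow(b) != n_frames)
      stop("block '", nm, "' has ", nrow(b), " rows, expected ", n_frames,
           call. = FALSE)
    lab <- if (nm == "freq" && !is.null(colnames(b))) colnames(b)
           else if (nm == "intercept") "intercept"
           else sprintf("%s_%d", nm, seq_len(ncol(b)))
    values <- cbind(values, unname(b))
    labels <- c(labels, lab)
  }
  qrd <- qr(values)
  if (qrd$rank < ncol(values)) {
    keep <- independent_columns(values)
    warning("design was rank-deficient; dropped ",
            ncol(values) - length(keep), " duplicate column(s): ",
            paste(utils::head(labels[-keep], 5), collapse = ", "),
            if (ncol(values) - length(keep) > 5) ", ..." else "")
    values <- values[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  d <- svd(scale(values, center = FALSE,
                 scale = sqrt(colSums(values^2))), nu = 0, nv = 0)$d
  if (d[length(d)] / d[1] <= 1e-10)
    stop("assembled design is numerically rank-deficient beyond repair",
         call. = FALSE)
  structure(list(values = values, column_labels = labels, band = band),
            class = "design_matrix")
}

# earliest maximal set of linearly independent columns (Gram-Schmidt sweep)
independent_columns <- function(X, tol = 1e-10) {
  basis <- matrix(0, nrow(X), 0)
  keep <- integer(0)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (ncol(basis)) v <- v - basis %*% crossprod(basis, v)
    nv <- sqrt(sum(v^2))
    if (nv > tol * max(1, sqrt(sum(X[, j]^2)))) {
      basis <- cbind(basis, v / nv)
      keep <- c(keep, j)
    }
  }
  keep
}

#' @export
print.design_matrix <- function(x, ...) {
  tab <- table(sub("_[0-9]+$", "", x$column_labels))
  cat(sprintf("<design_matrix> %d frames x %d columns (%s)%s\n",
              nrow(x$values), ncol(x$values),
              paste(names(tab), tab, sep = ":", collapse = ", "),
              if (!is.null(x$band)) paste0(", band ", format(x$band))
              else ""))
  invisible(x)
}
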