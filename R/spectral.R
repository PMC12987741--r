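#' Nyquist frequency of a frame duration
#'
#' The highest representable frequency of a series sampled every
#' `frame_duration` seconds: `1 / (2 * frame_duration)`. At 3 s frames this
#' is ~0.167 Hz, which is why band upper edges must shrink on
#' standard-framing scanners.
#'
#' @param frame_duration Frame length in seconds (> 0); vectorized.
#' @return Frequency in Hz.
#' @export
nyquist_frequency <- function(frame_duration) {
  if (any(frame_duration <= 0))
    stop("frame_duration must be positive", call. = FALSE)
  1 / (2 * frame_duration)
}

#' Aliased frequency of an undersampled component
#'
#' A component at `f` Hz sampled at `sampling_rate` Hz appears at
#' `min_n |f - n * fs|`, which always lies in `[0, fs/2]`. A respiratory
#' component near 0.3 Hz sampled at 3 s frames (fs = 1/3 Hz) folds to
#' ~0.033 Hz, inside the nominally "slow" band.
#'
#' @param f True frequency in Hz (>= 0); vectorized.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @return Apparent (aliased) frequency in Hz.
#' @export
alias_frequency <- function(f, sampling_rate) {
  if (any(f < 0)) stop("f must be >= 0", call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be positive",
                               call. = FALSE)
  abs(f - round(f / sampling_rate) * sampling_rate)
}

#' Remove the baseline uptake trend before spectral analysis
#'
#' Least-squares removal of either a polynomial trend basis (default cubic)
#' or of a previously assembled nuisance design containing the tissue
#' components; the residual has zero mean. Band-limited oscillations riding
#' on the trend are preserved.
#'
#' @param x A [region_timeseries()] or a numeric vector.
#' @param method `"polynomial"` or `"design"`.
#' @param order Polynomial order (default 3); must be below the series
#'   length.
#' @param design A [design_matrix()], required for `method = "design"`.
#' @param ... Passed to methods.
#' @return Object of the same type, detrended.
#' @export
remove_baseline_uptake <- function(x, method = c("polynomial", "design"),
                                   order = 3, design = NULL, ...)
  UseMethod("remove_baseline_uptake")

detrend_rows <- function(vals, onsets, method, order, design) {
  T <- ncol(vals)
  if (method == "polynomial") {
    if (order >= T)
      stop("polynomial order ", order, " must be below the series length ",
           T, call. = FALSE)
    B <- cbind(1, stats::poly(onsets, degree = order))
  } else {
    if (is.null(design) || !inherits(design, "design_matrix"))
      stop("method = \"design\" needs a design_matrix", call. = FALSE)
    B <- design$values
    if (nrow(B) != T)
      stop("design rows must match the number of frames", call. = FALSE)
  }
  t(qr.resid(qr(B), t(vals)))
}

#' @export
remove_baseline_uptake.region_timeseries <- function(x,
    method = c("polynomial", "design"), order = 3, design = NULL, ...) {
  method <- match.arg(method)
  res <- detrend_rows(x$values, x$frame_onsets, method, order, design)
  region_timeseries(res, x$region_ids, x$frame_duration, x$frame_onsets)
}

#' @rdname remove_baseline_uptake
#' @param frame_duration Sampling interval for the vector method.
#' @export
remove_baseline_uptake.numeric <- function(x,
    method = c("polynomial", "design"), order = 3, design = NULL,
    frame_duration = 1, ...) {
  method <- match.arg(method)
  onsets <- (seq_along(x) - 1) * frame_duration
  drop(detrend_rows(matrix(x, 1), onsets, method, order, design))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms over mean-removed, windowed, 50%
#' overlapping segments; the one-sided density is normalized so that
#' `sum(power) * df` recovers the time-domain variance (up to windowing
#' loss). For a [region_timeseries()] the per-region densities are
#' averaged unless a single `region` is requested.
#'
#' @param x Numeric vector or [region_timeseries()].
#' @param frame_duration Sampling interval in seconds (vector method).
#' @param segment_fraction Segment length as a fraction of the series;
#'   default 0.25.
#' @param overlap Segment overlap fraction; default 0.5.
#' @param window `"hann"` (default) or `"rectangular"`.
#' @param ... Passed to methods.
#' @return An object of class `psd_estimate`: `frequencies` (Hz, from 0 to
#'   Nyquist), `power` (same length, >= 0) and `meta` (segment length,
#'   overlap, window, number of segments).
#' @export
welch_psd <- function(x, ...) UseMethod("welch_psd")

#' @rdname welch_psd
#' @export
welch_psd.numeric <- function(x, frame_duration,
                              segment_fraction = 0.25, overlap = 0.5,
                              window = c("hann", "rectangular"), ...) {
  window <- match.arg(window)
  T <- length(x)
  L <- floor(T * segment_fraction)
  if (L < 4L) L <- min(T, 4L)
  if (L > T)
    stop("segment (", L, ") longer than series (", T, ")", call. = FALSE)
  w <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  else rep(1, L)
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, T - L + 1L, by = step)
  nf <- floor(L / 2) + 1L
  fs <- 1 / frame_duration
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg)[1:nf])^2
  }
  p <- acc / (length(starts) * sum(w^2) * fs)
  scale2 <- rep(2, nf)
  scale2[1] <- 1
  if (L %% 2 == 0) scale2[nf] <- 1
  structure(list(frequencies = (0:(nf - 1)) * fs / L,
                 power = p * scale2,
                 meta = list(segment_length = L, overlap = overlap,
                             window = window,
                             n_segments = length(starts))),
            class = "psd_estimate")
}

#' @rdname welch_psd
#' @param region Optional single region id; default averages the density
#'   over all regions.
#' @export
welch_psd.region_timeseries <- function(x, segment_fraction = 0.25,
                                        overlap = 0.5,
                                        window = c("hann", "rectangular"),
                                        region = NULL, ...) {
  window <- match.arg(window)
  rows <- if (is.null(region)) seq_len(nrow(x$values))
          else which(x$region_ids == region)
  if (!length(rows)) stop("region not found: ", region, call. = FALSE)
  ests <- lapply(rows, function(r)
    welch_psd(x$values[r, ], x$frame_duration, segment_fraction, overlap,
              window))
  out <- ests[[1]]
  if (length(ests) > 1L)
    out$power <- Reduce(`+`, lapply(ests, `[[`, "power")) / length(ests)
  out
}

#' Location of the dominant spectral peak
#'
#' @param psd A `psd_estimate`.
#' @param min_freq Ignore frequencies below this value (Hz), e.g. residual
#'   trend power near DC.
#' @return Frequency of the maximum power, in Hz.
#' @export
peak_frequency <- function(psd, min_freq = 0) {
  stopifnot(inherits(psd, "psd_estimate"))
  sel <- which(psd$frequencies >= min_freq)
  if (!length(sel)) stop("no frequencies at or above ", min_freq,
                         call. = FALSE)
  psd$frequencies[sel[which.max(psd$power[sel])]]
}

#' Write a PSD estimate as a two-column TSV (frequency, power)
#'
#' @param psd A `psd_estimate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psd <- function(psd, path) {
  stopifnot(inherits(psd, "psd_estimate"))
  utils::write.table(
    data.frame(frequency = psd$frequencies, power = psd$power),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
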