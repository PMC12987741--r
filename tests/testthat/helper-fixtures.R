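# Shared fixtures, all generated in code.

# small but fully featured simulation: 6 min at 1 s, 2 min equilibration
tiny_config <- function(seed = 7, ...) {
  defaults <- list(grid = c(12, 12, 8), n_frames = 360, frame_duration = 1,
                   exclude_s = 120, n_parcels = 6, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# valid connectivity matrix derived from random regional data
random_connectivity <- function(R = 6, T = 50, seed = 1) {
  vals <- with_test_seed(seed, matrix(rnorm(R * T), R, T))
  pearson_connectivity(region_timeseries(vals, seq_len(R), 1))
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# series wrapper for quick construction
quick_series <- function(X, grid, dt = 1, ...)
  dynamic_series(array(X, c(grid, length(X) / prod(grid))), dt, ...)

# least-squares amplitude of a sinusoid at known frequency, central window
fit_amplitude <- function(x, freq, dt, trim = 0.1) {
  T <- length(x)
  keep <- seq(floor(T * trim) + 1, ceiling(T * (1 - trim)))
  t <- (keep - 1) * dt
  B <- cbind(cos(2 * pi * freq * t), sin(2 * pi * freq * t))
  co <- qr.solve(B, x[keep])
  sqrt(sum(co^2))
}

# analytic amplitude gain of a zero-phase (forward-backward) order-n
# Butterworth band-pass: |H(f)|^2 with |H|^2 = 1/(1 + Omega^(2n))
butter_bp_gain <- function(f, low, high, n = 4) {
  om <- (f^2 - low * high) / (f * (high - low))
  1 / (1 + om^(2 * n))
}

# brute-force Ward agglomeration: heights sqrt(2 * ESS increase),
# returning merge heights plus the implied cophenetic matrix
ward_oracle <- function(X) {
  n <- nrow(X)
  cl <- as.list(seq_len(n))
  hts <- numeric(0)
  coph <- matrix(0, n, n)
  while (length(cl) > 1) {
    best <- NULL; bd <- Inf
    for (i in seq_len(length(cl) - 1)) for (j in (i + 1):length(cl)) {
      ci <- colMeans(X[cl[[i]], , drop = FALSE])
      cj <- colMeans(X[cl[[j]], , drop = FALSE])
      ni <- length(cl[[i]]); nj <- length(cl[[j]])
      d <- ni * nj / (ni + nj) * sum((ci - cj)^2)
      if (d < bd) { bd <- d; best <- c(i, j) }
    }
    h <- sqrt(2 * bd)
    hts <- c(hts, h)
    coph[cl[[best[1]]], cl[[best[2]]]] <- h
    coph[cl[[best[2]]], cl[[best[1]]]] <- h
    cl[[best[1]]] <- c(cl[[best[1]]], cl[[best[2]]])
    cl[[best[2]]] <- NULL
  }
  list(heights = hts, coph = coph)
}
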