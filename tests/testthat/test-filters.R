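toy_design <- function(T = 30, seed = 21) {
  blocks <- with_test_seed(seed, matrix(rnorm(T * 4), T, 4))
  assemble_design(blocks, n_frames = T)
}

test_that("CompCor residuals satisfy the projection identities", {
  d <- toy_design()
  D <- d$values
  # a time course equal to a design column is annihilated
  x <- matrix(D[, 2], 1)
  expect_lt(max(abs(compcor_residualize(x, d))), 1e-10)
  # a course orthogonal to all non-intercept columns is only de-meaned
  q <- qr.Q(qr(D), complete = TRUE)[, ncol(D) + 1]
  y <- q + 5
  res <- compcor_residualize(matrix(y, 1), d)
  expect_lt(max(abs(res - (y - mean(y)))), 1e-10)
})

test_that("CompCor equals the explicit normal-equations oracle", {
  d <- toy_design(30, seed = 22)
  D <- d$values
  Y <- with_test_seed(23, matrix(rnorm(5 * 30), 5, 30))
  res <- compcor_residualize(Y, d)
  oracle <- t(t(Y) - D %*% solve(crossprod(D), crossprod(D, t(Y))))
  expect_lt(max(abs(res - oracle)), 1e-9)
  # orthogonality of every residual to every design column
  dots <- abs(crossprod(D, t(res))) /
    outer(sqrt(colSums(D^2)), sqrt(rowSums(res^2)))
  expect_lt(max(dots), 1e-8)
  # linearity for a fixed design
  a <- compcor_residualize(Y[1, , drop = FALSE], d)
  b <- compcor_residualize(Y[2, , drop = FALSE], d)
  ab <- compcor_residualize(2 * Y[1, , drop = FALSE] -
                              3 * Y[2, , drop = FALSE], d)
  expect_lt(max(abs(ab - (2 * a - 3 * b))), 1e-8)
  rep <- attr(res, "filter_report")
  expect_true(all(rep$variance_removed >= 0 & rep$variance_removed <= 1))
})

test_that("voxel-wise CompCor cleans only masked voxels", {
  sim <- simulate_subject(tiny_config(seed = 71))
  s <- exclude_uptake_window(sim$series, 120)
  wm <- threshold_tissue_mask(sim$tpm$WM, 0.05)
  comp <- extract_tissue_components(s, wm)
  d <- assemble_design(comp, n_frames = fpetmc:::n_frames(s))
  gm <- sim$parcels$labels > 0
  clean <- compcor_residualize(s, d, mask = gm)
  X0 <- fpetmc:::series_matrix(s)
  X1 <- fpetmc:::series_matrix(clean)
  expect_identical(X1[!as.vector(gm), ], X0[!as.vector(gm), ])
  expect_false(isTRUE(all.equal(X1[as.vector(gm), ], X0[as.vector(gm), ])))
})

test_that("Butterworth band-pass passes the band and kills the stopband", {
  T <- 1500; dt <- 1
  b <- frequency_band(0.01, 0.1)
  mk <- function(f) region_timeseries(
    rbind(sin(2 * pi * f * (0:(T - 1)) * dt), rnorm(T)), 1:2, dt)
  # zero in, zero out
  z <- butterworth_bandpass(region_timeseries(matrix(0, 2, T) + 0:1, 1:2,
                                              dt), b)
  expect_lt(max(abs(z$values)), 1e-10)
  # geometric band center: amplitude preserved within 5%
  fc <- sqrt(0.01 * 0.1)
  yc <- butterworth_bandpass(mk(fc), b)
  expect_equal(fit_amplitude(yc$values[1, ], fc, dt), 1, tolerance = 0.05)
  # deep stopband at 0.45 Hz
  ys <- butterworth_bandpass(mk(0.45), b)
  expect_lt(fit_amplitude(ys$values[1, ], 0.45, dt), 0.01)
  # >= 40 dB at 10x the upper edge (band chosen so 10x is sub-Nyquist)
  b2 <- frequency_band(0.004, 0.04)
  y40 <- butterworth_bandpass(mk(0.4), b2)
  expect_lt(fit_amplitude(y40$values[1, ], 0.4, dt), 0.01)
  expect_error(butterworth_bandpass(mk(0.1), frequency_band(0.01, 0.5)),
               "Nyquist")
  short <- region_timeseries(matrix(rnorm(40), 2, 20), 1:2, dt)
  expect_error(butterworth_bandpass(short, b), "padding")
})

test_that("bidirectional response tracks the analytic order-4 curve", {
  T <- 1500; dt <- 1
  b <- frequency_band(0.01, 0.1)
  sweep <- c(0.004, 0.02, sqrt(0.001), 0.05, 0.08, 0.095, 0.12, 0.15,
             0.2, 0.3)
  for (f in sweep) {
    x <- sin(2 * pi * f * (0:(T - 1)) * dt)
    y <- butterworth_bandpass(region_timeseries(rbind(x, 0.5 * x), 1:2, dt),
                              b)
    measured <- fit_amplitude(y$values[1, ], f, dt)
    expect_lt(abs(measured - butter_bp_gain(f, 0.01, 0.1)), 0.02)
  }
})

test_that("Gaussian smoothing preserves constants, mass and width", {
  grid <- c(21, 21, 9)
  const <- quick_series(rep(3, prod(grid) * 2), grid, spatial_zoom = c(2, 2, 2))
  expect_identical(gaussian_smooth(const, 0), const)    # fwhm 0 = identity
  sm <- gaussian_smooth(const, 8)
  expect_lt(max(abs(sm$data - 3)), 1e-10)               # constant unchanged

  imp <- array(0, c(grid, 2))
  imp[11, 11, 5, ] <- 1
  s <- dynamic_series(imp, 1, spatial_zoom = c(2, 2, 2))
  out <- gaussian_smooth(s, 8)
  expect_equal(sum(out$data[, , , 1]), 1, tolerance = 1e-6)  # mass
  # profile-scan oracle: width at half max along x, in mm
  prof <- out$data[, 11, 5, 1]
  half <- max(prof) / 2
  above <- which(prof >= half)
  fwhm_est <- (max(above) - min(above) + 1) * 2          # voxel -> mm
  expect_lt(abs(fwhm_est - 8), 2 + 1e-9)                 # within one voxel
})

test_that("edNLM is exact in its analytic limits", {
  grid <- c(5, 5, 4)
  const <- quick_series(rep(2.5, prod(grid) * 6), grid)
  out <- ednlm_filter(const, temporal_frames = c(3, 5), h = 1, fwhm_mm = 0)
  expect_lt(max(abs(out$data - 2.5)), 1e-10)

  # h -> infinity: one pass tends to the clamped-window mean
  arr <- with_test_seed(31, array(rnorm(prod(grid) * 7), c(grid, 7)))
  s <- dynamic_series(arr, 1)
  big <- ednlm_filter(s, temporal_frames = 3, h = 1e9, fwhm_mm = 0)
  win_mean <- fpetmc:::box_sum(arr, c(1, 1, 1, 1)) / (27 * 3)
  expect_lt(max(abs(big$data - win_mean)), 1e-6)
  expect_error(ednlm_filter(dynamic_series(arr[, , , 1:3, drop = FALSE], 1),
                            temporal_frames = 5), "shorter")
})

test_that("edNLM matches a brute-force patch-weighting oracle", {
  dm <- c(4, 4, 3, 5)
  arr <- with_test_seed(32, array(rnorm(prod(dm)), dm))
  h <- 2
  out <- fpetmc:::nlm_pass(arr, tr = 1L, h = h)
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  patch <- as.matrix(expand.grid(-1:1, -1:1, -1:1, -1:1))
  for (vox in list(c(1, 1, 1, 1), c(2, 3, 2, 3), c(4, 4, 3, 5))) {
    num <- 0; den <- 0
    for (o in seq_len(nrow(patch))) {
      off <- patch[o, ]
      d2 <- 0
      for (p in seq_len(nrow(patch))) {
        i1 <- clamp(vox + patch[p, ], dm)
        i2 <- clamp(i1 + off, dm)
        d2 <- d2 + (arr[matrix(i1, 1)] - arr[matrix(i2, 1)])^2
      }
      j <- clamp(vox + off, dm)
      w <- exp(-d2 / h^2)
      num <- num + w * arr[matrix(j, 1)]
      den <- den + w
    }
    expect_equal(out[matrix(vox, 1)], num / den, tolerance = 1e-10)
  }
})

test_that("frame downsampling averages blocks and rescales timing", {
  grid <- c(2, 2, 2)
  s6 <- quick_series(rep(1:6, each = prod(grid)), grid, dt = 1)
  expect_identical(downsample_frames(s6, 1), s6)
  d <- downsample_frames(s6, 3)
  expect_equal(as.vector(d$data[1, 1, 1, ]), c(2, 5))
  expect_equal(d$frame_duration, 3)

  s1500 <- quick_series(rep(seq_len(1500), each = prod(grid)), grid, dt = 1)
  d500 <- downsample_frames(s1500, 3)
  expect_equal(fpetmc:::n_frames(d500), 500)
  expect_equal(d500$frame_duration, 3)
  s7 <- quick_series(rep(1:7, each = prod(grid)), grid)
  expect_message(downsample_frames(s7, 3), "trailing")
  expect_error(downsample_frames(s6, 0), ">= 1")
})

test_that("uptake-window exclusion keeps late frames with absolute onsets", {
  grid <- c(2, 2, 2)
  s <- quick_series(rnorm(prod(grid) * 1500), grid, dt = 1)
  e <- exclude_uptake_window(s, 600)
  expect_equal(fpetmc:::n_frames(e), 900)
  expect_equal(e$frame_onsets[1], 600)
  s3 <- quick_series(rnorm(prod(grid) * 400), grid, dt = 3)
  expect_equal(fpetmc:::n_frames(exclude_uptake_window(s3, 600)), 200)
  expect_identical(exclude_uptake_window(s, 0)$data, s$data)
  expect_error(exclude_uptake_window(s, 1e6), "no frames")
})
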