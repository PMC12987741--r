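test_that("uptake curve obeys its closed-form limits", {
  t <- seq(0, 1500, by = 0.5)
  expect_equal(uptake_curve(t, alpha = 0, bolus_amp = 0), rep(0, length(t)))
  expect_equal(uptake_curve(0, alpha = 1, bolus_amp = 3), 0)
  # pure infusion: U(2t) - U(t) -> alpha * t once saturation has passed
  a <- 0.05
  u <- uptake_curve(c(5000, 10000), alpha = a, tau_sat = 300)
  expect_equal(u[2] - u[1], a * 5000, tolerance = 1e-6)
  expect_error(uptake_curve(t, alpha = 1, tau_sat = -1), "positive")
})

test_that("default uptake curve is non-decreasing after the bolus transient", {
  cfg <- sim_config(seed = 1)
  up <- cfg$uptake
  t <- seq(0, 1500, by = 0.25)  # dense brute-force evaluation
  U <- uptake_curve(t, alpha = up$alpha, tau_sat = up$tau_sat,
                    bolus_amp = fpetmc:::bolus_amplitude(up, 1500),
                    tau_decay = up$tau_decay, tau_rise = up$tau_rise)
  late <- U[t > 120]
  expect_true(all(diff(late) >= -1e-9))
  expect_true(all(is.finite(U)))
  # bolus peak sits at ~20:80 relative to the end-of-scan amplitude
  bolus <- U - uptake_curve(t, alpha = up$alpha, tau_sat = up$tau_sat)
  expect_equal(max(bolus) / U[length(U)], 0.2 / 0.8, tolerance = 0.01)
})

test_that("band-limited latents concentrate their periodogram in band", {
  band <- frequency_band(0.04, 0.06)
  Z <- band_limited_latents(1500, 1, band, n_latents = 3, seed = 5)
  expect_equal(dim(Z), c(3, 1500))
  for (j in 1:3) {
    x <- Z[j, ]
    expect_lt(abs(mean(x)), 1e-12)
    # independent periodogram oracle via raw FFT
    p <- Mod(fft(x))^2 / length(x)
    f <- (seq_along(x) - 1) / length(x)
    inb <- f >= band$low & f <= band$high
    inb <- inb | (1 - f) >= band$low & (1 - f) <= band$high  # mirrored half
    expect_gte(sum(p[inb]) / sum(p[-1]), 0.9)
  }
  # whitened set has exactly unit sample covariance
  expect_lt(max(abs(tcrossprod(Z) / (1500 - 1) - diag(3))), 1e-10)
})

test_that("latents are reproducible and respect the Nyquist edge", {
  b <- frequency_band(0.01, 0.1)
  expect_identical(band_limited_latents(200, 1, b, 2, seed = 9),
                   band_limited_latents(200, 1, b, 2, seed = 9))
  # upper edge exactly at Nyquist is accepted, above is not
  expect_silent(band_limited_latents(100, 1, frequency_band(0.4, 0.5), 1,
                                     seed = 1))
  expect_error(band_limited_latents(100, 1, frequency_band(0.4, 0.51), 1,
                                    seed = 1), "Nyquist")
})

test_that("noiseless single-network simulation is exactly identifiable", {
  cfg <- tiny_config(seed = 3, sigma0 = 0,
                     physio = list(amplitudes = c(0, 0)),
                     motion = list(coupling = 0))
  sim <- simulate_subject(cfg)
  regions <- extract_regional_timeseries(sim$series, sim$parcels)
  # subtract the known per-region uptake contribution, then correlate
  clean <- regions$values -
    outer(sim$truth$region_uptake_gain, sim$truth$uptake)
  est <- cor(t(clean))
  expect_lt(max(abs(est - sim$truth$truth_connectivity[[1]]$values)), 1e-6)
})

test_that("simulation is bit-identical under the master seed", {
  a <- simulate_subject(tiny_config(seed = 21))
  b <- simulate_subject(tiny_config(seed = 21))
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$motion$params, b$motion$params)
  expect_identical(a$truth$truth_connectivity[[1]]$values,
                   b$truth$truth_connectivity[[1]]$values)
  c <- simulate_subject(tiny_config(seed = 22))
  expect_false(identical(a$series$data, c$series$data))
})

test_that("standard-sensitivity profile carries sqrt(176/15) more noise", {
  base <- list(grid = c(8, 8, 6), n_frames = 200, frame_duration = 3,
               networks = list(), physio = list(amplitudes = c(0, 0)),
               motion = list(coupling = 0), exclude_s = 0, n_parcels = 4,
               seed = 31)
  noise_sd <- function(profile, sigma0) {
    noisy <- do.call(sim_config, c(base, list(scanner_profile = profile,
                                              sigma0 = sigma0)))
    clean <- do.call(sim_config, c(base, list(scanner_profile = profile,
                                              sigma0 = 0)))
    sd(simulate_subject(noisy)$series$data -
         simulate_subject(clean)$series$data)
  }
  ratio <- noise_sd("standard_3s", 1) / noise_sd("high_sensitivity_1s", 1)
  expect_equal(ratio, sqrt(176 / 15), tolerance = 0.02)
})

test_that("stored truth equals the normalized loading cross-product", {
  sim <- simulate_subject(tiny_config(seed = 41))
  L <- sim$truth$network_loadings[[1]]
  ref <- tcrossprod(L)   # rows are unit-norm, latents whitened
  est <- sim$truth$truth_connectivity[[1]]$values
  expect_lt(max(abs(est - ref)), 0.02)
})

test_that("a 0.3 Hz oscillation sampled at 3 s aliases to 1/30 Hz", {
  cfg <- sim_config("standard_3s", grid = c(8, 8, 6), n_frames = 200,
                    frame_duration = 3, networks = list(), sigma0 = 0,
                    motion = list(coupling = 0), exclude_s = 120,
                    n_parcels = 4, seed = 51)
  sim <- simulate_subject(cfg)
  s <- exclude_uptake_window(sim$series, 120)  # drop the bolus transient
  csf <- threshold_tissue_mask(sim$tpm$CSF, 0.05)
  x <- colMeans(fpetmc:::series_matrix(s)[as.vector(csf), ])
  xd <- remove_baseline_uptake(x, frame_duration = 3)
  p <- Mod(fft(xd))^2
  f <- (seq_along(xd) - 1) / (length(xd) * 3)
  half <- 2:floor(length(xd) / 2)
  peak <- f[half][which.max(p[half])]
  expect_equal(peak, alias_frequency(0.3, 1 / 3),
               tolerance = 1 / (length(xd) * 3) + 1e-9)
})

test_that("simulation bundles round-trip through the on-disk layout", {
  sim <- simulate_subject(tiny_config(seed = 61))
  dir <- file.path(tempdir(), "simout")
  write_simulation(sim, dir)
  s2 <- read_dynamic_series(file.path(dir, "pet.nii.gz"))
  expect_identical(s2$data, sim$series$data)
  pm <- read_parcellation(file.path(dir, "parcels.nii.gz"),
                          file.path(dir, "parcels.tsv"))
  expect_equal(nrow(pm$region_table), 6)
  tr <- read_connectivity(file.path(dir, "truth_band1.tsv"))
  expect_lt(max(abs(tr$values - sim$truth$truth_connectivity[[1]]$values)),
            1e-12)
})
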