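#' Scanner sensitivity profiles
#'
#' Two profiles bracket current instrumentation: a high-sensitivity
#' large-axial-field-of-view system framing at 1 s (NEMA sensitivity
#' ~176 kcps/MBq, 1500 frames) and a standard-sensitivity hybrid system
#' framing at 3 s (~15.0 kcps/MBq, 400 frames). Noise in the simulator
#' scales with the inverse square root of sensitivity, so the standard
#' profile carries sqrt(176/15) = 3.43 times the noise of the
#' high-sensitivity profile at equal `sigma0`.
#'
#' @return Named list of profile definitions.
#' @export
scanner_profiles <- function() {
  list(
    high_sensitivity_1s = list(frame_duration = 1, n_frames = 1500,
                               sensitivity_kcps = 176),
    standard_3s = list(frame_duration = 3, n_frames = 400,
                       sensitivity_kcps = 15)
  )
}

# noise multiplier of a profile relative to the high-sensitivity reference
sensitivity_noise_scale <- function(sensitivity_kcps)
  sqrt(176 / sensitivity_kcps)

#' Specify one band-limited ground-truth network
#'
#' A network is a set of regional signals sharing `n_latents` latent
#' band-limited factors through a loading matrix; its ground-truth
#' connectivity is the correlation structure of those noiseless regional
#' components.
#'
#' @param band [frequency_band()] the latent factors live in.
#' @param n_latents Number of latent factors (>= 1).
#' @param amplitude Regional component standard deviation (signal units).
#' @param loading Optional R-by-`n_latents` loading matrix; rows are
#'   normalized to unit norm. If `NULL`, a loading matrix is drawn from the
#'   simulation's seeded random stream.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(band, n_latents = 3, amplitude = 1,
                         loading = NULL) {
  stopifnot(inherits(band, "frequency_band"))
  if (n_latents < 1) stop("n_latents must be >= 1", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (!is.null(loading)) {
    loading <- as.matrix(loading)
    if (ncol(loading) != n_latents)
      stop("loading must have n_latents columns", call. = FALSE)
    if (all(rowSums(abs(loading)) == 0))
      stop("loading matrix must have at least one nonzero row",
           call. = FALSE)
  }
  structure(list(band = band, n_latents = as.integer(n_latents),
                 amplitude = amplitude, loading = loading),
            class = "network_spec")
}

#' Simulation configuration
#'
#' Defines the synthetic constant-infusion fPET study conditions: phantom
#' grid, framing (from the scanner profile unless overridden), uptake
#' kinetics, ground-truth networks, physiological oscillations, motion
#' random walk and heteroscedastic noise. The scan must be at least twice
#' the uptake-exclusion window long so an analyzable window remains.
#'
#' @param scanner_profile `"high_sensitivity_1s"` or `"standard_3s"`.
#' @param grid Phantom dimensions in voxels, length 3.
#' @param n_frames,frame_duration Override the profile's framing.
#' @param n_parcels Number of equal-size gray-matter parcels.
#' @param networks List of [network_spec()] objects.
#' @param uptake List with `alpha` (infusion ramp slope, units/s),
#'   `tau_sat` (ramp saturation time constant, s), `tau_decay`/`tau_rise`
#'   (bolus shape time constants, s) and `bolus_fraction` (bolus peak as a
#'   fraction of total amplitude; 0.2 mirrors a 20:80 bolus:infusion split).
#' @param physio List with `freqs` (Hz) and `amplitudes` (signal units) of
#'   CSF-weighted physiological oscillations; defaults place components at
#'   0.3 Hz (respiration) and 1.0 Hz (cardiac).
#' @param motion List with random-walk step sizes `step_trans` (mm),
#'   `step_rot` (rad) and per-voxel `coupling` gain sd (signal units per
#'   unit parameter).
#' @param sigma0 Noise scale: voxel noise sd is
#'   `sigma0 * sqrt(max(U(t), eps))` for the high-sensitivity profile,
#'   multiplied by `sqrt(176 / sensitivity)` otherwise.
#' @param exclude_s Uptake-equilibration window (s) excluded from analysis.
#' @param spatial_zoom Voxel size in mm.
#' @param seed Master seed; fully determines all outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(scanner_profile = c("high_sensitivity_1s",
                                           "standard_3s"),
                       grid = c(24, 24, 16),
                       n_frames = NULL, frame_duration = NULL,
                       n_parcels = 20,
                       networks = list(
                         network_spec(frequency_band(0.01, 0.1))),
                       uptake = list(),
                       physio = list(),
                       motion = list(),
                       sigma0 = 1,
                       exclude_s = 600,
                       spatial_zoom = c(8, 8, 10),
                       seed = 1L) {
  scanner_profile <- match.arg(scanner_profile)
  prof <- scanner_profiles()[[scanner_profile]]
  if (is.null(n_frames)) n_frames <- prof$n_frames
  if (is.null(frame_duration)) frame_duration <- prof$frame_duration
  up <- utils::modifyList(list(alpha = 0.067, tau_sat = 300,
                               tau_decay = 25, tau_rise = 10,
                               bolus_fraction = 0.2), uptake)
  ph <- utils::modifyList(list(freqs = c(0.3, 1.0),
                               amplitudes = c(1.5, 0.8)), physio)
  mo <- utils::modifyList(list(step_trans = 0.02, step_rot = 5e-4,
                               coupling = 0.5), motion)
  if (length(ph$freqs) != length(ph$amplitudes))
    stop("physio freqs and amplitudes must have equal length",
         call. = FALSE)
  if (any(ph$amplitudes < 0) || sigma0 < 0 || mo$coupling < 0)
    stop("all amplitudes must be >= 0", call. = FALSE)
  if (length(grid) != 3L || any(grid < 4))
    stop("grid must be three dimensions of at least 4 voxels",
         call. = FALSE)
  if (n_frames * frame_duration < 2 * exclude_s)
    stop("scan duration ", n_frames * frame_duration, " s must be at ",
         "least twice the exclusion window (", 2 * exclude_s, " s)",
         call. = FALSE)
  for (nw in networks)
    if (!inherits(nw, "network_spec"))
      stop("networks must be a list of network_spec objects", call. = FALSE)
  structure(list(scanner_profile = scanner_profile,
                 sensitivity_kcps = prof$sensitivity_kcps,
                 grid = as.integer(grid), n_frames = as.integer(n_frames),
                 frame_duration = frame_duration, n_parcels = n_parcels,
                 networks = networks, uptake = up, physio = ph,
                 motion = mo, sigma0 = sigma0, exclude_s = exclude_s,
                 spatial_zoom = spatial_zoom, seed = seed),
            class = "sim_config")
}

#' Bolus-plus-constant-infusion uptake curve
#'
#' Closed form
#' `U(t) = A_b (exp(-t/tau_decay) - exp(-t/tau_rise)) +
#'  alpha t (1 - exp(-t/tau_sat))`:
#' a transient bolus passage riding on a saturating infusion ramp.
#' `U(0) = 0`, and for the default parameter set the curve is
#' non-decreasing once the bolus transient has washed out (t > ~2 min).
#'
#' @param t Ascending time vector in seconds (>= 0).
#' @param alpha Infusion ramp slope, units/s.
#' @param tau_sat Ramp saturation time constant, s.
#' @param bolus_amp Bolus amplitude `A_b` (units).
#' @param tau_decay,tau_rise Bolus decay/rise time constants, s
#'   (`tau_decay > tau_rise`).
#' @return Activity values, same length as `t`.
#' @export
uptake_curve <- function(t, alpha, tau_sat = 300, bolus_amp = 0,
                         tau_decay = 25, tau_rise = 10) {
  if (tau_sat <= 0 || tau_decay <= 0 || tau_rise <= 0)
    stop("time constants must be positive", call. = FALSE)
  if (any(t < 0) || any(diff(t) < 0))
    stop("t must be ascending and non-negative", call. = FALSE)
  bolus_amp * (exp(-t / tau_decay) - exp(-t / tau_rise)) +
    alpha * t * (1 - exp(-t / tau_sat))
}

# bolus amplitude yielding a peak equal to bolus_fraction/(1-bolus_fraction)
# of the end-of-scan infusion amplitude
bolus_amplitude <- function(up, total_s) {
  pk_t <- log(up$tau_decay / up$tau_rise) *
    up$tau_decay * up$tau_rise / (up$tau_decay - up$tau_rise)
  pk <- exp(-pk_t / up$tau_decay) - exp(-pk_t / up$tau_rise)
  u_end <- up$alpha * total_s * (1 - exp(-total_s / up$tau_sat))
  up$bolus_fraction / (1 - up$bolus_fraction) * u_end / pk
}

config_uptake <- function(config) {
  up <- config$uptake
  t <- (seq_len(config$n_frames) - 1) * config$frame_duration
  uptake_curve(t, alpha = up$alpha, tau_sat = up$tau_sat,
               bolus_amp = bolus_amplitude(up, max(t)),
               tau_decay = up$tau_decay, tau_rise = up$tau_rise)
}

#' Band-limited latent time courses
#'
#' Draws `n_latents` zero-mean series whose discrete spectra are supported
#' only on Fourier grid frequencies inside `[low, high]` (so the full
#' periodogram mass lies in band). With more than one latent the set is
#' empirically whitened: the sample covariance is exactly the identity,
#' which keeps linear-mixture ground truths analytically exact.
#'
#' @param n_frames Series length T.
#' @param frame_duration Sampling interval in seconds.
#' @param band [frequency_band()]; the upper edge may equal the Nyquist
#'   frequency but not exceed it.
#' @param n_latents Number of series.
#' @param seed Optional seed (RNG state is restored afterwards).
#' @param whiten Logical; decorrelate the latents empirically.
#' @return `n_latents`-by-T matrix, rows unit variance.
#' @export
band_limited_latents <- function(n_frames, frame_duration, band,
                                 n_latents = 1, seed = NULL,
                                 whiten = TRUE) {
  stopifnot(inherits(band, "frequency_band"))
  check_band_nyquist(band, frame_duration)
  T <- as.integer(n_frames)
  kmax <- floor(T / 2)
  f <- (1:kmax) / (T * frame_duration)
  sel <- which(f >= band$low - 1e-15 & f <= band$high + 1e-15)
  if (!length(sel))
    stop("no Fourier grid frequency of a length-", T, " series at ",
         frame_duration, " s lies inside the band ", format(band),
         call. = FALSE)
  even_nyq <- (T %% 2 == 0)
  Z <- with_seed(seed, {
    out <- matrix(0, n_latents, T)
    for (j in seq_len(n_latents)) {
      spec <- complex(length.out = T)
      for (k in sel) {
        if (even_nyq && k == kmax) {
          spec[k + 1] <- complex(real = stats::rnorm(1))
        } else {
          spec[k + 1] <- complex(real = stats::rnorm(1),
                                 imaginary = stats::rnorm(1))
          spec[T + 1 - k] <- Conj(spec[k + 1])
        }
      }
      x <- Re(stats::fft(spec, inverse = TRUE)) / T
      out[j, ] <- x / stats::sd(x)
    }
    out
  })
  n_dof <- 2 * length(sel) - as.integer(even_nyq && kmax %in% sel)
  if (whiten && n_latents > 1 && n_dof > n_latents) {
    S <- tcrossprod(Z) / (T - 1)
    Z <- t(solve(chol(S))) %*% Z
  }
  Z
}

# deterministic phantom geometry: concentric CSF core / WM shell / GM ribbon
# inside an ellipsoid, with equal-size angular-sector parcels on the ribbon
phantom_geometry <- function(grid, n_parcels) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  xs <- (seq_len(nx) - cx) / (0.45 * nx)
  ys <- (seq_len(ny) - cy) / (0.45 * ny)
  zs <- (seq_len(nz) - cz) / (0.45 * nz)
  rx <- array(rep(xs, times = ny * nz), grid)
  ry <- array(rep(rep(ys, each = nx), times = nz), grid)
  rz <- array(rep(zs, each = nx * ny), grid)
  r <- sqrt(rx^2 + ry^2 + rz^2)
  brain <- r <= 1
  csf <- brain & r <= 0.35
  wm <- brain & r > 0.35 & r <= 0.7
  gm <- brain & r > 0.7
  # in-class probabilities ramp with shell depth; out-of-class residuals
  # decay with radius so that values are (near-)distinct and the
  # tie-inclusive 5% threshold retains only genuine top voxels
  ramp <- function(mask, mid, half)
    ifelse(mask, pmin(0.98, 0.85 + 0.13 * (1 - abs(r - mid) / half)), 0)
  leak <- function(mask, base) ifelse(brain & !mask, base * (1 - 0.3 * r), 0)
  p_gm <- ramp(gm, 0.85, 0.15) + leak(gm, 0.04)
  p_wm <- ramp(wm, 0.525, 0.175) + leak(wm, 0.04)
  p_csf <- ramp(csf, 0, 0.35) + leak(csf, 0.02)
  # equal-size parcels: order ribbon voxels by (z half, angle) and chunk
  gm_idx <- which(gm)
  theta <- atan2(ry[gm_idx], rx[gm_idx])
  zhalf <- as.integer(rz[gm_idx] > 0)
  ord <- order(zhalf, theta, r[gm_idx])
  sizes <- rep(floor(length(gm_idx) / n_parcels), n_parcels)
  sizes[seq_len(length(gm_idx) - sum(sizes))] <-
    sizes[seq_len(length(gm_idx) - sum(sizes))] + 1L
  labels <- array(0L, grid)
  labels[gm_idx[ord]] <- rep(seq_len(n_parcels), times = sizes)
  nets <- c("Visual", "Somatomotor", "DorsalAttention", "VentralAttention",
            "Limbic", "Frontoparietal", "Default", "Subcortical")
  tab <- data.frame(label = seq_len(n_parcels),
                    name = sprintf("Parcel_%03d", seq_len(n_parcels)),
                    network = nets[(seq_len(n_parcels) - 1) %% 8 + 1])
  list(p_gm = p_gm, p_wm = p_wm, p_csf = p_csf, labels = labels,
       region_table = tab)
}

#' Simulate one synthetic fPET subject with known ground truth
#'
#' Voxel signals are assembled additively: a tissue-weighted uptake curve
#' (GM 1.0, WM 0.7, CSF 0.3), band-limited network components on the
#' gray-matter parcels, CSF-weighted physiological sinusoids sampled at the
#' frame onsets (so super-Nyquist components alias exactly as in a real
#' scanner), a motion artifact equal to the inner product of the rigid-body
#' parameters with a per-voxel gain vector, and Gaussian noise with sd
#' proportional to the square root of instantaneous activity scaled by
#' scanner sensitivity.
#'
#' @param config A [sim_config()].
#' @return List of class `fpet_simulation` with elements `series`
#'   ([dynamic_series()]), `tpm` (list of GM/WM/CSF
#'   [tissue_probability_map()]s), `motion` ([motion_trace()]), `parcels`
#'   ([parcel_map()]) and `truth` (class `simulation_truth`: config echo,
#'   per-network noiseless regional components and ground-truth
#'   connectivity, uptake curve, per-region uptake gains and the motion
#'   trace used).
#' @export
simulate_subject <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  T <- config$n_frames; dt <- config$frame_duration
  V <- prod(config$grid)
  geom <- phantom_geometry(config$grid, config$n_parcels)
  t <- (seq_len(T) - 1) * dt
  U <- config_uptake(config)
  with_seed(config$seed, {
    # ground-truth networks on the parcels
    R <- config$n_parcels
    comps <- vector("list", length(config$networks))
    truths <- vector("list", length(config$networks))
    loadings <- vector("list", length(config$networks))
    for (i in seq_along(config$networks)) {
      nw <- config$networks[[i]]
      Z <- band_limited_latents(T, dt, nw$band, nw$n_latents)
      L <- nw$loading
      if (is.null(L)) L <- matrix(stats::rnorm(R * nw$n_latents), R)
      if (nrow(L) != R)
        stop("network loading must have one row per parcel", call. = FALSE)
      rn <- sqrt(rowSums(L^2))
      rn[rn == 0] <- 1
      L <- L / rn
      S <- nw$amplitude * (L %*% Z)
      comps[[i]] <- S
      loadings[[i]] <- L
      truths[[i]] <- connectivity_matrix(safe_cor(t(S)),
                                         region_ids = seq_len(R),
                                         method = "pearson",
                                         band = nw$band)
    }
    # motion random walk and per-voxel coupling gains
    steps <- matrix(stats::rnorm(T * 6), T, 6) %*%
      diag(rep(c(config$motion$step_trans, config$motion$step_rot),
               each = 3))
    M <- apply(steps, 2, cumsum)
    gains <- matrix(stats::rnorm(V * 6), V, 6) * config$motion$coupling
    phases <- stats::runif(length(config$physio$freqs), 0, 2 * pi)

    w_up <- 1.0 * as.vector(geom$p_gm) + 0.7 * as.vector(geom$p_wm) +
      0.3 * as.vector(geom$p_csf)
    X <- tcrossprod(w_up, U)
    lab_v <- as.vector(geom$labels)
    gm_vox <- which(lab_v > 0)
    for (S in comps)
      X[gm_vox, ] <- X[gm_vox, ] + S[lab_v[gm_vox], ]
    p_t <- rep(0, T)
    for (k in seq_along(config$physio$freqs))
      p_t <- p_t + config$physio$amplitudes[k] *
        sin(2 * pi * config$physio$freqs[k] * t + phases[k])
    X <- X + tcrossprod(as.vector(geom$p_csf), p_t)
    X <- X + gains %*% t(M)
    if (config$sigma0 > 0) {
      sd_t <- config$sigma0 * sqrt(pmax(U, 1e-8)) *
        sensitivity_noise_scale(config$sensitivity_kcps)
      X <- X + matrix(stats::rnorm(V * T), V, T) * rep(sd_t, each = V)
    }
    gain_r <- vapply(seq_len(R),
                     function(r) mean(w_up[lab_v == r]), 0)
    series <- dynamic_series(array(X, c(config$grid, T)), dt,
                             spatial_zoom = config$spatial_zoom)
    tpm <- list(
      GM = tissue_probability_map(geom$p_gm, "GM", config$spatial_zoom),
      WM = tissue_probability_map(geom$p_wm, "WM", config$spatial_zoom),
      CSF = tissue_probability_map(geom$p_csf, "CSF", config$spatial_zoom))
    motion <- motion_trace(M, dt)
    parcels <- parcel_map(geom$labels, geom$region_table)
    truth <- structure(list(config = config,
                            network_components = comps,
                            network_loadings = loadings,
                            truth_connectivity = truths,
                            uptake = U,
                            region_uptake_gain = gain_r,
                            motion = motion),
                       class = "simulation_truth")
    structure(list(series = series, tpm = tpm, motion = motion,
                   parcels = parcels, truth = truth),
              class = "fpet_simulation")
  })
}

# correlation that reports degenerate (constant) columns by index
safe_cor <- function(x) {
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant time series for region(s): ",
         paste(which(sds == 0), collapse = ", "), call. = FALSE)
  stats::cor(x)
}

#' Write all outputs of a simulated subject to a directory
#'
#' Emits the NIfTI series (+ JSON sidecar), tissue probability maps, motion
#' text file, parcellation (NIfTI + TSV), the per-band ground-truth
#' connectivity matrices (TSV) and a JSON echo of the configuration.
#'
#' @param sim Result of [simulate_subject()].
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "fpet_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dynamic_series(sim$series, file.path(dir, "pet.nii.gz"))
  for (cls in names(sim$tpm)) {
    img <- RNifti::asNifti(sim$tpm[[cls]]$prob, datatype = "double")
    RNifti::writeNifti(img, file.path(dir, sprintf("tpm_%s.nii.gz",
                                                   tolower(cls))))
  }
  write_motion_trace(sim$motion, file.path(dir, "motion.txt"))
  write_parcellation(sim$parcels, file.path(dir, "parcels.nii.gz"),
                     file.path(dir, "parcels.tsv"))
  for (i in seq_along(sim$truth$truth_connectivity))
    write_connectivity(sim$truth$truth_connectivity[[i]],
                       file.path(dir, sprintf("truth_band%d.tsv", i)))
  cfg <- sim$truth$config
  echo <- list(scanner_profile = cfg$scanner_profile, grid = cfg$grid,
               n_frames = cfg$n_frames, frame_duration = cfg$frame_duration,
               n_parcels = cfg$n_parcels, sigma0 = cfg$sigma0,
               exclude_s = cfg$exclude_s, seed = cfg$seed,
               bands = lapply(cfg$networks,
                              function(nw) c(nw$band$low, nw$band$high)))
  jsonlite::write_json(echo, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
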