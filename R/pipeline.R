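#' CompCor denoising and connectivity pipeline
#'
#' The unified regression path: crop the uptake-equilibration window, build
#' the nuisance design on the analyzed window (white-matter and CSF
#' principal components from the top-probability masks, PCA of the
#' 24-parameter motion expansion, and sine/cosine regressors for all
#' out-of-band grid frequencies), residualize every gray-matter voxel in a
#' single regression, extract parcel means and correlate them (Pearson).
#'
#' @param series A [dynamic_series()].
#' @param tpm_wm,tpm_csf White-matter and CSF [tissue_probability_map()]s.
#' @param motion A [motion_trace()] aligned with the full series.
#' @param parcels A [parcel_map()]; its nonzero labels define the
#'   gray-matter voxels to clean.
#' @param band Optional [frequency_band()] of interest; `NULL` omits the
#'   frequency block.
#' @param t_exclude Initial window to discard, seconds (default 600).
#' @param tissue_fraction Top-probability mask fraction (default 0.05).
#' @param variance_target,max_components Tissue PCA stopping rule.
#' @param motion_variance_target Motion PCA stopping rule.
#' @return List with `connectivity` ([connectivity_matrix()]), `regions`
#'   (cleaned [region_timeseries()]), `design` ([design_matrix()]),
#'   `series` (cleaned cropped [dynamic_series()]) and `report`.
#' @export
run_compcor <- function(series, tpm_wm, tpm_csf, motion, parcels,
                        band = NULL, t_exclude = 600,
                        tissue_fraction = 0.05, variance_target = 0.5,
                        max_components = 6,
                        motion_variance_target = 0.99) {
  s <- exclude_uptake_window(series, t_exclude)
  m <- exclude_uptake_window(motion, t_exclude,
                             onsets = series$frame_onsets)
  T <- n_frames(s)
  wm_mask <- threshold_tissue_mask(tpm_wm, tissue_fraction)
  csf_mask <- threshold_tissue_mask(tpm_csf, tissue_fraction)
  wm_pcs <- extract_tissue_components(s, wm_mask, variance_target,
                                      max_components)
  csf_pcs <- extract_tissue_components(s, csf_mask, variance_target,
                                       max_components)
  mot_pcs <- motion_pca(expand_motion_friston24(m),
                        motion_variance_target)
  freq <- if (!is.null(band))
    build_band_regressors(T, s$frame_duration, band)
  design <- assemble_design(wm_pcs, csf_pcs, mot_pcs, freq, T,
                            band = band)
  clean <- compcor_residualize(s, design, mask = parcels$labels > 0)
  regions <- extract_regional_timeseries(clean, parcels)
  list(connectivity = pearson_connectivity(regions, band = band),
       regions = regions, design = design, series = clean,
       report = attr(clean, "filter_report"))
}

#' Butterworth band-pass connectivity pipeline
#'
#' The region-wise filtering path: crop the uptake-equilibration window,
#' extract parcel means, apply the zero-phase fourth-order Butterworth
#' band-pass, and estimate partial correlations controlling for the six
#' rigid-body motion parameters.
#'
#' @inheritParams run_compcor
#' @param band [frequency_band()] with upper edge strictly below Nyquist.
#' @param order Butterworth order (default 4).
#' @param causal Single forward pass instead of zero-phase.
#' @return List with `connectivity`, `regions` (filtered) and `report`.
#' @export
run_butterworth <- function(series, motion, parcels, band,
                            t_exclude = 600, order = 4, causal = FALSE) {
  s <- exclude_uptake_window(series, t_exclude)
  m <- exclude_uptake_window(motion, t_exclude,
                             onsets = series$frame_onsets)
  regions <- extract_regional_timeseries(s, parcels)
  filt <- butterworth_bandpass(regions, band, order = order,
                               causal = causal)
  list(connectivity = partial_corr_connectivity(filt, m$params,
                                                band = band),
       regions = filt, report = attr(filt, "filter_report"))
}
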