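---
title: "Denoising and metabolic connectivity for constant-infusion fPET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising and metabolic connectivity for constant-infusion fPET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpetmc)
```

## The problem

A bolus-plus-constant-infusion [^18F]FDG protocol produces a voxel signal
that is, to first order, a monotone uptake ramp. The quantity of interest
for metabolic connectivity is the small band-limited fluctuation riding on
that ramp; its between-region correlation is confounded by everything the
regions share that is not neuronal: the ramp itself, cardiac and
respiratory oscillations, residual head motion, and count noise whose
variance grows with instantaneous activity. At 3 s framing the Nyquist
frequency is only 1/(2·3) ≈ 0.167 Hz, so respiration near 0.3 Hz does not
disappear — it folds to |0.3 − 1/3| ≈ 0.033 Hz and masquerades as slow
"connectivity". This package implements a unified regression filter for
these confounds, the conventional band-pass alternative, and the
downstream spectral, clustering and reliability machinery, validated
end-to-end on a simulator with known ground truth.

## The unified CompCor regression

For each gray-matter voxel time course $y$ on the analyzed window (after
discarding the first 10 min of equilibration) we fit one least-squares
model $y = X\beta + \varepsilon$ and keep $\hat\varepsilon$. The columns
of $X$:

* **Tissue components.** White matter and CSF probability maps are
  thresholded to the upper 5% of nonzero-probability voxels (ties with the
  cutoff included, so the mask never depends on voxel order). Voxel time
  series inside each mask are mean-centered and variance-normalized —
  correlation PCA, so hot voxels do not dominate — and the smallest number
  of principal components reaching 50% cumulative explained variance is
  kept, capped at 6 per compartment. "Half the variance" operationalizes
  a *majority* of compartment variance; the cap keeps the design
  well-conditioned, and both knobs are exposed
  (`variance_target`, `max_components`). Because the uptake ramp is the
  dominant shared signal in these compartments, the first component
  absorbs it: on simulated data the WM/CSF subspace captures more than
  95% of the injected uptake curve's variance (this is a test).
* **Motion.** The six rigid-body parameters are expanded to the
  24-regressor model (parameters, backward-difference derivatives with a
  leading zero row, and both sets squared) and reduced by PCA at a 99%
  variance target. The derivative convention and the separate PCA for the
  motion block (rather than a joint PCA with tissue components) follow
  the standard expansion practice; running the blocks separately keeps
  the provenance of every column interpretable.
* **Frequency regressors.** For every Fourier grid frequency
  $f_k = k/(T\Delta t)$ of the analyzed window lying strictly outside the
  band of interest, a cosine/sine pair evaluated at the frame onsets is
  added (the identically zero sine at the exact Nyquist frequency is
  dropped). Regressing these out is algebraically equivalent to an ideal
  brick-wall filter on the window's frequency grid and, crucially, happens
  *simultaneously* with the confound regression, so no sequential step can
  reintroduce removed variance. The grid is computed on the cropped
  window, not the full scan, because regression filtering must match the
  window actually analyzed.

An intercept is always present; rank-deficient assemblies are repaired by
dropping later duplicate columns (warned, labels preserved). Residuals are
orthogonal to every column by construction — the package tests this at
1e-8 on simulated subjects — and component signs are fixed (largest
element positive) so identical inputs give bit-identical designs.

The Butterworth path mirrors common practice: parcel-mean extraction,
zero-phase (forward–backward) 4th-order band-pass with odd-reflection
padding of three filter lengths, then partial correlation controlling for
the six raw motion parameters. Zero-phase application was chosen because
correlation is phase-sensitive; a `causal = TRUE` flag restores the
single-pass behavior. The six raw parameters (not the 24-term expansion)
are used as partial-correlation confounds, matching the usual reading of
"motion parameters"; the confound set is an argument.

## The simulator

`simulate_subject()` builds a deterministic phantom — concentric CSF core,
WM shell and GM ribbon inside an ellipsoid, with the ribbon split into
equal-size angular parcels — and assembles voxel signals additively:

* **Uptake** $U(t) = A_b(e^{-t/\tau_d} - e^{-t/\tau_r}) +
  \alpha t(1 - e^{-t/\tau_s})$, weighted 1.0/0.7/0.3 for GM/WM/CSF.
  Defaults: $\alpha = 0.067$ units/s and $\tau_s = 300$ s give a plateau
  of ~100 units at 25 min; $\tau_d = 25$ s, $\tau_r = 10$ s and a bolus
  fraction of 0.2 put the bolus peak at 20:80 relative to the infusion
  amplitude, mirroring a 20:80 bolus:infusion administration split, and
  make the curve non-decreasing once the transient has washed out
  (t ≳ 2 min) — both properties are tested against dense evaluation of
  the closed form.
* **Networks.** Each ground-truth network draws C = 3 latent series whose
  discrete spectra live only on grid frequencies inside its band, whitens
  them to an exactly identity sample covariance, and mixes them through a
  row-normalized loading matrix. Whitening makes the two ground-truth
  routes — correlation of the stored noiseless components and the
  normalized $LL^\top$ — agree to machine precision, and, being a linear
  mix of band-limited series, preserves band-limitation. The latent-factor
  construction is a stand-in for unknown physiology: its parameters are
  exposed, not asserted as biology.
* **Physiology.** CSF-weighted sinusoids at 0.3 Hz (amplitude 1.5) and
  1.0 Hz (0.8), evaluated at the frame onsets, so super-Nyquist components
  alias exactly as in a real scanner. At integer-second framing the 1 Hz
  component folds to DC (|1 − n·f_s| = 0 for both 1 s and 3 s frames) and
  is absorbed by the intercept — a genuine consequence of the aliasing
  formula, not a defect.
* **Motion.** A Gaussian random walk (steps 0.02 mm, 5·10⁻⁴ rad) coupled
  into each voxel through a random 6-vector gain (sd 0.5 signal units),
  i.e. additive at signal level rather than by resampling volumes:
  deterministic, testable, and sufficient for validating motion
  regression.
* **Noise.** Gaussian with sd $\sigma_0\sqrt{\max(U(t),\epsilon)}$ scaled
  by $\sqrt{176/\text{sensitivity}}$ — pseudo-Poisson heteroscedasticity.
  The two profiles use NEMA-style sensitivities of 176 (high-sensitivity,
  1 s frames, 1500 of them) and 15 kcps/MBq (standard, 3 s frames, 400),
  so the standard profile carries √(176/15) ≈ 3.43× the noise. The
  default $\sigma_0 = 1$ corresponds to ~10% voxel-level noise at plateau
  on the high-sensitivity profile — a deliberately benign desk-scale
  regime for an 8–10 mm voxel grid.

A master seed fully determines all outputs (tested bit-identical). The
default grid is 24×24×16 voxels with 20 parcels; 114 parcels (mirroring a
100-cortical + 14-subcortical atlas) are available via `n_parcels`.

What the simulator does **not** emulate: realistic anatomy, tomographic
reconstruction and its spatially correlated noise, attenuation/scatter
effects, kinetic heterogeneity across regions, true Poisson counts, or
actual displacement-induced resampling. Passing tests therefore show that
the *algorithms* behave as specified under controlled confounds, not that
any particular real-data effect size will be reproduced; published
real-data agreement and reliability values depend on scans this package
does not ship.

## Numerical choices

* Residualization uses QR (`qr.resid`); tests cross-check against explicit
  normal equations.
* PCA uses SVD of the standardized data matrix; tests cross-check against
  an eigendecomposition of the Gram matrix.
* The zero-phase Butterworth magnitude is validated against the analytic
  order-4 band-pass response $|H|^2 = (1+\Omega^8)^{-1}$,
  $\Omega = (f^2 - f_l f_h)/(f(f_h - f_l))$, squared for bidirectional
  application; amplitudes are measured by least-squares sinusoid fits on
  the central 80% of long series to stay clear of edge transients.
* Welch PSD: Hann window, segments of T/4 with 50% overlap, mean removal
  per segment, one-sided density normalized so integrated power matches
  the variance (Parseval is tested on white noise at 10%). The estimator
  choice is an implementation decision — the method of published PSDs is
  typically unstated — and all parameters are exposed.
* Baseline removal before PSD defaults to cubic polynomial detrending;
  a `design` mode reuses the CompCor tissue components instead.
* Ward clustering operates on Euclidean distances between connectivity
  *profiles* (matrix rows) in the `ward.D2` convention (heights
  √(2·ΔESS)); merge order is verified against exhaustive enumeration at
  R = 4. Using profile rows as feature vectors is a documented assumption
  — hierarchical clustering of "a connectivity matrix" needs a feature
  vector and the profile row is the field's default.
* Split-half reliability partitions frames at random (non-contiguous)
  within each subject, the natural reading of random data splits;
  `contiguous = TRUE` gives first/second halves. The 95% CI is the
  2.5/97.5 percentile of the permutation distribution. Group-mean
  matrices (not subject-level) are correlated between halves.
* Group averaging uses raw correlations by default (`fisher_z = TRUE`
  optional) for fidelity to reported connectivity magnitudes.
* Region tables are stored and processed in label order; any
  network-based ordering is a display concern only.
* edNLM is a generic re-implementation of spatiotemporal non-local means
  (two passes, 3×3×3×{3,5} patches, search window equal to the patch
  window, edge-clamped patch coordinates, Gaussian weights normalized to
  unit sum, then 5 mm smoothing), with the bandwidth `h` exposed and an
  `"auto"` rule of robust-noise-sd × patch size. It is not a bit-exact
  port of any toolbox.

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on small phantoms (typically 12×12×8 voxels,
360 frames) where every invariant is checked exactly; the end-to-end
checks use the full default conditions (24×24×16, 1500 frames of 1 s,
20 regions, and 400 frames of 3 s for the standard profile). The
acceptance script estimates split-half reliability from 6 simulated
subjects at 200 permutations — the permutation distribution is extremely
tight on simulated data, so these sizes characterize it fully; the
function default remains 5000 permutations.

## Known limitations

* The frequency-regressor filter is exact only on the analyzed window's
  Fourier grid; signal at off-grid frequencies leaks slightly across the
  band edge, as with any finite-window filter.
* With very short windows the out-of-band regressor block approaches the
  number of frames and the residual degrees of freedom shrink; the design
  constructor enforces numerical full rank but connectivity estimates
  from few residual degrees of freedom are noisy.
* Partial correlation with many confounds at short T inherits the same
  caveat.
* The edNLM filter is O(window × patch × voxels × frames) in plain R and
  is intended for desk-scale arrays and method comparison, not whole-brain
  production smoothing.
* Reliability of a *pure-noise* null fluctuates at ~1/√(number of edges)
  per dataset; null checks therefore average several independent
  datasets.
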