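---
title: "Compression MR elastography of tumors: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compression MR elastography of tumors: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmre)
```

## The scientific problem

Malignant tumors are mechanically abnormal: they are stiffer and more viscous
than normal tissue, and they carry elevated solid stress (pressure exerted by
the solid constituents) and interstitial fluid pressure (IFP). Viscoelasticity
can be measured non-invasively with MR elastography (MRE); the pressure
components normally require invasive catheter measurements. A candidate
non-invasive marker of solid stress is the **compression stiffening rate**:
when a tumor is measured by MRE while an external, known compression is
applied, the apparent elasticity increases roughly linearly with the applied
stress, and the slope of that line (elasticity in kPa versus compression in
kPa, hence dimensionless) carries information about solid stress that basal
stiffness alone does not.

`cmre` implements a complete in-silico version of such a study in mice
bearing two xenografted liver tumor types (hepatocellular carcinoma, HCC, and
cholangiocarcinoma, CCA): a calibrated cohort generator, a forward wave
simulator, the inversion pipeline, synthetic digital histology with
quantification, and the full statistical battery.

## The reconstruction model

MRE encodes the tissue displacement of a time-harmonic shear wave (600 Hz
here) into the MR phase. Per motion-encoding direction, four phase offsets
sample one vibration period. The pipeline is:

1. **Unwrapping.** Phase images are unwrapped per slice by integrating
   wrapped phase differences along a reference row and then along each column
   (Itoh's method), restricted to the tissue support, with a
   congruence-preserving `2*pi` alignment of consecutive slices. For fields
   whose true inter-voxel phase difference stays below `pi` — guaranteed here
   by the amplitude normalization of the simulator — this is exact, fully
   vectorized, and removes the need for a slower quality-sorted unwrap.
   Per-slice global `2*pi` offsets are harmless: they are spatially constant
   and are annihilated by the curl.
2. **Harmonic extraction.** A single-bin DFT over the offsets returns the
   complex displacement amplitude per voxel and direction, converted to
   micrometres via the encoding efficiency.
3. **Curl.** The complex curl `q = curl(u)` (central differences, anisotropic
   voxel spacing of 300 x 300 x 350 um) removes compressional, irrotational
   wave components, which do not obey the shear-wave dispersion relation.
4. **Helmholtz inversion.** For locally homogeneous, time-harmonic motion,
   every curl component obeys `G* = -rho * omega^2 * q / laplacian(q)`, with
   `rho = 1000 kg/m^3` (soft-tissue convention) and `omega = 2*pi*600` rad/s.
   The storage modulus G' ("elasticity") is the real part, the loss modulus
   G'' ("viscosity") the imaginary part, both in kPa.

### Numerical choices in the inversion

* **Smoothing.** The complex curl is smoothed with a separable, mask-aware
  Gaussian, default SD 0.9 voxel. The ratio `q / laplacian(q)` is invariant
  to any linear shift-invariant filter for a field with a single `k^2`
  (all simulated waves share the medium's wavenumber), so smoothing does not
  bias the noise-free answer; it suppresses the noise-induced downward bias
  of the least-squares combination (noise inflates `|laplacian|^2` in the
  denominator). The default was chosen against the package's own
  self-consistency oracles: at 0.03 rad phase noise the ROI-mean bias is
  about +0.3% (it was about -5% at SD 0.65); noise-free plane-wave recovery
  stays within 2% over G' in 1-4 kPa, G'' in 0.5-2 kPa. The SD is exposed as
  `smooth_sigma`.
* **Laplacian.** Second central differences per axis with a compact
  correction term `-h^2/12 * D2(D2 q)`. The plain stencil underestimates
  `k^2` by about 3% at 10 voxels per wavelength and 9% at 6; the corrected
  stencil is 4th-order accurate (0.06% and 1.2% respectively), which is what
  makes the 2% plane-wave oracle achievable at the acquisition's 6-8 voxels
  per wavelength. At the one-voxel ring where the wider stencil does not
  fit, the plain stencil is used; ROI erosion keeps that ring out of the
  statistics.
* **Component combination.** The three curl components are combined by a
  `|laplacian|^2`-weighted average, algebraically the least-squares estimate
  of G* across components; a component-wise median is available via
  `combine = "median"`. Components with `|laplacian|` below `1e-3` times the
  grid median are excluded per voxel (stability floor, configurable); voxels
  with no admissible component are masked rather than returned as infinities.
* **Negative loss moduli** (possible under noise) are clamped to zero and
  flagged in the `clamped` mask rather than discarded.
* **ROI rule.** Statistics use the five central slices of the nine-slice
  stack (slices 3-7, 1-based), the ROI eroded in-plane by one voxel to avoid
  tumor borders, intersected with the validity mask.

## The forward simulator

The simulator exists to exercise the reconstruction honestly, not to model a
scanner. It superposes three transverse plane waves from fixed azimuths
(15, 135, 255 degrees) with small out-of-plane tilts, mild amplitude taper,
and mixed polarizations, each with the complex wavenumber
`k = omega * sqrt(rho / G*)`, so the field decays as a lossy medium must. Two
practical consequences follow:

* At 600 Hz and the cohort's moduli, the penetration depth is one to three
  millimetres, so a plane wave cannot span the 26 mm field of view with
  resolvable phase. The simulated tumor is therefore a finite disk (radius 8
  voxels, through all slices) centred in the FOV; outside it the phase is
  pure background noise, as in a real acquisition. The ROI is the support
  eroded by 3 voxels.
* Wave amplitudes are normalized per scan so the steepest phase gradient
  stays near 2.4 rad/voxel — the in-silico analogue of choosing the motion
  encoding so the phase remains unwrappable. Stiffer tumors (longer
  wavelengths) then wrap by several cycles while soft, lossy ones stay below
  one, as in practice.

Compression enters through the linear law `G'(sigma) = G'_0 + slope * sigma`
with G'' held at its basal value (whether viscosity also stiffens under
compression is unknown; holding it constant is the conservative choice). The
applied compressions default to 0, 2 and 4 kPa: the balloon inflation
protocol the design mimics does not report its stresses in kPa, so the
package picks levels that keep the slope in the published dimensionless
range; they are configurable, and the slope's horizontal scale should be
read as instrument-specific.

A per-session lognormal factor (sdlog 0.08) multiplies both moduli of a scan
session, representing day-to-day positioning and physiological variability.
It was set from the published test-retest repeatability of about 22%
(`1.96 * sqrt(2) * 8% = 22.2%`) before any pipeline tuning, and it is what
makes the package's repeatability substudy land in that range.

## Cohort calibration

Covariates (solid stress, IFP, volume, collagen fraction, cellularity) are
drawn per tumor type from truncated multivariate Gaussians with the published
group means and SDs. The outcomes follow the published structural equations

* elasticity = a(type) + 0.17 IFP + 0.28 collagen + e
* viscosity  = a(type) + 0.13 IFP + 0.30 collagen + e
* slope      = a(type) - 0.06 SS - 0.44 collagen + 0.02 cellularity - 1.80 I(CCA) + e

with three layers of calibration:

1. **Intercepts** are solved against the realized covariate draws so each
   group's outcome mean equals its configured target exactly. (Tumor-type
   coding: CCA = 1; the per-type intercept absorbs the coding, so the group
   means are guaranteed either way.)
2. **Residual SDs** start from the closed form
   `sigma^2 = Var(eta) * (1 - R2) / R2` (with `Var(eta)` the pooled variance
   of the linear predictor) and are then refined by a deterministic internal
   pilot simulation so the *fitted* R^2 of each equation at large n matches
   the configured 0.82 / 0.87 / 0.75 despite the truncation described below.
3. **Within-group covariate correlations** are not published. Under
   independence, the structural betas and covariate SDs make the published
   partial correlations unattainable (collagen-elasticity would be ~0.57, not
   0.84). The defaults cor(IFP, collagen) = 0.92, cor(SS, collagen) = 0.217,
   cor(SS, cellularity) = -0.314, cor(collagen, cellularity) = -0.181 are the
   exact solution reproducing the published partial-correlation rows for the
   stiffening rate and the collagen-elasticity entry, given the betas and
   R^2-matched residuals. Two caveats are worth stating plainly: the
   published pair (0.84 collagen, 0.70 IFP versus elasticity) is *jointly*
   infeasible for any Gaussian structural model with these betas (their
   contributions are nearly equal, so their partial correlations cannot
   differ by that much), and the implied AUC of the negated stiffening rate
   for high solid stress is about 0.74 rather than the published 0.86 —
   with Gaussian covariates, the group whose slope mean is higher also
   contributes most of the high-solid-stress positives, which partially
   cancels the within-group association. Both are properties of the printed
   summary statistics, not of this implementation, and neither calibration
   was adjusted toward those downstream quantities.

Physical validity is enforced by redrawing residuals (exact truncated-normal
draws) so that basal moduli are positive and `G'(sigma)` stays positive over
the configured compression range — every generated subject has a measurable
compression series, matching a cohort retained for analysis.

```{r calibration}
cfg <- cohort_config()
calibrate_structure(cfg)
```

## Synthetic histology

* **Picrosirius-red tiles.** Red fibrillar strokes are drawn over a pale
  counterstained tissue disk until the stained pixels cover exactly the
  target fraction of tissue (the last fibre is trimmed pixel by pixel), so
  the renderer's ground truth is exact. Quantification mirrors the standard
  reading: optical-density colour deconvolution with a stain matrix matched
  to the renderer's palette (overridable), Otsu thresholding of the collagen
  channel with an absolute floor so unstained tiles return zero instead of
  split noise, and background exclusion by OD norm.
* **Nucleus fields.** `round(density x area)` bright ellipses (7-10 um
  diameter) on a dark background, a configurable fraction placed as touching
  pairs; counting is Otsu thresholding, hole filling, distance-transform
  watershed, and a 25 um^2 minimum-area floor (the rendered nuclei all
  exceed it). At 20% touching nuclei the count stays within 2% of truth.

What the generator does **not** emulate: scanner physics (relaxation,
k-space, coils), wave reflections and mode conversion, spatial heterogeneity
within a tumor, stain variability across laboratories, necrosis, and the
balloon-slippage failures that excluded animals from the original protocol.
Passing tests therefore demonstrate that the *pipeline* is correct and
well-calibrated under its stated model, not that it would produce these
numbers on raw scanner data.

## Statistics

The battery mirrors a small-animal tumor study: Mann-Whitney group
comparisons (exact p below a combined n of 20 without ties), partial
correlations with tumor type as covariate (t test on n - 3 df), MedCalc-style
stepwise regression (enter p < 0.05, remove p > 0.10, both configurable),
rank-estimator AUCs with Hanley-McNeil standard errors and a two-sided z test
against 0.5, and the AUC-based sample-size search (smallest positive-group
size whose Hanley-McNeil power reaches the target; at expected AUC 0.85,
alpha 0.05, power 80%, negative:positive ratio 1.7 it returns 22 subjects).
Markers negatively associated with their condition (the stiffening rate
against solid stress) are negated before ranking, and the negation is
recorded in the result. The 15.6 mmHg solid-stress threshold is applied as
">= cutoff" (the boundary value is positive).

## Problem sizes

The packaged default reproduces the study scale: 15 + 9 subjects, three
compressions, 87 x 67 x 9 acquisitions, one 512-px picrosirius tile and one
1-mm^2 nucleus field per subject, five HCC subjects scanned twice for
repeatability. A full `run_experiment()` at that scale takes a few minutes on
one CPU; the package's tests run reduced versions of everything except the
acceptance checks, which use the full acquisition geometry.

## Known limitations

* The compression stiffening rate's horizontal scale is instrument-specific
  (applied stresses in kPa are assumed, not measured).
* The inversion assumes local homogeneity; the simulator honours it, real
  tumors do not.
* The Itoh unwrap assumes inter-voxel phase steps below pi; the simulator's
  amplitude normalization guarantees it, strongly undersampled data would
  need a quality-guided unwrap.
* Gaussian cohort calibration reproduces printed means, SDs, R^2 and partial
  correlations, but cannot simultaneously reproduce every printed rank-based
  quantity (see the AUC caveat above).
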