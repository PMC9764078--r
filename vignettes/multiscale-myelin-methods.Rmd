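---
title: "Methods: multiscale myelin tissue assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale myelin tissue assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxmyelin)
```

## Overview

`mxmyelin` implements a three-modality pipeline for assessing myelinated
brain tissue at complementary length scales:

1. **Scanning micro-X-ray diffraction (SμXRD)** probes the nanometre-scale
   ultrastructure of the myelin sheath: the lamellar repeat distance of the
   multilamellar membrane stack and a minority planar-hexagonal lipid
   phase.
2. **Diffusion tensor imaging (DTI)** summarizes micron-scale water
   diffusion per voxel with the standard single-tensor model.
3. **Quantitative histology** measures the structure-tensor anisotropy of
   myelin-stained sections and cell density on Nissl-stained sections.

Per-region metric tables from the three modalities are then compared with
pooled multiple linear regression, including a collinearity screen and
noncentral-F confidence intervals for the squared multiple correlation.
Every stage is driven end-to-end by a synthetic-data generator with known
ground truth, so the whole pipeline is testable without any raw
acquisition.

## The two-phase Bragg-peak model

A corrected radial profile $I(q)$ ($q = (4\pi/\lambda)\sin\theta$, with
$2\theta$ the full scattering angle) is modelled as the sum of two phases,

$$I(q) = I_L(q) + I_H(q),$$

where the multilamellar component has Gaussian quasi-Bragg peaks at

$$q_L^h = \frac{2\pi h}{\lambda_L}, \qquad h = 2, 3,$$

and the hexagonal component at

$$q_H^{h,k} = \frac{4\pi}{\sqrt{3}\,\lambda_H}\sqrt{h^2 + hk + k^2}$$

for the reflections $(1,0)$, $(2,0)$ and $(2,3)$.  The first lamellar
order is not used because it sits behind the beamstop at short
camera lengths.  The $(2,3)$ reflection (spacing ratio $\sqrt{19}$
relative to $(1,0)$) is kept as the configured indexing; the reflection
list is an explicit argument of `phase_fit_config()` for users who prefer
a different indexing.

`fit_two_phase()` fits this model by bounded Levenberg–Marquardt least
squares with the peak **centers hard-constrained to the lattice**: each
phase contributes a single shared lattice unit, and only amplitudes
($\ge 0$), widths ($> 0$) and an optional residual linear baseline are
otherwise free.  The shared-parameter constraint is what makes the fit
return lattice *units* rather than unrelated peak positions, and it
stabilizes the weak hexagonal reflections — in particular at the
commensurate point $\eta = \lambda_L/\lambda_H = \sqrt{3}/2 \approx
0.866$, where the hexagonal $(2,0)$ ring coincides exactly with the
lamellar $h = 2$ ring and per-peak amplitude assignment would otherwise be
degenerate.

Numerical choices:

* Initialization: $\lambda_L$ from the intensity argmax in
  $q \in [0.55, 0.90]$ nm$^{-1}$ mapped through $h = 2$; $\lambda_H$ from
  the strongest residual peak in the $(1,0)$ search window.  Bounds
  $\lambda_L \in [12, 25]$ nm, $\lambda_H \in [12, 30]$ nm bracket the
  physiological myelin period around the healthy standard
  $\lambda_L^* = 17.6$ nm.
* Termination: relative tolerances $10^{-10}$, at most 500 iterations;
  non-convergence is a flagged result, never a silent value.
* A profile with no peak above the noise floor (5 times a robust
  difference-based noise scale) in the lamellar window is classified
  "no myelin" — a flagged result excluded from maps, not an exception.
* If no hexagonal signal is detected, the hexagonal component is removed
  from the model rather than left free (it would otherwise absorb
  lamellar residue through the coincident $(2,0)$ ring); $\lambda_H$ is
  then reported unidentifiable and $C_H = 0$.

Phase contents are the analytic Gaussian integrals
$C_{Phase} = \sum_{peaks} A\sigma\sqrt{2\pi}$, which the tests verify
against numerical quadrature to $10^{-6}$ relative.  Fitted tiles are
classified against the literature standards $\lambda_L^* = 17.6$ nm and
$\eta^* = 0.866$ (`reference_standards()`): compressed/expanded periods
and sub-/super-commensurate packing outside a relative tolerance band
(default 1%).

## DTI fitting and metrics

`fit_tensor()` uses weighted log-linear least squares on
$\ln S = \ln S_0 - b\,g^T D g$: an ordinary pass followed by one
reweighting with weights equal to the squared predicted signals.  This
estimator is deterministic, exact on noiseless data, and adequate at the
signal-to-noise ratios of the synthetic fixtures; no iterative NLLS is
needed.  Negative eigenvalues are clamped to zero for metric computation
(keeping FA $\le 1$) and flagged per voxel.

The scalar metrics are MD $= (\lambda_1+\lambda_2+\lambda_3)/3$,
AD $= \lambda_1$, RD $= (\lambda_2+\lambda_3)/2$, the usual FA, and the
**trace-normalized** Westin shape indices
CL $= (\lambda_1-\lambda_2)/\mathrm{tr}$,
CP $= 2(\lambda_2-\lambda_3)/\mathrm{tr}$,
CS $= 3\lambda_3/\mathrm{tr}$.  The trace-normalized variant is chosen
because it makes CL + CP + CS $= 1$ an exact identity, which — together
with MD $= ($AD$ + 2\,$RD$)/3$ — is precisely the *structural
collinearity* the cross-modal screen must detect when all seven metrics
enter a regression.  The $\lambda_1$-normalized variant is exposed via
`tensor_metrics(..., normalization = "lambda1")` for users following the
other convention.  No diffusion preprocessing (denoising, Gibbs removal,
bias field, eddy correction) is reimplemented: published tools exist for
those steps and the pipeline accepts already-clean volumes.

## Histological metrics

`structure_tensor()` computes per pixel the 2×2 tensor of Gaussian-
derivative gradients (scale $\sigma_g$, default 0.5 µm) smoothed by a
Gaussian window ($\sigma_w$, default 2 µm), and the anisotropy index
$AI = (\lambda_1-\lambda_2)/(\lambda_1+\lambda_2) \in [0,1]$.  The
defaults target axon-scale texture at the photomicrograph sampling of
0.013 µm²/pixel; both scales are arguments, since AI depends on them.
Flat regions (tensor energy below $10^{-6}\times$ the image variance — a
scale-free guard, with an absolute floor for numerically constant images)
are flagged and reported as AI = 0; `roi_ai()` averages the *pixelwise*
AI over a region, excluding flagged pixels (mean of pixel AI, not AI of
the mean tensor).  RGB input is converted by luminance; no stain
deconvolution is attempted (gold-chloride myelin staining is effectively
monochrome).

`detect_cells()` reimplements a standard automated counting chain:
inversion (stained somata are dark), background flattening by large-scale
Gaussian subtraction (15 µm), Otsu threshold, distance-transform watershed
to split touching cells, and an area filter (defaults 20–400 µm²,
the neuron/glia soma range).  All stages are exposed in
`cell_count_config()` since no canonical parameter set exists.  Cell
density is centroid count divided by ROI area in cells/µm² (displays
conventionally scale this by $10^2$).

## Cross-modal regression

`assemble_table()` pivots per-(animal, region) metric records into the
pooled table — by default 5 animals × 5 regions = 25 rows.  Pooling
ignores within-animal correlation deliberately: the comparison model is
a simple i.i.d.-error OLS regression
$y_{kj} = b^T x_{kj} + c + e_{kj}$, fitted by `fit_mlr()`, with missing
cells handled by listwise deletion (the least surprising OLS behavior).
Reported statistics satisfy the identities
$R^2_{adj} = 1-(1-R^2)(n-1)/(n-k-1)$ and
$F = (R^2/k)/((1-R^2)/(n-k-1))$ to machine precision.

`collinearity_screen()` standardizes the predictor matrix and removes one
column of each dependent group while the smallest singular value is below
$10^{-8}$ times the largest.  Which member of a group to drop is pure
convention; the screen consults a `prefer_drop` list first (default
`c("RD", "CL")`, the conventional exclusions for full tensor-metric
predictor sets, where RD is redundant given AD and MD, and CL given CP
and CS) and otherwise drops the last-listed member.

`r2_confidence_interval()` inverts the noncentral-F distribution of the
observed overall F over the noncentrality parameter, using the
fixed-regressor convention $\rho^2 = \Lambda/(\Lambda+n)$, and floors the
lower bound at zero.  When the observed F is small the interval can
collapse to a point at zero — a known feature of this inversion, not a
bug.  The suite verifies 95% ± 2% empirical coverage at $\rho^2 = 0.3$,
$n = 25$, $k = 5$ over 2000 replicates.

## The synthetic-data generator

The generator produces every input with known truth, at the study's
acquisition settings:

* **Diffraction** (`make_radial_profile`, `make_detector_frame`,
  `make_scan`): Gaussian peaks on a polynomial background over
  $q \in [0.1, 12]$ nm$^{-1}$, 2 µm scan step, with Poisson counting
  noise (the natural model for photon counts; the default main-peak
  amplitude of 2500 counts corresponds to a peak SNR of 50).  Default
  amplitudes make the lamellar peaks ~5× the hexagonal ones, reflecting a
  dominant multilamellar phase.  Frames render the radial model
  azimuthally symmetrically at 12.6 keV; the consistency fixtures use a
  600 mm camera with a 512² detector at 75 µm pixels so the Gaussian line
  shapes span many radial pixels and azimuthal integration resolves them
  (at 135 mm the SAXS peaks are only ~2 pixels wide; the q–pixel mapping
  itself is validated separately at that geometry).
* **DWI** (`make_dwi`, `make_dwi_volume`): $S = S_0\exp(-b\,g^TDg)$ under
  the two-shell protocol (4 b0, 30 directions each at b = 3000 and
  6000 s/mm², deterministic spherical-Fibonacci directions), with Rician
  noise (the standard model for magnitude MR data).
* **Histology** (`make_myelin_image`, `make_nissl_image`): superposed
  sinusoidal gratings whose orientations follow a wrapped normal around
  the true direction — the dispersion controls anisotropy, and the
  ground truth for AI is an *ordering* (higher dispersion ⇒ lower AI),
  not an absolute value, since AI depends on the analysis scales; and
  soft-edged dark discs with controlled radii and separation
  (rejection-sampled, erroring after bounded retries).
* **Tables** (`make_crossmodal_table`): multivariate-normal predictors and
  a response whose coefficient vector is rescaled so the *population*
  $R^2$ equals the target exactly; the suite confirms the fitted $R^2$
  converges to the target at $n = 10^4$.

Every generator is a deterministic function of (spec, seed).

What the generator does **not** emulate: realistic brain geometry, X-ray
form factors, absorption or detector point spread; MR acquisition
artifacts (eddy currents, Gibbs ringing, bias fields); staining
variability or anisotropic illumination.  Passing tests therefore
demonstrate correctness of the estimators on their own generative models,
not robustness to every artifact of real acquisitions.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use desk-scale problem sizes
chosen to exercise every code path: 20-seed Monte Carlo for the noisy
lamellar fit, 3×3 scan grids, 512² synthetic frames, 1000 random tensors
for the metric identities, and 2000 replicates for interval coverage.
`scripts/acceptance.R --seed S --out f.json` recomputes all headline
quantities from scratch under a single seed.

## Known limitations

* The single-tensor diffusion model under-represents crossing-fiber
  voxels by construction; that limitation is embraced, not fixed.
* Hexagonal-phase content is intrinsically hard to separate from lamellar
  content at exact commensurability (coincident rings); $\lambda_H$
  remains well identified through the $(1,0)$ and $(2,3)$ reflections.
* No spatial registration across modalities is provided; regions are
  matched by expert labels, not coordinates.
* The regression layer reports raw two-sided p-values without
  multiple-testing correction, matching common practice for small
  exploratory animal studies.
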