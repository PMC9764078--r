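# mxmyelin

Multiscale assessment of myelinated brain tissue from three complementary
modalities: scanning micro-X-ray diffraction (SμXRD), diffusion tensor
imaging (DTI), and quantitative histology — plus the pooled multiple
linear regression that relates them region by region.

The package is aimed at researchers analysing small-animal white-matter
studies (e.g. traumatic brain injury models) who need a tested, scriptable
replacement for one-off beamline/MATLAB analysis code.

## What it computes

**SμXRD.** Radial integration of 2D diffraction frames to I(q)
(q = 4π sin θ / λ), flux normalization and background subtraction, and a
two-phase Bragg-peak fit `I(q) = I_L(q) + I_H(q)` with Gaussian line
shapes whose centers are hard-constrained to the lattices

- multilamellar: `q_L^h = 2πh/λ_L`, h = 2, 3;
- hexagonal: `q_H^{h,k} = (4π/√3 λ_H)·√(h² + hk + k²)`, reflections
  (1,0), (2,0), (2,3).

The fit returns the myelin lamellar period λ_L, the hexagonal lattice
unit λ_H, the phase contents `C = Σ A·σ·√(2π)` (analytic ∫I_Phase dq),
and the commensurability η = λ_L/λ_H. Fitted values are classified
against the healthy-tissue standards λ_L* = 17.6 nm and η* = 0.866
(compressed/expanded; sub-/super-commensurate). Scan-level helpers map
these per tile and build kernel-density PDFs of λ_L per region.

**DTI.** Weighted log-linear tensor fitting of two-shell
(b = 3000/6000 s/mm², 30 directions each, 4 b0) diffusion data, and the
seven scalar metrics FA, MD, AD, RD and trace-normalized Westin CL, CP,
CS (so CL + CP + CS = 1 and MD = (AD + 2RD)/3 exactly).

**Histology.** Pixelwise structure-tensor anisotropy index
AI = (λ1 − λ2)/(λ1 + λ2) on myelin-stained images, and automated cell
counting (background flattening, Otsu, watershed, area filter) with cell
density CD = count/area on Nissl-stained images.

**Cross-modal regression.** `y_kj = bᵀx_kj + c + e_kj` pooled over
animals k and regions j (default 5 × 5 = 25 rows), with a structural-
collinearity screen (which, on a full 7-metric DTI predictor set,
excludes RD and CL), adjusted R², overall F, per-coefficient t/p, and a
noncentral-F confidence interval for R².

A synthetic-data generator produces every input — profiles, detector
frames, scans, DW signals, striped/cell images, metric tables — with
known ground truth, so the full pipeline is testable offline.

## Worked example

```r
library(mxmyelin)

# synthetic corrected profile at the healthy standard, Poisson noise
prof <- make_radial_profile(diffraction_sim_spec(noise = "poisson",
                                                 seed = 7))
fit <- fit_two_phase(prof)
fit
#> Phase fit: lambda_L = 17.5983 nm, lambda_H = 20.3288 nm, eta = 0.8657
#>   C_L = 182.3, C_H = 34.42, converged = TRUE
unlist(classify_state(fit))
#>          period         packing
#> "near-standard"  "commensurate"
```

The fitted lamellar period (17.598 nm) and commensurability (0.866) sit
within a fraction of a percent of the generating truth (17.6 nm, 0.866),
so the tile is classified near-standard and commensurate.

```r
sim <- make_dwi(dwi_sim_spec(eigenvalues = c(1.6e-3, 3e-4, 3e-4),
                             snr = 40, seed = 7))
round(tensor_metrics(fit_tensor(sim$signals, sim$protocol)), 4)
#>     FA     MD     AD     RD     CL     CP     CS
#> 0.7217 0.0006 0.0013 0.0003 0.5106 0.0201 0.4693
```

A prolate ("stick-like") tensor at SNR 40 yields high FA and CL, as
expected for a coherent fiber bundle; diffusivities are in mm²/s.

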