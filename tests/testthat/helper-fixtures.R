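# Shared fixtures, all generated in code.

# commensurate two-phase standard: lambda_L* = 17.6 nm, eta* = 0.866
std_spec <- function(...) {
  args <- utils::modifyList(list(lambda_L_true = 17.6,
                                 lambda_H_true = 17.6 / 0.866),
                            list(...))
  do.call(diffraction_sim_spec, args)
}

# lamellar-only profile spec (no hexagonal phase)
lamellar_only_spec <- function(...) {
  diffraction_sim_spec(lambda_H_true = NA, amp_H = numeric(0), ...)
}

# long-camera fixture geometry: SAXS peaks span many radial pixels, so
# azimuthal integration resolves the Gaussian line shapes
fixture_geometry <- function() {
  detector_geometry(energy_keV = 12.6, distance_mm = 600,
                    beam_center_px = c(256, 256), pixel_um = 75,
                    beamstop_px = 6)
}

fixture_q_grid <- function() seq(0.15, 2.0, length.out = 200L)

# narrow-q profile spec for scan fitting tests (fast)
fast_spec <- function(...) {
  diffraction_sim_spec(q_range = c(0.1, 2.5), ...)
}

# random positive-definite diffusion tensor eigenvalues (mm^2/s scale)
random_eigenvalues <- function() {
  sort(stats::runif(3, 0.05e-3, 2.5e-3), decreasing = TRUE)
}

# random 3D rotation matrix
random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

# 25-row table of the 7 DTI metrics derived from random tensors
random_dti_metric_table <- function(n = 25) {
  m <- t(vapply(seq_len(n), function(i) {
    tensor_metrics(random_eigenvalues())
  }, numeric(7)))
  as.data.frame(m)
}
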