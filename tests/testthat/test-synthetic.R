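test_that("radial-profile generator places peaks at the indexed positions", {
  spec <- lamellar_only_spec()
  prof <- make_radial_profile(spec)
  # local maxima at 2*pi*h/17.6 for h = 2, 3
  for (q0 in c(4 * pi / 17.6, 6 * pi / 17.6)) {
    win <- which(abs(prof$q - q0) < 0.05)
    expect_lt(abs(prof$q[win][which.max(prof$intensity[win])] - q0),
              spec$dq)
  }
  # zero amplitudes and background give the all-zero profile
  z <- make_radial_profile(lamellar_only_spec(amp_L = c(0, 0)))
  expect_true(all(z$intensity == 0))
  # seeded Poisson noise is bitwise reproducible
  a <- make_radial_profile(std_spec(noise = "poisson", seed = 42))
  b <- make_radial_profile(std_spec(noise = "poisson", seed = 42))
  expect_identical(a$intensity, b$intensity)
  # peaks outside the q range are rejected
  expect_error(make_radial_profile(
    diffraction_sim_spec(q_range = c(0.8, 12))), "q_range")
})

test_that("detector frames are consistent with the 1D generator", {
  geom <- fixture_geometry()
  qg <- fixture_q_grid()
  for (spec in list(std_spec(), lamellar_only_spec(),
                    std_spec(lambda_L_true = 16.2, background = 50))) {
    frame <- make_detector_frame(spec, geom, c(512L, 512L))
    prof <- radial_integrate(frame, geom, q_grid = qg)
    ref <- approx(make_radial_profile(spec)$q,
                  make_radial_profile(spec)$intensity, xout = qg)$y
    ok <- is.finite(prof$intensity)
    rms <- sqrt(mean((prof$intensity[ok] - ref[ok])^2)) /
      sqrt(mean(ref[ok]^2))
    expect_lt(rms, 0.02)
  }
})

test_that("ring radii follow r = D tan(2 asin(q lambda / 4 pi))", {
  geom <- detector_geometry(wavelength_nm = 0.0984, distance_mm = 135,
                            beam_center_px = c(128, 128), pixel_um = 75)
  q0 <- 0.714
  r_mm <- 135 * tan(2 * asin(q0 * 0.0984 / (4 * pi)))
  expect_equal(r_mm, 1.5096, tolerance = 1e-4)
  # q_of_pixel inverts the relation at that radius (~20 px)
  expect_equal(q_of_pixel(c(128, 128 + r_mm / 0.075), geom), q0,
               tolerance = 1e-6)
  # a flat frame integrates to a flat profile
  flat <- matrix(7, 128, 128)
  p <- radial_integrate(flat, detector_geometry(
    wavelength_nm = 0.0984, distance_mm = 135,
    beam_center_px = c(64, 64), pixel_um = 75), q_range = c(0.5, 3))
  expect_true(all(abs(p$intensity[is.finite(p$intensity)] - 7) < 1e-12))
})

test_that("scan generator stores a truth map and reproduces under a seed", {
  spec <- fast_spec(grid_shape = c(2L, 3L), noise = "poisson", seed = 5)
  s1 <- make_scan(spec)
  s2 <- make_scan(spec)
  expect_identical(s1$profiles[[4]]$intensity, s2$profiles[[4]]$intensity)
  expect_equal(nrow(s1$truth), 6)
  expect_true(all(s1$truth$lambda_L == 17.6))
  # step field: two-region truth map carries the step
  fld <- matrix(c(16, 16, 16, 19, 19, 19), 2, 3)
  s3 <- make_scan(fast_spec(grid_shape = c(2L, 3L)), lambda_L_field = fld)
  expect_equal(sort(unique(s3$truth$lambda_L)), c(16, 19))
  expect_equal(unique(diff(sort(unique(s3$y)))), spec$step)
})

test_that("DWI generator matches the closed-form tensor signal", {
  # stick tensor along g, b = 3000, lambda1 = 1e-3 -> S/S0 = exp(-3)
  s2 <- 1 / sqrt(2)
  proto <- dti_protocol(
    c(0, rep(3000, 6)),
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
          c(s2, s2, 0), c(s2, 0, s2), c(0, s2, s2)))
  sim <- make_dwi(dwi_sim_spec(eigenvalues = c(1e-3, 0, 0),
                               principal_direction = c(1, 0, 0),
                               S0 = 1, protocol = proto))
  expect_equal(sim$signals[2], exp(-3), tolerance = 1e-12)
  expect_equal(sim$signals[1], 1)            # b = 0 -> S = S0
  expect_equal(sim$signals[3], 1)            # g orthogonal to the stick
  # isotropic tensor: identical signal in every direction of a shell
  iso <- make_dwi(dwi_sim_spec(eigenvalues = rep(7e-4, 3)))
  sh <- iso$protocol$bvals == 3000
  expect_lt(diff(range(iso$signals[sh])), 1e-12)
  # Rician noise is seeded
  n1 <- make_dwi(dwi_sim_spec(snr = 20, seed = 9))
  n2 <- make_dwi(dwi_sim_spec(snr = 20, seed = 9))
  expect_identical(n1$signals, n2$signals)
})

test_that("histology generators encode their ground truth", {
  # isotropic limit: uniform orientations
  iso <- make_myelin_image(myelin_image_spec(dispersion_deg = Inf,
                                             seed = 2))
  expect_equal(attr(iso, "truth")$dispersion_deg, Inf)
  # oriented stripes carry their orientation
  st <- make_myelin_image(myelin_image_spec(orientation_deg = 30,
                                            dispersion_deg = 0))
  expect_equal(attr(st, "truth")$orientation_deg, 30)
  # 50 discs place 50 truth centroids, reproducibly
  spec <- nissl_image_spec(seed = 3)
  img <- make_nissl_image(spec)
  expect_equal(nrow(attr(img, "truth")), 50)
  expect_identical(img, make_nissl_image(spec))
  # impossible separation constraint errors after bounded retries
  expect_error(make_nissl_image(
    nissl_image_spec(dim_px = c(40L, 40L), n_cells = 400L,
                     max_tries = 20L)), "could not place")
})

test_that("table generator hits the target population R-squared", {
  # fitted R2 at n = 10 000 falls within sampling error of the target
  sp <- table_sim_spec(n_animals = 100L, n_regions = 100L,
                       target_r2 = 0.9, seed = 13)
  tab <- make_crossmodal_table(sp)
  fit <- fit_mlr(tab, sp$dependent, sp$predictors)
  expect_gt(fit$r2, 0.88); expect_lt(fit$r2, 0.92)
  # target 0 zeroes the effective coefficients: y is pure noise
  sp0 <- table_sim_spec(target_r2 = 0)
  expect_true(all(sp0$b_effective == 0))
  expect_error(table_sim_spec(target_r2 = 1), "target_r2")
  # seeded reproducibility and default 25-row layout
  t1 <- make_crossmodal_table(table_sim_spec(seed = 8))
  t2 <- make_crossmodal_table(table_sim_spec(seed = 8))
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 25)
})
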