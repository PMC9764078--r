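test_that("lattice position formulas and their ratios", {
  # h = 2 peak of the standard period: 4*pi/17.6
  expect_equal(unname(lamellar_positions(17.6)["h2"]), 4 * pi / 17.6)
  expect_equal(unname(lamellar_positions(17.6)["h2"]), 0.71400,
               tolerance = 1e-5)
  q <- lamellar_positions(23.1)
  expect_equal(unname(q["h3"] / q["h2"]), 1.5)
  expect_lt(max(lamellar_positions(1e6)), 1e-4)   # large-period limit
  expect_error(lamellar_positions(17.6, orders = 0), "positive")

  h <- hexagonal_positions(20.3)
  expect_equal(unname(h["h1k0"]), 4 * pi / (sqrt(3) * 20.3))
  expect_equal(unname(h["h2k0"] / h["h1k0"]), 2)
  expect_equal(unname(h["h2k3"] / h["h1k0"]), sqrt(19))
  expect_error(hexagonal_positions(20, rbind(c(0, 0))), "reflection")
})

test_that("commensurability is the ratio of lattice units", {
  expect_equal(commensurability(17.6, 17.6), 1)
  expect_equal(commensurability(17.6, 20.323), 0.866, tolerance = 1e-4)
  # scale invariance
  expect_equal(commensurability(17.6 * 3, 20.3 * 3),
               commensurability(17.6, 20.3))
  expect_true(is.na(commensurability(17.6, NA)))
})

test_that("q_of_pixel is monotone in radius and flags the beamstop", {
  geom <- detector_geometry(energy_keV = 12.6, distance_mm = 135,
                            beam_center_px = c(100, 100), pixel_um = 75,
                            beamstop_px = 5)
  expect_equal(1.239842 / 12.6, geom$wavelength_nm)
  r <- seq(6, 90, by = 1)
  qs <- q_of_pixel(cbind(100, 100 + r), geom)
  expect_true(all(diff(qs) > 0))
  expect_true(is.na(q_of_pixel(c(100, 102), geom)))  # inside beamstop
  # small-angle regime: doubling the radius doubles q within 0.1%
  q1 <- q_of_pixel(c(100, 110), geom)
  q2 <- q_of_pixel(c(100, 120), geom)
  expect_equal(q2 / q1, 2, tolerance = 1e-3)
  # q -> 0 at the beam center (no beamstop)
  geom0 <- detector_geometry(energy_keV = 12.6, distance_mm = 135,
                             beam_center_px = c(100, 100), pixel_um = 75)
  expect_equal(q_of_pixel(c(100, 100), geom0), 0)
})

test_that("azimuthally symmetric frames integrate independently of tilt", {
  geom <- fixture_geometry()
  frame <- make_detector_frame(std_spec(), geom, c(512L, 512L))
  expect_error(radial_integrate(frame[1:100, ], geom), "match")
  expect_warning(p <- radial_integrate(
    frame, geom, q_range = c(0.5, 1),
    mask = matrix(FALSE, 512, 512)), "masked")
  expect_true(all(is.na(p$intensity)))
})

test_that("profile correction normalizes flux and subtracts background", {
  q <- seq(0.2, 2, by = 0.01)
  a <- radial_profile(q, rep(4, length(q)), flux = 2)
  b <- radial_profile(q, rep(2, length(q)), flux = 1)
  corr <- correct_profile(a, b)
  expect_true(all(abs(corr$intensity) < 1e-12))  # identical after scaling
  expect_true(corr$flags$flux_normalized &&
                corr$flags$background_subtracted)
  # doubling flux with identical counts halves intensities
  c1 <- correct_profile(radial_profile(q, rep(4, length(q)), flux = 1),
                        radial_profile(q, rep(0, length(q))))
  c2 <- correct_profile(radial_profile(q, rep(4, length(q)), flux = 2),
                        radial_profile(q, rep(0, length(q))))
  expect_equal(c2$intensity, c1$intensity / 2)
  # generator profile + known background recovers the peak-only profile
  spec_bg <- std_spec(background = c(100, -20, 2))
  with_bg <- make_radial_profile(spec_bg)
  bg_only <- make_radial_profile(std_spec(amp_L = c(0, 0),
                                          amp_H = c(0, 0, 0),
                                          background = c(100, -20, 2)))
  peaks <- make_radial_profile(std_spec())
  rec <- correct_profile(with_bg, bg_only)
  expect_equal(rec$intensity, peaks$intensity, tolerance = 1e-10)
  expect_error(correct_profile(a, radial_profile(q + 1, rep(0, length(q)))),
               "grids")
})

test_that("two-phase fit recovers noiseless lattice units to 1e-4 nm", {
  prof <- make_radial_profile(std_spec())
  fit <- fit_two_phase(prof)
  expect_true(fit$converged)
  expect_lt(abs(fit$lambda_L - 17.6), 1e-4)
  expect_lt(abs(fit$lambda_H - 17.6 / 0.866), 1e-4)
  expect_equal(fit$eta, fit$lambda_L / fit$lambda_H)
  # fitted centers satisfy the indexing relations exactly
  pk <- fit$peaks
  expect_equal(pk$center[pk$phase == "lamellar"],
               unname(lamellar_positions(fit$lambda_L)))
  expect_equal(pk$center[pk$phase == "hexagonal"],
               as.numeric(hexagonal_positions(fit$lambda_H)))
})

test_that("lamellar-only profiles flag the hexagonal phase unidentifiable", {
  fit <- fit_two_phase(make_radial_profile(lamellar_only_spec()))
  expect_true(fit$hex_unidentifiable)
  expect_true(is.na(fit$lambda_H))
  expect_equal(fit$C_H, 0)
  expect_lt(abs(fit$lambda_L - 17.6), 1e-3)
})

test_that("profiles without peaks yield a flagged no-myelin result", {
  q <- seq(0.1, 2.5, by = 0.005)
  flatp <- radial_profile(q, rep(0, length(q)))
  fit <- fit_two_phase(flatp)
  expect_true(fit$no_myelin)
  expect_false(fit$converged)
  # mild noise, still no peak
  set.seed(1)
  noisy <- radial_profile(q, rnorm(length(q), 10, 1))
  expect_true(fit_two_phase(noisy)$no_myelin)
})

test_that("phase contents equal the analytic Gaussian integrals", {
  fit <- fit_two_phase(make_radial_profile(std_spec()))
  cc <- phase_content(fit)
  truth <- attr(make_radial_profile(std_spec()), "truth")
  # single peak A = 1, sigma = 0.1 integrates to sqrt(2*pi)*0.1
  expect_equal(1 * 0.1 * sqrt(2 * pi), 0.2506628, tolerance = 1e-6)
  # numerical quadrature of the fitted components agrees to 1e-6 relative
  q <- seq(0.01, 3, by = 1e-4)
  pk <- fit$peaks
  num <- vapply(c("lamellar", "hexagonal"), function(ph) {
    rows <- which(pk$phase == ph)
    y <- rowSums(vapply(rows, function(i)
      pk$amplitude[i] * exp(-0.5 * ((q - pk$center[i]) / pk$sigma[i])^2),
      numeric(length(q))))
    sum(y) * 1e-4
  }, numeric(1))
  expect_equal(unname(cc["C_L"]), unname(num["lamellar"]),
               tolerance = 1e-6)
  expect_equal(unname(cc["C_H"]), unname(num["hexagonal"]),
               tolerance = 1e-6)
  # contents scale linearly with amplitude
  f2 <- fit_two_phase(make_radial_profile(
    std_spec(amp_L = 2 * c(2500, 1000), amp_H = 2 * c(500, 200, 100))))
  expect_equal(f2$C_L / fit$C_L, 2, tolerance = 1e-4)
  expect_equal(f2$C_H / fit$C_H, 2, tolerance = 1e-3)
  expect_equal(cc[["C_L"]], truth$C_L, tolerance = 1e-4)
})

test_that("classification against the standards uses the tolerance band", {
  std <- reference_standards()
  mk <- function(lamL, eta) list(lambda_L = lamL, eta = eta)
  expect_equal(classify_state(mk(17.6, 0.866), std)$period, "near-standard")
  expect_equal(classify_state(mk(16.0, 0.87), std)$period, "compressed")
  expect_equal(classify_state(mk(19.0, 0.87), std)$period, "expanded")
  expect_equal(classify_state(mk(17.6, 0.80), std)$packing,
               "sub-commensurate")
  expect_equal(classify_state(mk(17.6, 0.866), std)$packing,
               "commensurate")
  expect_true(is.na(classify_state(mk(17.6, NA), std)$packing))
})

test_that("scan fitting recovers constant and stepped truth maps", {
  spec <- fast_spec(grid_shape = c(2L, 2L))
  map <- fit_scan(make_scan(spec))
  expect_true(all(map$valid))
  expect_lt(max(abs(map$lambda_L - 17.6)), 1e-3)
  # two-region field: the step is recovered tile by tile
  fld <- matrix(c(16.5, 16.5, 18.5, 18.5), 2, 2)
  map2 <- fit_scan(make_scan(fast_spec(grid_shape = c(2L, 2L)),
                             lambda_L_field = fld))
  expect_equal(round(sort(map2$lambda_L), 1), c(16.5, 16.5, 18.5, 18.5))
  # all-background scan: empty quality mask
  fld_na <- matrix(NA_real_, 2, 2)
  map3 <- fit_scan(make_scan(fast_spec(grid_shape = c(2L, 2L)),
                             lambda_L_field = fld_na))
  expect_false(any(map3$valid))
})

test_that("lamellar-period PDFs integrate to one", {
  spec <- fast_spec(grid_shape = c(3L, 3L), noise = "poisson", seed = 21)
  map <- fit_scan(make_scan(spec))
  pdf <- roi_lambda_pdf(map)
  trapz <- sum(diff(pdf$x) * (pdf$density[-1] +
                                pdf$density[-length(pdf$density)]) / 2)
  expect_lt(abs(trapz - 1), 1e-6)
  # huge bandwidth: flat but still unit mass
  pdf2 <- roi_lambda_pdf(map, bandwidth = 100)
  trapz2 <- sum(diff(pdf2$x) * (pdf2$density[-1] +
                                  pdf2$density[-length(pdf2$density)]) / 2)
  expect_lt(abs(trapz2 - 1), 1e-6)
  expect_gt(pdf2$bandwidth, diff(range(map$lambda_L)))  # oversmoothed
  # bimodal truth map: two modes recovered
  fld <- matrix(rep(c(15, 20), each = 4), 4, 2)
  mapb <- fit_scan(make_scan(fast_spec(grid_shape = c(4L, 2L)),
                             lambda_L_field = fld))
  pdfb <- roi_lambda_pdf(mapb, bandwidth = 0.3)
  dens_at <- function(v) pdfb$density[which.min(abs(pdfb$x - v))]
  expect_gt(dens_at(15), dens_at(17.5) * 5)
  expect_gt(dens_at(20), dens_at(17.5) * 5)
  # fewer than two tiles is an error
  expect_error(roi_lambda_pdf(map[1, , drop = FALSE]), "at least 2")
})
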