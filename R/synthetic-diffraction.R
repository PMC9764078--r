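#' Specification of a synthetic two-phase diffraction profile
#'
#' Describes the generating model of a corrected radial profile: Gaussian
#' quasi-Bragg peaks of the multilamellar phase at \eqn{2\pi h/\lambda_L}
#' (h = 2, 3), the hexagonal reflections (1,0), (2,0), (2,3), a polynomial
#' background, and optional Poisson counting noise.  Default amplitudes
#' make the lamellar peaks about five times the hexagonal ones, reflecting
#' a dominant multilamellar phase with a minority hexagonal phase.  With
#' the default `amp_L[1] = 2500` counts, Poisson noise gives a peak
#' signal-to-noise ratio of 50.
#'
#' @param lambda_L_true lamellar period (nm).
#' @param lambda_H_true hexagonal lattice unit (nm); `NA` for a
#'   lamellar-only profile.
#' @param orders lamellar orders.
#' @param reflections hexagonal (h, k) reflections (two-column matrix).
#' @param amp_L,amp_H peak amplitudes (counts).
#' @param sigma_L,sigma_H Gaussian widths (1/nm).
#' @param background polynomial coefficients (intercept first) in counts.
#' @param noise `"none"` or `"poisson"`.
#' @param q_range q interval (1/nm).
#' @param dq grid spacing (1/nm).
#' @param grid_shape scan layout `c(ny, nz)` (used by [make_scan()]).
#' @param step scan step in um (the acquisition raster step; default 2).
#' @param seed RNG seed for the noise.
#' @return List of class `diffraction_sim_spec`.
#' @export
diffraction_sim_spec <- function(lambda_L_true = 17.6,
                                 lambda_H_true = 17.6 / 0.866,
                                 orders = c(2L, 3L),
                                 reflections = rbind(c(1, 0), c(2, 0),
                                                     c(2, 3)),
                                 amp_L = c(2500, 1000),
                                 amp_H = c(500, 200, 100),
                                 sigma_L = rep(0.02, length(orders)),
                                 sigma_H = rep(0.02, nrow(reflections)),
                                 background = 0,
                                 noise = c("none", "poisson"),
                                 q_range = c(0.1, 12),
                                 dq = 0.005,
                                 grid_shape = c(8L, 8L),
                                 step = 2,
                                 seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(lambda_L_true > 0, all(sigma_L > 0), all(sigma_H > 0),
            length(amp_L) == length(orders),
            is.na(lambda_H_true) || length(amp_H) == nrow(reflections),
            q_range[2] > q_range[1], dq > 0, step > 0)
  structure(as.list(environment()), class = "diffraction_sim_spec")
}

# continuous generating intensity (expected counts) at momentum transfer q
.sim_intensity <- function(spec, q) {
  y <- rep(0, length(q))
  for (j in seq_along(spec$background))
    y <- y + spec$background[j] * q^(j - 1)
  ctrL <- 2 * pi * spec$orders / spec$lambda_L_true
  for (i in seq_along(ctrL))
    y <- y + spec$amp_L[i] * exp(-0.5 * ((q - ctrL[i]) / spec$sigma_L[i])^2)
  if (!is.na(spec$lambda_H_true)) {
    m2 <- spec$reflections[, 1]^2 +
      spec$reflections[, 1] * spec$reflections[, 2] + spec$reflections[, 2]^2
    ctrH <- (4 * pi / (sqrt(3) * spec$lambda_H_true)) * sqrt(m2)
    for (i in seq_along(ctrH))
      y <- y + spec$amp_H[i] * exp(-0.5 * ((q - ctrH[i]) / spec$sigma_H[i])^2)
  }
  y
}

.sim_truth <- function(spec) {
  list(lambda_L = spec$lambda_L_true,
       lambda_H = spec$lambda_H_true,
       eta = if (is.na(spec$lambda_H_true)) NA_real_
             else spec$lambda_L_true / spec$lambda_H_true,
       C_L = sum(spec$amp_L * spec$sigma_L) * sqrt(2 * pi),
       C_H = if (is.na(spec$lambda_H_true)) 0
             else sum(spec$amp_H * spec$sigma_H) * sqrt(2 * pi))
}

#' Generate a synthetic radial profile with known ground truth
#'
#' Evaluates the generating model (background + indexed Gaussian peaks) on
#' the q grid and optionally applies Poisson counting noise.  The
#' generating parameters are attached as the `truth` attribute.
#'
#' @param spec a [diffraction_sim_spec()].
#' @return A [radial_profile()] with attribute `truth`.
#' @examples
#' p <- make_radial_profile(diffraction_sim_spec())
#' attr(p, "truth")$lambda_L
#' @export
make_radial_profile <- function(spec) {
  stopifnot(inherits(spec, "diffraction_sim_spec"))
  q <- seq(spec$q_range[1], spec$q_range[2], by = spec$dq)
  pos <- c(2 * pi * spec$orders / spec$lambda_L_true,
           if (!is.na(spec$lambda_H_true))
             as.numeric(hexagonal_positions(spec$lambda_H_true,
                                            spec$reflections)))
  out_of_range <- pos < spec$q_range[1] | pos > spec$q_range[2]
  if (any(out_of_range))
    stop("peak position(s) ", paste(signif(pos[out_of_range], 4),
         collapse = ", "), " 1/nm outside q_range")
  y <- .sim_intensity(spec, q)
  if (spec$noise == "poisson") {
    if (any(y < 0)) stop("Poisson noise requires nonnegative intensities")
    y <- withr::with_seed(spec$seed, stats::rpois(length(y), y))
  }
  prof <- radial_profile(q, y, flux = 1, flux_normalized = TRUE,
                         background_subtracted = all(spec$background == 0))
  attr(prof, "truth") <- .sim_truth(spec)
  prof
}

#' Generate a synthetic 2D detector frame
#'
#' Renders the generating radial intensity as azimuthally symmetric rings
#' on an area detector: each pixel receives the continuous model intensity
#' at its own momentum transfer, so radial integration reproduces the 1D
#' generator within discretization error.  Beamstop pixels are zeroed.
#'
#' @param spec a [diffraction_sim_spec()].
#' @param geometry a [detector_geometry()].
#' @param shape detector dimensions `c(rows, cols)`.
#' @return Numeric matrix with attribute `truth`; a warning lists
#'   reflections whose rings fall outside the detector.
#' @export
make_detector_frame <- function(spec, geometry, shape = c(256L, 256L)) {
  stopifnot(inherits(spec, "diffraction_sim_spec"),
            inherits(geometry, "detector_geometry"))
  nr <- shape[1]; nc <- shape[2]
  rows <- rep(seq_len(nr) - 1, times = nc) + 0.5
  cols <- rep(seq_len(nc) - 1, each = nr) + 0.5
  q <- q_of_pixel(cbind(rows, cols), geometry)
  qmax <- max(q, na.rm = TRUE)
  pos <- c(2 * pi * spec$orders / spec$lambda_L_true,
           if (!is.na(spec$lambda_H_true))
             as.numeric(hexagonal_positions(spec$lambda_H_true,
                                            spec$reflections)))
  lost <- pos > qmax
  if (any(lost))
    warning("reflection ring(s) at q = ",
            paste(signif(pos[lost], 4), collapse = ", "),
            " 1/nm fall outside the detector")
  y <- .sim_intensity(spec, ifelse(is.na(q), 0, q))
  y[is.na(q)] <- 0  # beamstop shadow
  if (spec$noise == "poisson")
    y <- withr::with_seed(spec$seed, stats::rpois(length(y), pmax(y, 0)))
  frame <- matrix(y, nr, nc)
  attr(frame, "truth") <- .sim_truth(spec)
  frame
}

#' Generate a raster scan of synthetic profiles with a true parameter map
#'
#' One radial profile per (y, z) scan position, with the lamellar period
#' taken from a per-tile field (constant by default).  The true maps are
#' attached for end-to-end validation of [fit_scan()].
#'
#' @param spec a [diffraction_sim_spec()]; `grid_shape` and `step` set the
#'   scan layout.
#' @param lambda_L_field optional matrix (dim `grid_shape`) of per-tile
#'   lamellar periods in nm; `NA` entries produce background-only tiles
#'   (no myelin signal).
#' @return List of class `sxrd_scan`: `profiles`, `y`, `z` (um), `step`,
#'   `truth` (data frame of per-tile generating values).
#' @export
make_scan <- function(spec, lambda_L_field = NULL) {
  stopifnot(inherits(spec, "diffraction_sim_spec"))
  ny <- spec$grid_shape[1]; nz <- spec$grid_shape[2]
  if (is.null(lambda_L_field))
    lambda_L_field <- matrix(spec$lambda_L_true, ny, nz)
  if (!all(dim(lambda_L_field) == c(ny, nz)))
    stop("lambda_L_field dimensions must match grid_shape")
  profiles <- vector("list", ny * nz)
  yy <- zz <- lamb <- numeric(ny * nz)
  idx <- 0L
  for (jz in seq_len(nz)) for (iy in seq_len(ny)) {
    idx <- idx + 1L
    lam <- lambda_L_field[iy, jz]
    tile <- spec
    tile$seed <- spec$seed + idx
    if (is.na(lam)) {          # background-only tile
      tile$amp_L[] <- 0
      tile$amp_H[] <- 0
      tile$lambda_H_true <- NA_real_
      tile$amp_H <- numeric(0)
    } else {
      tile$lambda_L_true <- lam
    }
    profiles[[idx]] <- make_radial_profile(tile)
    yy[idx] <- (iy - 1) * spec$step
    zz[idx] <- (jz - 1) * spec$step
    lamb[idx] <- lam
  }
  structure(list(profiles = profiles, y = yy, z = zz, step = spec$step,
                 truth = data.frame(y = yy, z = zz, lambda_L = lamb)),
            class = "sxrd_scan")
}
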