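#' Detector geometry for transmission scattering
#'
#' Describes a flat area detector perpendicular (up to two small tilt
#' angles) to the direct beam.  Wavelength may be given directly in nm or
#' through the photon energy via \eqn{\lambda[nm] = 1.239842 / E[keV]}.
#'
#' @param wavelength_nm X-ray wavelength in nm (exclusive with
#'   `energy_keV`).
#' @param energy_keV photon energy in keV.
#' @param distance_mm sample-detector distance in mm.
#' @param beam_center_px beam center `c(row, col)` in 0-based pixel
#'   coordinates (fractional allowed).
#' @param pixel_um pixel edge in micrometres.
#' @param tilt_deg two tilt angles (degrees): rotation of the detector
#'   plane about its horizontal and vertical axes.
#' @param beamstop_px beamstop radius in pixels around the beam center;
#'   pixels inside are invalid for integration.
#' @return Object of class `detector_geometry`.
#' @examples
#' detector_geometry(energy_keV = 12.6, distance_mm = 135,
#'                   beam_center_px = c(128, 128), pixel_um = 75)
#' @export
detector_geometry <- function(wavelength_nm = NULL, energy_keV = NULL,
                              distance_mm, beam_center_px, pixel_um,
                              tilt_deg = c(0, 0), beamstop_px = 0) {
  if (is.null(wavelength_nm)) {
    if (is.null(energy_keV)) stop("give wavelength_nm or energy_keV")
    wavelength_nm <- 1.239842 / energy_keV
  }
  stopifnot(wavelength_nm > 0, distance_mm > 0, pixel_um > 0,
            length(beam_center_px) == 2L, beamstop_px >= 0)
  if (length(tilt_deg) == 1L) tilt_deg <- c(tilt_deg, 0)
  structure(list(wavelength_nm = wavelength_nm,
                 distance_mm = distance_mm,
                 beam_center_px = as.numeric(beam_center_px),
                 pixel_um = pixel_um,
                 tilt_deg = as.numeric(tilt_deg),
                 beamstop_px = beamstop_px),
            class = "detector_geometry")
}

# In-plane detector offsets (mm) -> 3D lab position of the pixel, with the
# plane tilted about its horizontal (tilt 1) then vertical (tilt 2) axis.
.pixel_lab_position <- function(u_mm, v_mm, geom) {
  t1 <- geom$tilt_deg[1] * pi / 180
  t2 <- geom$tilt_deg[2] * pi / 180
  # basis vectors of the tilted detector plane in lab frame (z along beam)
  e1 <- c(cos(t2), 0, sin(t2))                       # horizontal axis
  e2 <- c(sin(t1) * sin(t2), cos(t1), -sin(t1) * cos(t2))  # vertical axis
  list(x = u_mm * e1[1] + v_mm * e2[1],
       y = u_mm * e1[2] + v_mm * e2[2],
       z = geom$distance_mm + u_mm * e1[3] + v_mm * e2[3])
}

#' Momentum transfer of a detector pixel
#'
#' \eqn{q = (4\pi/\lambda)\sin\theta} with \eqn{2\theta} the full
#' scattering angle between the direct beam and the ray to the pixel
#' (tilt-corrected).  `q` is monotone increasing in the beam-center
#' distance.
#'
#' @param pixel numeric `c(row, col)` (0-based, fractional ok) or an n x 2
#'   matrix of pixel coordinates.
#' @param geometry a [detector_geometry()].
#' @return q in 1/nm (vector for matrix input).  Pixels inside the
#'   beamstop radius are returned as `NA` (flagged invalid).
#' @export
q_of_pixel <- function(pixel, geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  p <- if (is.matrix(pixel)) pixel else matrix(pixel, ncol = 2L)
  drow <- p[, 1] - geometry$beam_center_px[1]
  dcol <- p[, 2] - geometry$beam_center_px[2]
  px_mm <- geometry$pixel_um / 1000
  pos <- .pixel_lab_position(dcol * px_mm, drow * px_mm, geometry)
  two_theta <- atan2(sqrt(pos$x^2 + pos$y^2), pos$z)
  q <- (4 * pi / geometry$wavelength_nm) * sin(two_theta / 2)
  q[sqrt(drow^2 + dcol^2) < geometry$beamstop_px] <- NA_real_
  q
}

#' Construct a radial scattering profile
#'
#' A 1D intensity profile \eqn{I(q)} on a strictly increasing q grid in
#' 1/nm, with the incident-flux monitor value and processing flags.
#'
#' @param q strictly increasing q grid (1/nm).
#' @param intensity intensities (same length as `q`; `NA` allowed for
#'   missing bins).
#' @param flux incident-beam monitor value (> 0).
#' @param flux_normalized,background_subtracted processing flags.
#' @return Object of class `radial_profile`.
#' @export
radial_profile <- function(q, intensity, flux = 1,
                           flux_normalized = FALSE,
                           background_subtracted = FALSE) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    stop("q and intensity must have the same length")
  if (any(diff(q) <= 0)) stop("q grid must be strictly increasing")
  if (!is.finite(flux) || flux <= 0) stop("flux must be positive")
  structure(list(q = q, intensity = intensity, flux = flux,
                 flags = list(flux_normalized = flux_normalized,
                              background_subtracted = background_subtracted)),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat("Radial profile: ", length(x$q), " bins, q in [",
      format(min(x$q)), ", ", format(max(x$q)), "] 1/nm\n", sep = "")
  invisible(x)
}

#' Azimuthal (radial) integration of a 2D diffraction frame
#'
#' Bins every valid pixel by its momentum transfer and averages the
#' intensity per bin, emulating azimuthal integration of an area-detector
#' frame.  Bin edges are the midpoints of the supplied q grid.
#'
#' @param frame numeric matrix of detector counts, indexed (row, col).
#' @param geometry a [detector_geometry()]; beamstop pixels are excluded.
#' @param q_grid bin centers in 1/nm; default 600 bins over `q_range`.
#' @param q_range used when `q_grid` is `NULL`.
#' @param mask optional logical matrix, `TRUE` = pixel valid.
#' @return A [radial_profile()] with attribute `n_pixels` (pixels per
#'   bin); bins with no valid pixel are `NA`.
#' @export
radial_integrate <- function(frame, geometry, q_grid = NULL,
                             q_range = c(0.1, 12), mask = NULL) {
  stopifnot(is.matrix(frame), inherits(geometry, "detector_geometry"))
  if (any(!is.finite(frame[if (is.null(mask)) TRUE else mask])))
    stop("frame contains non-finite values")
  if (!is.null(mask) && !identical(dim(mask), dim(frame)))
    stop("mask dimensions do not match frame")
  nr <- nrow(frame); nc <- ncol(frame)
  bc <- geometry$beam_center_px
  if (bc[1] < 0 || bc[1] > nr || bc[2] < 0 || bc[2] > nc)
    stop("geometry beam center (", bc[1], ", ", bc[2],
         ") does not match frame shape ", nr, "x", nc)
  rows <- rep(seq_len(nr) - 1, times = nc) + 0.5
  cols <- rep(seq_len(nc) - 1, each = nr) + 0.5
  q <- q_of_pixel(cbind(rows, cols), geometry)
  ok <- !is.na(q)
  if (!is.null(mask)) ok <- ok & as.vector(mask)
  if (is.null(q_grid))
    q_grid <- seq(q_range[1], q_range[2], length.out = 600L)
  edges <- c(q_grid[1] - diff(q_grid[1:2]) / 2,
             q_grid[-length(q_grid)] + diff(q_grid) / 2,
             q_grid[length(q_grid)] + diff(q_grid)[length(q_grid) - 1] / 2)
  if (!any(ok)) {
    warning("all pixels masked; returning all-missing profile")
    out <- radial_profile(q_grid, rep(NA_real_, length(q_grid)))
    attr(out, "n_pixels") <- integer(length(q_grid))
    return(out)
  }
  bin <- findInterval(q[ok], edges, rightmost.closed = TRUE)
  inb <- bin >= 1L & bin <= length(q_grid)
  sums <- rep(0, length(q_grid)); cnts <- integer(length(q_grid))
  t_s <- tapply(as.vector(frame)[ok][inb], bin[inb], sum)
  idx <- as.integer(names(t_s))
  sums[idx] <- t_s
  t_c <- tapply(rep(1L, sum(inb)), bin[inb], sum)
  cnts[idx] <- t_c
  inten <- ifelse(cnts > 0L, sums / pmax(cnts, 1L), NA_real_)
  out <- radial_profile(q_grid, inten)
  attr(out, "n_pixels") <- cnts
  out
}

#' Flux-normalize and background-subtract a radial profile
#'
#' Each profile is divided by its own incident-flux monitor value and the
#' (flux-normalized) background profile, measured in areas without myelin
#' peaks, is subtracted.  Negative corrected intensities are retained, not
#' clipped; their count is recorded in the `n_negative` attribute.
#'
#' @param profile,background [radial_profile()]s on identical q grids.
#' @return Corrected [radial_profile()] with both flags set.
#' @export
correct_profile <- function(profile, background) {
  stopifnot(inherits(profile, "radial_profile"),
            inherits(background, "radial_profile"))
  if (length(profile$q) != length(background$q) ||
      any(abs(profile$q - background$q) > 1e-9))
    stop("profile and background q grids differ")
  if (profile$flux <= 0 || background$flux <= 0)
    stop("flux must be positive")
  corr <- profile$intensity / profile$flux -
    background$intensity / background$flux
  out <- radial_profile(profile$q, corr, flux = 1,
                        flux_normalized = TRUE,
                        background_subtracted = TRUE)
  attr(out, "n_negative") <- sum(corr < 0, na.rm = TRUE)
  out
}
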