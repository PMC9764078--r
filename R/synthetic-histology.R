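#' Specification of a synthetic myelin-stained (striped) image
#'
#' An oriented stripe texture emulating myelinated fiber bundles: the sum
#' of `n_components` sinusoidal gratings whose orientations are drawn from
#' a wrapped normal around `orientation_deg` with standard deviation
#' `dispersion_deg` (`Inf` = uniform orientations, i.e. isotropic texture;
#' ground-truth anisotropy is then 0).  Higher dispersion yields lower
#' structure-tensor anisotropy; the truth is an ordering, not an absolute
#' AI value, since AI depends on the analysis scales.
#'
#' @param dim_px image dimensions `c(rows, cols)`.
#' @param orientation_deg mean stripe direction, degrees from the x
#'   (column) axis.
#' @param dispersion_deg wrapped-normal angular spread (degrees); `Inf`
#'   for isotropic.
#' @param period_um stripe period in um (axon-bundle scale).
#' @param n_components number of superposed gratings.
#' @param n_dark_spots count of dark blobs emulating focal axonal damage.
#' @param pixel_size um/pixel.
#' @param noise_sd additive Gaussian intensity noise.
#' @param seed RNG seed.
#' @return List of class `histo_sim_spec`.
#' @export
myelin_image_spec <- function(dim_px = c(192L, 192L), orientation_deg = 30,
                              dispersion_deg = 2, period_um = 1.5,
                              n_components = 12L, n_dark_spots = 0L,
                              pixel_size = sqrt(0.013), noise_sd = 0,
                              seed = 1L) {
  stopifnot(period_um > 0, n_components >= 1L, n_dark_spots >= 0L,
            pixel_size > 0, dispersion_deg >= 0)
  structure(as.list(environment()), class = "histo_sim_spec")
}

#' Generate a striped myelin-like image with known orientation
#'
#' @param spec a [myelin_image_spec()].
#' @return Numeric matrix in [0, 1] (darker = more stain) with attribute
#'   `truth` (`orientation_deg`, `dispersion_deg`).
#' @export
make_myelin_image <- function(spec) {
  stopifnot(inherits(spec, "histo_sim_spec"))
  nr <- spec$dim_px[1]; nc <- spec$dim_px[2]
  x <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc) * spec$pixel_size
  y <- matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc) * spec$pixel_size
  img <- withr::with_seed(spec$seed, {
    acc <- matrix(0, nr, nc)
    for (k in seq_len(spec$n_components)) {
      th <- if (is.infinite(spec$dispersion_deg))
        stats::runif(1, 0, 180)
      else (spec$orientation_deg +
              stats::rnorm(1, 0, spec$dispersion_deg)) %% 180
      # stripes run along th; the grating wave vector is normal to them
      a <- (th + 90) * pi / 180
      ph <- stats::runif(1, 0, 2 * pi)
      acc <- acc + cos(2 * pi * (x * cos(a) + y * sin(a)) /
                         spec$period_um + ph)
    }
    acc <- acc / spec$n_components
    if (spec$n_dark_spots > 0L) {
      for (s in seq_len(spec$n_dark_spots)) {
        cx <- stats::runif(1, 0, nc * spec$pixel_size)
        cy <- stats::runif(1, 0, nr * spec$pixel_size)
        r2 <- (stats::runif(1, 1, 2))^2
        acc <- acc - 2 * exp(-((x - cx)^2 + (y - cy)^2) / (2 * r2))
      }
    }
    if (spec$noise_sd > 0)
      acc <- acc + stats::rnorm(length(acc), 0, spec$noise_sd)
    acc
  })
  img <- (img - min(img)) / max(diff(range(img)), .Machine$double.eps)
  attr(img, "truth") <- list(orientation_deg = spec$orientation_deg,
                             dispersion_deg = spec$dispersion_deg)
  img
}

#' Specification of a synthetic Nissl-stained (cell) image
#'
#' Dark discs (stained somata) on a bright background.  Cell centers are
#' placed by rejection sampling honoring a minimum center separation
#' expressed via `overlap_fraction` (0 = discs may just touch; negative
#' values enforce extra clearance); explicit `centers`/`radii` override
#' random placement.
#'
#' @param dim_px image dimensions `c(rows, cols)`.
#' @param n_cells number of cells.
#' @param radius_um_range min/max disc radius in um.
#' @param overlap_fraction maximum allowed overlap of two discs as a
#'   fraction of the smaller radius (0 = non-overlapping).
#' @param pixel_size um/pixel.
#' @param centers optional explicit centers (data frame `row`, `col`, px).
#' @param radii_um optional explicit radii (um), with `centers`.
#' @param max_tries placement retries per cell before erroring.
#' @param seed RNG seed.
#' @return List of class `nissl_sim_spec`.
#' @export
nissl_image_spec <- function(dim_px = c(256L, 256L), n_cells = 50L,
                             radius_um_range = c(3, 5),
                             overlap_fraction = -0.2,
                             pixel_size = sqrt(0.013) * 4,
                             centers = NULL, radii_um = NULL,
                             max_tries = 2000L, seed = 1L) {
  stopifnot(n_cells >= 0L, all(radius_um_range > 0), pixel_size > 0)
  structure(as.list(environment()), class = "nissl_sim_spec")
}

#' Generate a Nissl-like image of dark discs with known centroids
#'
#' @param spec a [nissl_image_spec()].
#' @return Numeric matrix in [0, 1] with attribute `truth` (data frame of
#'   centroid `row`, `col` (0-based px, at pixel centers), `radius_um`).
#' @export
make_nissl_image <- function(spec) {
  stopifnot(inherits(spec, "nissl_sim_spec"))
  nr <- spec$dim_px[1]; nc <- spec$dim_px[2]
  ps <- spec$pixel_size
  placed <- withr::with_seed(spec$seed, {
    if (!is.null(spec$centers)) {
      data.frame(row = spec$centers$row, col = spec$centers$col,
                 radius_um = spec$radii_um)
    } else if (spec$n_cells == 0L) {
      data.frame(row = numeric(0), col = numeric(0),
                 radius_um = numeric(0))
    } else {
      rows <- cols <- rad <- numeric(0)
      for (i in seq_len(spec$n_cells)) {
        ok <- FALSE
        for (t in seq_len(spec$max_tries)) {
          r_um <- stats::runif(1, spec$radius_um_range[1],
                               spec$radius_um_range[2])
          r_px <- r_um / ps
          cr <- stats::runif(1, r_px + 1, nr - r_px - 1)
          cc <- stats::runif(1, r_px + 1, nc - r_px - 1)
          if (length(rows)) {
            d_um <- sqrt((cr - rows)^2 + (cc - cols)^2) * ps
            min_sep <- (r_um + rad) -
              spec$overlap_fraction * pmin(r_um, rad)
            if (any(d_um < min_sep)) next
          }
          rows <- c(rows, cr); cols <- c(cols, cc); rad <- c(rad, r_um)
          ok <- TRUE
          break
        }
        if (!ok)
          stop("could not place cell ", i, " of ", spec$n_cells,
               " at the requested separation after ", spec$max_tries,
               " tries")
      }
      data.frame(row = rows, col = cols, radius_um = rad)
    }
  })
  img <- matrix(1, nr, nc)
  if (nrow(placed)) {
    rr <- matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc)
    cc <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
    for (i in seq_len(nrow(placed))) {
      d <- sqrt((rr - placed$row[i])^2 + (cc - placed$col[i])^2) * ps
      # soft-edged disc: full stain inside, ~1 px antialiased rim
      img <- pmin(img, 0.2 + 0.8 * stats::plogis((d - placed$radius_um[i]) /
                                                   (0.5 * ps) * 4))
    }
  }
  attr(img, "truth") <- placed
  img
}
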