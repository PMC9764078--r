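# Gaussian and Gaussian-derivative 1D kernels (pixel units)
.gauss_kernel <- function(sigma, deriv = 0L) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (deriv == 0L) return(g)
  -x / sigma^2 * g
}

# separable 2D convolution with replicated borders, kernels kr (rows, y)
# and kc (cols, x)
.sep_conv <- function(img, kr, kc) {
  k2 <- outer(kr, kc)
  EBImage::filter2(img, k2, boundary = "replicate")
}

#' Pixelwise 2D structure tensor of a histological image
#'
#' Image gradients are taken with Gaussian-derivative filters at scale
#' `sigma_gradient` and the gradient outer products are averaged with a
#' Gaussian window of scale `sigma_window` (both in micrometres).  Per
#' pixel the tensor eigenvalues \eqn{\lambda_1 \ge \lambda_2 \ge 0} give
#' the anisotropy index \eqn{AI = (\lambda_1 - \lambda_2)/(\lambda_1 +
#' \lambda_2)}, defined as 0 (and flagged) where the tensor energy
#' \eqn{\lambda_1 + \lambda_2} falls below \eqn{\epsilon = 10^{-6}
#' \mathrm{var}(image)} (scale-free flat-region guard).
#'
#' AI is invariant to affine rescaling of the intensities; the reported
#' orientation is the local structure (stripe) direction in degrees,
#' measured from the image x (column) axis, in [0, 180).
#'
#' @param image numeric matrix (grayscale; RGB arrays are converted by
#'   luminance) indexed (row, col).
#' @param sigma_gradient,sigma_window scales in um.
#' @param pixel_size um/pixel (default `sqrt(0.013)`).
#' @return Object of class `st_field`: matrices `AI`, `orientation_deg`,
#'   `energy`, `lambda1`, `lambda2`, logical `flat` (flagged pixels).
#' @export
structure_tensor <- function(image, sigma_gradient = 0.5, sigma_window = 2,
                             pixel_size = sqrt(0.013)) {
  if (length(dim(image)) == 3L)
    image <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] +
      0.0722 * image[, , 3]
  stopifnot(is.matrix(image), all(is.finite(image)),
            sigma_gradient > 0, sigma_window > 0, pixel_size > 0)
  sg <- sigma_gradient / pixel_size
  sw <- sigma_window / pixel_size
  if (min(dim(image)) < 6 * sw)
    stop("image smaller than 6 sigma_window (", round(6 * sw),
         " px) along one axis")
  g0g <- .gauss_kernel(sg, 0L); g1g <- .gauss_kernel(sg, 1L)
  # x = column direction, y = row direction
  Ix <- .sep_conv(image, g0g, g1g)
  Iy <- .sep_conv(image, g1g, g0g)
  g0w <- .gauss_kernel(sw, 0L)
  Jxx <- .sep_conv(Ix * Ix, g0w, g0w)
  Jyy <- .sep_conv(Iy * Iy, g0w, g0w)
  Jxy <- .sep_conv(Ix * Iy, g0w, g0w)
  tr <- Jxx + Jyy
  disc <- sqrt(pmax((Jxx - Jyy)^2 / 4 + Jxy^2, 0))
  l1 <- tr / 2 + disc
  l2 <- pmax(tr / 2 - disc, 0)
  # scale-free guard plus an absolute floor for numerically flat images
  eps <- max(1e-6 * stats::var(as.vector(image)),
             (1e-10 * (max(abs(image)) + 1))^2, .Machine$double.xmin)
  flat <- tr < eps
  AI <- ifelse(flat, 0, (l1 - l2) / pmax(tr, .Machine$double.xmin))
  # gradient orientation, then +90 deg for the structure direction
  grad_deg <- 0.5 * atan2(2 * Jxy, Jxx - Jyy) * 180 / pi
  orient <- (grad_deg + 90) %% 180
  structure(list(AI = AI, orientation_deg = orient, energy = tr,
                 lambda1 = l1, lambda2 = l2, flat = flat,
                 pixel_size = pixel_size),
            class = "st_field")
}

#' Mean anisotropy index over an ROI
#'
#' Mean of the pixelwise AI over the mask, excluding flat-flagged pixels.
#'
#' @param field an [structure_tensor()] result.
#' @param mask an [roi_mask()] or logical matrix of the image shape.
#' @return Named list: `AI` (scalar mean) and `n_pixels`.
#' @export
roi_ai <- function(field, mask) {
  stopifnot(inherits(field, "st_field"))
  m <- if (inherits(mask, "roi_mask"))
    rasterize_roi(mask, dim(field$AI)) else mask
  stopifnot(identical(dim(m), dim(field$AI)))
  if (!any(m)) stop("empty ROI mask")
  use <- m & !field$flat
  if (!any(use)) stop("all ROI pixels are flagged flat")
  list(AI = mean(field$AI[use]), n_pixels = sum(use))
}

#' Configuration for automated cell counting
#'
#' @param min_area,max_area accepted per-cell area range in um^2
#'   (soma-scale defaults).
#' @param bg_sigma_um background-flattening Gaussian scale in um.
#' @param watershed_tolerance,watershed_ext `EBImage::watershed` controls.
#' @return List of class `cell_count_config`.
#' @export
cell_count_config <- function(min_area = 20, max_area = 400,
                              bg_sigma_um = 15,
                              watershed_tolerance = 0.3,
                              watershed_ext = 1L) {
  structure(as.list(environment()), class = "cell_count_config")
}

#' Automated cell detection on a Nissl-type image
#'
#' Stages: intensity inversion (stained cells are dark), background
#' flattening by large-scale Gaussian subtraction, Otsu global threshold,
#' distance-transform watershed to split touching cells, and an area
#' filter.  A blank image yields zero cells; a degenerate threshold (all
#' pixels one class) yields zero cells with a warning.
#'
#' @param image numeric matrix, bright background with dark cells.
#' @param pixel_size um/pixel.
#' @param config a [cell_count_config()].
#' @return Object of class `cell_detection`: `centroids` (data frame with
#'   0-based `row`, `col` in px and `x_um`, `y_um`), `areas_um2`, `count`,
#'   `labels` (label matrix).
#' @export
detect_cells <- function(image, pixel_size = sqrt(0.013),
                         config = cell_count_config()) {
  stopifnot(is.matrix(image), pixel_size > 0)
  inv <- max(image) - image
  rng <- diff(range(inv))
  empty <- function(msg = NULL) {
    if (!is.null(msg)) warning(msg)
    structure(list(centroids = data.frame(row = numeric(0),
                                          col = numeric(0),
                                          x_um = numeric(0),
                                          y_um = numeric(0)),
                   areas_um2 = numeric(0), count = 0L,
                   labels = matrix(0L, nrow(image), ncol(image))),
              class = "cell_detection")
  }
  if (rng <= .Machine$double.eps) return(empty())
  inv <- inv / rng
  bg <- .sep_conv(inv, .gauss_kernel(config$bg_sigma_um / pixel_size),
                  .gauss_kernel(config$bg_sigma_um / pixel_size))
  flat <- inv - bg
  flat <- (flat - min(flat)) / max(diff(range(flat)), .Machine$double.eps)
  thr <- EBImage::otsu(EBImage::Image(flat), range = c(0, 1))
  mask <- flat > thr
  if (!any(mask) || all(mask))
    return(empty("degenerate threshold: no foreground/background split"))
  dm <- EBImage::distmap(EBImage::Image(mask))
  lab <- EBImage::watershed(dm, tolerance = config$watershed_tolerance,
                            ext = config$watershed_ext)
  lab <- EBImage::imageData(lab)
  ids <- sort(unique(as.integer(lab[lab > 0])))
  if (!length(ids)) return(empty())
  px_area <- pixel_size^2
  rows <- row(lab) - 1L; cols <- col(lab) - 1L
  keep_rows <- list(); areas <- numeric(0)
  for (id in ids) {
    sel <- lab == id
    a <- sum(sel) * px_area
    if (a < config$min_area || a > config$max_area) next
    cr <- mean(rows[sel]) + 0.5; cc <- mean(cols[sel]) + 0.5
    keep_rows[[length(keep_rows) + 1L]] <-
      data.frame(row = cr, col = cc,
                 x_um = cc * pixel_size, y_um = cr * pixel_size)
    areas <- c(areas, a)
  }
  if (!length(keep_rows)) return(empty())
  cents <- do.call(rbind, keep_rows)
  structure(list(centroids = cents, areas_um2 = areas,
                 count = nrow(cents), labels = lab),
            class = "cell_detection")
}

#' @export
print.cell_detection <- function(x, ...) {
  cat("Cell detection:", x$count, "cells\n")
  invisible(x)
}

#' Cell density over an ROI
#'
#' Count of detected centroids inside the mask divided by the mask area.
#' The conventional display scale is cells/um^2 x 1e-2; this function
#' returns the unscaled density in cells/um^2.
#'
#' @param detection a [detect_cells()] result.
#' @param mask an [roi_mask()].
#' @param image_shape image dimensions, needed to rasterize polygon masks.
#' @return Named list: `CD` (cells/um^2), `count`, `area_um2`.
#' @export
cell_density <- function(detection, mask, image_shape = dim(detection$labels)) {
  stopifnot(inherits(detection, "cell_detection"),
            inherits(mask, "roi_mask"))
  area <- roi_area(mask)   # errors on zero-area masks
  r <- rasterize_roi(mask, image_shape)
  if (detection$count == 0L)
    return(list(CD = 0, count = 0L, area_um2 = area))
  ri <- pmin(pmax(floor(detection$centroids$row), 0), nrow(r) - 1L) + 1L
  ci <- pmin(pmax(floor(detection$centroids$col), 0), ncol(r) - 1L) + 1L
  inside <- r[cbind(ri, ci)]
  list(CD = sum(inside) / area, count = sum(inside), area_um2 = area)
}
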