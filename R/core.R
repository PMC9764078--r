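#' Reference standards for healthy myelin ultrastructure
#'
#' Literature values against which fitted lamellar periods and
#' commensurability ratios are judged: the standard lamellar period
#' \eqn{\lambda_L^* = 17.6} nm of the multilamellar myelin stack and the
#' standard commensurability \eqn{\eta^* = 0.866} between the lamellar and
#' hexagonal lattice units.
#'
#' @param lambda_L_star standard lamellar period in nm (> 0).
#' @param eta_star standard commensurability ratio, in (0, 1].
#' @return An object of class `reference_standards`.
#' @examples
#' reference_standards()
#' @export
reference_standards <- function(lambda_L_star = 17.6, eta_star = 0.866) {
  stopifnot(is.numeric(lambda_L_star), length(lambda_L_star) == 1L,
            lambda_L_star > 0,
            is.numeric(eta_star), length(eta_star) == 1L,
            eta_star > 0, eta_star <= 1)
  structure(list(lambda_L_star = lambda_L_star, eta_star = eta_star),
            class = "reference_standards")
}

#' @export
print.reference_standards <- function(x, ...) {
  cat("Reference standards: lambda_L* =", x$lambda_L_star, "nm, eta* =",
      x$eta_star, "\n")
  invisible(x)
}

#' Canonical region-of-interest labels
#'
#' The five brain regions evaluated region-by-region across modalities.
#'
#' @return Character vector of the five ROI labels.
#' @export
roi_labels <- function() {
  c("external capsule", "cortex layer VI", "cingulum",
    "corpus callosum", "internal capsule")
}

#' Construct a region-of-interest mask
#'
#' A mask is either a binary raster (logical/0-1 matrix, `TRUE` inside) or a
#' polygon in continuous 0-based image coordinates (`x` = column, `y` = row,
#' origin at the top-left corner of pixel (0, 0); the center of pixel
#' (i, j) sits at (x = j + 0.5, y = i + 0.5)).
#'
#' @param geometry a logical or 0/1 matrix (raster) or a data frame / matrix
#'   with columns `x`, `y` (polygon vertices, pixel units).
#' @param pixel_size pixel edge length in micrometres (> 0).
#' @param label region label (free text; see [roi_labels()] for the
#'   canonical set).
#' @param bregma optional bregma coordinate in mm.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(geometry, pixel_size, label = NA_character_,
                     bregma = NA_real_) {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive number (um/pixel)")
  if (is.matrix(geometry) && (is.logical(geometry) ||
      all(geometry %in% c(0, 1)))) {
    raster <- matrix(as.logical(geometry), nrow(geometry), ncol(geometry))
    if (!any(raster)) stop("empty mask: raster contains no inside pixels")
    out <- list(kind = "raster", raster = raster, polygon = NULL)
  } else {
    poly <- as.data.frame(geometry)
    if (is.null(poly$x) || is.null(poly$y)) {
      if (ncol(poly) >= 2L) names(poly)[1:2] <- c("x", "y")
    }
    if (nrow(poly) < 3L) stop("empty mask: polygon needs at least 3 vertices")
    out <- list(kind = "polygon", raster = NULL,
                polygon = poly[, c("x", "y")])
  }
  out$pixel_size <- pixel_size
  out$label <- label
  out$bregma <- bregma
  class(out) <- "roi_mask"
  out
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("ROI mask [", x$kind, "]",
      if (!is.na(x$label)) paste0(" '", x$label, "'"), ": area ",
      format(roi_area(x)), " um^2\n", sep = "")
  invisible(x)
}

# Even-odd (ray crossing) point-in-polygon test, vectorized over points.
# Points exactly on a horizontal edge follow the half-open crossing rule.
.point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py[crosses] - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

#' Rasterize an ROI mask
#'
#' Converts a polygon mask to a binary raster by the pixel-center inclusion
#' rule; raster masks pass through unchanged (idempotent).
#'
#' @param mask an [roi_mask()].
#' @param image_shape integer vector `c(rows, cols)` of the target image.
#' @return Logical matrix of dimension `image_shape`, `TRUE` inside the ROI.
#' @export
rasterize_roi <- function(mask, image_shape) {
  stopifnot(inherits(mask, "roi_mask"), length(image_shape) == 2L)
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  if (mask$kind == "raster") {
    r <- mask$raster
    if (!identical(dim(r), c(nr, nc)))
      stop("raster mask dimensions ", paste(dim(r), collapse = "x"),
           " do not match image_shape ", nr, "x", nc)
    return(r)
  }
  poly <- mask$polygon
  bad <- which(poly$x < 0 | poly$x > nc | poly$y < 0 | poly$y > nr)
  if (length(bad))
    stop("polygon vertex ", bad[1], " at (", poly$x[bad[1]], ", ",
         poly$y[bad[1]], ") lies outside image bounds [0,", nc, "] x [0,",
         nr, "]")
  cx <- rep(seq_len(nc) - 0.5, each = nr)   # pixel-center x (column)
  cy <- rep(seq_len(nr) - 0.5, times = nc)  # pixel-center y (row)
  inside <- .point_in_polygon(cx, cy, poly$x, poly$y)
  matrix(inside, nr, nc)
}

#' ROI area in square micrometres
#'
#' Area is the inside-pixel count times the squared pixel size; polygon
#' masks are measured by the shoelace formula (consistent with the raster
#' count to within one pixel row).
#'
#' @param mask an [roi_mask()].
#' @return Area in um^2.
#' @export
roi_area <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  if (mask$kind == "raster") {
    n <- sum(mask$raster)
    if (n == 0L) stop("mask has zero area")
    return(n * mask$pixel_size^2)
  }
  x <- mask$polygon$x; y <- mask$polygon$y
  n <- length(x)
  a <- abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
  if (a <= 0) stop("mask has zero area")
  a * mask$pixel_size^2
}

#' Modalities of the standard per-region metrics
#'
#' Maps metric names to the imaging modality they originate from: the seven
#' diffusion-tensor metrics, the two histological metrics, and the four
#' diffraction metrics.
#'
#' @return Named character vector metric -> modality.
#' @export
metric_modalities <- function() {
  c(FA = "dti", AD = "dti", RD = "dti", MD = "dti",
    CL = "dti", CP = "dti", CS = "dti",
    AI = "histology", CD = "histology",
    C_L = "diffraction", lambda_L = "diffraction",
    C_H = "diffraction", lambda_H = "diffraction")
}

#' Create a per-region metric record table
#'
#' One row per (animal, region, modality, metric) with a numeric value.
#' Keys must be unique; missing values are permitted and flagged.
#'
#' @param animal,group,region,modality,metric,value vectors of equal length.
#' @return A `data.frame` of class `metric_table`, ordered by
#'   (animal, region, metric).
#' @export
metric_table <- function(animal, group, region, modality, metric, value) {
  df <- data.frame(animal = as.character(animal),
                   group = as.character(group),
                   region = as.character(region),
                   modality = as.character(modality),
                   metric = as.character(metric),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  key <- paste(df$animal, df$region, df$modality, df$metric, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate metric record(s): ",
         paste(unique(gsub("\r", "/", key[dup])), collapse = ", "))
  df <- df[order(df$animal, df$region, df$metric), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("metric_table", "data.frame")
  df
}

#' Read a metric table from CSV
#'
#' Expects header `animal,group,region,modality,metric,value`.  The string
#' `NA` (or an empty field) in `value` parses as missing and is flagged in
#' the `missing_rows` attribute; any other non-numeric value is an error
#' naming the offending row.
#'
#' @param path CSV file path.
#' @return A `metric_table`.
#' @export
read_metric_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  need <- c("animal", "group", "region", "modality", "metric", "value")
  if (!all(need %in% names(raw)))
    stop("metric table must have columns: ", paste(need, collapse = ","))
  vstr <- trimws(raw$value)
  is_na <- vstr == "" | toupper(vstr) == "NA"
  val <- suppressWarnings(as.numeric(vstr))
  bad <- which(!is_na & is.na(val))
  if (length(bad))
    stop("non-numeric value '", vstr[bad[1]], "' in row ", bad[1])
  tab <- metric_table(raw$animal, raw$group, raw$region, raw$modality,
                      raw$metric, val)
  if (anyNA(tab$value)) attr(tab, "missing_rows") <- which(is.na(tab$value))
  tab
}

#' Write a metric table to CSV
#'
#' Inverse of [read_metric_table()]: writing then reading returns an
#' identical table (stable (animal, region, metric) row order).
#'
#' @param table a `metric_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) {
  stopifnot(inherits(table, "metric_table"))
  df <- as.data.frame(table)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}
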