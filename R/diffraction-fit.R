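#' Quasi-Bragg peak positions of the multilamellar phase
#'
#' \eqn{q_L^h = 2\pi h / \lambda_L}; for myelin the observable orders are
#' h = 2, 3 (the first order lies behind the beamstop at typical
#' geometries).
#'
#' @param lambda_L lamellar period in nm (> 0).
#' @param orders positive integer reflection orders.
#' @return Ascending q positions in 1/nm, named by order.
#' @examples
#' lamellar_positions(17.6)  # 0.714, 1.071
#' @export
lamellar_positions <- function(lambda_L, orders = c(2L, 3L)) {
  stopifnot(is.numeric(lambda_L), lambda_L > 0)
  if (any(orders <= 0)) stop("reflection orders must be positive")
  q <- sort(2 * pi * orders / lambda_L)
  names(q) <- paste0("h", sort(orders))
  q
}

#' Reflection positions of the planar hexagonal phase
#'
#' \eqn{q_H^{h,k} = (4\pi/\sqrt{3}\lambda_H)\sqrt{h^2 + hk + k^2}} for the
#' indexed reflections (default (1,0), (2,0), (2,3)).
#'
#' @param lambda_H hexagonal lattice unit in nm (> 0).
#' @param reflections two-column matrix (or list of pairs) of (h, k)
#'   indices.
#' @return Ascending q positions in 1/nm, named `h<h>k<k>`, with the
#'   reflection multiplicity recorded in the `multiplicity` attribute.
#' @export
hexagonal_positions <- function(lambda_H,
                                reflections = rbind(c(1, 0), c(2, 0),
                                                    c(2, 3))) {
  stopifnot(is.numeric(lambda_H), lambda_H > 0)
  if (is.list(reflections)) reflections <- do.call(rbind, reflections)
  h <- reflections[, 1]; k <- reflections[, 2]
  m2 <- h^2 + h * k + k^2
  if (any(m2 == 0)) stop("(0,0) is not a valid reflection")
  q <- (4 * pi / (sqrt(3) * lambda_H)) * sqrt(m2)
  # multiplicity of the 2D hexagonal lattice: 6 for (h,0)/(h,h), else 12
  mult <- ifelse(k == 0 | h == 0 | h == k, 6L, 12L)
  ord <- order(q)
  q <- q[ord]
  names(q) <- paste0("h", h[ord], "k", k[ord])
  attr(q, "multiplicity") <- mult[ord]
  q
}

#' Commensurability of the lamellar and hexagonal lattices
#'
#' \eqn{\eta = \lambda_L / \lambda_H}; the standard commensurate value is
#' 0.866 (= sqrt(3)/2, at which the lamellar h = 2 and hexagonal (2,0)
#' reflections coincide).
#'
#' @param lambda_L,lambda_H lattice units in nm (> 0); `lambda_H = NA`
#'   (unidentifiable) yields `NA`.
#' @return The dimensionless ratio.
#' @export
commensurability <- function(lambda_L, lambda_H) {
  stopifnot(lambda_L > 0)
  if (is.na(lambda_H)) return(NA_real_)
  stopifnot(lambda_H > 0)
  lambda_L / lambda_H
}

#' Fit configuration for the two-phase Bragg model
#'
#' @param orders lamellar reflection orders.
#' @param reflections hexagonal (h, k) reflections (two-column matrix).
#' @param lambda_L_bounds,lambda_H_bounds search brackets in nm.
#' @param init_window q window (1/nm) searched for the lamellar h = 2 peak
#'   when initializing.
#' @param fit_window q window actually fitted.
#' @param baseline fit a residual linear baseline alongside the peaks.
#' @param sigma_init initial Gaussian width (1/nm).
#' @param sigma_bounds allowed Gaussian width range (1/nm).
#' @param snr_min peak must exceed `snr_min` times the noise scale to count
#'   as detected.
#' @param ptol,ftol,maxiter Levenberg-Marquardt termination controls.
#' @return List of class `phase_fit_config`.
#' @export
phase_fit_config <- function(orders = c(2L, 3L),
                             reflections = rbind(c(1, 0), c(2, 0), c(2, 3)),
                             lambda_L_bounds = c(12, 25),
                             lambda_H_bounds = c(12, 30),
                             init_window = c(0.55, 0.90),
                             fit_window = c(0.15, 2.0),
                             baseline = TRUE,
                             sigma_init = 0.02,
                             sigma_bounds = c(1e-4, 0.25),
                             snr_min = 5,
                             ptol = 1e-10, ftol = 1e-10, maxiter = 500L) {
  structure(as.list(environment()), class = "phase_fit_config")
}

# Sum-of-Gaussians + linear baseline model on grid q for parameter vector
# p = (lambda_L, lambda_H, ampL..., ampH..., sigL..., sigH..., b0, b1)
.two_phase_model <- function(p, q, nL, nH, cfg) {
  lamL <- p[1]; lamH <- p[2]
  ampL <- p[3:(2 + nL)]
  ampH <- if (nH > 0) p[(3 + nL):(2 + nL + nH)] else numeric(0)
  sig <- p[(3 + nL + nH):(2 + 2 * nL + 2 * nH)]
  sigL <- sig[seq_len(nL)]
  sigH <- if (nH > 0) sig[nL + seq_len(nH)] else numeric(0)
  base <- p[length(p) - 1] + p[length(p)] * q
  ctrL <- 2 * pi * cfg$orders / lamL
  y <- base
  for (i in seq_len(nL))
    y <- y + ampL[i] * exp(-0.5 * ((q - ctrL[i]) / sigL[i])^2)
  if (nH > 0) {
    m2 <- cfg$reflections[, 1]^2 +
      cfg$reflections[, 1] * cfg$reflections[, 2] + cfg$reflections[, 2]^2
    ctrH <- (4 * pi / (sqrt(3) * lamH)) * sqrt(m2)
    for (i in seq_len(nH))
      y <- y + ampH[i] * exp(-0.5 * ((q - ctrH[i]) / sigH[i])^2)
  }
  y
}

# robust noise scale of a corrected profile: MAD of successive differences
# in the fit window (insensitive to the smooth peaks themselves)
.noise_scale <- function(intensity) {
  d <- diff(intensity[is.finite(intensity)])
  stats::mad(d, center = 0) / sqrt(2)
}

#' Fit the two-phase (lamellar + hexagonal) Bragg-peak model
#'
#' Nonlinear least squares with Gaussian line shapes whose centers are hard
#' constrained to the lattice positions [lamellar_positions()] and
#' [hexagonal_positions()], so each phase contributes a single shared
#' lattice unit (\eqn{\lambda_L}, \eqn{\lambda_H}).  Free parameters are
#' the two lattice units, one amplitude (>= 0) and width (> 0) per peak,
#' and an optional residual linear baseline.
#'
#' If no peak rises above the noise floor in the lamellar search window the
#' profile is classified "no myelin" (a flagged result, not an error).  If
#' the hexagonal component is absent its amplitudes converge to zero and
#' \eqn{\lambda_H} is reported `NA` with the `hex_unidentifiable` flag.
#'
#' @param profile a corrected [radial_profile()].
#' @param config a [phase_fit_config()].
#' @return Object of class `phase_fit` with elements `lambda_L`,
#'   `lambda_H`, `eta`, `peaks` (data frame phase/label/center/amplitude/
#'   sigma), `C_L`, `C_H`, `baseline`, `residual_norm`, `converged`,
#'   `no_myelin`, `hex_unidentifiable`, `niter`.
#' @export
fit_two_phase <- function(profile, config = phase_fit_config()) {
  stopifnot(inherits(profile, "radial_profile"),
            inherits(config, "phase_fit_config"))
  cfg <- config
  sel <- profile$q >= cfg$fit_window[1] & profile$q <= cfg$fit_window[2] &
    is.finite(profile$intensity)
  q <- profile$q[sel]; y <- profile$intensity[sel]
  if (length(q) < 10L) stop("too few valid points in the fit window")

  noise <- .noise_scale(y)
  win <- q >= cfg$init_window[1] & q <= cfg$init_window[2]
  if (!any(win)) stop("lamellar init window not covered by the profile")
  pk_height <- max(y[win]) - stats::median(y)
  floor_abs <- max(cfg$snr_min * noise, 1e-12 * max(abs(y), 1e-300))
  if (!is.finite(pk_height) || pk_height <= floor_abs) {
    out <- list(lambda_L = NA_real_, lambda_H = NA_real_, eta = NA_real_,
                peaks = NULL, C_L = NA_real_, C_H = NA_real_,
                baseline = c(0, 0), residual_norm = NA_real_,
                converged = FALSE, no_myelin = TRUE,
                hex_unidentifiable = TRUE, niter = 0L)
    class(out) <- "phase_fit"
    return(out)
  }

  nL <- length(cfg$orders); nH <- nrow(cfg$reflections)
  # init lambda_L from the argmax in the h = 2 window
  q_pk <- q[win][which.max(y[win])]
  lamL0 <- min(max(2 * pi * 2 / q_pk, cfg$lambda_L_bounds[1]),
               cfg$lambda_L_bounds[2])
  ampL0 <- rep(pk_height, nL) * c(1, rep(0.4, nL - 1))

  # init lambda_H from the strongest residual local max in the (1,0) window
  resid0 <- y - .two_phase_model(
    c(lamL0, 20, ampL0, rep(0, nH), rep(cfg$sigma_init, nL + nH),
      stats::median(y), 0), q, nL, nH, cfg)
  q10_win <- 4 * pi / (sqrt(3) * rev(cfg$lambda_H_bounds))
  hwin <- q >= q10_win[1] & q <= q10_win[2]
  hex_detect <- any(hwin) &&
    (max(resid0[hwin]) > max(cfg$snr_min * noise, 0.02 * pk_height))
  # model only includes the hexagonal component when it is detected;
  # otherwise it would freely absorb lamellar residue (the (2,0)
  # reflection coincides with the lamellar h = 2 peak at commensurability)
  nHf <- if (hex_detect) nH else 0L
  lamH0 <- if (hex_detect)
    min(max(4 * pi / (sqrt(3) * q[hwin][which.max(resid0[hwin])]),
            cfg$lambda_H_bounds[1]), cfg$lambda_H_bounds[2])
  else mean(cfg$lambda_H_bounds)
  ampH0 <- rep(0.2 * pk_height, nHf)

  p0 <- c(lamL0, lamH0, ampL0, ampH0, rep(cfg$sigma_init, nL + nHf),
          if (cfg$baseline) c(stats::median(y), 0) else c(0, 0))
  lower <- c(cfg$lambda_L_bounds[1], cfg$lambda_H_bounds[1],
             rep(0, nL + nHf), rep(cfg$sigma_bounds[1], nL + nHf),
             if (cfg$baseline) c(-Inf, -Inf) else c(0, 0))
  upper <- c(cfg$lambda_L_bounds[2], cfg$lambda_H_bounds[2],
             rep(Inf, nL + nHf), rep(cfg$sigma_bounds[2], nL + nHf),
             if (cfg$baseline) c(Inf, Inf) else c(0, 0))
  cfg_fit <- cfg
  if (!hex_detect) cfg_fit$reflections <- cfg$reflections[0, , drop = FALSE]

  fit <- minpack.lm::nls.lm(
    par = p0,
    lower = lower, upper = upper,
    fn = function(p) y - .two_phase_model(p, q, nL, nHf, cfg_fit),
    control = minpack.lm::nls.lm.control(ptol = cfg$ptol, ftol = cfg$ftol,
                                         maxiter = cfg$maxiter))
  p <- fit$par
  converged <- fit$info %in% 1:4
  lamL <- p[1]; lamH <- p[2]
  ampL <- p[3:(2 + nL)]
  ampH <- if (nHf > 0) p[(3 + nL):(2 + nL + nHf)] else rep(0, nH)
  sig <- p[(3 + nL + nHf):(2 + 2 * nL + 2 * nHf)]
  sigL <- sig[seq_len(nL)]
  sigH <- if (nHf > 0) sig[nL + seq_len(nHf)]
  else rep(cfg$sigma_init, nH)

  hex_unident <- !hex_detect || all(ampH <= max(1e-8 * max(ampL), 1e-12))
  if (hex_unident) { lamH <- NA_real_; ampH[] <- 0 }

  ctrL <- lamellar_positions(lamL, cfg$orders)
  ctrH <- if (!is.na(lamH)) hexagonal_positions(lamH, cfg$reflections)
  else rep(NA_real_, nH)
  peaks <- data.frame(
    phase = c(rep("lamellar", nL), rep("hexagonal", nH)),
    label = c(names(ctrL),
              paste0("h", cfg$reflections[, 1], "k", cfg$reflections[, 2])),
    center = c(as.numeric(ctrL), as.numeric(ctrH)),
    amplitude = c(ampL, ampH),
    sigma = c(sigL, sigH),
    stringsAsFactors = FALSE)

  out <- list(lambda_L = lamL, lambda_H = lamH,
              eta = commensurability(lamL, lamH),
              peaks = peaks,
              C_L = sum(ampL * sigL) * sqrt(2 * pi),
              C_H = sum(ampH * sigH) * sqrt(2 * pi),
              baseline = p[(length(p) - 1):length(p)],
              residual_norm = sqrt(sum(fit$fvec^2)),
              converged = converged, no_myelin = FALSE,
              hex_unidentifiable = hex_unident,
              niter = fit$niter)
  class(out) <- "phase_fit"
  out
}

#' @export
print.phase_fit <- function(x, ...) {
  if (x$no_myelin) { cat("Phase fit: no myelin signal\n"); return(invisible(x)) }
  cat(sprintf("Phase fit: lambda_L = %.4f nm, lambda_H = %s nm, eta = %s\n",
              x$lambda_L,
              if (is.na(x$lambda_H)) "NA" else sprintf("%.4f", x$lambda_H),
              if (is.na(x$eta)) "NA" else sprintf("%.4f", x$eta)))
  cat(sprintf("  C_L = %.4g, C_H = %.4g, converged = %s\n",
              x$C_L, x$C_H, x$converged))
  invisible(x)
}

#' Integrated phase contents from a converged fit
#'
#' \eqn{C_{Phase} = \int I_{Phase}(q)\,dq}, evaluated analytically as
#' \eqn{\sum_{peaks} A\,\sigma\sqrt{2\pi}} per phase.
#'
#' @param fit a converged [fit_two_phase()] result.
#' @return Named numeric `c(C_L, C_H)`.
#' @export
phase_content <- function(fit) {
  stopifnot(inherits(fit, "phase_fit"))
  if (!isTRUE(fit$converged)) stop("phase content requires a converged fit")
  pk <- fit$peaks
  lam <- pk$phase == "lamellar"
  c(C_L = sum(pk$amplitude[lam] * pk$sigma[lam]) * sqrt(2 * pi),
    C_H = sum(pk$amplitude[!lam] * pk$sigma[!lam]) * sqrt(2 * pi))
}

#' Classify a fitted tile against the healthy-myelin standards
#'
#' The lamellar period is compressed when \eqn{\lambda_L <
#' \lambda_L^*(1 - tol)}, expanded when \eqn{\lambda_L >
#' \lambda_L^*(1 + tol)}, else near-standard; analogously the packing is
#' sub-/super-commensurate or commensurate relative to \eqn{\eta^*}.
#'
#' @param fit a [fit_two_phase()] result (or a list with `lambda_L`,
#'   `eta`).
#' @param standards a [reference_standards()].
#' @param tolerance relative tolerance band (default 1%).
#' @return List with `period` and `packing` classifications (`packing` is
#'   `NA` when \eqn{\eta} is unidentifiable).
#' @export
classify_state <- function(fit, standards = reference_standards(),
                           tolerance = 0.01) {
  stopifnot(tolerance > 0)
  lamL <- fit$lambda_L; eta <- fit$eta
  per <- if (lamL < standards$lambda_L_star * (1 - tolerance)) "compressed"
  else if (lamL > standards$lambda_L_star * (1 + tolerance)) "expanded"
  else "near-standard"
  pack <- if (is.na(eta)) NA_character_
  else if (eta < standards$eta_star * (1 - tolerance)) "sub-commensurate"
  else if (eta > standards$eta_star * (1 + tolerance)) "super-commensurate"
  else "commensurate"
  list(period = per, packing = pack)
}

#' Fit every tile of a scan and assemble parameter maps
#'
#' Applies [fit_two_phase()] to each profile of a raster scan and collects
#' per-tile lattice units, contents and commensurability, together with a
#' quality mask (converged and above the myelin signal floor).
#'
#' @param scan a scan object from [make_scan()] or a list with elements
#'   `profiles` (list of [radial_profile()]), `y`, `z` (tile coordinates,
#'   um) and `step`.
#' @param config a [phase_fit_config()].
#' @return Object of class `scan_map`: a data frame (one row per tile:
#'   y, z, lambda_L, lambda_H, eta, C_L, C_H, converged, valid) with the
#'   scan step and per-map mean/SD summaries attached as attributes.
#' @export
fit_scan <- function(scan, config = phase_fit_config()) {
  stopifnot(is.list(scan$profiles))
  n <- length(scan$profiles)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fit_two_phase(scan$profiles[[i]], config)
    rows[[i]] <- data.frame(
      y = scan$y[i], z = scan$z[i],
      lambda_L = f$lambda_L, lambda_H = f$lambda_H, eta = f$eta,
      C_L = f$C_L, C_H = f$C_H,
      converged = f$converged,
      valid = f$converged && !f$no_myelin)
  }
  map <- do.call(rbind, rows)
  attr(map, "step") <- scan$step
  ok <- map$valid
  attr(map, "summary") <- if (any(ok)) data.frame(
    metric = c("lambda_L", "eta", "C_L", "C_H"),
    mean = c(mean(map$lambda_L[ok]), mean(map$eta[ok], na.rm = TRUE),
             mean(map$C_L[ok]), mean(map$C_H[ok])),
    sd = c(stats::sd(map$lambda_L[ok]), stats::sd(map$eta[ok], na.rm = TRUE),
           stats::sd(map$C_L[ok]), stats::sd(map$C_H[ok])))
  else NULL
  class(map) <- c("scan_map", "data.frame")
  map
}

#' Kernel density of the lamellar period over an ROI
#'
#' Gaussian-kernel probability density of the per-tile \eqn{\lambda_L}
#' values inside an ROI, renormalized so the curve integrates to 1 (within
#' 1e-6), plus the underlying histogram.
#'
#' @param map a [fit_scan()] result.
#' @param mask optional logical vector (per tile) or [roi_mask()] raster
#'   over the scan grid selecting tiles; default all valid tiles.
#' @param bandwidth kernel bandwidth in nm; default `stats::bw.nrd0`.
#' @return List with `x` (nm grid), `density`, `bandwidth`, `n`, and
#'   `histogram` (a `hist` object).
#' @export
roi_lambda_pdf <- function(map, mask = NULL, bandwidth = NULL) {
  stopifnot(inherits(map, "scan_map") || is.data.frame(map))
  keep <- map$valid & is.finite(map$lambda_L)
  if (!is.null(mask)) {
    m <- if (inherits(mask, "roi_mask")) as.vector(mask$raster) else as.vector(mask)
    stopifnot(length(m) == nrow(map))
    keep <- keep & m
  }
  vals <- map$lambda_L[keep]
  if (length(vals) < 2L)
    stop("need at least 2 valid tiles in the ROI (got ", length(vals), ")")
  bw <- if (is.null(bandwidth)) {
    b <- stats::bw.nrd0(vals)
    if (!is.finite(b) || b <= 0) 0.05 else b
  } else bandwidth
  d <- stats::density(vals, bw = bw, n = 1024L, cut = 4)
  # trapezoid renormalization to machine-level unit mass
  area <- sum(diff(d$x) * (d$y[-1] + d$y[-length(d$y)]) / 2)
  list(x = d$x, density = d$y / area, bandwidth = bw, n = length(vals),
       histogram = graphics::hist(vals, breaks = "FD", plot = FALSE))
}
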