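#' Diffusion acquisition protocol
#'
#' Per-volume b-values (s/mm^2) and unit gradient directions.  The default
#' two-shell ex vivo protocol has 4 b0 volumes and the same 30 directions
#' at b = 3000 and b = 6000 s/mm^2.
#'
#' @param bvals numeric vector of b-values, one per volume.
#' @param bvecs 3 x n or n x 3 matrix of gradient directions; non-b0
#'   directions must be unit norm within 1e-6.
#' @return Object of class `dti_protocol` with `bvals` and `bvecs`
#'   (n x 3).
#' @export
dti_protocol <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  if (nrow(as.matrix(bvecs)) == 3L && ncol(as.matrix(bvecs)) != 3L)
    bvecs <- t(bvecs)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != length(bvals))
    stop("bvals and bvecs describe different numbers of volumes")
  nb <- sqrt(rowSums(bvecs^2))
  dw <- bvals > 0
  if (any(abs(nb[dw] - 1) > 1e-6))
    stop("non-unit gradient direction at volume ",
         which(dw & abs(nb - 1) > 1e-6)[1])
  if (length(bvals) < 7L)
    stop("need at least 7 volumes (1 b0 + 6 directions)")
  if (qr(.tensor_design(bvals, bvecs))$rank < 7L)
    stop("rank-deficient protocol: fewer than 6 independent directions")
  structure(list(bvals = bvals, bvecs = bvecs), class = "dti_protocol")
}

#' Default two-shell protocol (4 b0 + 30 directions x {3000, 6000})
#'
#' Directions are a deterministic spherical Fibonacci set on the upper
#' hemisphere (antipodally equivalent for diffusion encoding).
#'
#' @param n_dir directions per shell.
#' @param bvals_shell shell b-values in s/mm^2.
#' @param n_b0 number of b0 volumes.
#' @return A [dti_protocol()].
#' @export
default_dti_protocol <- function(n_dir = 30L, bvals_shell = c(3000, 6000),
                                 n_b0 = 4L) {
  i <- seq_len(n_dir) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n_dir              # upper hemisphere
  r <- sqrt(1 - z^2)
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  bv <- c(rep(0, n_b0), rep(bvals_shell, each = n_dir))
  gv <- rbind(matrix(0, n_b0, 3),
              do.call(rbind, rep(list(dirs), length(bvals_shell))))
  dti_protocol(bv, gv)
}

# design matrix of the log-linear tensor model:
# ln S = ln S0 - b (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz
#                   + 2 gx gy Dxy + 2 gx gz Dxz + 2 gy gz Dyz)
.tensor_design <- function(bvals, bvecs) {
  g <- bvecs
  cbind(1,
        -bvals * g[, 1]^2, -bvals * g[, 2]^2, -bvals * g[, 3]^2,
        -2 * bvals * g[, 1] * g[, 2],
        -2 * bvals * g[, 1] * g[, 3],
        -2 * bvals * g[, 2] * g[, 3])
}

.vec_to_tensor <- function(d) {
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3, 3)
}

#' Fit a single diffusion tensor to one voxel's signals
#'
#' Weighted log-linear least squares on \eqn{\ln S = \ln S_0 - b\,
#' g^T D g}: an ordinary LS pass on the log signals followed by one
#' reweighted pass with weights equal to the squared predicted signals
#' (noiseless data are recovered exactly).  Nonpositive signals cannot be
#' log-transformed; the voxel is flagged and such volumes dropped.
#'
#' @param signals numeric vector, one per protocol volume.
#' @param protocol a [dti_protocol()].
#' @param weighted use the reweighted pass (default `TRUE`).
#' @return Object of class `diffusion_tensor`: `D` (symmetric 3 x 3,
#'   mm^2/s), `S0`, `eigenvalues` (sorted decreasing), `eigenvectors`,
#'   `negative_eigenvalues` flag, `dropped_volumes`.
#' @export
fit_tensor <- function(signals, protocol, weighted = TRUE) {
  stopifnot(inherits(protocol, "dti_protocol"))
  if (length(signals) != length(protocol$bvals))
    stop("signals length does not match protocol")
  keep <- is.finite(signals) & signals > 0
  dropped <- sum(!keep)
  bv <- protocol$bvals[keep]; gv <- protocol$bvecs[keep, , drop = FALSE]
  if (all(bv == 0)) stop("no diffusion-weighted volumes with usable signal")
  X <- .tensor_design(bv, gv)
  if (qr(X)$rank < 7L)
    stop("rank-deficient design: fewer than 6 independent directions")
  ly <- log(signals[keep])
  beta <- stats::lm.fit(X, ly)$coefficients
  if (weighted) {
    w <- exp(X %*% beta)^2          # squared predicted signal
    beta <- stats::lm.wfit(X, ly, as.vector(w))$coefficients
  }
  D <- .vec_to_tensor(beta[-1])
  e <- eigen(D, symmetric = TRUE)
  structure(list(D = D, S0 = unname(exp(beta[1])),
                 eigenvalues = e$values, eigenvectors = e$vectors,
                 negative_eigenvalues = any(e$values < 0),
                 dropped_volumes = dropped),
            class = "diffusion_tensor")
}

#' Scalar metrics of a diffusion tensor
#'
#' From the sorted eigenvalues \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3}
#' (negative eigenvalues clamped to 0, with a flag):
#' MD = mean eigenvalue, AD = \eqn{\lambda_1}, RD =
#' \eqn{(\lambda_2+\lambda_3)/2},
#' FA = \eqn{\sqrt{3/2}\,\sqrt{\sum(\lambda_i - MD)^2}/\sqrt{\sum
#' \lambda_i^2}}, and the trace-normalized Westin shape indices
#' CL = \eqn{(\lambda_1-\lambda_2)/\sum\lambda}, CP =
#' \eqn{2(\lambda_2-\lambda_3)/\sum\lambda}, CS =
#' \eqn{3\lambda_3/\sum\lambda}, which satisfy CL + CP + CS = 1.
#' An eigenvalue-normalized variant (divide by \eqn{3\lambda_1}) is
#' available via `normalization = "lambda1"` (those indices no longer sum
#' to 1).
#'
#' @param tensor a [fit_tensor()] result, a symmetric 3 x 3 matrix, or a
#'   length-3 eigenvalue vector.
#' @param normalization `"trace"` (default) or `"lambda1"` for the Westin
#'   indices.
#' @return Named numeric: FA, MD, AD, RD, CL, CP, CS, plus attributes
#'   `clamped` and `degenerate`.
#' @export
tensor_metrics <- function(tensor, normalization = c("trace", "lambda1")) {
  normalization <- match.arg(normalization)
  ev <- if (inherits(tensor, "diffusion_tensor")) tensor$eigenvalues
  else if (is.matrix(tensor)) eigen(tensor, symmetric = TRUE)$values
  else sort(as.numeric(tensor), decreasing = TRUE)
  clamped <- any(ev < 0)
  ev <- pmax(ev, 0)
  l1 <- ev[1]; l2 <- ev[2]; l3 <- ev[3]
  tr <- l1 + (l2 + l3)   # association makes MD = (AD + 2 RD)/3 bit-exact
  md <- tr / 3
  out <- c(FA = 0, MD = md, AD = l1, RD = (l2 + l3) / 2,
           CL = 0, CP = 0, CS = 0)
  degenerate <- tr <= 0
  if (!degenerate) {
    out["FA"] <- sqrt(1.5) * sqrt(sum((ev - md)^2)) / sqrt(sum(ev^2))
    den <- if (normalization == "trace") tr else 3 * l1
    out["CL"] <- (l1 - l2) / den
    out["CP"] <- 2 * (l2 - l3) / den
    out["CS"] <- 3 * l3 / den
  }
  attr(out, "clamped") <- clamped
  attr(out, "degenerate") <- degenerate
  out
}

#' Fit a whole DWI volume and produce metric maps
#'
#' Applies [fit_tensor()] and [tensor_metrics()] voxelwise over a 4D array
#' (x, y, z, volume).  Voxels where the fit fails (e.g. all-nonpositive
#' signal) are `NA` in every map and `TRUE` in the `failed` mask.
#'
#' @param dwi 4D numeric array; 4th dimension indexes protocol volumes.
#' @param protocol a [dti_protocol()].
#' @param mask optional logical 3D array restricting the fit.
#' @inheritParams tensor_metrics
#' @return List of 3D arrays `FA`, `MD`, `AD`, `RD`, `CL`, `CP`, `CS`,
#'   `S0` plus logical `failed`.
#' @export
fit_dwi_volume <- function(dwi, protocol, mask = NULL,
                           normalization = "trace") {
  stopifnot(length(dim(dwi)) == 4L)
  dims <- dim(dwi)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  nm <- c("FA", "MD", "AD", "RD", "CL", "CP", "CS", "S0")
  maps <- stats::setNames(rep(list(array(NA_real_, dims)), length(nm)), nm)
  failed <- array(FALSE, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      if (!mask[i, j, k]) next
      res <- tryCatch({
        tf <- fit_tensor(dwi[i, j, k, ], protocol)
        m <- tensor_metrics(tf, normalization)
        c(m, S0 = tf$S0)
      }, error = function(e) NULL)
      if (is.null(res)) { failed[i, j, k] <- TRUE; next }
      for (nmi in nm) maps[[nmi]][i, j, k] <- res[[nmi]]
    }
  maps$failed <- failed
  maps
}

#' Per-ROI means of DTI metric maps
#'
#' Arithmetic mean of each metric over the in-mask voxels, excluding
#' flagged (failed/NA) voxels; the contributing voxel count is reported
#' per metric.
#'
#' @param maps named list of metric arrays (e.g. from [fit_dwi_volume()]).
#' @param mask logical array of the same dimension.
#' @return Data frame with columns `metric`, `mean`, `n_voxels`.
#' @export
roi_dti <- function(maps, mask) {
  metric_names <- setdiff(names(maps), c("failed", "S0"))
  stopifnot(length(metric_names) > 0)
  if (!any(mask)) stop("empty ROI mask")
  res <- lapply(metric_names, function(nm) {
    v <- maps[[nm]][mask]
    v <- v[is.finite(v)]
    data.frame(metric = nm, mean = mean(v), n_voxels = length(v))
  })
  do.call(rbind, res)
}

#' Simulation specification for two-shell diffusion-weighted signals
#'
#' @param eigenvalues length-3 vector (mm^2/s), sorted decreasing, >= 0.
#' @param principal_direction unit 3-vector of the largest eigenvalue.
#' @param S0 b0 signal level.
#' @param snr Rician signal-to-noise ratio (S0 / Gaussian sigma); `Inf`
#'   for noiseless.
#' @param protocol a [dti_protocol()].
#' @param seed RNG seed.
#' @return List of class `dwi_sim_spec`.
#' @export
dwi_sim_spec <- function(eigenvalues = c(1.5e-3, 4e-4, 4e-4),
                         principal_direction = c(1, 0, 0),
                         S0 = 1000, snr = Inf,
                         protocol = default_dti_protocol(),
                         seed = 1L) {
  stopifnot(length(eigenvalues) == 3L, all(eigenvalues >= 0),
            !is.unsorted(rev(eigenvalues)), snr > 0)
  principal_direction <- principal_direction /
    sqrt(sum(principal_direction^2))
  structure(as.list(environment()), class = "dwi_sim_spec")
}

# orthonormal frame with given first axis
.frame_from_axis <- function(v1) {
  a <- if (abs(v1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v2 <- a - sum(a * v1) * v1; v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  cbind(v1, v2, v3)
}

#' Generate diffusion-weighted signals from a known tensor
#'
#' \eqn{S = S_0 \exp(-b\, g^T D g)} per volume, optionally corrupted by
#' Rician noise (magnitude of the complex signal plus i.i.d. Gaussian
#' noise of standard deviation \eqn{S_0 / SNR} in both channels).
#'
#' @param spec a [dwi_sim_spec()].
#' @return List of class `dwi_sim`: `signals`, `protocol`, `tensor`
#'   (true D), `spec`.
#' @export
make_dwi <- function(spec) {
  stopifnot(inherits(spec, "dwi_sim_spec"))
  R <- .frame_from_axis(spec$principal_direction)
  D <- R %*% diag(spec$eigenvalues) %*% t(R)
  g <- spec$protocol$bvecs; b <- spec$protocol$bvals
  expo <- rowSums((g %*% D) * g) * b
  s <- spec$S0 * exp(-expo)
  if (is.finite(spec$snr)) {
    sigma <- spec$S0 / spec$snr
    s <- withr::with_seed(spec$seed, {
      n1 <- stats::rnorm(length(s), 0, sigma)
      n2 <- stats::rnorm(length(s), 0, sigma)
      sqrt((s + n1)^2 + n2^2)
    })
  }
  structure(list(signals = s, protocol = spec$protocol, tensor = D,
                 spec = spec),
            class = "dwi_sim")
}

#' Generate a small multi-region DWI volume with known tensors
#'
#' Fills a 4D volume whose x-axis is split into contiguous regions, each
#' with its own diffusion tensor, and applies Rician noise per voxel.
#'
#' @param region_specs list of [dwi_sim_spec()]s, one per region.
#' @param dims 3D volume dimensions `c(nx, ny, nz)`; `nx` must be a
#'   multiple of `length(region_specs)`.
#' @param seed RNG seed.
#' @return List: `dwi` (4D array), `protocol`, `tensors` (list of true D),
#'   `region` (3D integer array of region labels).
#' @export
make_dwi_volume <- function(region_specs, dims = c(4L, 4L, 2L), seed = 1L) {
  nreg <- length(region_specs)
  stopifnot(dims[1] %% nreg == 0L)
  protocol <- region_specs[[1]]$protocol
  nvol <- length(protocol$bvals)
  dwi <- array(NA_real_, c(dims, nvol))
  region <- array(0L, dims)
  tensors <- vector("list", nreg)
  vox <- 0L
  for (r in seq_len(nreg)) {
    xs <- ((r - 1) * dims[1] / nreg + 1):(r * dims[1] / nreg)
    for (i in xs) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
      vox <- vox + 1L
      sp <- region_specs[[r]]
      sp$seed <- seed + vox
      sim <- make_dwi(sp)
      dwi[i, j, k, ] <- sim$signals
      region[i, j, k] <- r
      tensors[[r]] <- sim$tensor
    }
  }
  list(dwi = dwi, protocol = protocol, tensors = tensors, region = region)
}
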