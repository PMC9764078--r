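#' Specification of a synthetic cross-modal ROI table
#'
#' Generates pooled (animal, region) rows with multivariate-normal
#' predictor metrics and a response following the pooled linear model
#' \eqn{y = c + b^T x + e} with i.i.d. normal errors.  The coefficient
#' vector is rescaled so the population \eqn{R^2} -- the variance of the
#' linear predictor over the total variance -- equals `target_r2` exactly
#' (a target of 0 therefore zeroes the effective coefficients).
#'
#' @param n_animals,n_regions table layout (default 5 x 5 = 25 rows).
#' @param predictors predictor metric names.
#' @param dependent response metric name.
#' @param b direction of the true coefficient vector (rescaled to hit
#'   `target_r2`).
#' @param intercept true intercept c.
#' @param sigma_x predictor covariance matrix (positive semidefinite).
#' @param target_r2 population R-squared in [0, 1).
#' @param noise_sd error standard deviation (fixed; coefficients scale).
#' @param seed RNG seed.
#' @return List of class `table_sim_spec` with the derived effective
#'   coefficients in `$b_effective`.
#' @export
table_sim_spec <- function(n_animals = 5L, n_regions = 5L,
                           predictors = c("AI", "CD"),
                           dependent = "FA",
                           b = rep(1, length(predictors)),
                           intercept = 0,
                           sigma_x = diag(length(predictors)),
                           target_r2 = 0.5,
                           noise_sd = 1,
                           seed = 1L) {
  stopifnot(n_animals >= 1L, n_regions >= 1L,
            length(b) == length(predictors),
            all(dim(sigma_x) == length(predictors)), noise_sd > 0)
  if (target_r2 < 0 || target_r2 >= 1)
    stop("target_r2 must be in [0, 1)")
  ev <- eigen(sigma_x, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10))
    stop("sigma_x must be positive semidefinite")
  vb <- as.numeric(t(b) %*% sigma_x %*% b)
  scale_b <- if (target_r2 == 0 || vb == 0) 0
  else sqrt(target_r2 / (1 - target_r2)) * noise_sd / sqrt(vb)
  out <- as.list(environment())
  out$b_effective <- b * scale_b
  structure(out, class = "table_sim_spec")
}

#' Generate a cross-modal ROI table with known population R-squared
#'
#' @param spec a [table_sim_spec()].
#' @return An `roi_table` data frame (columns `animal`, `group`, `region`,
#'   predictors, dependent) with attribute `truth` (`b`, `intercept`,
#'   `target_r2`, `noise_sd`).
#' @export
make_crossmodal_table <- function(spec) {
  stopifnot(inherits(spec, "table_sim_spec"))
  n <- spec$n_animals * spec$n_regions
  p <- length(spec$predictors)
  regions <- if (spec$n_regions == 5L) roi_labels()
  else paste0("region", seq_len(spec$n_regions))
  dat <- withr::with_seed(spec$seed, {
    X <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = spec$sigma_x)
    e <- stats::rnorm(n, 0, spec$noise_sd)
    y <- spec$intercept + as.numeric(X %*% spec$b_effective) + e
    list(X = X, y = y)
  })
  wide <- data.frame(
    animal = rep(paste0("animal", seq_len(spec$n_animals)),
                 each = spec$n_regions),
    group = rep(c("sham", "mTBI")[1 + (seq_len(spec$n_animals) %% 2)],
                each = spec$n_regions),
    region = rep(regions, times = spec$n_animals),
    stringsAsFactors = FALSE)
  colnames(dat$X) <- spec$predictors
  wide <- cbind(wide, as.data.frame(dat$X))
  wide[[spec$dependent]] <- dat$y
  attr(wide, "truth") <- list(b = spec$b_effective,
                              intercept = spec$intercept,
                              target_r2 = spec$target_r2,
                              noise_sd = spec$noise_sd)
  class(wide) <- c("roi_table", "data.frame")
  wide
}
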