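#' Pivot metric records to a wide per-(animal, region) table
#'
#' One row per (animal, region) pair, one column per metric.  Metrics
#' present for no animal are dropped with a warning; conflicting duplicate
#' records are an error; remaining missing cells are reported in the
#' `missingness` attribute.
#'
#' @param records a [metric_table()] (long format).
#' @return Data frame of class `roi_table` with columns `animal`, `group`,
#'   `region` followed by the metric columns.
#' @export
assemble_table <- function(records) {
  stopifnot(inherits(records, "metric_table") || is.data.frame(records))
  key <- paste(records$animal, records$region, records$metric, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("conflicting duplicate record for ", gsub("\r", "/", d))
  }
  metrics <- unique(records$metric)
  all_na <- vapply(metrics, function(m)
    all(is.na(records$value[records$metric == m])), logical(1))
  if (any(all_na)) {
    warning("dropping metric(s) with no values: ",
            paste(metrics[all_na], collapse = ", "))
    metrics <- metrics[!all_na]
  }
  cells <- unique(records[, c("animal", "group", "region")])
  cells <- cells[order(cells$animal, cells$region), , drop = FALSE]
  wide <- cells
  for (m in metrics) {
    sub <- records[records$metric == m, ]
    idx <- match(paste(cells$animal, cells$region),
                 paste(sub$animal, sub$region))
    wide[[m]] <- sub$value[idx]
  }
  rownames(wide) <- NULL
  miss <- which(is.na(as.matrix(wide[metrics])), arr.ind = TRUE)
  attr(wide, "missingness") <-
    if (nrow(miss)) data.frame(animal = wide$animal[miss[, 1]],
                               region = wide$region[miss[, 1]],
                               metric = metrics[miss[, 2]])
    else NULL
  class(wide) <- c("roi_table", "data.frame")
  wide
}

#' Screen predictors for structural collinearity
#'
#' Detects exact or near-exact linear dependences among (standardized)
#' predictor columns via the singular value decomposition: while the
#' smallest singular value is below `tol` times the largest, one column of
#' the dependent group (the columns loading on the offending singular
#' vector) is removed and the screen repeats.
#'
#' Which member of a dependent group to drop is a pure convention; the
#' `prefer_drop` list is consulted first (its default, `c("RD", "CL")`,
#' reproduces the published exclusions for tensor-derived predictor sets,
#' where MD = (AD + 2 RD)/3 and CL + CP + CS = 1 make RD and CL
#' redundant), falling back to the last-listed group member.
#'
#' @param X numeric matrix or data frame of predictor columns (named).
#' @param tol relative singular-value threshold (default 1e-8).
#' @param prefer_drop character vector of column names to drop
#'   preferentially when they belong to a dependent group.
#' @return List: `retained` (column names), `excluded` (character), and
#'   `dependences` (one entry per exclusion: the group and the
#'   approximate linear relation found).
#' @export
collinearity_screen <- function(X, tol = 1e-8,
                                prefer_drop = c("RD", "CL")) {
  X <- as.matrix(as.data.frame(X))
  if (ncol(X) < 2L) stop("need at least 2 predictor columns")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) stop("all predictor columns are constant")
  active <- colnames(X)[sds > 0]
  excluded <- character(0)
  dependences <- list()
  repeat {
    Z <- scale(X[, active, drop = FALSE])
    sv <- svd(Z)
    if (length(active) < 2L || sv$d[length(sv$d)] > tol * sv$d[1]) break
    v <- sv$v[, length(sv$d)]
    group <- active[abs(v) > 1e-6 * max(abs(v))]
    pref <- intersect(prefer_drop, group)
    drop_col <- if (length(pref)) pref[1] else group[length(group)]
    rel <- stats::setNames(round(v[match(group, active)], 6), group)
    dependences[[drop_col]] <- list(group = group, relation = rel)
    excluded <- c(excluded, drop_col)
    active <- setdiff(active, drop_col)
  }
  list(retained = active, excluded = excluded, dependences = dependences)
}

#' Adjusted squared multiple correlation
#'
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - k - 1)}.
#'
#' @param r2 squared multiple correlation.
#' @param n sample size.
#' @param k number of predictors.
#' @return Adjusted R-squared.
#' @examples
#' adjusted_r2(0.566, 25, 5)  # 0.452
#' @export
adjusted_r2 <- function(r2, n, k) {
  stopifnot(n > k + 1)
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' F statistic of the overall regression
#'
#' \eqn{F = (R^2/k) / ((1 - R^2)/(n - k - 1))}.
#'
#' @inheritParams adjusted_r2
#' @return The overall F statistic on (k, n - k - 1) degrees of freedom.
#' @export
r2_to_F <- function(r2, n, k) {
  stopifnot(n > k + 1, r2 <= 1)
  if (r2 >= 1) return(Inf)   # perfect fit
  (r2 / k) / ((1 - r2) / (n - k - 1))
}

#' Confidence interval for the squared multiple correlation
#'
#' Inverts the noncentral-F distribution of the observed overall F over
#' the noncentrality parameter (fixed-regressor convention: noncentrality
#' \eqn{\Lambda} maps to \eqn{\rho^2 = \Lambda/(\Lambda + n)}).  The lower
#' bound is floored at 0; a degenerate upper bound (observed F below the
#' lower inversion point of the central distribution) collapses to 0.
#'
#' @param r2 observed R-squared, in [0, 1).
#' @param n sample size (> k + 1).
#' @param k number of predictors.
#' @param level confidence level in (0, 1).
#' @return Numeric `c(lower, upper)` on the R-squared scale.
#' @export
r2_confidence_interval <- function(r2, n, k, level = 0.95) {
  stopifnot(r2 >= 0, r2 <= 1, n > k + 1)
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  if (r2 >= 1) return(c(lower = 1, upper = 1))   # degenerate perfect fit
  alpha <- 1 - level
  df1 <- k; df2 <- n - k - 1
  Fobs <- r2_to_F(r2, n, k)
  ncp_to_r2 <- function(ncp) ncp / (ncp + n)
  solve_ncp <- function(target_p) {
    # find ncp with P(F <= Fobs | ncp) = target_p; P is decreasing in ncp
    f <- function(ncp) stats::pf(Fobs, df1, df2, ncp = ncp) - target_p
    if (f(0) <= 0) return(0)
    hi <- 1
    while (f(hi) > 0 && hi < 1e8) hi <- hi * 2
    if (f(hi) > 0) return(hi)
    stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  }
  lo <- ncp_to_r2(solve_ncp(1 - alpha / 2))
  hi <- ncp_to_r2(solve_ncp(alpha / 2))
  c(lower = max(0, lo), upper = max(0, hi, lo))
}

#' Fit the pooled per-region multiple linear regression
#'
#' Ordinary least squares for \eqn{y_{kj} = b^T x_{kj} + c + e_{kj}} over
#' the pooled (animal k, region j) rows, with i.i.d. normal errors; rows
#' with missing values are deleted listwise.  Reports \eqn{R^2}, adjusted
#' \eqn{R^2}, the overall F with its p-value, per-coefficient t statistics
#' and two-sided p-values, and the confidence interval for \eqn{R^2} from
#' [r2_confidence_interval()].
#'
#' @param table an [assemble_table()] result (or any data frame).
#' @param dependent name of the response column.
#' @param predictors character vector of predictor columns (screen them
#'   first with [collinearity_screen()]).
#' @param ci_level confidence level for the R-squared interval.
#' @return Object of class `regression_result`.
#' @export
fit_mlr <- function(table, dependent, predictors, ci_level = 0.95) {
  stopifnot(dependent %in% names(table), all(predictors %in% names(table)))
  dat <- table[, c(dependent, predictors), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat); k <- length(predictors)
  if (n <= k + 1)
    stop("too few complete rows (n = ", n, ") for ", k, " predictors")
  fm <- stats::as.formula(paste0("`", dependent, "` ~ ",
                                 paste0("`", predictors, "`",
                                        collapse = " + ")))
  fit <- stats::lm(fm, data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("singular design: screen predictors for collinearity first")
  sm <- summary(fit)
  r2 <- sm$r.squared
  Fst <- r2_to_F(r2, n, k)
  coefs <- sm$coefficients
  rownames(coefs) <- gsub("`", "", rownames(coefs))
  structure(list(dependent = dependent, predictors = predictors,
                 coefficients = stats::setNames(
                   coefs[predictors, "Estimate"], predictors),
                 intercept = coefs["(Intercept)", "Estimate"],
                 r2 = r2, adj_r2 = adjusted_r2(r2, n, k),
                 F = Fst,
                 p_F = stats::pf(Fst, k, n - k - 1, lower.tail = FALSE),
                 t = stats::setNames(coefs[predictors, "t value"],
                                     predictors),
                 p_t = stats::setNames(coefs[predictors, "Pr(>|t|)"],
                                       predictors),
                 r2_ci = r2_confidence_interval(r2, n, k, ci_level),
                 n = n, k = k, lm = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, digits = 3, ...) {
  cat(sprintf("%s ~ %s  (n = %d, k = %d)\n", x$dependent,
              paste(x$predictors, collapse = " + "), x$n, x$k))
  cat(sprintf("  R2 = %.*f (%.*f-%.*f), R2adj = %.*f, F = %.*f, p = %.4g\n",
              digits, x$r2, digits, x$r2_ci[1], digits, x$r2_ci[2],
              digits, x$adj_r2, digits, x$F, x$p_F))
  invisible(x)
}

#' Explain one modality's metrics with another's
#'
#' Fits one pooled regression per metric of the target modality, with the
#' (collinearity-screened) metrics of the predictor modality as
#' regressors, mirroring the published cross-modality comparison tables.
#'
#' @param table an [assemble_table()] result.
#' @param target_modality,predictor_modality modality names (`"dti"`,
#'   `"histology"`, `"diffraction"`).
#' @param modalities named map metric -> modality (default
#'   [metric_modalities()]), restricted to columns present in `table`.
#' @param prefer_drop passed to [collinearity_screen()].
#' @return Object of class `modality_comparison`: list of
#'   `regression_result`s plus `screen`; `as.data.frame()` renders the
#'   publication-style summary (one row per dependent: R2, CI, adjusted
#'   R2, F and its p, then per-predictor t and p).
#' @export
explain_modality <- function(table, target_modality, predictor_modality,
                             modalities = metric_modalities(),
                             prefer_drop = c("RD", "CL")) {
  present <- intersect(names(modalities), names(table))
  targets <- present[modalities[present] == target_modality]
  preds <- present[modalities[present] == predictor_modality]
  if (!length(targets)) stop("no metrics of modality ", target_modality)
  if (!length(preds)) stop("no metrics of modality ", predictor_modality)
  screen <- if (length(preds) >= 2L)
    collinearity_screen(table[, preds, drop = FALSE],
                        prefer_drop = prefer_drop)
  else list(retained = preds, excluded = character(0), dependences = list())
  fits <- lapply(targets, function(dep)
    fit_mlr(table, dep, screen$retained))
  names(fits) <- targets
  structure(list(results = fits, screen = screen,
                 target_modality = target_modality,
                 predictor_modality = predictor_modality),
            class = "modality_comparison")
}

#' @export
as.data.frame.modality_comparison <- function(x, ...) {
  rows <- lapply(x$results, function(r) {
    base <- data.frame(dependent = r$dependent, R2 = r$r2,
                       ci_lower = r$r2_ci[1], ci_upper = r$r2_ci[2],
                       adj_R2 = r$adj_r2, F = r$F, p = r$p_F)
    for (p in r$predictors) {
      base[[paste0("t_", p)]] <- r$t[[p]]
      base[[paste0("p_", p)]] <- r$p_t[[p]]
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.modality_comparison <- function(x, ...) {
  cat(sprintf("Explaining %s metrics with %s metrics", x$target_modality,
              x$predictor_modality))
  if (length(x$screen$excluded))
    cat(" (excluded for collinearity: ",
        paste(x$screen$excluded, collapse = ", "), ")", sep = "")
  cat("\n")
  print(as.data.frame(x), digits = 3)
  invisible(x)
}
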