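test_that("assemble_table pivots records and reports missingness", {
  vals <- round(runif(25), 4)
  rec <- metric_table(rep(paste0("a", 1:5), each = 5),
                      rep(c("sham", "mTBI"), c(10, 15)),
                      rep(roi_labels(), 5), "dti", "FA", vals)
  wide <- assemble_table(rec)
  expect_equal(nrow(wide), 25)
  expect_true("FA" %in% names(wide))
  expect_null(attr(wide, "missingness"))
  # one missing cell: still 25 rows, flagged
  vals2 <- vals; vals2[3] <- NA
  rec2 <- metric_table(rep(paste0("a", 1:5), each = 5), "sham",
                       rep(roi_labels(), 5), "dti", "FA", vals2)
  wide2 <- assemble_table(rec2)
  expect_equal(nrow(wide2), 25)
  expect_equal(nrow(attr(wide2, "missingness")), 1)
  # a metric with no values at all is dropped with a warning
  rec3 <- rbind(as.data.frame(rec2),
                data.frame(animal = "a1", group = "sham",
                           region = "cingulum", modality = "dti",
                           metric = "MD", value = NA))
  expect_warning(w3 <- assemble_table(rec3), "no values")
  expect_false("MD" %in% names(w3))
  # conflicting duplicates are an error
  rec4 <- rbind(as.data.frame(rec)[c(1, 1), ])
  expect_error(assemble_table(rec4), "duplicate")
})

test_that("structural collinearity of tensor metrics excludes RD and CL", {
  set.seed(2)
  for (rep in 1:3) {
    tab <- random_dti_metric_table()
    sc <- collinearity_screen(tab[, c("FA", "AD", "RD", "MD",
                                      "CL", "CP", "CS")])
    expect_setequal(sc$excluded, c("RD", "CL"))
    expect_setequal(sc$retained, c("FA", "AD", "MD", "CP", "CS"))
  }
  # each exclusion reports the dependence group it came from
  tab <- random_dti_metric_table()
  sc <- collinearity_screen(tab[, c("FA", "AD", "RD", "MD",
                                    "CL", "CP", "CS")])
  expect_true(all(lengths(lapply(sc$dependences, `[[`, "group")) >= 2))
})

test_that("independent predictors pass the screen untouched", {
  set.seed(3)
  X <- matrix(rnorm(25 * 5), 25,
              dimnames = list(NULL, paste0("v", 1:5)))
  sc <- collinearity_screen(X)
  expect_length(sc$excluded, 0)
  # a duplicated column loses exactly one of the pair
  sc2 <- collinearity_screen(cbind(X, v1b = X[, 1]))
  expect_length(sc2$excluded, 1)
  expect_true(sc2$excluded %in% c("v1", "v1b"))
  expect_error(collinearity_screen(matrix(1, 10, 3)), "constant")
})

test_that("regression summary identities hold to machine precision", {
  set.seed(5)
  tab <- make_crossmodal_table(table_sim_spec(
    predictors = c("FA", "AD", "MD", "CP", "CS"), dependent = "AI",
    b = c(1, -0.4, 0.3, 0.2, -0.1), target_r2 = 0.5, seed = 5))
  fit <- fit_mlr(tab, "AI", c("FA", "AD", "MD", "CP", "CS"))
  expect_equal(fit$adj_r2,
               1 - (1 - fit$r2) * (fit$n - 1) / (fit$n - fit$k - 1))
  expect_equal(fit$F, (fit$r2 / fit$k) /
                 ((1 - fit$r2) / (fit$n - fit$k - 1)))
  expect_equal(unname(fit$p_F),
               unname(pf(fit$F, fit$k, fit$n - fit$k - 1,
                         lower.tail = FALSE)))
  # exactly linear response: R2 = 1, zero residuals
  tab$lin <- 2 + 3 * tab$FA - tab$AD
  fl <- suppressWarnings(fit_mlr(tab, "lin", c("FA", "AD")))  # exact fit
  expect_equal(fl$r2, 1)
  expect_lt(max(abs(residuals(fl$lm))), 1e-10)
  # four-point simple regression matches the closed form b = Sxy/Sxx
  d4 <- data.frame(x = c(0, 1, 2, 4), y = c(1, 2, 2.5, 5))
  f4 <- fit_mlr(d4, "y", "x")
  Sxx <- sum((d4$x - mean(d4$x))^2)
  Sxy <- sum((d4$x - mean(d4$x)) * (d4$y - mean(d4$y)))
  expect_equal(unname(f4$coefficients["x"]), Sxy / Sxx)
  expect_equal(unname(f4$intercept), mean(d4$y) - Sxy / Sxx * mean(d4$x))
})

test_that("R2 and t statistics are invariant to predictor rescaling/order", {
  set.seed(6)
  tab <- make_crossmodal_table(table_sim_spec(
    predictors = c("AI", "CD"), dependent = "FA", b = c(1, 0.5),
    target_r2 = 0.4, seed = 6))
  f1 <- fit_mlr(tab, "FA", c("AI", "CD"))
  tab2 <- tab; tab2$AI <- 100 * tab2$AI + 7
  f2 <- fit_mlr(tab2, "FA", c("AI", "CD"))
  expect_equal(f1$r2, f2$r2)
  expect_equal(abs(unname(f1$t)), abs(unname(f2$t)), tolerance = 1e-10)
  f3 <- fit_mlr(tab, "FA", c("CD", "AI"))
  expect_equal(sort(unname(f1$t)), sort(unname(f3$t)), tolerance = 1e-10)
})

test_that("adjusted R2 recomputes the published table cells", {
  # DTI -> histology / diffraction rows (n = 25, k = 5)
  expect_equal(round(adjusted_r2(0.566, 25, 5), 3), 0.452)
  expect_equal(round(adjusted_r2(0.267, 25, 5), 3), 0.074)
  expect_equal(round(adjusted_r2(0.073, 25, 5), 3), -0.171)
  # histology -> diffraction rows (n = 25, k = 2)
  expect_equal(round(adjusted_r2(0.274, 25, 2), 3), 0.208)
  expect_equal(round(adjusted_r2(0.233, 25, 2), 3), 0.163)
  # the F identity reproduces the printed overall F to R2 rounding
  expect_equal(r2_to_F(0.274, 25, 2), 4.150, tolerance = 2e-3)
  expect_equal(r2_to_F(0.566, 25, 5), 4.965, tolerance = 3e-3)
})

test_that("R2 confidence intervals invert the noncentral F", {
  # small R2: lower bound floored at zero (published lambda_L row)
  ci <- r2_confidence_interval(0.042, 25, 5)
  expect_equal(unname(ci["lower"]), 0)
  # the strongly identified published row brackets reproduce
  ci2 <- r2_confidence_interval(0.566, 25, 5)
  expect_lt(abs(ci2[["lower"]] - 0.100), 0.005)
  expect_lt(abs(ci2[["upper"]] - 0.670), 0.005)
  # interval shrinks toward 1 as n grows with R2 near 1
  ci3 <- r2_confidence_interval(0.95, 1000, 5)
  expect_gt(ci3["lower"], 0.9)
  expect_lt(ci3["upper"] - ci3["lower"], 0.05)
  expect_error(r2_confidence_interval(0.5, 25, 5, level = 2), "level")
})

test_that("the interval attains nominal coverage at rho2 = 0.3", {
  set.seed(11)
  n <- 25; k <- 5; rho2 <- 0.3
  X <- matrix(rnorm(n * k), n)
  S <- crossprod(scale(X, scale = FALSE)) / n  # fixed-scores covariance
  b <- rep(1, k)
  b <- b * sqrt(rho2 / (1 - rho2) / drop(t(b) %*% S %*% b))
  hits <- replicate(2000, {
    y <- drop(X %*% b) + rnorm(n)
    r2 <- summary(lm(y ~ X))$r.squared
    ci <- r2_confidence_interval(r2, n, k)
    ci[1] <= rho2 && rho2 <= ci[2]
  })
  expect_lt(abs(mean(hits) - 0.95), 0.02)
})

test_that("explain_modality mirrors the published table layout", {
  set.seed(99)  # decoupled from the generator seed below
  # build a 25-row table with all three modalities
  tab <- make_crossmodal_table(table_sim_spec(
    predictors = c("FA", "AD", "MD", "CP", "CS"), dependent = "AI",
    b = c(1, 0.5, -0.5, 0.2, 0.1), target_r2 = 0.6, seed = 8))
  tab$CD <- rnorm(25)
  for (m in c("C_L", "lambda_L", "C_H", "lambda_H")) tab[[m]] <- rnorm(25)
  # histology -> diffraction: one regression per diffraction metric
  res <- explain_modality(tab, "diffraction", "histology")
  expect_length(res$results, 4)
  expect_setequal(names(res$results),
                  c("C_L", "lambda_L", "C_H", "lambda_H"))
  df <- as.data.frame(res)
  expect_true(all(c("R2", "ci_lower", "ci_upper", "adj_R2", "F", "p",
                    "t_AI", "p_AI", "t_CD", "p_CD") %in% names(df)))
  # known linear model is recovered within sampling error of the target
  res2 <- explain_modality(tab, "histology", "dti")
  fitAI <- res2$results$AI
  expect_gt(fitAI$r2, 0.3); expect_lt(fitAI$r2, 0.9)
  # null predictors: E[R2] ~ k/(n-1)
  set.seed(9)
  r2s <- replicate(300, {
    tabn <- data.frame(matrix(rnorm(25 * 6), 25))
    names(tabn) <- c("y", paste0("x", 1:5))
    fit_mlr(tabn, "y", paste0("x", 1:5))$r2
  })
  expect_lt(abs(mean(r2s) - 5 / 24), 0.03)
})
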