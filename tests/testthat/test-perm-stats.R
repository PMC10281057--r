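test_that("spearman_rho handles monotone, reversed and tied data", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearman_rho(1:4, c(40, 30, 20, 10)), -1)
  # mid-rank Pearson on x = (1,1,2,3), y = (2,1,3,4), worked by hand:
  # rx = (1.5, 1.5, 3, 4), ry = (2, 1, 3, 4) -> rho = 4.5/sqrt(4.5*5)
  expect_equal(spearman_rho(c(1, 1, 2, 3), c(2, 1, 3, 4)),
               4.5 / sqrt(4.5 * 5), tolerance = 1e-12)
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("exhaustive permutation p equals independent enumeration", {
  # perfect concordance at n = 4, one-sided: exactly 1 of 24 permutations
  r <- perm_spearman(1:4, c(10, 20, 30, 40), alternative = "greater")
  expect_true(r$exhaustive)
  expect_identical(r$p_perm, 1 / 24)

  set.seed(11)
  for (alt in c("greater", "less", "two_sided")) {
    x <- rnorm(6); y <- rnorm(6)
    r2 <- perm_spearman(x, y, alternative = alt)
    expect_true(r2$exhaustive)
    expect_equal(r2$p_perm, brute_perm_spearman(x, y, alt), tolerance = 1e-12)
  }
})

test_that("sampled permutation p agrees with the exhaustive value at n = 7", {
  set.seed(5)
  x <- rnorm(7); y <- x + rnorm(7)
  exact <- perm_spearman(x, y, alternative = "greater")$p_perm
  sampled <- perm_spearman(x, y, n_perm = 99999, seed = 9,
                           alternative = "greater",
                           exhaustive = FALSE)$p_perm
  mc_se <- sqrt(exact * (1 - exact) / 99999)
  expect_lt(abs(sampled - exact), 2.5 * mc_se + 1e-5)
})

test_that("permutation p-values respect the add-one floor and symmetry", {
  set.seed(3)
  x <- rnorm(16); y <- x + rnorm(16, sd = 0.1)
  r <- perm_spearman(x, y, n_perm = 999, seed = 1, alternative = "greater")
  expect_gte(r$p_perm, 1 / 1000)
  expect_gt(r$p_perm, 0)

  r2 <- perm_spearman(x, y, n_perm = 999, seed = 4, alternative = "two_sided")
  r3 <- perm_spearman(x, -y, n_perm = 999, seed = 4, alternative = "two_sided")
  expect_equal(r2$p_perm, r3$p_perm, tolerance = 1e-12)
})

test_that("correlation_matrix produces all pairwise entries", {
  co <- simulate_cohort(cohort_params(seed = 8))
  vars <- rownames(pilot_target_rho())
  cm <- correlation_matrix(co, vars, n_perm = 999, seed = 2)
  expect_equal(nrow(cm), choose(11, 2))
  expect_true(all(cm$rho >= -1 & cm$rho <= 1))
  expect_true(all(cm$p_perm > 0 & cm$p_perm <= 1))
  # pairwise-complete deletion: grip pairs lose the missing participant
  expect_true(all(cm$n[cm$var1 == "grip_kg" | cm$var2 == "grip_kg"] == 15))
  expect_true(all(cm$n[cm$var1 != "grip_kg" & cm$var2 != "grip_kg"] == 16))
  expect_error(correlation_matrix(co, c("age", "nope")), "unknown")
})

test_that("permutation regression recovers structure and matches lm", {
  set.seed(13)
  n <- 16
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- 2 * X$x1 - 1 * X$x2 + rnorm(n, sd = 0.5)
  fit <- fit_perm_regression(y, X, n_perm = 999, seed = 1)

  # parametric pieces match the standard linear model on z-scored data
  zs <- function(v) (v - mean(v)) / sd(v)
  ref <- lm(zs(y) ~ zs(X$x1) + zs(X$x2))
  expect_equal(unname(fit$beta_std), unname(coef(ref)[-1]), tolerance = 1e-10)
  expect_equal(unname(fit$t_stats),
               unname(summary(ref)$coefficients[-1, "t value"]),
               tolerance = 1e-10)
  expect_equal(fit$r2, summary(ref)$r.squared, tolerance = 1e-10)
  expect_equal(fit$adj_r2, summary(ref)$adj.r.squared, tolerance = 1e-10)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-8)
  expect_lte(fit$adj_r2, fit$r2)
  expect_true(all(fit$vif >= 1))

  # an exact linear response drives every p to the resolution floor
  y2 <- 1.5 * X$x1 + 0.5 * X$x2
  fit2 <- fit_perm_regression(y2, X, n_perm = 999, seed = 2)
  expect_equal(fit2$r2, 1, tolerance = 1e-10)
  expect_equal(unname(fit2$p_perm), rep(1 / 1000, 2))
  expect_equal(fit2$p_perm_model, 1 / 1000)

  # input scaling leaves the standardized fit untouched
  Xs <- data.frame(x1 = 100 * X$x1, x2 = X$x2 / 7)
  fit3 <- fit_perm_regression(y, Xs, n_perm = 999, seed = 1)
  expect_equal(fit3$beta_std, fit$beta_std, tolerance = 1e-10)
  expect_equal(fit3$t_stats, fit$t_stats, tolerance = 1e-10)
  expect_equal(fit3$aic, fit$aic, tolerance = 1e-10)
  expect_equal(unname(fit3$vif), unname(fit$vif), tolerance = 1e-10)

  # binary predictors are coded then standardized; collinearity is named
  Xb <- data.frame(x1 = X$x1, grp = rep(c("a", "b"), 8))
  expect_s3_class(fit_perm_regression(y, Xb, n_perm = 999, seed = 3),
                  "perm_regression_result")
  Xc <- data.frame(x1 = X$x1, x1b = X$x1)
  expect_error(fit_perm_regression(y, Xc, n_perm = 999, seed = 4),
               "multicollinearity.*x1b")
})

test_that("freedman-lane scheme agrees with manly on a clear signal", {
  set.seed(17)
  n <- 20
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- X$x1 + rnorm(n, sd = 0.8)
  fm <- fit_perm_regression(y, X, n_perm = 1999, seed = 5, scheme = "manly")
  fl <- fit_perm_regression(y, X, n_perm = 1999, seed = 5,
                            scheme = "freedman_lane")
  expect_equal(unname(fm$beta_std), unname(fl$beta_std))
  expect_lt(abs(fm$p_perm[["x1"]] - fl$p_perm[["x1"]]), 0.02)
})

test_that("standardized-beta recovery on generator cohorts", {
  # cohorts built with known elevation/grip signal on MMSE: the mean
  # recovered standardized coefficients stay near truth
  set.seed(19)
  n <- 16
  reps <- 200
  betas <- replicate(reps, {
    elev <- rnorm(n); grip <- rnorm(n)
    y <- 0.43 * elev + 0.45 * grip + rnorm(n, sd = sqrt(1 - 0.43^2 - 0.45^2))
    fit <- fit_perm_regression(y, data.frame(elev = elev, grip = grip),
                               n_perm = 999, seed = 1)
    fit$beta_std
  })
  expect_lt(abs(mean(betas["elev", ]) - 0.43), 0.1)
  expect_lt(abs(mean(betas["grip", ]) - 0.45), 0.1)
})

test_that("vif equals its definition and an independent implementation", {
  set.seed(23)
  X <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  X[, 2] <- X[, 1] * 0.8 + rnorm(40, sd = 0.5)
  v <- vif(X)
  for (j in 1:5) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
  expect_true(all(v >= 1))
  # cross-check against the standard implementation
  if (requireNamespace("car", quietly = TRUE)) {
    df <- as.data.frame(X); df$y <- rnorm(40)
    expect_equal(unname(v), unname(car::vif(lm(y ~ ., data = df))),
                 tolerance = 1e-8)
  }
  # orthogonal design and exact duplication
  Xo <- cbind(a = c(1, 1, -1, -1, 1, -1, 1, -1), b = c(1, -1, 1, -1, -1, 1, 1, -1))
  expect_equal(unname(vif(Xo)), c(1, 1), tolerance = 1e-10)
  Xd <- cbind(x1 = rnorm(10), x2 = 0)
  Xd[, 2] <- Xd[, 1]
  expect_warning(expect_warning(vd <- vif(Xd), "collinearity"), "collinearity")
  expect_true(all(is.infinite(vd)))
})

test_that("aic ladder ranks candidates by the stated Gaussian AIC", {
  set.seed(29)
  n <- 16
  dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  dat$y <- dat$x1 + 0.5 * dat$x2 + rnorm(n, sd = 0.4)
  cands <- list("x1", "x2", c("x1", "x2"), c("x1", "x2", "x3"))
  lad <- aic_ladder(dat, "y", cands)
  expect_true(all(diff(lad$aic) >= 0))
  expect_true(lad$best[1] && !any(lad$best[-1]))
  # absolute values agree with stats::AIC under the same convention
  for (i in seq_len(nrow(lad))) {
    terms <- strsplit(lad$model[i], " \\+ ")[[1]]
    ref <- AIC(lm(stats::reformulate(terms, "y"), data = dat))
    expect_equal(lad$aic[i], ref, tolerance = 1e-8)
  }
  # equal complexity: lower RSS wins; extra noise predictor is penalized
  expect_lt(lad$aic[lad$model == "x1 + x2"], lad$aic[lad$model == "x1 + x2 + x3"])
  expect_error(aic_ladder(dat, "y", list("zz")), "unknown")
})

test_that("null permutation p-values are uniform on the achievable grid", {
  set.seed(31)
  reps <- 400
  pvals <- replicate(reps, {
    x <- rnorm(12); y <- rnorm(12)
    perm_spearman(x, y, n_perm = 999, seed = sample.int(1e6, 1),
                  alternative = "greater")$p_perm
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
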