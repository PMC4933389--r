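test_that("the collinearity screen flags exactly the offending pairs", {
  set.seed(60)
  x1 <- rnorm(10)
  x2 <- x1 + rnorm(10, sd = 0.02)     # |r| ~ 0.999
  x3 <- rnorm(10)
  expect_warning(r <- check_collinearity(cbind(x1, x2, x3)), "collinear")
  expect_equal(nrow(r$flagged), 1L)
  expect_equal(sort(c(r$flagged$var1, r$flagged$var2)), c("x1", "x2"))

  o <- check_collinearity(cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1)))
  expect_equal(o$correlations["a", "b"], 0)

  expect_warning(check_collinearity(cbind(c = rep(1, 5), d = rnorm(5))),
                 "degenerate")
})

test_that("permutational regression reproduces closed-form OLS", {
  set.seed(61)
  X <- matrix(rnorm(7 * 3), 7, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(7, sd = 0.3)
  fit <- permutational_regression(y, X, n_perm = 199, seed = 62)
  ref <- summary(lm(y ~ X))
  expect_equal(fit$r2, ref$r.squared, tolerance = 1e-12)
  expect_equal(unname(fit$pseudo_f), unname(ref$fstatistic[1]),
               tolerance = 1e-9)

  # exact linear response: R2 = 1 and the minimal achievable p
  ylin <- drop(X %*% c(2, 1, -1))
  fl <- permutational_regression(ylin, X, n_perm = 199, seed = 63)
  expect_equal(fl$r2, 1)
  expect_equal(fl$p_perm, 1 / 200)

  expect_error(permutational_regression(rnorm(4), X[1:4, ]), "insufficient")
  expect_error(permutational_regression(rnorm(7),
                                        cbind(X, d = X[, "a"])), "rank")
})

test_that("the permutation p is invariant to affine response transforms", {
  set.seed(64)
  X <- matrix(rnorm(8 * 2), 8, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(8)
  p1 <- permutational_regression(y, X, n_perm = 299, seed = 65)$p_perm
  p2 <- permutational_regression(5 - 3 * y, X, n_perm = 299, seed = 65)$p_perm
  expect_equal(p1, p2)
})

test_that("AIC subset search recovers the generating predictor", {
  # a predictor that generates the response exactly is selected alone
  exact_hits <- 0L
  for (s in 1:20) {
    sim <- simulate_trait_table(10, beta = c(2, 0, 0, 0, 0),
                                noise_sd = 0, seed = 100 + s)
    sel <- aic_subset_search(sim$response, sim$predictors,
                             n_perm = 0)$best$selected
    if (identical(sel, "x1")) exact_hits <- exact_hits + 1L
  }
  expect_equal(exact_hits, 20L)

  # under small noise the true predictor is always in the selected subset
  # (AIC admits a spurious companion with probability ~P(chisq_1 > 2) per
  # candidate, so exact recovery is not the calibrated property)
  contain_hits <- 0L
  for (s in 1:20) {
    sim <- simulate_trait_table(10, beta = c(2, 0, 0, 0, 0),
                                noise_sd = 0.1, seed = 200 + s)
    sel <- aic_subset_search(sim$response, sim$predictors,
                             n_perm = 0)$best$selected
    if ("x1" %in% sel) contain_hits <- contain_hits + 1L
  }
  expect_gte(contain_hits, 18L)
})

test_that("removing the AIC penalty reduces selection to max R2", {
  set.seed(66)
  sim <- simulate_trait_table(9, beta = c(1, -1, 0), noise_sd = 0.5)
  out <- aic_subset_search(sim$response, sim$predictors, n_perm = 0,
                           penalty = 0)
  expect_equal(out$table$r2[1], max(out$table$r2))
})

test_that("permutational ANOVA partitions squared differences", {
  # identical group means: pseudo-F = 0, p = 1
  a <- permutational_anova(c(1, 2, 1, 2), c("g1", "g1", "g2", "g2"),
                           n_perm = 99, seed = 67)
  expect_equal(a$pseudo_f, 0)
  expect_equal(a$p_perm, 1)

  # fully separated groups: near-minimal p at this permutation count
  b <- permutational_anova(c(1, 1, 1, 9, 9, 9, 9),
                           c("x", "x", "x", "y", "y", "y", "y"),
                           n_perm = 999, seed = 68)
  expect_lt(b$p_perm, 0.05)

  expect_error(permutational_anova(1:4, rep("only", 4)), "factor error")
})

test_that("the heteroscedasticity screen flags unequal spread, not unequal means", {
  set.seed(71)
  g <- rep(c("a", "b"), each = 12)
  # equal spread, very different means: not flagged
  y_means <- c(rnorm(12, 0, 1), rnorm(12, 50, 1))
  expect_false(check_heteroscedasticity(y_means, g, n_perm = 499,
                                        seed = 72)$heteroscedastic)
  # equal means, very different spread: flagged
  y_spread <- c(rnorm(12, 0, 0.1), rnorm(12, 0, 8))
  expect_true(check_heteroscedasticity(y_spread, g, n_perm = 499,
                                       seed = 73)$heteroscedastic)
})

test_that("noiseless synthetic traits are recovered exactly", {
  sim <- simulate_trait_table(8, beta = c(1.5, -0.7), noise_sd = 0, seed = 69)
  fit <- permutational_regression(sim$response, sim$predictors, n_perm = 99,
                                  seed = 70)
  expect_equal(fit$r2, 1)
  expect_equal(unname(fit$coefficients[-1]), c(1.5, -0.7), tolerance = 1e-10)
})
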