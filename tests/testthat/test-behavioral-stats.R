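test_that("pearson_r matches limits and the sampling envelope", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.9)
  expect_equal(pearson_r(x, x)$r, 1)
  y <- c(1, -1, 1, -1)
  z <- c(1, 1, -1, -1)
  expect_equal(pearson_r(y, z)$r, 0)
  expect_error(pearson_r(x, rep(2, 6)), "constant")
  # 20 subjects at population correlation 0.5: r inside the 95% Fisher-z
  # envelope 0.5 +/- 0.35
  set.seed(23)
  a <- rnorm(20); b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(20)
  r <- pearson_r(a, b)$r
  expect_gt(r, 0.15); expect_lt(r, 0.85)
  # p agrees with the base implementation it wraps
  pr <- pearson_r(a, b)
  expect_equal(pr$p, cor.test(a, b)$p.value)
  expect_equal(pr$se_z, 1 / sqrt(17))
})

test_that("R-squared closed form reproduces the printed regression summaries", {
  # success ~ vividness + precision
  expect_equal(round(r2_from_correlations(0.543, 0.527, 0.519), 3), 0.377)
  # precision ~ success + vividness
  expect_equal(round(r2_from_correlations(0.527, 0.519, 0.543), 3), 0.355)
  # vividness ~ success + precision
  expect_equal(round(r2_from_correlations(0.543, 0.519, 0.527), 3), 0.370)
  # orthogonal predictors reduce to the sum of squared correlations
  expect_equal(r2_from_correlations(0.3, 0.4, 0), 0.25)
  expect_error(r2_from_correlations(0.5, 0.5, 1), "collinear")
})

test_that("standardized regression from printed correlations matches the report", {
  rg <- regression_from_correlations(0.543, 0.527, 0.519, n = 20,
                                     names = c("vividness", "precision"))
  expect_equal(round(rg$beta[["vividness"]], 3), 0.369)
  expect_equal(round(rg$t[["vividness"]], 2), 1.65)
  # the published F was computed from unrounded correlations; propagating
  # the 3-dp rounding of the inputs moves F by up to ~0.015, so the check
  # is a band, not 2-dp equality (closed form gives 5.146 here)
  expect_lt(abs(rg$f - 5.14), 0.015)
  expect_equal(rg$df, c(2, 17))
  expect_equal(rg$unexplained, 1 - rg$r2)
  expect_equal(round(100 * (1 - rg$r2), 1), 62.3)
})

test_that("regression block agrees with an lm oracle on standardized data", {
  set.seed(37)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    x1 <- rnorm(n); x2 <- 0.4 * x1 + rnorm(n)
    y <- 0.5 * x1 + 0.3 * x2 + rnorm(n)
    rg <- standardized_regression(y, x1, x2)
    ora <- lm(scale(y) ~ scale(x1) + scale(x2))
    s <- summary(ora)
    expect_equal(rg$r2, s$r.squared, tolerance = 1e-12)
    expect_equal(unname(rg$beta), unname(coef(ora)[2:3]), tolerance = 1e-10)
    expect_equal(unname(rg$t), unname(s$coefficients[2:3, "t value"]),
                 tolerance = 1e-8)
    expect_equal(rg$f, unname(s$fstatistic["value"]), tolerance = 1e-8)
    # closed-form identity: regression R2 equals the correlation form
    expect_equal(rg$r2, r2_from_correlations(cor(y, x1), cor(y, x2),
                                             cor(x1, x2)),
                 tolerance = 1e-12)
  }
})

test_that("dissociation report is complete, deterministic and permutation-invariant", {
  set.seed(43)
  z <- matrix(rnorm(20 * 3), 20, 3) %*% chol(matrix(c(1, .5, .5,
                                                      .5, 1, .5,
                                                      .5, .5, 1), 3))
  sm <- data.frame(subject = 1:20, retrieval_success = plogis(z[, 1]),
                   precision = exp(2 + 0.3 * z[, 2]),
                   vividness = 50 + 15 * z[, 3])
  rep1 <- build_dissociation_report(sm)
  expect_named(rep1$correlations,
               c("success_precision", "success_vividness",
                 "precision_vividness"))
  expect_named(rep1$regressions, c("success", "precision", "vividness"))
  for (rg in rep1$regressions) {
    expect_gte(rg$r2, 0); expect_lte(rg$r2, 1); expect_gte(rg$f, 0)
    expect_equal(rg$unexplained, 1 - rg$r2)
  }
  rep2 <- build_dissociation_report(sm[sample(20), ])
  expect_equal(rep1$correlations, rep2$correlations)
  expect_equal(rep1$regressions, rep2$regressions)
  # degenerate input errors
  sm$vividness <- 50
  expect_error(build_dissociation_report(sm), "constant")
  expect_error(build_dissociation_report(sm[1:3, ]), ">= 4")
})
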