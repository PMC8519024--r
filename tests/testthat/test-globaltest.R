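test_that("the ratio statistic has its closed-form values and invariances", {
  # residual orthogonal to every column -> numerator vanishes
  X <- cbind(c(1, 0, 0), c(0, 1, 0))
  y_orth <- c(0, 0, 2)
  expect_equal(gt_statistic_linear(X, y_orth, c(0, 0)), 0)
  # identity design: numerator equals denominator
  expect_equal(gt_statistic_linear(diag(4), rnorm(4)), 1)
  # hand arithmetic: X = (1, 0)', y = (2, 2)', beta0 = 0 -> 4/8
  expect_equal(gt_statistic_linear(matrix(c(1, 0)), c(2, 2), 0), 0.5)
  # invariant to rescaling the residual around X beta0
  dat <- fixture_linear(12, 3, seed = 21)
  b0 <- c(0.5, -1, 0)
  s1 <- gt_statistic_linear(dat$x, dat$y, b0)
  y_scaled <- drop(dat$x %*% b0) + 7.3 * (dat$y - drop(dat$x %*% b0))
  expect_equal(gt_statistic_linear(dat$x, y_scaled, b0), s1)
  expect_error(gt_statistic_linear(dat$x, drop(dat$x %*% b0), b0), "saturated")
})

test_that("the score-form statistic is the squared score norm", {
  expect_equal(gt_statistic_score(numeric(3)), 0)
  expect_equal(gt_statistic_score(c(3, 4)), 25)
  dat <- fixture_linear(10, 4, seed = 31)
  b0 <- rep(0.2, 4)
  r <- dat$y - drop(dat$x %*% b0)
  expect_equal(
    gt_statistic_score(drop(crossprod(dat$x, r))),
    gt_statistic_linear(dat$x, dat$y, b0) * sum(r^2)
  )
})

test_that("exact linear p-values hit the boundary cases and the Monte Carlo tail", {
  X <- fixture_design(30, 5, seed = 41)
  sp <- design_spectrum(X)
  expect_equal(gt_pvalue_linear(sp, 0), 1)
  expect_equal(gt_pvalue_linear(sp, sp$gamma[1] * 1.01), 0)
  s_obs <- sum(sp$gamma) / 30 * 1.3   # moderately above the null mean
  p <- gt_pvalue_linear(sp, s_obs)
  emp <- withr::with_seed(42, {
    e <- matrix(rnorm(30 * 2e5), 30)
    mean(colSums(crossprod(X, e)^2) / colSums(e^2) > s_obs)
  })
  se <- sqrt(emp * (1 - emp) / 2e5)
  expect_lt(abs(p - emp), 3 * se)
})

test_that("p-values are uniform under the linear null", {
  X <- fixture_design(30, 5, seed = 43)
  sp <- design_spectrum(X)
  pv <- vapply(seq_len(1000), function(i) {
    e <- withr::with_seed(5000 + i, rnorm(30))
    gt_pvalue_linear(sp, gt_statistic_linear(X, e))
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("critical values invert the null distribution and are monotone", {
  X <- fixture_design(25, 6, seed = 51)
  sp <- design_spectrum(X)
  c05 <- gt_critical_value(sp, 0.05)
  c50 <- gt_critical_value(sp, 0.50)
  expect_equal(gt_pvalue_linear(sp, c05), 0.05, tolerance = 1e-6)
  expect_equal(gt_pvalue_linear(sp, c50), 0.50, tolerance = 1e-6)
  expect_gt(c05, c50)
  # alpha near 1 pushes the critical value toward 0
  expect_lt(gt_critical_value(sp, 0.999), c50 / 10)
  expect_error(gt_critical_value(sp, 1.2), "alpha")
})

test_that("the asymptotic branch reduces to chi-squared and matches a bootstrap", {
  # identity covariance: the null is chi^2_p
  sc <- c(1.2, -0.4, 2)
  res <- gt_pvalue_asymptotic(sc, diag(3))
  expect_equal(res$pvalue, pchisq(sum(sc^2), 3, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(gt_pvalue_asymptotic(numeric(3), diag(3))$pvalue, 1)
  expect_error(gt_pvalue_asymptotic(c(1, 1), matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")

  # logistic score test against a 1e4-replicate parametric bootstrap
  X <- fixture_design(40, 3, seed = 1)
  beta0 <- c(0.3, -0.2, 0)
  mu0 <- 1 / (1 + exp(-drop(X %*% beta0)))
  y <- withr::with_seed(1, rbinom(40, 1, mu0))
  score <- drop(crossprod(X, y - mu0))
  info <- crossprod(X * (mu0 * (1 - mu0)), X)
  res <- gt_pvalue_asymptotic(score, info)
  emp <- withr::with_seed(2, {
    yy <- matrix(rbinom(40 * 1e4, 1, mu0), 40)
    mean(colSums(crossprod(X, yy - mu0)^2) > res$statistic)
  })
  se <- sqrt(emp * (1 - emp) / 1e4)
  expect_lt(abs(res$pvalue - emp), 3 * se)
})

test_that("gt_test_linear assembles a tidy-able result with exact-ratio weights", {
  dat <- fixture_linear(20, 4, seed = 61)
  res <- gt_test_linear(dat$x, dat$y)
  sp <- design_spectrum(dat$x)
  expect_s3_class(res, "gt_result")
  expect_equal(res$method, "exact_ratio")
  expect_length(res$weights, 20)           # rank + (n - rank) padding
  expect_equal(sort(res$weights, decreasing = TRUE)[seq_len(sp$rank)],
               sp$gamma - res$statistic)
  td <- tidy(res)
  expect_named(td, c("statistic", "p.value", "method"))
  expect_gte(res$statistic, 0)
  expect_true(res$pvalue >= 0 && res$pvalue <= 1)
})
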