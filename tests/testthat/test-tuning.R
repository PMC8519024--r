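test_that("alpha_of_lambda spans from the global-null p-value to saturation", {
  dat <- fixture_linear(40, 6, seed = 71, beta = rep(0.3, 6), sigma = 1)
  # lambda = Inf tests beta = 0
  expect_equal(
    alpha_of_lambda(dat$x, dat$y, Inf),
    gt_test_linear(dat$x, dat$y, 0)$pvalue
  )
  # lambda = 0 with n > p: residual orthogonal to X, p-value 1
  expect_equal(alpha_of_lambda(dat$x, dat$y, 0), 1, tolerance = 1e-8)
  # nonincreasing in lambda over an increasing 50-point grid
  lams <- 10^seq(-2, 6, length.out = 50)
  pv <- vapply(lams, function(l) alpha_of_lambda(dat$x, dat$y, l), numeric(1))
  expect_true(all(diff(pv) <= 1e-8))
})

test_that("the globaltest selector honors the sup definition on a dense grid", {
  dat <- fixture_linear(50, 8, seed = 81, beta = rep(0.4, 8), sigma = 1)
  alpha <- 0.2
  fit <- select_lambda_gt(dat$x, dat$y, alpha)
  expect_lt(fit$pvalue_null, alpha)   # signal: the null is rejected
  expect_true(is.finite(fit$lambda))
  # dense-grid oracle: the largest of 1e4 log-spaced lambdas kept inside
  sp <- design_spectrum(dat$x)
  crit <- gt_critical_value(sp, alpha)
  dense <- 10^seq(log10(min(sp$gamma) * 1e-4), log10(max(sp$gamma) * 1e4),
                  length.out = 1e4)
  stats <- vapply(dense, function(l)
    gt_statistic_linear(dat$x, dat$y, ridge_estimate_linear(sp, dat$y, l)),
    numeric(1))
  oracle <- max(dense[stats <= crit])
  step <- log(dense[2] / dense[1])
  expect_lt(abs(log(fit$lambda) - log(oracle)), 2 * step)
  # the path touches the boundary at the selection
  expect_equal(alpha_of_lambda(dat$x, dat$y, fit$lambda), alpha,
               tolerance = 1e-2)
})

test_that("lambda(alpha) is nonincreasing and the selector round-trips", {
  dat <- fixture_linear(40, 5, seed = 91, beta = rep(0.5, 5), sigma = 1)
  alphas <- c(0.05, 0.2, 0.5, 0.8)
  lams <- vapply(alphas, function(a)
    select_lambda_gt(dat$x, dat$y, a)$lambda, numeric(1))
  expect_true(all(diff(lams) <= 1e-8))
  # duality: selecting at the level implied by lambda0 recovers >= lambda0
  lam0 <- 20
  a0 <- alpha_of_lambda(dat$x, dat$y, lam0)
  lam_back <- select_lambda_gt(dat$x, dat$y, a0)$lambda
  expect_gte(lam_back, lam0 * (1 - 1e-3))
})

test_that("the null model is selected iff the global null is not rejected", {
  X <- fixture_design(30, 6, seed = 101)
  for (i in 1:10) {
    y <- withr::with_seed(200 + i, rnorm(30))
    fit <- select_lambda_gt(X, y, 0.5)
    expect_identical(is.infinite(fit$lambda), fit$pvalue_null >= 0.5)
    if (is.infinite(fit$lambda)) expect_equal(fit$mc, 0)
  }
})

test_that("the F statistic matches hand arithmetic and is calibrated", {
  # n = 3, p = 1, X = 1, y = (1,2,3): beta-hat = 2, sigma2 = 1, T = 12
  expect_equal(f_statistic(matrix(1, 3, 1), c(1, 2, 3), 0), 12)
  dat <- fixture_linear(25, 4, seed = 111)
  sp <- design_spectrum(dat$x)
  bols <- ridge_estimate_linear(sp, dat$y, 0)
  expect_equal(f_statistic(dat$x, dat$y, bols), 0, tolerance = 1e-16)
  expect_error(f_statistic(fixture_design(5, 8), rnorm(5)), "high dimensions")
  # F p-values uniform under a simulated point null
  X <- fixture_design(30, 4, seed = 112)
  b0 <- c(1, -1, 0.5, 0)
  pv <- vapply(seq_len(1000), function(i) {
    y <- withr::with_seed(3000 + i, drop(X %*% b0) + rnorm(30))
    pf(f_statistic(X, y, b0), 4, 26, lower.tail = FALSE)
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("the Scheffe selector agrees with the direct ellipsoid inequality", {
  dat <- fixture_linear(40, 2, seed = 121, beta = c(1, -0.5), sigma = 0.8)
  alpha <- 0.1
  fit <- select_lambda_ft(dat$x, dat$y, alpha)
  sp <- design_spectrum(dat$x)
  bols <- ridge_estimate_linear(sp, dat$y, 0)
  sigma2 <- sum((dat$y - drop(dat$x %*% bols))^2) / (40 - 2)
  bound <- 2 * sigma2 * qf(1 - alpha, 2, 38)
  member <- function(l) {
    b <- ridge_estimate_linear(sp, dat$y, l)
    drop(crossprod(b - bols, crossprod(dat$x) %*% (b - bols))) <= bound
  }
  expect_true(is.finite(fit$lambda))
  expect_true(member(fit$lambda))
  expect_false(member(fit$lambda * 1.01))
  # center of the ellipsoid is always inside
  expect_equal(f_statistic(dat$x, dat$y, bols), 0, tolerance = 1e-16)
  expect_error(select_lambda_ft(fixture_design(5, 8), rnorm(5), 0.1),
               "high dimensions")
})

test_that("the two-predictor boundary is classified by the conic discriminant", {
  g1 <- 4; g2 <- 1
  X <- diag(c(sqrt(g1), sqrt(g2)))    # X'X = diag(4, 1)
  expect_equal(conic_classify(X, 2), "hyperbola")       # g2 < c < g1
  expect_equal(conic_classify(X, 0.5), "ellipse")       # c < g2
  expect_equal(conic_classify(X, 1), "parallel_lines")  # c = g2 exactly
  expect_error(conic_classify(fixture_design(5, 3), 1), "two predictors")
  # sign pattern of the quadratic form on a dense circle of directions
  for (i in 1:25) {
    Xi <- fixture_design(8, 2, seed = 400 + i)
    ev <- eigen(crossprod(Xi), symmetric = TRUE, only.values = TRUE)$values
    cc <- mean(ev)    # between the eigenvalues -> indefinite form
    cls <- conic_classify(Xi, cc)
    angles <- seq(0, pi, length.out = 200)
    dirs <- rbind(cos(angles), sin(angles))
    qf_vals <- colSums(dirs * ((crossprod(Xi) %*% crossprod(Xi) -
                                  cc * crossprod(Xi)) %*% dirs))
    sign_pattern <- if (all(qf_vals > 0)) "ellipse" else
      if (all(qf_vals < 0)) "ellipse_neg" else "hyperbola"
    expect_equal(cls, sign_pattern)
    cls2 <- conic_classify(Xi, ev[2] * 0.9)
    expect_equal(cls2, "ellipse")
  }
})

test_that("the detectable-region covariance flags the powerful directions", {
  # equal eigenvalues: constant gamma, covariance 0
  expect_equal(detectable_cov(diag(2) * 2, c(1, 1), c(0, 0), 1), 0)
  # diagonal design, signal along the top eigenvector: positive
  X <- diag(c(2, 1))                   # X'X = diag(4, 1)
  expect_gt(detectable_cov(X, c(1, 0), c(0, 0), 0.5), 0)
  # spectral beta with strongly negative exponent: negative
  sp <- design_spectrum(X)
  b_neg <- make_beta(sp, -2)
  expect_lt(detectable_cov(sp, b_neg, c(0, 0), 0.5), 0)
  expect_error(detectable_cov(X, c(1, 0), c(1, 0), 1), "direction undefined")
})
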