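test_that("penalized logistic fits satisfy the stationarity and grid oracles", {
  X <- fixture_design(20, 2, seed = 131)
  y <- withr::with_seed(7, rbinom(20, 1, 1 / (1 + exp(-X[, 1]))))
  expect_identical(ridge_glm_fit(X, y, Inf), numeric(2))
  # separable data: the penalty guarantees a finite maximizer
  X_sep <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y_sep <- c(0, 0, 1, 1)
  b_sep <- ridge_glm_fit(X_sep, y_sep, 1)
  expect_true(is.finite(b_sep))
  # brute-force 200x200 grid oracle on the penalized objective
  lam <- 0.5
  b <- ridge_glm_fit(X, y, lam)
  obj <- function(b1, b2) {
    eta <- X %*% c(b1, b2)
    sum(y * eta - log1p(exp(eta))) - lam * (b1^2 + b2^2)
  }
  gr <- seq(-3, 3, length.out = 200)
  vals <- outer(gr, gr, Vectorize(obj))
  best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  expect_lt(abs(b[1] - gr[best[1]]), 2 * diff(gr[1:2]))
  expect_lt(abs(b[2] - gr[best[2]]), 2 * diff(gr[1:2]))
  expect_gte(obj(b[1], b[2]), max(vals))
  expect_error(ridge_glm_fit(X, y + 1, 1), "binary")
})

test_that("penalized Cox fits match grid search, coxph and rank invariance", {
  X <- fixture_design(40, 1, seed = 141)
  sv <- gen_survival(X, 0.8, baseline_rate = 1, censor_rate = 0.5, seed = 9)
  expect_identical(ridge_cox_fit(X, sv, Inf), numeric(1))
  # 1-D grid oracle on the penalized partial likelihood
  lam <- 0.7
  b <- ridge_cox_fit(X, sv, lam)
  gr <- seq(-2, 2, length.out = 2000)
  vals <- vapply(gr, function(bb)
    gtridge:::cox_quantities(X, sv, bb, what = "loglik")$loglik - lam * bb^2,
    numeric(1))
  expect_lt(abs(b - gr[which.max(vals)]), 2 * diff(gr[1:2]))
  # partial likelihood depends on time order only
  sv2 <- surv_data(2 * sv$time, sv$status)
  expect_equal(ridge_cox_fit(X, sv2, lam), b, tolerance = 1e-8)
  # near-zero penalty agrees with the unpenalized survival::coxph fit
  X3 <- fixture_design(60, 3, seed = 142)
  sv3 <- gen_survival(X3, c(0.5, -0.3, 0), 1, 0.7, seed = 10)
  b3 <- ridge_cox_fit(X3, sv3, 1e-8)
  cph <- survival::coxph(survival::Surv(sv3$time, sv3$status) ~ X3,
                         ties = "breslow")
  expect_equal(unname(b3), unname(coef(cph)), tolerance = 1e-6)
  expect_error(ridge_cox_fit(X, surv_data(sv$time, rep(0, 40)), 1),
               "no events")
})

test_that("the Cox score equals its risk-set definition and curvature is PSD", {
  # hand-computed 5-subject oracle at beta = 0: score = sum over events of
  # (x_i - mean of x over the risk set at t_i)
  x <- matrix(c(0.5, -1, 2, 0, 1))
  sv <- surv_data(time = c(1, 2, 3, 4, 5), status = c(1, 0, 1, 1, 0))
  q <- cox_score(x, sv, 0)
  hand <- (x[1] - mean(x[1:5])) + (x[3] - mean(x[3:5])) + (x[4] - mean(x[4:5]))
  expect_equal(q$score, hand)
  # stationarity at the unpenalized partial-MLE
  X <- fixture_design(50, 3, seed = 151)
  sv2 <- gen_survival(X, c(0.4, 0, -0.4), 1, 0.5, seed = 11)
  bhat <- ridge_cox_fit(X, sv2, 1e-10)
  expect_lt(max(abs(cox_score(X, sv2, bhat)$score)), 1e-5)
  # information is positive semidefinite on random instances
  for (i in 1:5) {
    Xi <- fixture_design(30, 4, seed = 160 + i)
    svi <- gen_survival(Xi, rep(0.2, 4), 1, 0.6, seed = 20 + i)
    ev <- eigen(cox_score(Xi, svi, rnorm(4) / 4)$information,
                symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("ties are handled by Breslow's rule, matching coxph on tied data", {
  X <- fixture_design(30, 2, seed = 171)
  sv <- gen_survival(X, c(0.5, -0.5), 1, 0.5, seed = 12)
  sv_tied <- surv_data(round(sv$time, 1), sv$status)  # induce ties
  b <- ridge_cox_fit(X, sv_tied, 1e-8)
  cph <- survival::coxph(survival::Surv(sv_tied$time, sv_tied$status) ~ X,
                         ties = "breslow")
  expect_equal(unname(b), unname(coef(cph)), tolerance = 1e-6)
})

test_that("cvpl equals a naive per-fold recomputation and is deterministic", {
  X <- fixture_design(60, 3, seed = 181)
  sv <- gen_survival(X, c(0.4, -0.2, 0.1), 1, 0.7, seed = 13)
  lam <- 2
  v1 <- cvpl(X, sv, lam, k = 5, seed = 99)
  expect_identical(cvpl(X, sv, lam, k = 5, seed = 99), v1)
  # naive recomputation on explicit folds
  folds <- rep_len(1:5, 60)
  v2 <- cvpl(X, sv, lam, folds = folds)
  naive <- 0
  for (kk in 1:5) {
    keep <- folds != kk
    b <- ridge_cox_fit(X[keep, , drop = FALSE], sv[keep, ], lam)
    naive <- naive +
      gtridge:::cox_quantities(X, sv, b, what = "loglik")$loglik -
      gtridge:::cox_quantities(X[keep, , drop = FALSE], sv[keep, ], b,
                               what = "loglik")$loglik
  }
  expect_equal(v2, naive)
  # lambda = Inf: deterministic value from the zero coefficient vector
  v_inf <- cvpl(X, sv, Inf, folds = folds)
  zero_sum <- 0
  for (kk in 1:5) {
    keep <- folds != kk
    zero_sum <- zero_sum +
      gtridge:::cox_quantities(X, sv, numeric(3), what = "loglik")$loglik -
      gtridge:::cox_quantities(X[keep, , drop = FALSE], sv[keep, ],
                               numeric(3), what = "loglik")$loglik
  }
  expect_equal(v_inf, zero_sum)
})

test_that("cvpl along the grid favors signal and the null appropriately", {
  X <- fixture_design(80, 10, seed = 191)
  sv_sig <- gen_survival(X, c(1, -1, 0.5, rep(0, 7)), 1, 0.3, seed = 14)
  lams <- c(10^seq(-1, 4, length.out = 10), Inf)
  v_sig <- vapply(lams, function(l) cvpl(X, sv_sig, l, seed = 7), numeric(1))
  expect_lt(which.max(v_sig), length(lams))   # finite maximizer under signal
  # under the null, overfitting at light penalties hurts held-out fit
  sv_null <- gen_survival(X, numeric(10), 1, 0.3, seed = 15)
  v_null <- vapply(lams, function(l) cvpl(X, sv_null, l, seed = 7), numeric(1))
  expect_gt(v_null[length(lams)], min(v_null[1:3]))
  expect_gt(which.max(v_null), 3)
})

test_that("the censoring-weighted Brier score matches its term-wise definition", {
  # no censoring, perfect predictions -> 0
  sv <- surv_data(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(brier_score(sv, c(0, 0, 1, 1), horizon = 2.5), 0)
  # no censoring, constant 0.5 -> 0.25
  expect_equal(brier_score(sv, rep(0.5, 4), horizon = 2.5), 0.25)
  # random censored instance vs a direct IPCW sum
  X <- fixture_design(50, 2, seed = 201)
  sv2 <- gen_survival(X, c(0.5, -0.5), 1, 0.8, seed = 16)
  pred <- withr::with_seed(17, runif(50))
  t_star <- stats::median(sv2$time)
  got <- brier_score(sv2, pred, t_star)
  cfit <- survival::survfit(survival::Surv(sv2$time, 1 - sv2$status) ~ 1)
  G <- stats::stepfun(cfit$time, c(1, cfit$surv), right = FALSE)
  Gm <- function(t) {
    idx <- which(cfit$time < t)
    if (length(idx) == 0) 1 else c(1, cfit$surv)[max(idx) + 1]
  }
  direct <- mean(vapply(seq_len(50), function(i) {
    if (sv2$time[i] <= t_star && sv2$status[i] == 1) {
      pred[i]^2 / Gm(sv2$time[i])
    } else if (sv2$time[i] > t_star) {
      (1 - pred[i])^2 / G(t_star)
    } else 0
  }, numeric(1)))
  expect_equal(got, direct)
  expect_error(brier_score(sv2, pred - 2, t_star), "probabilities")
})
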