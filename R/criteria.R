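# Baseline tuning-parameter selectors: information criteria on the ridge
# effective degrees of freedom, and cross-validation (k-fold, LOOCV, GCV).

ic_names <- c("AIC", "AICc", "BIC", "mBIC", "mBIC2", "GIC", "RIC")

#' Information-criterion penalty on ridge model complexity
#'
#' Evaluates the complexity penalty of the named criterion at effective
#' model complexity `mc` (a continuous effective parameter count, see
#' [model_complexity()]), sample size `n` and predictor count `p`:
#'
#' * AIC: `2 mc`
#' * AICc: `{2 + 2 (mc + 1) / (n - mc - 1)} mc`
#' * BIC: `log(n) mc`
#' * mBIC: `{log(n) + 2 log(p/4 - 1)} mc`
#' * mBIC2: `{log(n) + 2 log(p/4)} mc - 2 log(mc!)`
#' * GIC: `{log(log(n)) log(p)} mc`
#' * RIC: `2 log(p) mc`
#'
#' The factorial in mBIC2 is generalized to fractional `mc` through the
#' gamma function, `log(mc!) = lgamma(mc + 1)`.
#'
#' @param name One of AIC, AICc, BIC, mBIC, mBIC2, GIC, RIC.
#' @param mc Effective model complexity, `>= 0` (vectorized).
#' @param n Sample size.
#' @param p Predictor count.
#' @return Penalty value(s), same length as `mc`.
#' @export
ic_penalty <- function(name, mc, n, p) {
  name <- match.arg(name, ic_names)
  if (any(mc < 0)) abort("`mc` must be nonnegative")
  switch(
    name,
    AIC = 2 * mc,
    AICc = {
      if (any(n <= mc + 1)) abort("penalty undefined: AICc needs n > mc + 1")
      (2 + 2 * (mc + 1) / (n - mc - 1)) * mc
    },
    BIC = log(n) * mc,
    mBIC = {
      if (p <= 4) abort("mBIC penalty needs p > 4")
      (log(n) + 2 * log(p / 4 - 1)) * mc
    },
    mBIC2 = (log(n) + 2 * log(p / 4)) * mc - 2 * lgamma(mc + 1),
    GIC = log(log(n)) * log(p) * mc,
    RIC = 2 * log(p) * mc
  )
}

# Penalized Gaussian log-likelihood along the ridge path: the profile
# log-likelihood at beta_lambda (variance estimated as RSS/n) minus
# lambda ||beta_lambda||^2; the penalty term vanishes at lambda = Inf.
penalized_loglik_linear <- function(spec, y, lambda, penalized = TRUE) {
  d <- drop(crossprod(spec$u, y))
  g <- spec$gamma
  vapply(lambda, function(l) {
    rss <- ridge_rss(spec, y, l)
    ll <- gaussian_profile_loglik(rss, spec$n)
    if (penalized && is.finite(l)) {
      ll <- ll - l * sum(g * d^2 / (g + l)^2)
    }
    ll
  }, numeric(1))
}

#' Ridge tuning by an information criterion
#'
#' Minimizes `-2 l(lambda) + penalty(mc(lambda), n, p)` over a penalty grid
#' that always includes the `Inf` sentinel (null model), where `l(lambda)`
#' is the penalized Gaussian log-likelihood of the ridge fit and the
#' penalty is one of the [ic_penalty()] formulas.  Ties break toward the
#' larger penalty (the less complex model).
#'
#' @inheritParams select_lambda_gt
#' @param y Numeric response (linear model).
#' @param criterion Criterion name; see [ic_penalty()].
#' @param penalized Use the penalized log-likelihood in the fit term (the
#'   default); `FALSE` substitutes the unpenalized log-likelihood at the
#'   ridge estimate, exposed for sensitivity checks.
#' @return A `gt_tuning` object with `method = criterion`.
#' @export
ic_select <- function(x, y, criterion, grid = NULL, penalized = TRUE) {
  x <- as_design_matrix(x)
  criterion <- match.arg(criterion, ic_names)
  spec <- design_spectrum(x)
  grid <- grid %||% default_lambda_grid(spec)
  lambda <- c(Inf, rev(grid))
  mc <- model_complexity(spec, lambda)
  ll <- penalized_loglik_linear(spec, y, lambda, penalized = penalized)
  crit <- -2 * ll + ic_penalty(criterion, mc, spec$n, spec$p)
  best <- which.min(crit)   # first minimum = largest lambda on ties
  new_gt_tuning(lambda[best], NA_real_, NA_real_, criterion, "linear",
                mc = mc[best],
                profile = tibble(lambda = lambda, criterion = crit))
}

#' Ridge tuning by cross-validation
#'
#' Selects the penalty minimizing a cross-validation estimate of prediction
#' error on the grid (with the `Inf` sentinel included):
#'
#' * `kcv`: mean held-out squared error over seeded, shuffled folds;
#' * `loocv`: the leverage closed form
#'   `mean(((y_i - yhat_i) / (1 - h_ii))^2)` with `h_ii` from the ridge hat
#'   matrix, equal to literal leave-one-out refitting;
#' * `gcv`: `(RSS/n) / (1 - mc/n)^2`; grid points with `mc >= n` are
#'   skipped with a warning.
#'
#' @inheritParams ic_select
#' @param method CV flavor.
#' @param k Folds for `kcv`.
#' @param seed Integer seed driving the fold shuffle (`kcv` only).
#' @return A `gt_tuning` object with `method` set to the CV flavor.
#' @export
cv_select <- function(x, y, method = c("kcv", "loocv", "gcv"), grid = NULL,
                      k = 5L, seed = NULL) {
  method <- match.arg(method)
  x <- as_design_matrix(x)
  spec <- design_spectrum(x)
  grid <- grid %||% default_lambda_grid(spec)
  lambda <- c(Inf, rev(grid))
  n <- spec$n
  crit <- switch(
    method,
    gcv = {
      mc <- model_complexity(spec, lambda)
      rss <- vapply(lambda, function(l) ridge_rss(spec, y, l), numeric(1))
      out <- (rss / n) / (1 - mc / n)^2
      if (any(mc >= n)) {
        warn("skipping grid points with mc >= n in GCV")
        out[mc >= n] <- Inf
      }
      out
    },
    loocv = {
      d <- drop(crossprod(spec$u, y))
      u2 <- spec$u^2
      vapply(lambda, function(l) {
        a <- if (is.infinite(l)) rep(0, spec$rank) else
          spec$gamma / (spec$gamma + l)
        h <- drop(u2 %*% a)
        fit <- drop(spec$u %*% (a * d))
        mean(((y - fit) / (1 - h))^2)
      }, numeric(1))
    },
    kcv = {
      if (k < 2) abort("`k` must be at least 2")
      folds <- with_seed_opt(seed, sample(rep_len(seq_len(k), n)))
      sse <- numeric(length(lambda))
      for (fold in seq_len(k)) {
        hold <- folds == fold
        sp_tr <- design_spectrum(x[!hold, , drop = FALSE])
        y_tr <- y[!hold]
        for (j in seq_along(lambda)) {
          b <- ridge_estimate_linear(sp_tr, y_tr, lambda[j])
          pred <- drop(x[hold, , drop = FALSE] %*% b)
          sse[j] <- sse[j] + sum((y[hold] - pred)^2)
        }
      }
      sse / n
    }
  )
  best <- which.min(crit)
  new_gt_tuning(lambda[best], NA_real_, NA_real_, method, "linear",
                mc = model_complexity(spec, lambda[best]),
                profile = tibble(lambda = lambda, criterion = crit))
}
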