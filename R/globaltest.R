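#' Globaltest statistic for the linear model
#'
#' The score statistic for `H0: beta = beta0` against a high-dimensional
#' alternative, in its ratio form
#' `S = ||X'(y - X beta0)||^2 / ||y - X beta0||^2`.
#' It is invariant to rescaling of the residual, hence free of the error
#' variance.
#'
#' @param x Design matrix (n x p) or data frame.
#' @param y Response vector.
#' @param beta0 Tested coefficient vector (length p), or a single 0 for the
#'   global null.
#' @return The statistic, a nonnegative scalar.
#' @export
gt_statistic_linear <- function(x, y, beta0 = 0) {
  x <- as_design_matrix(x)
  if (length(y) != nrow(x)) abort("length(y) must equal nrow(x)")
  if (length(beta0) == 1L) beta0 <- rep(beta0, ncol(x))
  if (length(beta0) != ncol(x)) abort("length(beta0) must equal ncol(x)")
  r <- y - drop(x %*% beta0)
  den <- sum(r^2)
  if (den == 0) abort("saturated fit; statistic undefined (zero residual)")
  sum(drop(crossprod(x, r))^2) / den
}

#' Score-form globaltest statistic
#'
#' For generalized linear and Cox models the globaltest statistic is the
#' squared norm `s's` of the score vector at the tested point (the
#' information-trace term of the original statistic does not depend on the
#' response and is dropped).
#'
#' @param score Score vector at the tested coefficient value.
#' @return `sum(score^2)`.
#' @export
gt_statistic_score <- function(score) {
  if (!is.numeric(score) || anyNA(score) || any(!is.finite(score))) {
    abort("`score` must be a finite numeric vector")
  }
  sum(score^2)
}

# Quadratic-form weights of the exact linear null: S_obs exceeds s iff
# e'(XX' - s I)e > 0, so the weights are the eigenvalues of XX' - s I:
# gamma_i - s for the rank nonzero eigenvalues plus -s with multiplicity
# n - rank.
gt_weights_linear <- function(spec, s_obs) {
  c(spec$gamma - s_obs, rep(-s_obs, spec$n - spec$rank))
}

#' Exact p-value of the linear globaltest
#'
#' Under `y ~ N(X beta0, sigma^2 I)` the ratio statistic is a pivotal
#' function of the standardized errors, and `P(S > s)` equals the
#' probability that the indefinite quadratic form `e'(XX' - s I)e` is
#' positive, evaluated by [imhof_tail()].  The result is free of `sigma^2`.
#'
#' @param spec A [design_spectrum()] or the design matrix.
#' @param s_obs Observed statistic, `>= 0`.
#' @return A p-value in `[0, 1]`.
#' @export
gt_pvalue_linear <- function(spec, s_obs) {
  spec <- as_design_spectrum(spec)
  if (!is.numeric(s_obs) || length(s_obs) != 1L || is.na(s_obs) || s_obs < 0) {
    abort("`s_obs` must be a single nonnegative number")
  }
  if (s_obs == 0) return(1)
  if (s_obs >= spec$gamma[1]) return(0)
  imhof_tail(gt_weights_linear(spec, s_obs), 0)
}

#' Critical value of the linear globaltest
#'
#' The 1 - alpha quantile `c_alpha` of the exact null distribution of the
#' ratio statistic, found by root-finding `P(S > c) = alpha` on
#' `(0, gamma_1)`.  The globaltest confidence region is then
#' `{beta0 : S(beta0) <= c_alpha}`.
#'
#' @inheritParams gt_pvalue_linear
#' @param alpha Level in (0, 1).
#' @return The critical value, in `(0, gamma_1)`.
#' @export
gt_critical_value <- function(spec, alpha) {
  spec <- as_design_spectrum(spec)
  check_alpha(alpha)
  g1 <- spec$gamma[1]
  f <- function(c) gt_pvalue_linear(spec, c) - alpha
  lower <- g1 * 1e-10
  while (f(lower) < 0 && lower > g1 * 1e-300) lower <- lower / 1e10
  uniroot(f, c(lower, g1 * (1 - 1e-12)), tol = g1 * 1e-10)$root
}

#' Asymptotic globaltest from a score vector and its covariance
#'
#' For models where the exact ratio distribution is unavailable (logistic,
#' Cox), the null distribution of `s's` is approximated by the weighted
#' chi-squared form `sum_i omega_i chi^2_1` with `omega_i` the eigenvalues
#' of the score covariance (observed information), and the p-value computed
#' by [imhof_tail()].  Eigenvalues below `1e-10` times the largest are
#' dropped.
#'
#' @param score Score vector at the tested point.
#' @param score_cov Symmetric positive semidefinite covariance of the score.
#' @return A `gt_result` object; see [gt_test_linear()].
#' @export
gt_pvalue_asymptotic <- function(score, score_cov) {
  score_cov <- as.matrix(score_cov)
  if (nrow(score_cov) != ncol(score_cov) ||
      length(score) != nrow(score_cov)) {
    abort("`score_cov` must be square with dimension length(score)")
  }
  if (max(abs(score_cov - t(score_cov))) >
      1e-8 * max(1, max(abs(score_cov)))) {
    abort("`score_cov` must be symmetric")
  }
  ev <- eigen((score_cov + t(score_cov)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[1] <= 0) abort("degenerate form: score covariance is zero")
  if (min(ev) < -1e-8 * ev[1]) {
    abort("`score_cov` is not positive semidefinite")
  }
  omega <- ev[ev > 1e-10 * ev[1]]
  statistic <- gt_statistic_score(score)
  pvalue <- if (statistic == 0) 1 else imhof_tail(omega, statistic)
  new_gt_result(statistic, omega, pvalue, "asymptotic", beta0 = NULL)
}

#' Globaltest of a point null for the linear model
#'
#' Convenience wrapper combining [gt_statistic_linear()] and
#' [gt_pvalue_linear()] into a result object with [tidy()] and [glance()]
#' methods.
#'
#' @inheritParams gt_statistic_linear
#' @return A `gt_result`: list with `statistic`, `weights` (quadratic-form
#'   weights of the null), `pvalue`, `method` (`"exact_ratio"` or
#'   `"asymptotic"`) and `beta0`.
#' @export
gt_test_linear <- function(x, y, beta0 = 0) {
  x <- as_design_matrix(x)
  spec <- design_spectrum(x)
  if (length(beta0) == 1L) beta0 <- rep(beta0, ncol(x))
  s <- gt_statistic_linear(x, y, beta0)
  new_gt_result(
    s, gt_weights_linear(spec, s), gt_pvalue_linear(spec, s),
    "exact_ratio", beta0
  )
}

new_gt_result <- function(statistic, weights, pvalue, method, beta0) {
  structure(
    list(statistic = statistic, weights = weights, pvalue = pvalue,
         method = method, beta0 = beta0),
    class = "gt_result"
  )
}

#' @export
print.gt_result <- function(x, ...) {
  cat(sprintf("<gt_result> globaltest (%s)\n  S = %.6g, p = %.4g\n",
              x$method, x$statistic, x$pvalue))
  invisible(x)
}
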