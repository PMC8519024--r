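# Confidence-region tuning: membership of the ridge path in the globaltest
# (or Scheffe) region, the maps alpha(lambda) / lambda(alpha), conic
# classification of the p = 2 boundary, and the detectable-region
# diagnostic.

# Globaltest ratio statistic along the ridge path, O(rank) per lambda once
# the spectrum is available: with d = U'y and a_i = gamma_i/(gamma_i +
# lambda), the residual is y - U a d, so
#   ||X'r||^2 = sum gamma_i (1 - a_i)^2 d_i^2
#   ||r||^2   = ||y||^2 - ||d||^2 + sum (1 - a_i)^2 d_i^2.
gt_profile_linear <- function(spec, y, lambda) {
  d <- drop(crossprod(spec$u, y))
  perp <- max(sum(y^2) - sum(d^2), 0)
  g <- spec$gamma
  vapply(lambda, function(l) {
    one_m_a <- if (is.infinite(l)) rep(1, spec$rank) else l / (g + l)
    den <- perp + sum(one_m_a^2 * d^2)
    if (den == 0) abort("saturated fit; statistic undefined (zero residual)")
    sum(g * one_m_a^2 * d^2) / den
  }, numeric(1))
}

#' Smallest level at which the ridge estimate stays in the region
#'
#' Returns the globaltest p-value of `H0: beta = beta_lambda`, i.e. the
#' infimum over alpha such that the ridge estimate at `lambda` lies in the
#' 1 - alpha globaltest confidence region (the estimate is inside
#' `C_alpha` exactly when the returned value is `>= alpha`).  At
#' `lambda = Inf` this is the p-value of the global null `beta = 0`.
#'
#' @param x Design matrix.
#' @param response Response: numeric vector (linear, logistic) or survival
#'   data (see [surv_data()]) for the Cox model.
#' @param lambda Penalty in `[0, Inf]`.
#' @param model Model family.
#' @return A p-value in `[0, 1]`.
#' @export
alpha_of_lambda <- function(x, response, lambda,
                            model = c("linear", "logistic", "cox")) {
  model <- match.arg(model)
  x <- as_design_matrix(x)
  check_lambda(lambda)
  if (model == "linear") {
    spec <- design_spectrum(x)
    gt_pvalue_linear(spec, gt_profile_linear(spec, response, lambda))
  } else {
    gt_pvalue_at(x, response, lambda, model)$pvalue
  }
}

# Asymptotic-branch p-value of H0: beta = beta_hat(lambda) for logistic or
# Cox models; fits the penalized model, then score-tests that point.
gt_pvalue_at <- function(x, response, lambda, model, init = NULL) {
  if (model == "logistic") {
    b <- ridge_glm_fit(x, response, lambda, init = init)
    mu <- logistic_mu(drop(x %*% b))
    score <- drop(crossprod(x, response - mu))
    info <- crossprod(x * (mu * (1 - mu)), x)
  } else {
    b <- ridge_cox_fit(x, response, lambda, init = init)
    q <- cox_score(x, response, b)
    score <- q$score
    info <- q$information
  }
  res <- gt_pvalue_asymptotic(score, info)
  list(pvalue = res$pvalue, beta = b)
}

# Shared crossing search: `inside(lambda)` tests region membership of the
# ridge estimate.  Scans a descending grid for the largest lambda inside
# (the supremum definition: if the membership profile crosses several
# times, the largest crossing wins), extends the grid when the crossing
# falls outside it, then bisects in log lambda.  Boundary ties count as
# inside.
crossing_search <- function(inside, grid, tol = 1e-4) {
  lam_desc <- rev(grid)
  n_evals <- 0L
  inside_at <- function(l) { n_evals <<- n_evals + 1L; inside(l) }
  in_grid <- vapply(lam_desc, inside_at, logical(1))
  flags <- list(multi_crossing = FALSE, no_crossing = FALSE)
  if (!any(in_grid)) {
    # crossing (if any) is below the grid: extend downward
    lo <- lam_desc[length(lam_desc)]
    for (i in 1:30) {
      cand <- lo / 10
      if (inside_at(cand)) {
        return(bisect_crossing(inside_at, cand, lo, tol, n_evals, flags))
      }
      lo <- cand
    }
    flags$no_crossing <- TRUE
    return(list(lambda = 0, bracket = NULL, n_evals = n_evals, flags = flags))
  }
  idx <- which(in_grid)[1]
  flags$multi_crossing <- any(!in_grid[idx:length(in_grid)])
  if (idx == 1L) {
    # inside at the largest finite grid point but outside at Inf: extend up
    hi <- lam_desc[1]
    for (i in 1:30) {
      cand <- hi * 10
      if (!inside_at(cand)) {
        return(bisect_crossing(inside_at, hi, cand, tol, n_evals, flags))
      }
      hi <- cand
    }
    return(list(lambda = hi, bracket = NULL, n_evals = n_evals, flags = flags))
  }
  bisect_crossing(inside_at, lam_desc[idx], lam_desc[idx - 1L], tol,
                  n_evals, flags)
}

bisect_crossing <- function(inside_at, lo, hi, tol, n_evals, flags) {
  bracket <- c(lo, hi)
  while (log(hi / lo) > tol) {
    mid <- sqrt(lo * hi)
    if (inside_at(mid)) lo <- mid else hi <- mid
  }
  list(lambda = lo, bracket = bracket,
       n_evals = environment(inside_at)$n_evals %||% n_evals, flags = flags)
}

new_gt_tuning <- function(lambda, alpha, pvalue_null, method, model,
                          bracket = NULL, n_evals = NA_integer_,
                          mc = NA_real_, critical = NA_real_,
                          flags = list(), profile = NULL) {
  structure(
    list(lambda = lambda, alpha = alpha, pvalue_null = pvalue_null,
         method = method, model = model, crossing_bracket = bracket,
         n_evals = n_evals, mc = mc, critical = critical,
         diagnostics = flags, profile = profile),
    class = "gt_tuning"
  )
}

#' @export
print.gt_tuning <- function(x, ...) {
  lam <- if (is.infinite(x$lambda)) "Inf (null model)" else
    sprintf("%.6g", x$lambda)
  cat(sprintf("<gt_tuning> method = %s, model = %s\n  lambda = %s", x$method,
              x$model, lam))
  if (!is.na(x$alpha)) cat(sprintf(", alpha = %g", x$alpha))
  if (!is.na(x$mc)) cat(sprintf(", mc = %.3f", x$mc))
  cat("\n")
  invisible(x)
}

#' Ridge tuning by the globaltest confidence region
#'
#' Selects `lambda_gt(alpha) = sup{lambda : beta_lambda in C_alpha}`, the
#' least complex point of the ridge path still inside the 1 - alpha
#' globaltest confidence region.  If the whole path is inside -
#' equivalently, if the globaltest of the global null `beta = 0` has
#' p-value `>= alpha` - the null model `lambda = Inf` is selected; the
#' long-run frequency of that event under a true null is `1 - alpha`
#' (exactly so for linear models, where the null distribution is exact).
#' Otherwise the largest crossing of the region boundary is located by a
#' descending grid scan refined by bisection in log lambda.
#'
#' @inheritParams alpha_of_lambda
#' @param alpha Level in (0, 1); boundary ties (p-value equal to alpha)
#'   count as inside the region.
#' @param grid Increasing finite penalty grid for the crossing scan
#'   (default [default_lambda_grid()]).
#' @param tol Relative bisection tolerance in log lambda.
#' @param critical Optional precomputed [gt_critical_value()] (linear model
#'   only); useful when tuning many responses on one fixed design.
#' @return A `gt_tuning` object: selected `lambda` (possibly `Inf`), the
#'   `alpha` used, `pvalue_null` (globaltest p-value at `beta = 0`),
#'   `crossing_bracket`, `n_evals`, `mc` at the selection, and diagnostic
#'   flags (`multi_crossing`, `no_crossing`).
#' @export
select_lambda_gt <- function(x, response, alpha,
                             model = c("linear", "logistic", "cox"),
                             grid = NULL, tol = 1e-4, critical = NULL) {
  model <- match.arg(model)
  check_alpha(alpha)
  x <- as_design_matrix(x)
  if (model == "linear") {
    spec <- design_spectrum(x)
    grid <- grid %||% default_lambda_grid(spec)
    s_null <- gt_profile_linear(spec, response, Inf)
    pvalue_null <- gt_pvalue_linear(spec, s_null)
    if (pvalue_null >= alpha) {
      return(new_gt_tuning(Inf, alpha, pvalue_null, "gt", model,
                           mc = 0, profile = NULL))
    }
    crit <- critical %||% gt_critical_value(spec, alpha)
    inside <- function(l) gt_profile_linear(spec, response, l) <= crit
    hit <- crossing_search(inside, grid, tol)
    prof <- tibble(
      lambda = rev(grid),
      statistic = gt_profile_linear(spec, response, rev(grid))
    )
    new_gt_tuning(hit$lambda, alpha, pvalue_null, "gt", model,
                  bracket = hit$bracket, n_evals = hit$n_evals,
                  mc = model_complexity(spec, hit$lambda),
                  critical = crit, flags = hit$flags, profile = prof)
  } else {
    grid <- grid %||% default_lambda_grid(design_spectrum(x))
    pvalue_null <- gt_pvalue_at(x, response, Inf, model)$pvalue
    if (pvalue_null >= alpha) {
      return(new_gt_tuning(Inf, alpha, pvalue_null, "gt", model, mc = 0))
    }
    warm <- new.env()
    warm$beta <- NULL
    inside <- function(l) {
      res <- gt_pvalue_at(x, response, l, model, init = warm$beta)
      warm$beta <- res$beta
      res$pvalue >= alpha
    }
    hit <- crossing_search(inside, grid, tol)
    new_gt_tuning(hit$lambda, alpha, pvalue_null, "gt", model,
                  bracket = hit$bracket, n_evals = hit$n_evals,
                  mc = model_complexity(design_spectrum(x), hit$lambda),
                  flags = hit$flags)
  }
}

#' F statistic for a point null in the linear model
#'
#' `T = ||X beta_hat - X beta0||^2 / (p sigma_hat^2)` with
#' `sigma_hat^2 = ||y - X beta_hat||^2 / (n - p)`; under
#' `H0: beta = beta0` it follows `F(p, n - p)`.  Requires `n > p` and full
#' column rank.
#'
#' @inheritParams gt_statistic_linear
#' @export
f_statistic <- function(x, y, beta0 = 0) {
  x <- as_design_matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (p >= n) abort("F-test inapplicable in high dimensions (need n > p)")
  spec <- design_spectrum(x)
  if (spec$rank < p) abort("design matrix is rank deficient")
  if (length(beta0) == 1L) beta0 <- rep(beta0, p)
  bhat <- ridge_estimate_linear(spec, y, 0)
  rss <- sum((y - drop(x %*% bhat))^2)
  sigma2 <- rss / (n - p)
  if (sigma2 == 0) abort("saturated fit; statistic undefined")
  sum(drop(x %*% (bhat - beta0))^2) / (p * sigma2)
}

#' Ridge tuning by the Scheffe (F-test) confidence region
#'
#' The same supremum rule as [select_lambda_gt()] but with membership
#' tested in the exact F-test ellipsoid
#' `(beta0 - beta_hat)' X'X (beta0 - beta_hat) <= p sigma_hat^2 f_{p,n-p}(alpha)`
#' centered at the OLS estimate.  Only defined for `n > p` with a
#' full-column-rank design.
#'
#' @inheritParams select_lambda_gt
#' @param y Numeric response (linear model only).
#' @return A `gt_tuning` object with `method = "ft"`.
#' @export
select_lambda_ft <- function(x, y, alpha, grid = NULL, tol = 1e-4) {
  check_alpha(alpha)
  x <- as_design_matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (p >= n) abort("F-test inapplicable in high dimensions (need n > p)")
  spec <- design_spectrum(x)
  if (spec$rank < p) abort("design matrix is rank deficient")
  grid <- grid %||% default_lambda_grid(spec)
  d <- drop(crossprod(spec$u, y))
  rss <- max(sum(y^2) - sum(d^2), 0)
  sigma2 <- rss / (n - p)
  if (sigma2 == 0) abort("saturated fit; statistic undefined")
  g <- spec$gamma
  fstat <- function(l) {
    one_m_a <- if (is.infinite(l)) rep(1, p) else l / (g + l)
    sum(one_m_a^2 * d^2) / (p * sigma2)
  }
  crit <- qf(1 - alpha, p, n - p)
  pvalue_null <- pf(fstat(Inf), p, n - p, lower.tail = FALSE)
  if (pvalue_null >= alpha) {
    return(new_gt_tuning(Inf, alpha, pvalue_null, "ft", "linear", mc = 0,
                         critical = crit))
  }
  hit <- crossing_search(function(l) fstat(l) <= crit, grid, tol)
  new_gt_tuning(hit$lambda, alpha, pvalue_null, "ft", "linear",
                bracket = hit$bracket, n_evals = hit$n_evals,
                mc = model_complexity(spec, hit$lambda), critical = crit,
                flags = hit$flags)
}

#' Conic classification of the two-predictor region boundary
#'
#' For `p = 2` the boundary of the globaltest confidence region is a conic
#' section; its type is decided by the sign of
#' `delta = det(X'X X'X - c X'X)`: positive gives an ellipse, zero a pair
#' of parallel lines, negative a hyperbola.
#'
#' @param x Design matrix with exactly two columns.
#' @param critical The critical value `c` defining the region boundary.
#' @return One of `"ellipse"`, `"parallel_lines"`, `"hyperbola"`.
#' @export
conic_classify <- function(x, critical) {
  x <- as_design_matrix(x)
  if (ncol(x) != 2L) abort("classification defined for two predictors only")
  a <- crossprod(x)
  delta <- det(a %*% a - critical * a)
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(prod(abs(ev)), .Machine$double.xmin) *
    (max(abs(ev)) + abs(critical))^2
  if (abs(delta) <= 1e-9 * scale) "parallel_lines"
  else if (delta > 0) "ellipse"
  else "hyperbola"
}

#' Detectable-region diagnostic for the globaltest
#'
#' Computes the per-component explained-variance fractions
#' `r_i^2 = gamma_i (b'v_i)^2 / (b'X'X b + n sigma^2)` for the direction
#' `b = beta - beta0`, and returns the sample covariance between the
#' eigenvalue vector `gamma` and `r^2`.  A positive value places `beta0` in
#' the detectable region, where the globaltest has good power (the
#' large-variance principal components carry more of the signal); a
#' negative value signals the region where the test loses power.
#'
#' @param spec A [design_spectrum()] or design matrix.
#' @param beta True (or hypothesized alternative) coefficient vector.
#' @param beta0 Tested point; must differ from `beta`.
#' @param sigma2 Error variance, positive.
#' @return The covariance `cov(gamma, r^2)` (scalar).
#' @export
detectable_cov <- function(spec, beta, beta0 = 0, sigma2 = 1) {
  spec <- as_design_spectrum(spec)
  if (sigma2 <= 0) abort("`sigma2` must be positive")
  if (length(beta0) == 1L) beta0 <- rep(beta0, spec$p)
  b <- beta - beta0
  if (all(b == 0)) abort("direction undefined at the null point")
  proj <- drop(crossprod(spec$v, b))^2
  denom <- sum(spec$gamma * proj) + spec$n * sigma2
  r2 <- spec$gamma * proj / denom
  if (spec$rank < 2) return(0)
  cov(spec$gamma, r2)
}
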