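#' Singular value decomposition of a design matrix
#'
#' Computes the thin SVD `X = U diag(sqrt(gamma)) V'` and keeps only the
#' components with nonzero singular values.  The vector `gamma` holds the
#' nonzero eigenvalues of `X'X` (squared singular values), sorted in
#' decreasing order.  This object is the backbone of the closed-form ridge
#' solution path, the exact globaltest null distribution, and the spectral
#' coefficient constructions used in simulations.
#'
#' @param x Numeric design matrix (samples in rows, predictors in columns),
#'   or a data frame of numeric columns.
#' @param tol Relative cutoff: singular values below `tol` times the largest
#'   are treated as zero and dropped from the rank.
#' @param center_y,scale_x Unused here; see [standardize_design()] for the
#'   explicit preprocessing helpers.
#'
#' @return An object of class `design_spectrum`: a list with elements `n`,
#'   `p`, `rank`, `u` (n x rank), `v` (p x rank) and `gamma` (length rank,
#'   decreasing, strictly positive).
#' @export
#' @examples
#' X <- matrix(rnorm(50 * 5), 50, 5)
#' sp <- design_spectrum(X)
#' sp$rank
#' max(abs(sp$u %*% (sqrt(sp$gamma) * t(sp$v)) - X))
design_spectrum <- function(x, tol = 1e-12) {
  x <- as_design_matrix(x)
  if (!all(is.finite(x))) abort("`x` must be finite")
  if (all(x == 0)) abort("degenerate design: `x` has no nonzero entry")
  sv <- svd(x)
  keep <- sv$d >= tol * sv$d[1]
  structure(
    list(
      n = nrow(x), p = ncol(x), rank = sum(keep),
      u = sv$u[, keep, drop = FALSE],
      v = sv$v[, keep, drop = FALSE],
      gamma = sv$d[keep]^2
    ),
    class = "design_spectrum"
  )
}

#' @export
print.design_spectrum <- function(x, ...) {
  cat(sprintf(
    "<design_spectrum> n = %d, p = %d, rank = %d\n  gamma: %.4g ... %.4g\n",
    x$n, x$p, x$rank, x$gamma[1], x$gamma[x$rank]
  ))
  invisible(x)
}

#' @rdname design_spectrum
#' @export
as_design_spectrum <- function(x, tol = 1e-12) {
  if (inherits(x, "design_spectrum")) x else design_spectrum(x, tol = tol)
}

#' Center the response and/or center-scale the design columns
#'
#' The models in this package carry no intercept and no automatic
#' standardization; when either is wanted it is applied explicitly with
#' this helper before any fitting.
#'
#' @param x Design matrix.
#' @param y Optional response vector.
#' @param center_y Center `y` at its mean.
#' @param scale_x Center each column of `x` and scale it to unit standard
#'   deviation (constant columns are left centered but unscaled).
#' @return A list with elements `x` and `y`.
#' @export
standardize_design <- function(x, y = NULL, center_y = FALSE, scale_x = FALSE) {
  x <- as_design_matrix(x)
  if (scale_x) {
    x <- scale(x, center = TRUE, scale = FALSE)
    s <- apply(x, 2, stats::sd)
    s[s == 0] <- 1
    x <- sweep(x, 2, s, "/")
    attr(x, "scaled:center") <- NULL
  }
  if (center_y && !is.null(y)) y <- y - mean(y)
  list(x = x, y = y)
}

#' Closed-form linear ridge estimate
#'
#' Evaluates the spectral form of the linear ridge estimator,
#' `beta_lambda = sum_i sqrt(gamma_i)/(gamma_i + lambda) v_i u_i' y`,
#' which equals `(X'X + lambda I)^{-1} X'y`.  `lambda = Inf` returns the
#' zero vector (the null model).
#'
#' @param spec A [design_spectrum()], or the design matrix itself.
#' @param y Response vector of length `n`.
#' @param lambda Penalty, a single value in `[0, Inf]`.
#' @return A numeric vector of length `p`.
#' @export
ridge_estimate_linear <- function(spec, y, lambda) {
  spec <- as_design_spectrum(spec)
  check_lambda(lambda)
  if (length(y) != spec$n) {
    abort(sprintf("length(y) is %d but the design has %d rows",
                  length(y), spec$n))
  }
  if (is.infinite(lambda)) return(numeric(spec$p))
  d <- drop(crossprod(spec$u, y))
  drop(spec$v %*% (sqrt(spec$gamma) / (spec$gamma + lambda) * d))
}

#' Default penalty grid for a design
#'
#' Log-spaced grid spanning `[gamma_min * 1e-4, gamma_max * 1e4]`, wide
#' enough to cover the transition of the effective model complexity from
#' about `rank` down to about 0.  Returned in increasing order, without the
#' `Inf` sentinel (path constructors prepend it).
#'
#' @param spec A [design_spectrum()] or design matrix.
#' @param length Number of grid points.
#' @export
default_lambda_grid <- function(spec, length = 100L) {
  spec <- as_design_spectrum(spec)
  g <- spec$gamma
  10^seq(log10(min(g) * 1e-4), log10(max(g) * 1e4), length.out = length)
}

#' Ridge solution path on a penalty grid
#'
#' Materializes the closed-form linear ridge estimates on a grid of
#' penalties, always including the `Inf` sentinel (null model, exactly zero
#' coefficients) as the first, most-penalized point.  Also records the
#' effective model complexity `mc(lambda)` and the Gaussian profile
#' log-likelihood at each grid point.
#'
#' @inheritParams ridge_estimate_linear
#' @param grid Positive, finite, increasing penalty values; defaults to
#'   [default_lambda_grid()].
#' @return An object of class `ridge_path`: list with `lambda` (decreasing,
#'   `Inf` first), `beta` (length(lambda) x p matrix), `mc`, `loglik`.
#' @seealso [tidy.ridge_path()], [autoplot.ridge_path()]
#' @export
ridge_path <- function(spec, y, grid = NULL) {
  spec <- as_design_spectrum(spec)
  if (length(y) != spec$n) abort("length(y) must equal the sample count")
  grid <- grid %||% default_lambda_grid(spec)
  if (length(grid) == 0L) abort("empty penalty grid")
  if (any(!is.finite(grid)) || any(grid <= 0)) {
    abort("`grid` must contain positive finite values only")
  }
  if (is.unsorted(grid)) abort("`grid` must be sorted increasing")
  lambda <- c(Inf, rev(grid))
  d <- drop(crossprod(spec$u, y))
  g <- spec$gamma
  beta <- t(vapply(
    lambda,
    function(l) {
      if (is.infinite(l)) numeric(spec$p)
      else drop(spec$v %*% (sqrt(g) / (g + l) * d))
    },
    numeric(spec$p)
  ))
  rss <- vapply(lambda, function(l) ridge_rss(spec, y, l), numeric(1))
  structure(
    list(
      lambda = lambda,
      beta = beta,
      mc = model_complexity(spec, lambda),
      loglik = gaussian_profile_loglik(rss, spec$n)
    ),
    class = "ridge_path"
  )
}

# Residual sum of squares of the ridge fit at one lambda, O(rank) given the
# spectrum: the residual splits into the part orthogonal to col(U) and the
# shrunken part along U.
ridge_rss <- function(spec, y, lambda) {
  d <- drop(crossprod(spec$u, y))
  perp <- sum(y^2) - sum(d^2)
  a <- if (is.infinite(lambda)) rep(0, spec$rank) else
    spec$gamma / (spec$gamma + lambda)
  max(perp + sum((1 - a)^2 * d^2), 0)
}

gaussian_profile_loglik <- function(rss, n) {
  ifelse(rss <= 0, Inf, -n / 2 * (log(2 * pi * rss / n) + 1))
}

#' Effective model complexity of ridge regression
#'
#' `mc(lambda) = sum_i gamma_i / (gamma_i + lambda)`, the trace of the ridge
#' hat map: a continuous effective number of parameters, equal to the rank
#' at `lambda = 0` and to 0 at `lambda = Inf`.
#'
#' @inheritParams ridge_estimate_linear
#' @param lambda Penalty value(s), each in `[0, Inf]`.
#' @return Numeric vector the length of `lambda`.
#' @export
model_complexity <- function(spec, lambda) {
  spec <- as_design_spectrum(spec)
  check_lambda(lambda, several = TRUE)
  vapply(
    lambda,
    function(l) if (is.infinite(l)) 0 else sum(spec$gamma / (spec$gamma + l)),
    numeric(1)
  )
}
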