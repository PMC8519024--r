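# broom-style tidiers for the package's result objects.

#' Tidy a ridge path
#'
#' @param x A [ridge_path()] object.
#' @param ... Unused.
#' @return A long tibble with one row per (lambda, term): columns `lambda`,
#'   `term`, `estimate`.
#' @method tidy ridge_path
#' @export
tidy.ridge_path <- function(x, ...) {
  p <- ncol(x$beta)
  terms <- colnames(x$beta) %||% paste0("x", seq_len(p))
  tibble(
    lambda = rep(x$lambda, each = p),
    term = rep(terms, length(x$lambda)),
    estimate = as.vector(t(x$beta))
  )
}

#' @rdname tidy.ridge_path
#' @return For `glance()`: one row per grid point with `lambda`, `mc`,
#'   `loglik` and the L2 norm of the coefficient vector.
#' @method glance ridge_path
#' @export
glance.ridge_path <- function(x, ...) {
  tibble(
    lambda = x$lambda,
    mc = x$mc,
    loglik = x$loglik,
    l2_norm = sqrt(rowSums(x$beta^2))
  )
}

#' Tidy a globaltest result
#'
#' @param x A `gt_result` from [gt_test_linear()] or
#'   [gt_pvalue_asymptotic()].
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `p.value`, `method`.
#' @method tidy gt_result
#' @export
tidy.gt_result <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$pvalue, method = x$method)
}

#' @rdname tidy.gt_result
#' @method glance gt_result
#' @export
glance.gt_result <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$pvalue, method = x$method,
         n_weights = length(x$weights))
}

#' Tidy a tuning result
#'
#' @param x A `gt_tuning` from [select_lambda_gt()], [select_lambda_ft()],
#'   [ic_select()] or [cv_select()].
#' @param ... Unused.
#' @return A one-row tibble with the selected `lambda`, the `alpha` used
#'   (NA for non-region selectors), the global-null p-value, the effective
#'   complexity at the selection, and the method tag.
#' @method tidy gt_tuning
#' @export
tidy.gt_tuning <- function(x, ...) {
  tibble(
    lambda = x$lambda,
    alpha = x$alpha,
    p.value.null = x$pvalue_null,
    mc = x$mc,
    method = x$method,
    model = x$model
  )
}

#' @rdname tidy.gt_tuning
#' @method glance gt_tuning
#' @export
glance.gt_tuning <- function(x, ...) {
  tibble(
    lambda = x$lambda,
    alpha = x$alpha,
    p.value.null = x$pvalue_null,
    mc = x$mc,
    method = x$method,
    model = x$model,
    n_evals = x$n_evals,
    multi_crossing = isTRUE(x$diagnostics$multi_crossing),
    no_crossing = isTRUE(x$diagnostics$no_crossing)
  )
}

#' Tidy a design spectrum
#'
#' @param x A [design_spectrum()].
#' @param ... Unused.
#' @return A tibble with one row per retained component: `component`,
#'   `eigenvalue` (of `X'X`), `singular_value`.
#' @method tidy design_spectrum
#' @export
tidy.design_spectrum <- function(x, ...) {
  tibble(
    component = seq_len(x$rank),
    eigenvalue = x$gamma,
    singular_value = sqrt(x$gamma)
  )
}

#' @rdname tidy.design_spectrum
#' @method glance design_spectrum
#' @export
glance.design_spectrum <- function(x, ...) {
  tibble(n = x$n, p = x$p, rank = x$rank,
         condition_number = x$gamma[1] / x$gamma[x$rank])
}
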