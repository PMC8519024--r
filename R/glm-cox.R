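#' Survival response container
#'
#' A light tibble wrapper holding follow-up times and event indicators
#' (`status = 1`: the time is an observed event; `status = 0`: right
#' censored at that time).
#'
#' @param time Nonnegative follow-up times.
#' @param status 0/1 event indicators.
#' @return A tibble of class `surv_data` with columns `time` and `status`.
#' @export
surv_data <- function(time, status) {
  if (length(time) != length(status)) abort("time and status lengths differ")
  if (anyNA(time) || any(time < 0)) abort("`time` must be nonnegative")
  status <- as.integer(status)
  if (anyNA(status) || !all(status %in% c(0L, 1L))) {
    abort("`status` must be 0/1")
  }
  structure(tibble(time = as.double(time), status = status),
            class = c("surv_data", class(tibble())))
}

#' @rdname surv_data
#' @param x A `surv_data`, a data frame with `time`/`status` columns, or a
#'   `survival::Surv` object.
#' @export
as_surv_data <- function(x) {
  if (inherits(x, "surv_data")) return(x)
  if (inherits(x, "Surv")) return(surv_data(x[, "time"], x[, "status"]))
  if (is.data.frame(x) && all(c("time", "status") %in% names(x))) {
    return(surv_data(x$time, x$status))
  }
  abort("cannot interpret `x` as survival data (need time/status)")
}

logistic_mu <- function(eta) 1 / (1 + exp(-eta))

logistic_loglik <- function(x, y, beta) {
  eta <- drop(x %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

#' Ridge-penalized logistic regression
#'
#' Maximizes `l(beta) - lambda ||beta||^2` (binomial log-likelihood, no
#' intercept) by damped Newton iterations; the damping halves the step until
#' the penalized objective does not decrease.  For any `lambda > 0` the
#' objective is strictly concave so the maximizer exists even for separable
#' data; `lambda = 0` is accepted only when the unpenalized MLE exists (the
#' iteration errors out otherwise).  `lambda = Inf` returns the zero vector.
#'
#' @param x Design matrix.
#' @param y Binary 0/1 response.
#' @param lambda Ridge penalty in `[0, Inf]`.
#' @param family Only `"logistic"` is implemented; the tuning layer is
#'   family-agnostic through the score interface.
#' @param init Optional starting value (warm start).
#' @param max_iter,tol Newton controls; convergence requires the penalized
#'   gradient sup-norm below `tol`.
#' @return Coefficient vector of length `p`.
#' @export
ridge_glm_fit <- function(x, y, lambda, family = "logistic", init = NULL,
                          max_iter = 50L, tol = 1e-8) {
  family <- match.arg(family, "logistic")
  x <- as_design_matrix(x)
  check_lambda(lambda)
  if (!all(y %in% c(0, 1))) abort("`y` must be binary 0/1")
  if (length(y) != nrow(x)) abort("length(y) must equal nrow(x)")
  p <- ncol(x)
  if (is.infinite(lambda)) return(numeric(p))
  beta <- init %||% numeric(p)
  obj <- function(b) logistic_loglik(x, y, b) - lambda * sum(b^2)
  cur <- obj(beta)
  trace <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- logistic_mu(eta)
    grad <- drop(crossprod(x, y - mu)) - 2 * lambda * beta
    if (max(abs(grad)) < tol) return(beta)
    w <- mu * (1 - mu)
    hess <- crossprod(x * w, x)
    diag(hess) <- diag(hess) + 2 * lambda
    step <- solve(hess, grad)
    # step halving on objective decrease
    fac <- 1
    repeat {
      cand <- beta + fac * step
      val <- obj(cand)
      if (is.finite(val) && val >= cur - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-8) break
    }
    beta <- beta + fac * step
    cur <- obj(beta)
    trace[it] <- cur
  }
  eta <- drop(x %*% beta)
  grad <- drop(crossprod(x, y - logistic_mu(eta))) - 2 * lambda * beta
  if (max(abs(grad)) < tol) return(beta)
  abort(paste0(
    "ridge_glm_fit did not converge in ", max_iter, " iterations; ",
    "objective trace: ", paste(signif(trace, 6), collapse = ", ")
  ))
}

# Partial-likelihood quantities of the Cox model at a fixed coefficient
# vector, with Breslow handling of ties.  Returns the log partial
# likelihood, the score vector and the observed information, all computed
# in one sweep over event times: subjects enter the risk set in order of
# decreasing time and running weighted moments are updated incrementally.
cox_quantities <- function(x, surv, beta, what = c("loglik", "score", "info")) {
  surv <- as_surv_data(surv)
  x <- as_design_matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (nrow(surv) != n) abort("survival data and design sizes differ")
  if (sum(surv$status) == 0) abort("no events in the survival data")
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ord <- order(surv$time, decreasing = TRUE)
  t_s <- surv$time[ord]; d_s <- surv$status[ord]
  x_s <- x[ord, , drop = FALSE]; w_s <- w[ord]; eta_s <- eta[ord]

  loglik <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  s0 <- 0; s1 <- numeric(p); s2 <- matrix(0, p, p)
  i <- 1L
  while (i <= n) {
    # all subjects tied at this time join the risk set first
    j <- i
    while (j <= n && t_s[j] == t_s[i]) {
      xi <- x_s[j, ]
      s0 <- s0 + w_s[j]
      s1 <- s1 + w_s[j] * xi
      if ("info" %in% what) s2 <- s2 + w_s[j] * tcrossprod(xi)
      j <- j + 1L
    }
    ev <- i:(j - 1L)
    ev <- ev[d_s[ev] == 1L]
    m <- length(ev)
    if (m > 0) {
      xbar <- s1 / s0
      loglik <- loglik + sum(eta_s[ev]) - m * log(s0)
      score <- score + colSums(x_s[ev, , drop = FALSE]) - m * xbar
      if ("info" %in% what) info <- info + m * (s2 / s0 - tcrossprod(xbar))
    }
    i <- j
  }
  list(loglik = loglik, score = score, info = info)
}

#' Cox model score and observed information
#'
#' Score vector and observed information matrix of the Breslow partial
#' log-likelihood at a fixed coefficient vector.  Feeding these to
#' [gt_pvalue_asymptotic()] gives the Cox-model globaltest p-value at that
#' point, which is how the confidence-region tuning extends to survival
#' responses.
#'
#' @param x Design matrix.
#' @param surv Survival data; see [surv_data()].
#' @param beta0 Coefficient vector at which to evaluate.
#' @return A list with `score` (length p), `information` (p x p) and
#'   `loglik`.
#' @export
cox_score <- function(x, surv, beta0) {
  q <- cox_quantities(x, surv, beta0)
  list(score = q$score, information = q$info, loglik = q$loglik)
}

#' Ridge-penalized Cox regression
#'
#' Maximizes the Breslow partial log-likelihood minus `lambda ||beta||^2`
#' by damped Newton iterations; requires at least one event and
#' `lambda > 0` (or `Inf`, returning the zero vector); `lambda = 0` is
#' accepted when the unpenalized maximizer exists.
#'
#' @inheritParams ridge_glm_fit
#' @param surv Survival data; see [surv_data()].
#' @return Coefficient vector of length `p`.
#' @export
ridge_cox_fit <- function(x, surv, lambda, init = NULL, max_iter = 50L,
                          tol = 1e-8) {
  x <- as_design_matrix(x)
  surv <- as_surv_data(surv)
  check_lambda(lambda)
  p <- ncol(x)
  if (sum(surv$status) == 0) abort("no events in the survival data")
  if (is.infinite(lambda)) return(numeric(p))
  beta <- init %||% numeric(p)
  obj <- function(b) {
    cox_quantities(x, surv, b, what = "loglik")$loglik - lambda * sum(b^2)
  }
  cur <- obj(beta)
  trace <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    q <- cox_quantities(x, surv, beta)
    grad <- q$score - 2 * lambda * beta
    if (max(abs(grad)) < tol) return(beta)
    hess <- q$info
    diag(hess) <- diag(hess) + 2 * lambda
    step <- solve(hess, grad)
    fac <- 1
    repeat {
      val <- obj(beta + fac * step)
      if (is.finite(val) && val >= cur - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-8) break
    }
    beta <- beta + fac * step
    cur <- obj(beta)
    trace[it] <- cur
  }
  grad <- cox_quantities(x, surv, beta, what = "score")$score - 2 * lambda * beta
  if (max(abs(grad)) < tol) return(beta)
  abort(paste0(
    "ridge_cox_fit did not converge in ", max_iter, " iterations; ",
    "objective trace: ", paste(signif(trace, 6), collapse = ", ")
  ))
}

#' Cross-validated partial likelihood
#'
#' The Verweij-van Houwelingen form: for each fold k, fit the penalized Cox
#' model on the data without that fold and accumulate
#' `l(beta_{-k}) - l_{-k}(beta_{-k})`, where `l` is the full-data partial
#' log-likelihood and `l_{-k}` the one omitting fold k.  Higher values mean
#' better predictive ability.  Folds are stratified by event status so that
#' small data sets do not produce event-free folds; assignment is a pure
#' function of `seed`.
#'
#' @inheritParams ridge_cox_fit
#' @param k Number of folds (>= 2).
#' @param seed Integer seed controlling fold assignment.
#' @param folds Optional explicit fold labels (length n), overriding `seed`.
#' @return The cvpl value (a scalar; sums over folds).
#' @export
cvpl <- function(x, surv, lambda, k = 5L, seed = NULL, folds = NULL) {
  x <- as_design_matrix(x)
  surv <- as_surv_data(surv)
  check_lambda(lambda)
  n <- nrow(x)
  if (is.null(folds)) {
    if (k < 2) abort("`k` must be at least 2")
    folds <- make_folds(surv$status, k, seed)
  }
  total <- 0
  for (fold in sort(unique(folds))) {
    keep <- folds != fold
    if (sum(surv$status[keep]) == 0) abort("a fold has zero events")
    b <- ridge_cox_fit(x[keep, , drop = FALSE], surv[keep, ], lambda)
    ll_full <- cox_quantities(x, surv, b, what = "loglik")$loglik
    ll_out <- cox_quantities(x[keep, , drop = FALSE], surv[keep, ], b,
                             what = "loglik")$loglik
    total <- total + (ll_full - ll_out)
  }
  total
}

# Event-status-stratified fold labels; re-draws (bounded) if a training set
# would end up with zero events.
make_folds <- function(status, k, seed = NULL, max_retry = 10L) {
  n <- length(status)
  for (attempt in seq_len(max_retry)) {
    folds <- with_seed_opt(
      if (is.null(seed)) NULL else derive_seed(seed, attempt - 1L),
      {
        f <- integer(n)
        for (s in unique(status)) {
          idx <- which(status == s)
          f[idx] <- sample(rep_len(seq_len(k), length(idx)))
        }
        f
      }
    )
    ok <- all(vapply(seq_len(k),
                     function(j) sum(status[folds != j]) > 0, logical(1)))
    if (ok) return(folds)
  }
  abort("could not build folds with events in every training set")
}

#' Censoring-weighted Brier score at a horizon
#'
#' Inverse-probability-of-censoring-weighted mean squared difference between
#' predicted survival probabilities at `horizon` and the observed status.
#' Subjects with an observed event before the horizon contribute
#' `S_i(t*)^2` weighted by `1/G(t_i-)`; subjects still at risk at the
#' horizon contribute `(1 - S_i(t*))^2` weighted by `1/G(t*)`; subjects
#' censored before the horizon contribute nothing.  `G` is the Kaplan-Meier
#' estimate of the censoring distribution.  Lower is better.
#'
#' @param surv Survival data.
#' @param predicted Predicted survival probabilities `S_i(t*)`, in `[0,1]`.
#' @param horizon Evaluation time `t*`, within the follow-up range.
#' @return The Brier score (scalar).
#' @export
brier_score <- function(surv, predicted, horizon) {
  surv <- as_surv_data(surv)
  n <- nrow(surv)
  if (length(predicted) != n) abort("`predicted` must have one value per subject")
  if (anyNA(predicted) || any(predicted < 0 | predicted > 1)) {
    abort("`predicted` must be probabilities in [0, 1]")
  }
  if (horizon < 0 || horizon > max(surv$time)) {
    abort("`horizon` must lie within the follow-up range")
  }
  cens_fit <- survival::survfit(
    survival::Surv(surv$time, 1 - surv$status) ~ 1
  )
  G <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv), right = FALSE)
  # left limit G(t-): step function evaluated just below t
  G_minus <- function(t) {
    vapply(t, function(ti) {
      before <- cens_fit$time < ti
      if (!any(before)) 1 else c(1, cens_fit$surv)[max(which(before)) + 1L]
    }, numeric(1))
  }
  contrib <- numeric(n)
  event_before <- surv$time <= horizon & surv$status == 1L
  at_risk <- surv$time > horizon
  if (any(event_before)) {
    g <- G_minus(surv$time[event_before])
    if (any(g <= 0)) abort("weights undefined: censoring survival reaches 0")
    contrib[event_before] <- predicted[event_before]^2 / g
  }
  if (any(at_risk)) {
    g_star <- G(horizon)
    if (g_star <= 0) abort("weights undefined: censoring survival reaches 0")
    contrib[at_risk] <- (1 - predicted[at_risk])^2 / g_star
  }
  mean(contrib)
}
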