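# Simulation layer: spectral coefficient construction, noise calibration
# from the target explained-variance fraction, and the three experiment
# drivers (null-model selection frequency, globaltest-vs-F power
# comparison, relative prediction MSE).

#' Simulation scenario
#'
#' One cell of a simulation design: a fixed synthetic design matrix, a
#' spectral signal exponent `s`, a target explained-variance fraction `r2`
#' (0 encodes the global null), a replication count, and a seed.  Each
#' replication draws a fresh response on the fixed design; per-replication
#' seeds derive from the scenario seed by a counter so single replications
#' are reproducible in isolation.
#'
#' @param design A [design_spec()].
#' @param s Spectral exponent of the coefficient construction
#'   `beta = V gamma^{s/2}`; positive values align the signal with the
#'   large-variance principal components.
#' @param r2 Target fraction of response variance explained, in `[0, 1)`;
#'   0 means the null model (`beta` is not used, `y ~ N(0, I)`).
#' @param reps Number of replications.
#' @param alpha_levels Confidence-region levels used by region selectors.
#' @param seed Scenario seed.
#' @return A `simulation_scenario` object.
#' @export
simulation_scenario <- function(design, s = 0, r2 = 0, reps = 100L,
                                alpha_levels = c(0.05, 0.5), seed = 1L) {
  if (!inherits(design, "design_spec")) abort("`design` must be a design_spec")
  if (r2 < 0 || r2 >= 1) abort("`r2` must be in [0, 1)")
  if (reps < 1) abort("`reps` must be at least 1")
  structure(
    list(design = design, s = s, r2 = r2, reps = as.integer(reps),
         alpha_levels = alpha_levels, seed = as.integer(seed)),
    class = "simulation_scenario"
  )
}

#' Spectral coefficient construction
#'
#' `beta = V gamma^{s/2}`: the coefficient of the i-th principal component
#' direction is the i-th eigenvalue of `X'X` raised to `s/2`.  Positive `s`
#' loads the signal on the large-variance components (where the globaltest
#' is powerful), negative `s` on the small-variance ones.
#'
#' @param spec A [design_spectrum()] or design matrix.
#' @param s Spectral exponent.
#' @return Coefficient vector of length `p`; `beta'beta = sum(gamma^s)`.
#' @export
make_beta <- function(spec, s) {
  spec <- as_design_spectrum(spec)
  drop(spec$v %*% spec$gamma^(s / 2))
}

#' Noise variance matching a target explained-variance fraction
#'
#' Solves `r2 = beta'X'X beta / (beta'X'X beta + n sigma^2)` for `sigma^2`,
#' giving `sigma^2 = beta'X'X beta (1 - r2) / (n r2)`: the error variance
#' under which the true model explains exactly the fraction `r2` of the
#' response variance.
#'
#' @inheritParams make_beta
#' @param beta True coefficient vector (nonzero).
#' @param r2 Target fraction in (0, 1).
#' @return The variance `sigma^2`.
#' @export
sigma2_from_r2 <- function(spec, beta, r2) {
  spec <- as_design_spectrum(spec)
  if (r2 <= 0 || r2 >= 1) abort("`r2` must be in (0, 1)")
  signal <- sum(spec$gamma * drop(crossprod(spec$v, beta))^2)
  if (signal == 0) abort("zero signal: beta has no component in the design")
  signal * (1 - r2) / (spec$n * r2)
}

#' Draw one linear-model response
#'
#' `y = X beta + sigma epsilon` with standard normal errors; reproducible
#' given the seed.
#'
#' @param x Design matrix.
#' @param beta Coefficient vector.
#' @param sigma2 Error variance, `>= 0`.
#' @param seed Integer seed (NULL uses the ambient RNG stream).
#' @export
simulate_linear <- function(x, beta, sigma2, seed = NULL) {
  x <- as_design_matrix(x)
  if (sigma2 < 0) abort("`sigma2` must be nonnegative")
  with_seed_opt(seed, drop(x %*% beta) + sqrt(sigma2) * rnorm(nrow(x)))
}

#' Mean squared error of the linear predictor
#'
#' `MSE = mean((X beta - X beta_hat)^2)`, the in-sample prediction error of
#' an estimate against the true coefficients.
#'
#' @param x Design matrix.
#' @param beta_true,beta_hat Coefficient vectors.
#' @export
mse_of_estimate <- function(x, beta_true, beta_hat) {
  x <- as_design_matrix(x)
  mean(drop(x %*% (beta_true - beta_hat))^2)
}

# Parse method labels like "GT95", "FT50", "AIC", "GCV", "5-CV", "LOOCV"
# into a selector closure.  Region selectors get precomputed critical
# values through `ctx`.
parse_method <- function(label) {
  up <- toupper(label)
  if (grepl("^GT[0-9]+$", up)) {
    list(type = "gt", alpha = 1 - as.numeric(sub("GT", "", up)) / 100)
  } else if (grepl("^FT[0-9]+$", up)) {
    list(type = "ft", alpha = 1 - as.numeric(sub("FT", "", up)) / 100)
  } else if (up %in% toupper(ic_names)) {
    list(type = "ic", criterion = ic_names[match(up, toupper(ic_names))])
  } else if (up == "GCV") {
    list(type = "cv", method = "gcv")
  } else if (up == "LOOCV") {
    list(type = "cv", method = "loocv")
  } else if (grepl("^[0-9]+-?CV$", up)) {
    list(type = "cv", method = "kcv", k = as.integer(sub("-?CV", "", up)))
  } else if (up == "NULL") {
    list(type = "null")
  } else if (up == "ORACLE") {
    list(type = "oracle")
  } else {
    abort(sprintf("unknown method label '%s'", label))
  }
}

# Run one selector on (x, y), returning the selected lambda.
run_selector <- function(m, x, y, spec, grid, rep_seed, ctx) {
  switch(
    m$type,
    gt = select_lambda_gt(x, y, m$alpha, grid = grid,
                          critical = ctx$gt_critical[[as.character(m$alpha)]]
                          )$lambda,
    ft = select_lambda_ft(x, y, m$alpha, grid = grid)$lambda,
    ic = ic_select(x, y, m$criterion, grid = grid)$lambda,
    cv = cv_select(x, y, method = m$method, grid = grid,
                   k = m$k %||% 5L, seed = rep_seed)$lambda,
    `null` = Inf,
    oracle = abort("the oracle selector is defined only for MSE experiments")
  )
}

#' Null-model selection frequencies under a true null
#'
#' Simulates `y ~ N(0, I)` on the scenario's fixed design (the error scale
#' is immaterial: every selector involved is scale-free) and records, for
#' each method, the fraction of replications in which the null model
#' `lambda = Inf` is selected.  For the globaltest and F-test region
#' selectors this fraction estimates `1 - alpha` - the weak type-I error
#' guarantee of testimation - exactly pivotal for linear models.
#'
#' @param scenario A [simulation_scenario()] with `r2 = 0`.
#' @param methods Character labels: `"GT95"`, `"FT50"`, `"AIC"`, `"GCV"`,
#'   `"5-CV"`, `"LOOCV"`, ... (region-method digits give the confidence
#'   level in percent).
#' @param grid Optional penalty grid passed to every selector.
#' @return A tibble with columns `method`, `prop_null`, `se`, `reps`.
#' @export
run_null_experiment <- function(scenario, methods = c("GT95", "GT50"),
                                grid = NULL) {
  if (scenario$r2 != 0) abort("null experiment requires r2 = 0")
  x <- gen_design(scenario$design)
  spec <- design_spectrum(x)
  grid <- grid %||% default_lambda_grid(spec)
  parsed <- lapply(methods, parse_method)
  ctx <- list(gt_critical = list())
  for (m in parsed) {
    if (m$type == "gt") {
      key <- as.character(m$alpha)
      if (is.null(ctx$gt_critical[[key]])) {
        ctx$gt_critical[[key]] <- gt_critical_value(spec, m$alpha)
      }
    }
  }
  hits <- matrix(FALSE, scenario$reps, length(methods))
  for (i in seq_len(scenario$reps)) {
    rep_seed <- derive_seed(scenario$seed, i)
    y <- with_seed_opt(rep_seed, rnorm(spec$n))
    for (j in seq_along(parsed)) {
      lam <- run_selector(parsed[[j]], x, y, spec, grid, rep_seed, ctx)
      hits[i, j] <- is.infinite(lam)
    }
  }
  prop <- colMeans(hits)
  tibble(
    method = methods,
    prop_null = prop,
    se = sqrt(prop * (1 - prop) / scenario$reps),
    reps = scenario$reps
  )
}

#' Globaltest-vs-F-test power comparison
#'
#' For each replication of the scenario, draws a response from the linear
#' model with coefficients `beta = V gamma^{s/2}` and noise calibrated to
#' `r2`, selects the penalty by both region methods at the given level, and
#' records the fraction of replications with `lambda_gt < lambda_ft`
#' (strictly; `Inf` compares larger than any finite value, and two `Inf`
#' selections count as not-less).  A smaller selected penalty means the
#' test that defines the region rejected more of the path: the more
#' powerful test selects the less conservative model.
#'
#' @inheritParams run_null_experiment
#' @param alpha Region level for both selectors.
#' @return A tibble with columns `s`, `r2`, `prop_lt`, `se`, `reps`.
#' @export
run_power_comparison <- function(scenario, alpha = 0.05, grid = NULL) {
  if (scenario$r2 <= 0) abort("power comparison requires r2 > 0")
  x <- gen_design(scenario$design)
  spec <- design_spectrum(x)
  if (spec$p >= spec$n) abort("F-test requires n > p")
  grid <- grid %||% default_lambda_grid(spec)
  beta <- make_beta(spec, scenario$s)
  sigma2 <- sigma2_from_r2(spec, beta, scenario$r2)
  crit <- gt_critical_value(spec, alpha)
  less <- logical(scenario$reps)
  for (i in seq_len(scenario$reps)) {
    y <- simulate_linear(x, beta, sigma2, seed = derive_seed(scenario$seed, i))
    lam_gt <- select_lambda_gt(x, y, alpha, grid = grid,
                               critical = crit)$lambda
    lam_ft <- select_lambda_ft(x, y, alpha, grid = grid)$lambda
    less[i] <- lam_gt < lam_ft
  }
  prop <- mean(less)
  tibble(s = scenario$s, r2 = scenario$r2, prop_lt = prop,
         se = sqrt(prop * (1 - prop) / scenario$reps), reps = scenario$reps)
}

#' Relative prediction error of tuning methods
#'
#' For each replication, selects a penalty with every method, forms the
#' ridge estimate at the selection, and records its prediction MSE divided
#' by the null-model MSE `||X beta||^2 / n`.  Values below 1 mean the
#' method beats always choosing the null model.  The label `"null"` runs
#' the degenerate selector that always returns `lambda = Inf` (relative
#' MSE exactly 1, a sanity anchor), and `"oracle"` plugs in the true
#' coefficients (relative MSE exactly 0).
#'
#' @inheritParams run_null_experiment
#' @return A tibble with columns `method`, `rel_mse`, `se`, `reps`.
#' @export
run_mse_experiment <- function(scenario, methods = c("GT50", "GT95"),
                               grid = NULL) {
  if (scenario$r2 <= 0) abort("MSE experiment requires r2 > 0")
  x <- gen_design(scenario$design)
  spec <- design_spectrum(x)
  grid <- grid %||% default_lambda_grid(spec)
  beta <- make_beta(spec, scenario$s)
  sigma2 <- sigma2_from_r2(spec, beta, scenario$r2)
  mse_null <- mse_of_estimate(x, beta, numeric(spec$p))
  parsed <- lapply(methods, parse_method)
  ctx <- list(gt_critical = list())
  for (m in parsed) {
    if (m$type == "gt") {
      key <- as.character(m$alpha)
      if (is.null(ctx$gt_critical[[key]])) {
        ctx$gt_critical[[key]] <- gt_critical_value(spec, m$alpha)
      }
    }
  }
  rel <- matrix(NA_real_, scenario$reps, length(methods))
  for (i in seq_len(scenario$reps)) {
    rep_seed <- derive_seed(scenario$seed, i)
    y <- simulate_linear(x, beta, sigma2, seed = rep_seed)
    for (j in seq_along(parsed)) {
      bhat <- if (parsed[[j]]$type == "oracle") beta else
        ridge_estimate_linear(
          spec, y, run_selector(parsed[[j]], x, y, spec, grid, rep_seed, ctx)
        )
      rel[i, j] <- mse_of_estimate(x, beta, bhat) / mse_null
    }
  }
  tibble(
    method = methods,
    rel_mse = colMeans(rel),
    se = apply(rel, 2, stats::sd) / sqrt(scenario$reps),
    reps = scenario$reps
  )
}
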