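# Seeded generators for design matrices with controllable spectra and for
# right-censored survival responses.  Every generator is a pure function of
# its spec: identical inputs give bit-identical output.

#' Synthetic design specification
#'
#' Describes a reproducible random design matrix:
#'
#' * `iid`: independent standard normal entries;
#' * `ar1`: rows drawn from a multivariate normal with AR(1) correlation
#'   `rho^|j - k|` between columns j and k, emulating the smoothly decaying
#'   eigenvalue spectra of correlated predictors;
#' * `spiked`: columns built as `Z D^{1/2} Q'` with iid normal `Z`, a random
#'   rotation `Q`, and target eigenvalues `d_j` proportional to
#'   `j^{-decay}` (normalized to mean 1), so the eigenvalues of `X'X/n`
#'   approximate a power-law decay like those of expression data.
#'
#' @param kind Design family.
#' @param n,p Dimensions.
#' @param rho AR(1) correlation in `[0, 1)` (`ar1` only).
#' @param decay Eigenvalue decay exponent `> 0` (`spiked` only).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `design_spec` object.
#' @export
design_spec <- function(kind = c("iid", "ar1", "spiked"), n, p, rho = 0.5,
                        decay = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (n < 1 || p < 1) abort("`n` and `p` must be positive")
  if (kind == "ar1" && (rho < 0 || rho >= 1)) {
    abort("`rho` must be in [0, 1)")
  }
  if (kind == "spiked" && decay <= 0) abort("`decay` must be positive")
  structure(
    list(kind = kind, n = as.integer(n), p = as.integer(p), rho = rho,
         decay = decay, seed = as.integer(seed)),
    class = "design_spec"
  )
}

#' Generate a synthetic design matrix
#'
#' @param spec A [design_spec()].
#' @return An `n x p` numeric matrix, deterministic given the spec.
#' @export
gen_design <- function(spec) {
  if (!inherits(spec, "design_spec")) abort("`spec` must be a design_spec")
  withr::with_seed(spec$seed, {
    z <- matrix(rnorm(spec$n * spec$p), spec$n, spec$p)
    switch(
      spec$kind,
      iid = z,
      ar1 = {
        if (spec$rho == 0) z
        else z %*% chol(stats::toeplitz(spec$rho^(0:(spec$p - 1))))
      },
      spiked = {
        d <- seq_len(spec$p)^(-spec$decay)
        d <- d * spec$p / sum(d)
        q <- qr.Q(qr(matrix(rnorm(spec$p^2), spec$p, spec$p)))
        z %*% (sqrt(d) * t(q))
      }
    )
  })
}

#' Generate right-censored proportional-hazards survival data
#'
#' Event times are exponential with subject hazard
#' `baseline_rate * exp(x_i' beta)`; censoring times are independent
#' exponentials with rate `censor_rate` (no censoring when 0).  The
#' recorded time is the earlier of the two and `status = 1` marks an
#' observed event.
#'
#' @param x Design matrix.
#' @param beta Coefficient vector.
#' @param baseline_rate Baseline hazard rate, positive.
#' @param censor_rate Censoring hazard rate, `>= 0`.
#' @param seed Integer seed.
#' @return A [surv_data()] tibble.
#' @export
gen_survival <- function(x, beta, baseline_rate = 1, censor_rate = 0,
                         seed = 1L) {
  x <- as_design_matrix(x)
  if (baseline_rate <= 0) abort("`baseline_rate` must be positive")
  if (censor_rate < 0) abort("`censor_rate` must be nonnegative")
  eta <- drop(x %*% beta)
  withr::with_seed(seed, {
    t_event <- rexp(nrow(x), rate = baseline_rate * exp(eta))
    t_cens <- if (censor_rate > 0) rexp(nrow(x), rate = censor_rate) else
      rep(Inf, nrow(x))
    time <- pmin(t_event, t_cens)
    status <- as.integer(t_event <= t_cens)
    if (sum(status) == 0) abort("no events in generated data")
    surv_data(time, status)
  })
}
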