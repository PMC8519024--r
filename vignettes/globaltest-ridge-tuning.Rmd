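---
title: "Tuning ridge regression with globaltest confidence regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tuning ridge regression with globaltest confidence regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtridge)
```

## The model and the selection rule

Throughout, `X` is an $n \times p$ design matrix with thin SVD
$X = U\Gamma^{1/2}V^\top$ and $\gamma_1 \ge \dots \ge \gamma_r > 0$ the
nonzero eigenvalues of $X^\top X$.  The models carry no intercept and no
automatic column standardization; `standardize_design()` applies either
explicitly when wanted (expression matrices are often already centered,
and silent standardization changes the spectrum that everything below
depends on).

For the Gaussian linear model $y \sim N(X\beta, \sigma^2 I_n)$ the score
test of $H_0{:}\ \beta = \beta_0$ against an unstructured alternative uses
the ratio statistic
$$
S(\beta_0) \;=\; \frac{\lVert X^\top (y - X\beta_0)\rVert_2^2}
                      {\lVert y - X\beta_0\rVert_2^2},
$$
which is free of $\sigma^2$: under $H_0$ the residual is exchangeable
noise and $S$ is a pivotal ratio of quadratic forms.  Its exact null tail
is
$P(S > s) = P\bigl(\varepsilon^\top (XX^\top - sI)\varepsilon > 0\bigr)$
for standard normal $\varepsilon$, an indefinite quadratic form with
weights $\{\gamma_i - s\} \cup \{-s\ (n - r \text{ times})\}$, evaluated
by `imhof_tail()`.  Inverting the test gives the confidence region
$C_\alpha = \{\beta_0 : S(\beta_0) \le c_\alpha\}$ with $c_\alpha$ the
$1-\alpha$ null quantile (`gt_critical_value()`), and the selected penalty
is
$$
\lambda(\alpha) \;=\; \sup\{\lambda \in [0,\infty):
\hat\beta_\lambda \in C_\alpha\},
$$
with $\lambda = \infty$ (the null model, $\beta = 0$) returned whenever
the whole ridge path lies inside the region — equivalently, whenever the
globaltest of the global null has p-value $\ge \alpha$.  Because the
linear-model null distribution is exact, the null model is kept with
probability exactly $1-\alpha$ under a true null; this is the method's
weak type-I-error guarantee, and the property the acceptance script
measures.

For logistic and Cox models the exact ratio law is unavailable; there the
statistic is the squared score norm $s^\top s$ at the tested point and the
null is approximated by $\sum_i \omega_i \chi^2_1$ with $\omega_i$ the
eigenvalues of the observed information (`gt_pvalue_asymptotic()`).  The
logistic dispersion is the binomial one (fixed at 1); no method-of-moments
rescaling is applied, since the score covariance used for the weights is
the observed information at the tested point itself.

The F-test (Scheffé) region
$(\beta_0-\hat\beta)^\top X^\top X (\beta_0-\hat\beta) \le
p\hat\sigma^2 f^\alpha_{p,n-p}$ with $\hat\sigma^2 =
\lVert y - X\hat\beta\rVert^2/(n-p)$ is provided as the classical
low-dimensional baseline (`select_lambda_ft()`); it requires $n > p$ and a
full-rank design and deliberately offers no high-dimensional fallback.
For $p = 2$ the globaltest region boundary is a conic section whose type
(ellipse, parallel lines, hyperbola) is decided by the sign of
$\delta = \det(X^\top X X^\top X - c_\alpha X^\top X)$
(`conic_classify()`); the region need not be an ellipsoid, which is
exactly why it can be tighter than Scheffé's along strong principal
components.  `detectable_cov()` computes the covariance between the
spectrum $\gamma$ and the per-component explained-variance fractions
$r_i^2$; a positive value marks tested points against which the globaltest
has good power (signal on large-variance components), a negative value the
directions where the F-test is preferable.

## Tunable parameters

* `alpha` — the level of the region, in $(0,1)$.  It is the tuning knob:
  $\alpha = 0.05$ gives stringent control and conservative fits,
  $\alpha = 0.5$ tracks the effective type-I error of cross-validation
  style selectors.  Boundary ties (p-value exactly $\alpha$) count as
  inside the region, matching the closed region definition.
* `lambda` grid — `default_lambda_grid()` uses 100 log-spaced points on
  $[\gamma_{\min}\times 10^{-4},\ \gamma_1 \times 10^{4}]$, which covers
  the transition of the effective complexity
  $mc(\lambda) = \sum_i \gamma_i/(\gamma_i+\lambda)$ from $\approx r$ down
  to $\approx 0$ for any spectrum.
* `tol` — the boundary crossing is refined by bisection in
  $\log\lambda$ to relative tolerance $10^{-4}$; at that point the
  p-value at the selection agrees with $\alpha$ to well under a percent
  on smooth profiles.
* `tol` in `design_spectrum()` — singular values below $10^{-12}$ times
  the largest are treated as zero, so exactly collinear columns reduce
  the rank rather than polluting the weights of the null distribution.

## Numerical choices

**Quadratic-form tails.**  `imhof_tail()` inverts the characteristic
function.  Three regimes are distinguished because no single quadrature
strategy covers all of them: (i) threshold $0$ (the exact linear p-value):
the phase is bounded, and adaptive quadrature over a geometrically split
domain handles arbitrary weight scales; (ii) nonzero threshold: the
integrand oscillates with asymptotically constant frequency $x/2$, so the
integral is summed between consecutive zeros of the sine and the
alternating series is Euler-accelerated — this is what keeps single-weight
(chi-squared) cases accurate to $10^{-7}$ even though their envelope
decays only like $u^{-3/2}$; (iii) sign-definite weights with a threshold
on the wrong side return 0 or 1 without quadrature.  Negative thresholds
are reflected into positive ones.  The unit tests pin the implementation
against chi-squared closed forms and $10^6$-draw Monte Carlo.

**Crossing search.**  The supremum in $\lambda(\alpha)$ is located by a
descending scan of the grid followed by log-scale bisection.  If the
p-value profile crosses the level more than once (numerically possible on
rough profiles), the *largest* crossing is returned — the literal supremum
— and a `multi_crossing` diagnostic is set rather than silently picking
the first crossing encountered.  If the largest finite grid point is still
inside the region while $\lambda = \infty$ is not, the grid is extended
upward by factors of 10; if no grid point is inside, it is extended
downward, and `no_crossing` is flagged if the region is never entered.
For linear models the scan compares the statistic against the
precomputed critical value, so a full selection costs one
characteristic-function inversion (the global-null p-value) plus
$O(\text{grid})$ rank-length vector operations.

**Penalized fits.**  Logistic and Cox ridge estimates maximize
$\ell(\beta) - \lambda\lVert\beta\rVert_2^2$ by damped Newton iterations
(step halving on objective decrease, at most 50 steps, gradient sup-norm
below $10^{-8}$ at convergence).  The Cox partial likelihood uses
Breslow's tie rule — the simplest convention consistent with the score and
information sweeps, and the one `survival::coxph(ties = "breslow")`
reproduces, which the tests exploit as an independent check.  Note the
two penalty scalings in circulation: the linear path uses the closed form
$(X^\top X + \lambda I)^{-1}X^\top y$, while the likelihood families use
$\ell - \lambda\lVert\beta\rVert^2$; each family is internally consistent
and no cross-family comparison of raw $\lambda$ values is made anywhere.

**Information criteria.**  The criterion is
$-2\ell(\lambda) + \text{penalty}(mc, n, p)$ where $\ell(\lambda)$ is the
*penalized* Gaussian log-likelihood at $\hat\beta_\lambda$ with profile
variance $\lVert y - X\hat\beta_\lambda\rVert^2/n$ (a flag exposes the
unpenalized alternative for sensitivity checks).  The mBIC/mBIC2 penalties
read their dimension term as $p/4$ — the constant from the modified-BIC
literature; $p^4$ would make the penalty absurd already at $p = 50$ — and
$mc!$ is generalized to continuous complexity through
$\log\Gamma(mc+1)$.  Ties along the grid break toward larger $\lambda$,
the less complex model.  GCV skips (with a warning) grid points where
$mc \ge n$.

**Degenerate inputs.**  An all-zero design, a saturated fit (zero
residual), all-zero quadratic-form weights, survival data without events,
and event-free cross-validation folds are all hard errors with specific
messages, not silent NaNs; fold construction for `cvpl()` is stratified by
event status and re-drawn a bounded number of times before giving up.

## What the synthetic generators emulate

The full-scale experiments in this package run on synthetic designs:
real gene expression matrices are neither redistributable as test
fixtures nor necessary for validating the method's guarantees.  `design_spec()` provides iid Gaussian
entries, AR(1)-correlated rows (smooth eigenvalue decay), and a spiked
construction $X = ZD^{1/2}Q^\top$ with target spectrum
$d_j \propto j^{-\text{decay}}$ that mimics the power-law eigenvalue
decay of expression data.  Survival responses come from an exponential
proportional-hazards generator with independent exponential censoring.

What these generators do *not* emulate: heavy-tailed and skewed expression
distributions, batch structure, gene–gene correlation blocks, and
informative censoring.  Tests passing on these designs therefore validate
the *distribution theory and algorithics* (which for the linear globaltest
is exact for any fixed design), not robustness to real-data artifacts.
Quantities that depend on a specific expression matrix — power
comparisons between the region selectors, and the null-selection rates of
the IC/CV baselines — are checked as qualitative and monotone properties
on synthetic spectra, not as fixed numbers.

The simulation drivers fix $\beta = V\gamma^{s/2}$ per scenario cell
(deterministic given the design and $s$) and draw a fresh response per
replication on the fixed design, with per-replication seeds derived from
the scenario seed by a counter so any single replication can be replayed
in isolation.  The error variance is calibrated from the target explained
variance as $\sigma^2 = \beta^\top X^\top X\beta\,(1-r^2)/(nr^2)$.

## Problem sizes used in the checks

The acceptance computation uses one AR(1) design with $n = 300$,
$p = 50$ and 1000 null replications — large enough that the binomial
standard error of a 95%-level frequency is about 0.007.  The qualitative
experiments use a spiked design with $n = 100$, $p = 50$ and 200
replications per cell ($s \in \{-1, 0, 1\}$ at $r^2 = 0.1$ for the power
ordering; $s = 1$, $r^2 = 0.2$ for relative MSE), sizes at which each
cell completes in seconds while the orderings of interest are far outside
Monte-Carlo noise.  Distributional calibration uses 1000 linear and
F-test null p-values ($n = 30$, $p = 5$) and 500 Cox null p-values
($n = 200$, $p = 10$), each checked by a Kolmogorov–Smirnov test at level
0.01.

## Known limitations

* The Cox and logistic branches rely on the asymptotic weighted
  chi-squared null; at very small $n$ or extreme censoring their type-I
  error is only approximately $\alpha$ (the linear branch is exact).
* `alpha_of_lambda(..., lambda = 0)` is undefined for $p \ge n$ (the fit
  saturates and the ratio statistic degenerates); the crossing search
  never needs it, but direct calls error.
* The selector returns a single $\lambda$; no simultaneous inference
  across multiple $\alpha$ levels is attempted.
* Sparse or out-of-core designs are out of scope; the SVD is dense.
* For non-monotone p-value profiles the supremum rule is honored at grid
  resolution; pathological profiles oscillating faster than the grid
  spacing would need a finer grid.
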