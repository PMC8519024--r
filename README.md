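# gtridge

Confidence-region tuning for ridge regression, in low and high dimensions.

## The problem

Ridge regression shrinks all coefficients smoothly toward zero as its
penalty λ grows, and its practical value hinges entirely on how λ is
chosen.  Cross-validation and information criteria pick λ by optimizing a
prediction-error surrogate; neither says anything inferential about the
model they return, and under a true global null they keep selecting
nonzero coefficient vectors at substantial rates — a route by which false
predictive signatures enter the applied literature, notably in gene
expression studies where many weak effects are the norm.

`gtridge` implements a *testimation* alternative.  A confidence region for
the coefficient vector is built by inverting a score test, and the selected
model is the least complex point of the ridge path that the test cannot
reject:

* The **globaltest** statistic for H₀: β = β₀ is the squared score norm;
  for the linear model y ~ N(Xβ, σ²Iₙ) it takes the variance-free ratio
  form

  S(β₀) = ‖Xᵀ(y − Xβ₀)‖² / ‖y − Xβ₀‖²,

  whose exact null law is that of a ratio of quadratic forms in normals
  and is computed here by Imhof's characteristic-function inversion.  The
  1 − α confidence region is C_α = {β₀ : S(β₀) ≤ c_α}.  Unlike the F-test
  (Scheffé) ellipsoid, this region exists for p ≫ n, and the test behind
  it is powerful precisely against the many-weak-effects alternatives
  where ridge regression performs well.

* The **selected penalty** is λ(α) = sup{λ : β̂_λ ∈ C_α}, the first
  boundary crossing of the ridge path coming from λ = ∞.  If the whole
  path is inside the region, the null model (λ = ∞, β = 0) is selected —
  and under a true global null this happens with probability exactly
  1 − α for linear models.  The level α replaces the arbitrarily scaled λ
  as the tuning knob, with a direct type-I-error interpretation.

The same machinery runs for logistic and Cox models through the
asymptotic (weighted chi-squared) null of the score statistic, so the
method applies to censored survival responses from expression studies.
Baselines are built in for comparison: the Scheffé/F-test region (n > p),
AIC/AICc/BIC/mBIC/mBIC2/GIC/RIC on the ridge effective degrees of freedom
mc(λ) = Σᵢ γᵢ/(γᵢ+λ), and GCV/LOOCV/k-fold CV, plus cross-validated
partial likelihood and censoring-weighted Brier scores for survival
prediction.

## Worked example

A spiked-spectrum design (eigenvalues of XᵀX/n decaying like 1/j, similar
to expression data), with the signal aligned to the leading principal
components (spectral exponent s = 1) and noise calibrated so the true
model explains r² = 20% of the response variance:

```r
library(gtridge)

X     <- gen_design(design_spec("spiked", n = 100, p = 50, decay = 1, seed = 2024))
spec  <- design_spectrum(X)
beta  <- make_beta(spec, s = 1)
sigma2 <- sigma2_from_r2(spec, beta, r2 = 0.2)
y     <- simulate_linear(X, beta, sigma2, seed = 7)

fit <- select_lambda_gt(X, y, alpha = 0.5)
tidy(fit)
#> # A tibble: 1 × 6
#>   lambda alpha p.value.null    mc method model
#>    <dbl> <dbl>        <dbl> <dbl> <chr>  <chr>
#> 1   358.   0.5   0.00000472  7.75 gt     linear
```

The globaltest rejects the global null emphatically
(`p.value.null ≈ 4.7e-6`), so the null model is not an option; descending
the ridge path, the 50% confidence region is first entered at λ ≈ 358,
where the fit spends about 7.7 effective degrees of freedom.  The
selection is self-consistent — the path touches the region boundary at the
selected penalty:

```r
alpha_of_lambda(X, y, fit$lambda)
#> [1] 0.5000306
```

The ridge estimate at the selection predicts far better than the null
model (relative in-sample MSE against the true signal ≈ 0.19), while BIC
on the same data retreats to λ = ∞ and GCV lands nearby (λ ≈ 335):

```r
bh <- ridge_estimate_linear(spec, y, fit$lambda)
mse_of_estimate(X, beta, bh) / mse_of_estimate(X, beta, numeric(50))
#> [1] 0.1924818
ic_select(X, y, "BIC")$lambda   #> Inf
cv_select(X, y, "gcv")$lambda   #> 335.3061
```

`autoplot(fit)` draws the statistic profile with the critical value and
the selected λ; `ridge_path()`, `tidy()`, `glance()` and `autoplot()`
expose the whole solution path as tibbles and ggplots.  For survival data
see `select_lambda_gt(..., model = "cox")`, `cvpl()` and `brier_score()`;
a thin command-line wrapper lives at `inst/cli/gtridge.R`.

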