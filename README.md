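# lnreg

Generalized-normal modelling with the logistic-normal (LN) family: a
three-parameter symmetric generalization of the normal distribution and
its skewed extension, with maximum-likelihood fitting, quantile-based
shape diagnostics, a Monte-Carlo estimator-performance harness, and a
location-scale regression model for skewed responses.

## The model

Wrapping a baseline CDF *G* in a logistic kernel gives the Logistic-G
family

    F(x) = G^λ(x) / ( G^λ(x) + (1 − G(x))^λ ),   λ > 0.

With the normal baseline G = Φ((x−μ)/σ) this is the **logistic-normal**
LN(λ, μ, σ): symmetric about μ for every λ, exactly normal at λ = 1,
bimodal for λ below ≈ 0.5, with tail weight governed by λ
(f ~ e^{−λz²/2}|z|^{1−λ} in the tails). Raising the LN CDF to a power
α > 0 gives the **skew-LN**, whose extra parameter is a pure skewness
dial; α = λ = 1 recovers the normal. Both distributions have closed-form
quantile functions, so sampling is exact inverse transform.

On top of the distributions the package provides:

* `fit_ln()` / `fit_skew_ln()` — maximum likelihood with
  variance-matched starting values (λ₀ = π/(√3·sd(logit Φ(z_i)))),
  analytic gradients, standard errors from the numeric Hessian, AIC /
  AICC / BIC, and detection of samples whose likelihood diverges along
  the λ → ∞ (logistic-limit) ridge;
* `galton_skewness()`, `moors_kurtosis()`, `qskewnorm()`,
  `shape_surface()` — octile/quartile shape measures for any quantile
  function, including the Azzalini skew-normal comparison family;
* `run_simulation()` — relative bias and SD of the ML estimators over
  (n, λ, μ, σ) design cells;
* `fit_regression()`, `lr_test()`, `compare_models()` — the skew-LN
  location-scale regression y = xᵀβ + σZ, Z ~ skew-LN(0, 1, λ, α), with
  its nested LN / exponentiated-normal / Gaussian sub-models,
  likelihood-ratio tests and information criteria;
* `fit_normal_mixture()`, `ks_statistic()` — the bimodal-data baseline
  (two-component normal mixture by EM) and the Kolmogorov–Smirnov fit
  statistic;
* `generate_fixture()` and a command line (`inst/cli/lnreg`) for
  sampling, fitting and simulation from the shell.

## Worked example

```r
library(lnreg)

set.seed(42)
x <- rln(500, lam = 0.3, mu = 10, sigma = 1)   # strongly bimodal sample

fit <- fit_ln(x)
fit
#> Model: LN  (n = 500 )
#>                lam       mu    sigma
#> estimate  0.314798 9.942203 1.050923
#> std.error 0.060434 0.097230 0.132226
#> logLik = -1152.3771  AIC = 2310.7542  AICC = 2310.8026  BIC = 2323.3981

ln_modes(fit$estimates["lam"], fit$estimates["mu"], fit$estimates["sigma"])
#> Bimodal LN density; mode(s) at 8.1544863, 11.729919

ks_statistic(x, function(q) pln(q, fit$estimates["lam"],
                                fit$estimates["mu"], fit$estimates["sigma"]))
#> [1] 0.02858169
```

The fitted shape λ̂ ≈ 0.31 (truth 0.3) is in the bimodal regime; the
two modes sit symmetrically about μ̂ ≈ 9.94, and the K-S distance of
0.029 says the fitted CDF tracks the empirical one to within ~3% —
a close fit. Compare against a two-component normal mixture with
`fit_normal_mixture(x)` (5 parameters instead of 3).

For a skewed response regression:

```r
set.seed(7)
X <- matrix(rnorm(1000), 500, 2)
y <- 1 + X %*% c(2, -1) + 0.8 * rskewln(500, lam = 3, alpha = 2)
cmp <- compare_models(make_regression_data(y, X))
cmp$ic_table
#>     model    loglik      aic     aicc      bic k converged
#> 1 skew-LN -14.70120 41.40239 41.57278 66.69004 6      TRUE
#> 2      LN -22.37055 54.74110 54.86256 75.81414 5      TRUE
#> 3   Exp-N -15.28945 40.57889 40.70035 61.65193 5      TRUE
#> 4  normal -26.86188 61.72377 61.80458 78.58220 4      TRUE
```

The skewed error laws clearly beat the Gaussian and LN fits; the
log-likelihood ordering respects the nesting (skew-LN highest), and with
only one extra parameter the exponentiated-normal edges out the full
skew-LN on AIC for this draw. `cmp$lr_table` carries the matching LR
tests.

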