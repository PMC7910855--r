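---
title: "The logistic-normal family: models, estimation and regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The logistic-normal family: models, estimation and regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnreg)
```

## The model

The logistic-normal (LN) distribution arises from wrapping a baseline CDF
$G$ in a logistic kernel:

$$F_G(x) = \frac{G^\lambda(x)}{G^\lambda(x) + (1 - G(x))^\lambda},
\qquad \lambda > 0.$$

With the normal baseline $G(x) = \Phi((x-\mu)/\sigma)$ this gives the
three-parameter LN$(\lambda, \mu, \sigma)$ family. Its useful structure:

* it is **symmetric about $\mu$** for every $\lambda$, so the mean and
  median are both $\mu$;
* $\lambda = 1$ recovers the normal distribution exactly;
* $\lambda$ is a pure **kurtosis/modality dial**: for $\lambda$ roughly
  below 0.5 the density is bimodal with modes placed symmetrically about
  $\mu$, while for larger $\lambda$ it is unimodal at $\mu$ with tails
  that thin as $\lambda$ grows (in the tails
  $f \sim e^{-\lambda z^2/2}\,|z|^{1-\lambda}$ up to a constant);
* the quantile function is closed form,
  $Q(p) = \mu + \sigma\,\Phi^{-1}\!\big(\mathrm{logit}^{-1}(\mathrm{logit}(p)/\lambda)\big)$,
  which makes inverse-transform sampling exact and cheap.

Raising the LN CDF to a power $\alpha > 0$ gives the **skew-LN**
distribution. $\alpha$ is a skewness dial: $\alpha = 1$ is LN,
$\lambda = 1$ is the exponentiated (power) normal, and
$\alpha = \lambda = 1$ is the normal. The log-density used everywhere in
the package is

$$\log f(x) = \log\frac{\alpha\lambda}{\sigma} + \log\phi(z)
 + (\lambda\alpha - 1)\log\Phi(z) + (\lambda - 1)\log(1 - \Phi(z))
 - (\alpha + 1)\log\!\big[\Phi^\lambda(z) + (1-\Phi(z))^\lambda\big],$$

with $z = (x - \mu)/\sigma$.

### Numerical policy

Every CDF/density evaluation runs on the log scale: $\log\Phi$ and
$\log(1-\Phi)$ come from `pnorm(log.p = TRUE)` and the recurring
denominator $\log[\Phi^\lambda + (1-\Phi)^\lambda]$ is a two-term
log-sum-exp. This keeps evaluations finite for $|z|$ up to about 40 and
for shape parameters in the hundreds — real fits produce $\hat\lambda$
of that size. Beyond $|\log\lambda| = 15$ the two-term log-sum-exp loses
all significant digits to cancellation, so the likelihood optimizers cap
the shape parameters there; a fit that presses against the cap is flagged
as non-converged rather than reported.

The quantile function is evaluated as
`qnorm(plogis(qlogis(p) / lam))`, exact and stable at both ends of
$(0,1)$; the skew-LN quantile is the closed composition
$Q_{LN}(p^{1/\alpha})$ rather than numeric inversion.

## Modes

The printed stationarity condition for this family is awkward to use
directly, so the mode finder works from the derivative of the
log-density,

$$\frac{d}{dz}\log f = -z
 + (\lambda - 1)\,\phi(z)\frac{1 - 2\Phi(z)}{\Phi(z)(1-\Phi(z))}
 - 2\lambda\,\phi(z)\,
 \frac{\Phi^{\lambda-1}(z) - (1-\Phi(z))^{\lambda-1}}
      {\Phi^{\lambda}(z) + (1-\Phi(z))^{\lambda}},$$

evaluated on a 4001-point grid over $z \in [-12, 12]$; each sign change
is polished by bisection to $10^{-10}$. $z = 0$ is always a stationary
point; classification compares the density at each root with its
neighbourhood. A gradient-based search could silently miss one basin of
a bimodal density, which is why the grid-plus-bisection design was
chosen. The interval $[-12, 12]$ is generous: all modes of the family
lie within a few baseline standard deviations of $\mu$.

## Moments

Raw moments are assembled from the binomial expansion
$E[X^r] = \sum_j \binom{r}{j} 2^{j/2} \sigma^j \mu^{r-j} \xi_j$ where
$\xi_j$ is the $j$-th moment of
$\mathrm{erf}^{-1}$-transformed logistic noise. The substitution
$u = \mathrm{logit}^{-1}(\lambda t)$ turns each $\xi_j$ into a bounded
integral $\int_0^1 h(u)^j\,du$ with
$h(u) = \Phi^{-1}(\mathrm{logit}^{-1}(\mathrm{logit}(u)/\lambda))/\sqrt2$,
evaluated by adaptive quadrature (absolute tolerance $10^{-10}$). The
integrand is computed through the log-CDF so small $\lambda$ does not
overflow near $u = 1$. Odd $\xi_j$ vanish by symmetry; even ones are
integrated over the symmetric half and doubled. Moments agree with two
independent oracles in the test suite: direct quantile integrals
$\int_0^1 Q(p)^r dp$ and Monte-Carlo means over $10^6$ draws.

## Quantile-based shape measures

`galton_skewness()` and `moors_kurtosis()` are the standard quartile and
octile functionals, taking any quantile function. Two conventions are
worth stating because printed sources sometimes differ: the Moors
numerator used here is $E_7 - E_5 + E_3 - E_1$ (with the minus on the
first octile); only this form gives the normal reference value 1.2331
and positive kurtosis for symmetric laws. Galton's measure is the usual
$(Q_3 + Q_1 - 2Q_2)/(Q_3 - Q_1)$, validated against its half-normal
closed form 0.1443.

The Azzalini skew-normal ($2\phi(x)\Phi(\lambda x)$) serves as the
comparison family: its CDF is computed by adaptive quadrature of the
density (split at the kink at zero) and inverted by bracketed root
finding on $[-15, 15]$. Over its whole shape range the skew-normal
reaches only $|{\gamma_G}| \le 0.1443$ and Moors kurtosis in
$[1.1746, 1.2460]$; the skew-LN surface (`shape_surface()`) covers a
visibly wider region, which is the practical argument for the family.

## Maximum likelihood

`fit_ln()` and `fit_skew_ln()` maximize the exact log-likelihood by BFGS
in $(\log\lambda, \mu, \log\sigma[, \log\alpha])$ with analytic
gradients. Starting values follow the variance-matching construction:
$\mu_0 = \bar x$, $\sigma_0 = s$ (the $n-1$ sample SD throughout), and
$\lambda_0 = \pi/(\sqrt3\, s_T)$ where $s_T$ is the SD of
$t_i = \mathrm{logit}(\Phi((x_i - \bar x)/s))$ — under normality the
$t_i$ are exactly standard logistic, so $\lambda_0 \to 1$ there.

Three optimizer details matter and are deliberate:

* **Per-observation scaling.** The objective passed to the quasi-Newton
  routine is the mean (not the sum) negative log-likelihood. The first
  BFGS step is then of order one in the transformed parameters,
  behaving like a trust-region step; with the raw sum the first step can
  overshoot the interior optimum onto the ridge described next.
* **Convergence** requires the norm of the mean-log-likelihood gradient
  below $10^{-5}$ (a criterion that does not tighten artificially with
  $n$); unconverged runs are retried from shape starts jittered by
  factors of $1.5^{\pm 1}$, up to 10 times, keeping the best.
* **Boundary detection.** As $\lambda, \sigma \to \infty$ together the
  LN family degenerates to a logistic distribution, and for an
  appreciable fraction of small samples the likelihood increases
  monotonically along that ridge — the MLE does not exist. After
  convergence `fit_ln()` probes the profile likelihood at
  $\log\lambda + 0.5$ (re-optimizing $\mu, \sigma$): an interior local
  maximum loses likelihood there, a ridge does not. The result is the
  `boundary` flag. The probe is deliberately short-range and tight so
  weakly identified but genuine interior optima are not misclassified.

Standard errors come from the inverse numeric Hessian (central
differences, relative step $10^{-4}$) of the negative log-likelihood in
the original parameterization.

## The Monte-Carlo harness

`run_simulation()` reproduces the classical estimator-performance
design: for each $(n, \lambda, \mu, \sigma)$ cell it simulates by
inverse transform, fits each replicate, and reports the relative bias
$(\overline{\hat\theta} - \theta)/\theta$ and the SD of each estimator.
The default 2000 replications put the Monte-Carlo error on bias well
below the effects of interest at these sample sizes. Per-replicate seeds
are spawned from the master seed, so cells are independently
reproducible.

A replicate contributes only if it has a usable finite MLE: the
optimizer converged, the fit is not on the $\lambda \to \infty$ boundary
(the probe above), and $\hat\lambda \in [10^{-3}, 10^3]$. Dropped
replicates are counted (`n_converged`), and a cell losing more than 20%
is flagged. This matters scientifically: without boundary screening the
reported "bias of $\hat\lambda$" in hard cells is largely an average of
arbitrary optimizer stopping points along a flat ridge — it is
heavy-tailed and irreproducible across seeds and optimizers. With the
screening, the small-sample pattern is stable: $\hat\lambda$ and
$\hat\sigma$ are over-estimated when $\lambda < 1$ and under-estimated
when $\lambda > 1$, $\hat\mu$ is nearly unbiased, and all dispersions
shrink with $n$. Published bias figures for the hardest cell
($n = 30, \lambda = 0.5$) that are far above this package's stable
values can be reproduced only by keeping divergent replicates, which we
decline to do; the companion cell ($n = 70, \lambda = 1.5$) agrees
closely.

## Regression

The location-scale model $y_i = x_i^\top\beta + \sigma Z_i$ with
$Z_i \sim$ skew-LN$(0, 1, \lambda, \alpha)$ nests four error laws:
skew-LN (both shapes free), LN ($\alpha = 1$), exponentiated-normal
($\lambda = 1$) and the Gaussian linear model ($\alpha = \lambda = 1$),
with $k = p + 4, p + 3, p + 3, p + 2$ free parameters respectively.
Covariates are standardized by default (sample SD, $n - 1$ denominator),
with the centering/scaling pairs retained. $\beta$ and $\sigma$ start at
the least-squares solution and the shapes at 1; optimization is
L-BFGS-B with analytic gradients, the shape logs bounded by $\pm 15$
(a bound hit flags non-convergence). Wald p-values are two-sided normal;
`lr_test()` compares nested fits by $2(\ell_f - \ell_r)$ against the
chi-square — all the nulls tested here ($\alpha = 1$, $\lambda = 1$) are
interior points, so no boundary correction is needed. The skew-LN vs
normal test is mildly liberal in moderate samples (empirical size around
7% at $n$ of a few hundred) and approaches its nominal 5% by
$n = 2000$, where the test suite checks it over 500 null replications.

`compare_models()` fits all four, tabulating AIC, the small-sample
corrected AICC $= \mathrm{AIC} + 2k(k+1)/(n-k-1)$, and BIC, plus the LR
tests of the skew-LN model against each sub-model.

## What the synthetic-data generator does and does not cover

`generate_fixture()` produces LN/skew-LN samples by exact inverse
transform, regression datasets with independent standard-normal
covariates and skew-LN errors, and normal-mixture samples — the full
probabilistic structure the estimators assume, which is why parameter
recovery on fixtures is a meaningful test. Real data differ in ways the
generator deliberately does not emulate: correlated and non-Gaussian
covariates, heteroscedasticity, outliers and contamination, and
measurement rounding. Passing the suite therefore demonstrates
correctness of the computations and the estimators' behaviour under the
model, not robustness to misspecification.

## Problem sizes and defaults

The test suite uses what a desk check affords: recovery at $n = 5000$,
Kolmogorov–Smirnov checks at $n = 10^4$ draws, moment Monte-Carlo at
$10^6$, bias cells at 2000 replications (400 for companion trend cells),
and 500 null replications at $n = 500$ for the LR size. The shape-grid
searches use a coarse far grid plus shape $10^4$ for the half-normal
limit (Galton) and a 0.1-step grid near the minimum (Moors), which
locates both extrema well inside the quoted tolerances.

## Known limitations

* For small samples with $\lambda < 1$ the MLE is fragile (the paper
  trail of any such family shows the same): expect a visible share of
  boundary replicates and wide spreads.
* $\alpha$ and $\mu$ in the skew-LN are weakly identified in moderate
  samples; standard errors from the numeric Hessian can be large.
* The skew-normal quantile uses quadrature-plus-root-finding; it is
  accurate to $\sim 10^{-9}$ but not fast enough for very large grids.
* `ln_moment()` targets low-order moments ($r \lesssim 10$); large $r$
  would need specialized quadrature.
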