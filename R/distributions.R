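# Logistic-G family and the logistic-normal (LN) / skew-LN distributions.
#
# All CDF/PDF evaluations work on the log scale: log Phi and log(1 - Phi)
# come from pnorm(log.p = TRUE), and the recurring denominator term
# log(Phi^lam + (1 - Phi)^lam) is a two-term log-sum-exp.  This keeps the
# density finite for |z| up to ~40 and for shape parameters in the
# hundreds, which real fits produce.

check_ln_params <- function(lam, mu, sigma) {
  if (!is.numeric(lam) || any(!is.finite(lam)) || any(lam <= 0))
    stop("'lam' must be a finite positive number", call. = FALSE)
  if (!is.numeric(mu) || any(!is.finite(mu)))
    stop("'mu' must be finite", call. = FALSE)
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0))
    stop("'sigma' must be a finite positive number", call. = FALSE)
  invisible(TRUE)
}

check_skewln_params <- function(lam, mu, sigma, alpha) {
  check_ln_params(lam, mu, sigma)
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 0))
    stop("'alpha' must be a finite positive number", call. = FALSE)
  invisible(TRUE)
}

# log(exp(a) + exp(b)) elementwise, safe for very negative inputs
lse2 <- function(a, b) {
  m <- pmax(a, b)
  # if both are -Inf the result is -Inf, not NaN
  out <- m + log1p(exp(-abs(a - b)))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# shared log-scale pieces at standardized z: log Phi, log(1-Phi), and
# L = log(Phi^lam + (1-Phi)^lam)
ln_log_terms <- function(z, lam) {
  la <- pnorm(z, log.p = TRUE)
  lb <- pnorm(z, lower.tail = FALSE, log.p = TRUE)
  list(la = la, lb = lb, L = lse2(lam * la, lam * lb))
}

#' CDF of the Logistic-G family applied to a baseline CDF value
#'
#' The Logistic-G construction maps a baseline CDF value `u = G(x)` to
#' `u^lam / (u^lam + (1 - u)^lam)`.  With `lam = 1` the family reduces to
#' the baseline.  Computed in log space so extreme `u` does not underflow.
#'
#' @param u Baseline CDF value(s) in `[0, 1]`.
#' @param lam Positive shape parameter.
#' @return Probabilities in `[0, 1]`, nondecreasing in `u`.
#' @examples
#' logistic_g_cdf(0.75, lam = 2)  # 0.9
#' @export
logistic_g_cdf <- function(u, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("'lam' must be a finite positive scalar", call. = FALSE)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("'u' must lie in [0, 1]", call. = FALSE)
  lu <- log(u)
  l1u <- log1p(-u)
  exp(lam * lu - lse2(lam * lu, lam * l1u))
}

#' Quantile function of the Logistic-G family
#'
#' Inverts the Logistic-G CDF through the baseline quantile function:
#' `Q(p) = G^{-1}( (1 + (1/p - 1)^{1/lam})^{-1} )`.  The inner argument is
#' evaluated as `plogis(qlogis(p) / lam)`, which is exact and stable for
#' `p` near 0 or 1.
#'
#' @param p Probabilities in `(0, 1)`.
#' @param quantile_fn Baseline quantile function (e.g. `qnorm`).
#' @param lam Positive shape parameter.
#' @return Quantiles on the baseline scale.
#' @export
logistic_g_quantile <- function(p, quantile_fn, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("'lam' must be a finite positive scalar", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("'p' must lie in (0, 1)", call. = FALSE)
  quantile_fn(plogis(qlogis(p) / lam))
}

#' The logistic-normal (LN) distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the logistic-normal distribution: the Logistic-G family with a
#' normal baseline.  Its CDF is
#' \deqn{F(x) = \frac{\Phi^\lambda(z)}{\Phi^\lambda(z) + (1-\Phi(z))^\lambda},
#'       \quad z = (x-\mu)/\sigma,}
#' symmetric about \eqn{\mu} for every \eqn{\lambda > 0}, reducing to the
#' normal at \eqn{\lambda = 1}, and bimodal for small \eqn{\lambda}
#' (roughly \eqn{\lambda < 0.5}).
#'
#' @param x Vector of quantiles.
#' @param p Vector of probabilities in `(0, 1)`.
#' @param n Number of draws.
#' @param lam Positive shape parameter \eqn{\lambda} controlling kurtosis
#'   and uni/bimodality.
#' @param mu Location parameter (mean and median).
#' @param sigma Positive scale parameter.
#' @param log,log.p Logical; return log-density / accept log-probabilities.
#' @param lower.tail Logical; if `FALSE`, return `P(X > x)`.
#' @return `dln` the density, `pln` the CDF, `qln` quantiles, `rln` a
#'   numeric vector of draws (inverse transform, so reproducible under
#'   `set.seed`).
#' @examples
#' dln(0, lam = 2)            # unimodal peak at mu
#' pln(0, lam = 0.5)          # 0.5: the median is mu
#' qln(pln(1.3, lam = 3), lam = 3)
#' @name ln
NULL

#' @rdname ln
#' @export
dln <- function(x, lam, mu = 0, sigma = 1, log = FALSE) {
  check_ln_params(lam, mu, sigma)
  z <- (x - mu) / sigma
  tm <- ln_log_terms(z, lam)
  out <- log(lam) - log(sigma) + dnorm(z, log = TRUE) +
    (lam - 1) * (tm$la + tm$lb) - 2 * tm$L
  if (log) out else exp(out)
}

#' @rdname ln
#' @export
pln <- function(x, lam, mu = 0, sigma = 1, lower.tail = TRUE, log.p = FALSE) {
  check_ln_params(lam, mu, sigma)
  z <- (x - mu) / sigma
  tm <- ln_log_terms(z, lam)
  lF <- if (lower.tail) lam * tm$la - tm$L else lam * tm$lb - tm$L
  if (log.p) lF else exp(lF)
}

#' @rdname ln
#' @export
qln <- function(p, lam, mu = 0, sigma = 1) {
  check_ln_params(lam, mu, sigma)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("'p' must lie in (0, 1)", call. = FALSE)
  mu + sigma * qnorm(plogis(qlogis(p) / lam))
}

#' @rdname ln
#' @export
rln <- function(n, lam, mu = 0, sigma = 1) {
  check_ln_params(lam, mu, sigma)
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  # t ~ logistic with rate lam, then x = mu + sigma * qnorm(plogis(t));
  # collapses to the inverse transform qln(u)
  t <- qlogis(runif(n)) / lam
  mu + sigma * qnorm(plogis(t))
}

#' The skew logistic-normal (skew-LN) distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the exponentiated logistic-normal distribution with CDF
#' \eqn{F(x)^\alpha} where \eqn{F} is the LN CDF.  Reduces to LN at
#' \eqn{\alpha = 1}, to the exponentiated (power) normal at
#' \eqn{\lambda = 1}, and to the normal at \eqn{\alpha = \lambda = 1}.
#'
#' @inheritParams ln
#' @param alpha Positive skewness parameter \eqn{\alpha}.
#' @return `dskewln` the density, `pskewln` the CDF, `qskewln` quantiles,
#'   `rskewln` a numeric vector of draws.
#' @examples
#' pskewln(0, lam = 2, alpha = 3)
#' qskewln(0.5^3, lam = 2, alpha = 3)  # equals mu
#' @name skewln
NULL

#' @rdname skewln
#' @export
dskewln <- function(x, lam, mu = 0, sigma = 1, alpha = 1, log = FALSE) {
  check_skewln_params(lam, mu, sigma, alpha)
  z <- (x - mu) / sigma
  tm <- ln_log_terms(z, lam)
  out <- log(alpha) + log(lam) - log(sigma) + dnorm(z, log = TRUE) +
    (lam * alpha - 1) * tm$la + (lam - 1) * tm$lb - (alpha + 1) * tm$L
  if (log) out else exp(out)
}

#' @rdname skewln
#' @export
pskewln <- function(x, lam, mu = 0, sigma = 1, alpha = 1, log.p = FALSE) {
  check_skewln_params(lam, mu, sigma, alpha)
  lF <- alpha * pln(x, lam, mu, sigma, log.p = TRUE)
  if (log.p) lF else exp(lF)
}

#' @rdname skewln
#' @export
qskewln <- function(p, lam, mu = 0, sigma = 1, alpha = 1) {
  check_skewln_params(lam, mu, sigma, alpha)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("'p' must lie in (0, 1)", call. = FALSE)
  qln(exp(log(p) / alpha), lam, mu, sigma)
}

#' @rdname skewln
#' @export
rskewln <- function(n, lam, mu = 0, sigma = 1, alpha = 1) {
  check_skewln_params(lam, mu, sigma, alpha)
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  qskewln(runif(n), lam, mu, sigma, alpha)
}

# derivative of the LN log-density w.r.t. z at (0, 1, lam); vectorized.
# d/dz log f = -z + (lam-1) * phi * (1/Phi - 1/(1-Phi))
#            - 2 lam phi (Phi^{lam-1} - (1-Phi)^{lam-1}) / (Phi^lam + (1-Phi)^lam)
ln_dlogf_dz <- function(z, lam) {
  tm <- ln_log_terms(z, lam)
  ld <- dnorm(z, log = TRUE)
  hA <- exp(ld - tm$la)             # phi/Phi (hazard of the lower tail)
  hB <- exp(ld - tm$lb)             # phi/(1-Phi)
  wA <- exp(ld + (lam - 1) * tm$la - tm$L)  # phi Phi^{lam-1} / D
  wB <- exp(ld + (lam - 1) * tm$lb - tm$L)
  -z + (lam - 1) * (hA - hB) - 2 * lam * (wA - wB)
}

#' Modes of the LN distribution
#'
#' Locates all stationary points of the LN log-density from its analytic
#' derivative, evaluated on a dense grid of standardized values with each
#' sign change polished by bisection.  `z = 0` (i.e. `x = mu`) is always a
#' stationary point; for `lam` below roughly 0.5 it is a local minimum
#' flanked by two modes placed symmetrically about `mu`.
#'
#' @inheritParams ln
#' @param z_max Half-width of the standardized search interval.
#' @param grid_n Number of grid points used to bracket sign changes.
#' @return A list of class `ln_modes` with elements `modes` (sorted mode
#'   locations in data units, length 1 or 2) and `is_bimodal`.
#' @examples
#' ln_modes(lam = 2, mu = 3)$modes       # 3
#' ln_modes(lam = 0.3)$is_bimodal        # TRUE
#' @export
ln_modes <- function(lam, mu = 0, sigma = 1, z_max = 12, grid_n = 4001L) {
  check_ln_params(lam, mu, sigma)
  zg <- seq(-z_max, z_max, length.out = grid_n)
  g <- ln_dlogf_dz(zg, lam)
  roots <- 0                            # z = 0 is always stationary
  s <- sign(g)
  flip <- which(s[-1] * s[-length(s)] < 0)
  for (i in flip) {
    r <- uniroot(ln_dlogf_dz, lower = zg[i], upper = zg[i + 1], lam = lam,
                 tol = 1e-10)$root
    if (abs(r) > 1e-8) roots <- c(roots, r)
  }
  roots <- sort(unique(round(roots, 10)))
  # keep local maxima of the log-density
  h <- 1e-5
  f0 <- dln(mu + sigma * roots, lam, mu, sigma, log = TRUE)
  fp <- dln(mu + sigma * (roots + h), lam, mu, sigma, log = TRUE)
  fm <- dln(mu + sigma * (roots - h), lam, mu, sigma, log = TRUE)
  maxima <- roots[f0 >= fp & f0 >= fm]
  if (length(maxima) == 0L) maxima <- 0
  modes <- sort(mu + sigma * maxima)
  structure(list(modes = modes, is_bimodal = length(modes) == 2L),
            class = "ln_modes")
}

#' Raw moments of the LN distribution
#'
#' Computes \eqn{E[X^r]} through the auxiliary integrals
#' \eqn{\xi_j = \lambda \int \mathrm{erf}^{-1}(1 - 2(1+e^t)^{-1})^j
#' e^{\lambda t}(1+e^{\lambda t})^{-2}\,dt}, assembled with the binomial
#' expansion \eqn{E[X^r] = \sum_j \binom{r}{j} 2^{j/2} \sigma^j \mu^{r-j}
#' \xi_j}.  The substitution `u = plogis(lam * t)` maps each \eqn{\xi_j}
#' to a bounded integral \eqn{\int_0^1 h(u)^j du} with
#' `h(u) = qnorm(plogis(qlogis(u)/lam)) / sqrt(2)`, evaluated by adaptive
#' quadrature.  Odd \eqn{\xi_j} vanish by symmetry.
#'
#' @param r Nonnegative integer moment order.
#' @inheritParams ln
#' @param rel.tol Quadrature relative tolerance.
#' @return A list of class `ln_moment` with elements `order`, `value`
#'   (\eqn{E[X^r]}) and `xi` (numeric vector \eqn{\xi_0, \ldots, \xi_r}).
#' @examples
#' ln_moment(1, lam = 2, mu = 5)$value   # 5: the mean is mu
#' ln_moment(2, lam = 1)$value           # 1: standard normal variance
#' @export
ln_moment <- function(r, lam, mu = 0, sigma = 1, rel.tol = 1e-10) {
  check_ln_params(lam, mu, sigma)
  if (length(r) != 1L || !is.finite(r) || r < 0 || r != round(r))
    stop("'r' must be a nonnegative integer", call. = FALSE)
  # h(u) = qnorm(plogis(qlogis(u)/lam)) / sqrt(2), evaluated through the
  # log CDF so that lam < 1 does not overflow the inner logit near u = 1
  h <- function(u) {
    t <- abs(qlogis(u)) / lam
    sign(u - 0.5) *
      -qnorm(plogis(-t, log.p = TRUE), log.p = TRUE) / sqrt(2)
  }
  xi <- numeric(r + 1)
  xi[1] <- 1
  if (r >= 1) {
    for (j in seq_len(r)) {
      if (j %% 2L == 1L) {
        # odd: exactly 0 by symmetry; integrate one half as a check is
        # unnecessary, but we still evaluate to surface quadrature issues
        val <- tryCatch(
          integrate(function(u) h(u)^j, 0, 1, rel.tol = rel.tol,
                    abs.tol = 1e-10, subdivisions = 400L)$value,
          error = function(e) stop("quadrature failed for xi_", j, ": ",
                                   conditionMessage(e), call. = FALSE))
        xi[j + 1] <- val
      } else {
        # even: integrate the symmetric half and double
        val <- tryCatch(
          integrate(function(u) h(u)^j, 0.5, 1, rel.tol = rel.tol,
                    abs.tol = 1e-10, subdivisions = 400L)$value,
          error = function(e) stop("quadrature failed for xi_", j, ": ",
                                   conditionMessage(e), call. = FALSE))
        xi[j + 1] <- 2 * val
      }
    }
  }
  j <- 0:r
  value <- sum(choose(r, j) * 2^(j / 2) * sigma^j * mu^(r - j) * xi)
  structure(list(order = r, value = value, xi = xi), class = "ln_moment")
}

#' Ratio of the standard LN density to its tail approximation
#'
#' For large |z| the standard LN density behaves like
#' \eqn{e^{-\lambda z^2/2} |z|^{1 - \lambda}} up to a constant: in the
#' tail \eqn{\Phi \to 1}, \eqn{1 - \Phi \sim \phi/z} and the denominator
#' tends to 1, so \eqn{f \sim \lambda \phi^\lambda z^{-(\lambda-1)}}.
#' This returns `dln(z; 0, 1, lam)` divided by that envelope; as |z| grows
#' the log-ratio stabilizes (at \eqn{\log(\lambda (2\pi)^{-\lambda/2})}).
#'
#' @param z Standardized evaluation point(s); meaningful for |z| >= ~6.
#' @param lam Positive shape parameter.
#' @return The ratio (positive scalar/vector).
#' @export
ln_tail_ratio <- function(z, lam) {
  check_ln_params(lam, 0, 1)
  exp(dln(z, lam, 0, 1, log = TRUE) - (-lam * z^2 / 2 + (1 - lam) * log(abs(z))))
}

#' @export
print.ln_modes <- function(x, ...) {
  cat(if (x$is_bimodal) "Bimodal" else "Unimodal",
      "LN density; mode(s) at", paste(signif(x$modes, 8), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.ln_moment <- function(x, ...) {
  cat("E[X^", x$order, "] = ", format(x$value, digits = 10), "\n", sep = "")
  invisible(x)
}
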