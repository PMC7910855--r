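# Maximum-likelihood fitting of the LN and skew-LN distributions.
#
# Optimization runs unconstrained in (log lam, mu, log sigma[, log alpha])
# with analytic gradients; standard errors come from the numeric Hessian
# of the negative log-likelihood in the original parameterization.

#' LN log-likelihood
#'
#' Sum of LN log-densities over a sample, written as
#' `n log(lam/sigma) + sum log phi(z) + (lam-1) sum[log Phi(z) + log(1-Phi(z))]
#'  - 2 sum log[Phi^lam(z) + (1-Phi(z))^lam]`.
#'
#' @param x Numeric sample (length >= 1).
#' @inheritParams ln
#' @return The log-likelihood (a single number).
#' @export
ln_loglik <- function(x, lam, mu = 0, sigma = 1) {
  if (length(x) < 1L) stop("empty sample", call. = FALSE)
  sum(dln(x, lam, mu, sigma, log = TRUE))
}

#' Skew-LN log-likelihood
#'
#' @param x Numeric sample (length >= 1).
#' @inheritParams skewln
#' @return The log-likelihood (a single number).
#' @export
skewln_loglik <- function(x, lam, mu = 0, sigma = 1, alpha = 1) {
  if (length(x) < 1L) stop("empty sample", call. = FALSE)
  sum(dskewln(x, lam, mu, sigma, alpha, log = TRUE))
}

#' Starting values for LN fitting
#'
#' `mu0` is the sample mean and `sigma0` the sample SD (n-1 denominator).
#' For `lam0`, the standardized sample is pushed through the logit-normal
#' map `t_i = logit(Phi((x_i - mean)/sd))`: under the LN model the `t_i`
#' are approximately logistic with rate `lam`, whose variance is
#' `pi^2 / (3 lam^2)`, so matching variances gives
#' `lam0 = pi / (sqrt(3) * sd(t))`.
#'
#' @param x Numeric sample, length >= 3, nonconstant.
#' @return A list with `lam0`, `mu0`, `sigma0`.
#' @export
ln_initial_values <- function(x) {
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  mu0 <- mean(x)
  sigma0 <- sd(x)
  if (!is.finite(sigma0) || sigma0 <= 0)
    stop("sample is constant; cannot form starting values", call. = FALSE)
  z <- (x - mu0) / sigma0
  pz <- pmin(pmax(pnorm(z), 1e-12), 1 - 1e-12)
  t <- qlogis(pz)
  sT <- sd(t)
  list(lam0 = pi / (sqrt(3) * sT), mu0 = mu0, sigma0 = sigma0)
}

# negative log-likelihood and analytic gradient in transformed parameters
# theta = (log lam, mu, log sigma[, log alpha]); alpha fixed at 1 for LN.
skewln_negll_gr <- function(x, free_alpha) {
  n <- length(x)
  # shape parameters are capped at |log| <= 15: beyond that the two-term
  # log-sum-exp cancels catastrophically and fabricates huge likelihoods
  bad_theta <- function(theta) {
    shape_idx <- if (free_alpha) c(1L, 4L) else 1L
    any(!is.finite(theta)) || any(abs(theta) > 500) ||
      any(abs(theta[shape_idx]) > 15)
  }
  negll <- function(theta) {
    if (bad_theta(theta)) return(1e10)
    lam <- exp(theta[1]); mu <- theta[2]; sigma <- exp(theta[3])
    alpha <- if (free_alpha) exp(theta[4]) else 1
    v <- -sum(dskewln(x, lam, mu, sigma, alpha, log = TRUE))
    if (!is.finite(v)) v <- 1e10
    v
  }
  grad <- function(theta) {
    if (bad_theta(theta)) return(rep(0, length(theta)))
    lam <- exp(theta[1]); mu <- theta[2]; sigma <- exp(theta[3])
    alpha <- if (free_alpha) exp(theta[4]) else 1
    z <- (x - mu) / sigma
    tm <- ln_log_terms(z, lam)
    ld <- dnorm(z, log = TRUE)
    hA <- exp(ld - tm$la)
    hB <- exp(ld - tm$lb)
    wA <- exp(lam * tm$la - tm$L)    # softmax weight of the Phi^lam term
    wB <- exp(lam * tm$lb - tm$L)
    # d l / d z_i
    dldz <- -z + (lam * alpha - 1) * hA - (lam - 1) * hB -
      (alpha + 1) * lam * (wA * hA - wB * hB)
    dmu <- -sum(dldz) / sigma
    dsig <- -n / sigma - sum(z * dldz) / sigma
    dlam <- n / lam + alpha * sum(tm$la) + sum(tm$lb) -
      (alpha + 1) * sum(wA * tm$la + wB * tm$lb)
    g <- c(-dlam * lam, -dmu, -dsig * sigma)
    if (free_alpha) {
      dalpha <- n / alpha + lam * sum(tm$la) - sum(tm$L)
      g <- c(g, -dalpha * alpha)
    }
    g
  }
  list(negll = negll, grad = grad)
}

# shared optimizer driver with jittered restarts on the shape start values.
# Convergence is judged on the gradient of the MEAN log-likelihood (norm
# < grad_tol), so the criterion does not tighten artificially with n.
fit_mle_restarts <- function(x, theta0, free_alpha, restarts, grad_tol = 1e-5) {
  fns <- skewln_negll_gr(x, free_alpha)
  nobs <- length(x)
  # fnscale = n: quasi-Newton steps on the mean log-likelihood stay local,
  # like the trust-region steps of classical implementations; without it
  # the unit-Hessian first step can overshoot the interior optimum onto
  # the lam -> Inf ridge (where LN degenerates to a logistic fit)
  best <- NULL
  tried <- 0L
  jitter_idx <- if (free_alpha) c(1L, 4L) else 1L
  for (r in 0:restarts) {
    th <- theta0
    if (r > 0) {
      # multiplicative jitter 1.5^(+/-1) on the shape parameters
      th[jitter_idx] <- th[jitter_idx] +
        log(1.5) * sample(c(-1, 1), length(jitter_idx), replace = TRUE)
    }
    opt <- tryCatch(
      optim(th, fns$negll, fns$grad, method = "BFGS",
            control = list(maxit = 1000, reltol = 1e-14,
                           fnscale = length(x))),
      error = function(e) NULL)
    tried <- r
    if (is.null(opt)) next
    gn <- sqrt(sum((fns$grad(opt$par) / nobs)^2))
    # restarting BFGS from the optimum resets its Hessian approximation
    # and usually drives the gradient the rest of the way down
    polish <- 0L
    while (gn >= grad_tol && opt$value < 1e9 && polish < 3L) {
      opt2 <- tryCatch(
        optim(opt$par, fns$negll, fns$grad, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-14,
                           fnscale = length(x))),
        error = function(e) NULL)
      if (is.null(opt2) || opt2$value > opt$value) break
      opt <- opt2
      gn <- sqrt(sum((fns$grad(opt$par) / nobs)^2))
      polish <- polish + 1L
    }
    conv <- is.finite(opt$value) && opt$value < 1e9 && gn < grad_tol
    better <- is.null(best) || opt$value < best$value - 1e-12 ||
      (conv && !best$conv && opt$value < best$value + 1e-8)
    if (better) best <- list(par = opt$par, value = opt$value,
                             conv = conv, gnorm = gn)
    if (best$conv) break
  }
  if (is.null(best))
    stop("optimization failed in every restart", call. = FALSE)
  best$n_restarts_used <- tried
  best
}

#' Information criteria from a maximized log-likelihood
#'
#' AIC `= 2k - 2 loglik`, small-sample corrected AICC
#' `= AIC + 2k(k+1)/(n-k-1)`, and BIC `= k log(n) - 2 loglik`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size.
#' @return A named list with `aic`, `aicc`, `bic`.
#' @examples
#' information_criteria(-1444.2295, k = 8, n = 414)
#' @export
information_criteria <- function(loglik, k, n) {
  aic <- 2 * k - 2 * loglik
  list(aic = aic,
       aicc = aic + 2 * k * (k + 1) / (n - k - 1),
       bic = k * log(n) - 2 * loglik)
}

# numeric Hessian of f at par by central differences
num_hessian <- function(f, par, rel_step = 1e-4) {
  k <- length(par)
  h <- rel_step * pmax(abs(par), 1)
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- rep(0, k); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (f(par + ei) - 2 * f(par) + f(par - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(par + ei + ej) - f(par + ei - ej) -
             f(par - ei + ej) + f(par - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

se_from_hessian <- function(negll_orig, est) {
  H <- tryCatch(num_hessian(negll_orig, est), error = function(e) NULL)
  if (is.null(H)) return(rep(NA_real_, length(est)))
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) return(rep(NA_real_, length(est)))
  d <- diag(V)
  d[!is.finite(d) | d <= 0] <- NA_real_
  sqrt(d)
}

make_fit_result <- function(model, estimates, std_errors, loglik, n, k,
                            converged, n_restarts_used, extra = list()) {
  ic <- information_criteria(loglik, k, n)
  structure(c(list(model = model, estimates = estimates,
                   std_errors = std_errors, loglik = loglik,
                   aic = ic$aic, aicc = ic$aicc, bic = ic$bic,
                   n = n, k = k, converged = converged,
                   n_restarts_used = n_restarts_used), extra),
            class = "ln_fit")
}

#' @export
print.ln_fit <- function(x, ...) {
  cat("Model:", x$model, " (n =", x$n, ")\n")
  tab <- rbind(estimate = x$estimates, std.error = x$std_errors)
  print(round(tab, 6))
  cat(sprintf("logLik = %.4f  AIC = %.4f  AICC = %.4f  BIC = %.4f\n",
              x$loglik, x$aic, x$aicc, x$bic))
  if (!x$converged) cat("WARNING: optimizer did not meet the convergence criteria\n")
  invisible(x)
}

# Profile probe for a boundary (lam -> Inf) maximum.  The LN family
# degenerates to a logistic distribution as lam and sigma grow together,
# and for some samples the likelihood increases monotonically along that
# ridge: the MLE then does not exist (it sits at the boundary).  The probe
# re-maximizes the likelihood over (mu, sigma) with log(lam) pushed up by
# +0.5: at an interior local maximum the profile likelihood drops, on the
# ridge it does not.  The short step and tight band deliberately test only
# for a LOCAL maximum, so weakly identified interior optima (flat but
# genuine) are not misclassified.
ln_boundary_probe <- function(x, par, value) {
  fns <- skewln_negll_gr(x, free_alpha = FALSE)
  probe_ll <- Inf
  for (s0 in list(c(par[2], par[3]), c(par[2], par[3] + 0.5))) {
    o <- tryCatch(
      optim(s0, function(q) fns$negll(c(par[1] + 0.5, q)),
            method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o)) probe_ll <- min(probe_ll, o$value)
  }
  probe_ll <= value + 1e-3   # negll did not rise: on the ridge
}

#' Fit the LN distribution by maximum likelihood
#'
#' Maximizes the LN log-likelihood by quasi-Newton search in
#' `(log lam, mu, log sigma)` with analytic gradients, starting from
#' [ln_initial_values()] and retrying from jittered shape starts when the
#' gradient norm (of the mean log-likelihood) at the optimum exceeds the
#' tolerance.  Standard errors are from the inverse numeric Hessian in the
#' original parameterization.
#'
#' The LN likelihood can increase monotonically along the ridge
#' `lam, sigma -> Inf` on which the family degenerates to a logistic
#' distribution; for such samples no finite MLE exists.  When
#' `boundary_check = TRUE` the fit probes the profile likelihood above the
#' reported `lam` and sets the `boundary` flag if the optimum lies on that
#' ridge; boundary fits should not be interpreted as finite estimates.
#'
#' @param x Numeric sample, length >= 4.
#' @param restarts Maximum number of jittered restarts.
#' @param boundary_check Probe for a divergent (boundary) maximum.
#' @return A `ln_fit` object: `estimates` and `std_errors` (named `lam`,
#'   `mu`, `sigma`), `loglik`, `aic`, `aicc`, `bic`, `n`, `converged`,
#'   `boundary`, `n_restarts_used`.
#' @examples
#' set.seed(1)
#' fit_ln(rln(500, lam = 1.5, mu = 2, sigma = 1))
#' @export
fit_ln <- function(x, restarts = 10, boundary_check = TRUE) {
  if (length(x) < 4L) stop("need at least 4 observations", call. = FALSE)
  init <- ln_initial_values(x)
  theta0 <- c(log(init$lam0), init$mu0, log(init$sigma0))
  best <- fit_mle_restarts(x, theta0, free_alpha = FALSE, restarts = restarts)
  est <- c(lam = exp(best$par[1]), mu = best$par[2], sigma = exp(best$par[3]))
  boundary <- if (boundary_check)
    ln_boundary_probe(x, best$par, best$value) else NA
  negll_orig <- function(p) -ln_loglik(x, p[1], p[2], p[3])
  se <- se_from_hessian(negll_orig, est)
  names(se) <- names(est)
  make_fit_result("LN", est, se, -best$value, length(x), 3L,
                  best$conv, best$n_restarts_used,
                  extra = list(gradient_norm = best$gnorm, init = init,
                               boundary = boundary))
}

#' Fit the skew-LN distribution by maximum likelihood
#'
#' As [fit_ln()] with the extra skewness parameter `alpha`, started at 1.
#' With `fix_alpha = TRUE` the fit is constrained to `alpha = 1` and
#' reproduces [fit_ln()].
#'
#' @param x Numeric sample, length >= 5.
#' @param restarts Maximum number of jittered restarts.
#' @param fix_alpha Freeze `alpha` at 1 (LN sub-model).
#' @return A `ln_fit` object with parameters `lam`, `mu`, `sigma`, `alpha`.
#' @export
fit_skew_ln <- function(x, restarts = 10, fix_alpha = FALSE) {
  if (length(x) < 5L) stop("need at least 5 observations", call. = FALSE)
  if (fix_alpha) {
    f <- fit_ln(x, restarts = restarts)
    f$model <- "skew-LN (alpha fixed at 1)"
    f$estimates <- c(f$estimates, alpha = 1)
    f$std_errors <- c(f$std_errors, alpha = NA_real_)
    return(f)
  }
  init <- ln_initial_values(x)
  theta0 <- c(log(init$lam0), init$mu0, log(init$sigma0), 0)
  best <- fit_mle_restarts(x, theta0, free_alpha = TRUE, restarts = restarts)
  est <- c(lam = exp(best$par[1]), mu = best$par[2],
           sigma = exp(best$par[3]), alpha = exp(best$par[4]))
  negll_orig <- function(p) -skewln_loglik(x, p[1], p[2], p[3], p[4])
  se <- se_from_hessian(negll_orig, est)
  names(se) <- names(est)
  make_fit_result("skew-LN", est, se, -best$value, length(x), 4L,
                  best$conv, best$n_restarts_used,
                  extra = list(gradient_norm = best$gnorm, init = init))
}

#' One-sample Kolmogorov-Smirnov statistic against a fitted CDF
#'
#' `D = max_i max(i/n - F(x_(i)), F(x_(i)) - (i-1)/n)`, the sup-norm
#' distance between the empirical CDF and `cdf`.  Reported as a plain
#' descriptive fit statistic (no correction for estimated parameters).
#'
#' @param x Numeric sample.
#' @param cdf A vectorized CDF function.
#' @return The statistic, in `[0, 1]`.
#' @export
ks_statistic <- function(x, cdf) {
  n <- length(x)
  if (n < 1L) stop("empty sample", call. = FALSE)
  Fx <- cdf(sort(x))
  i <- seq_len(n)
  max(pmax(i / n - Fx, Fx - (i - 1) / n))
}

#' Fit a normal mixture by EM
#'
#' Standard EM for a k-component normal mixture (default two components:
#' parameters `pi_1..pi_{k-1}`, `mu_1..mu_k`, `sigma_1..sigma_k`).  The EM
#' log-likelihood trace is retained and is nondecreasing; degenerate
#' components (vanishing scale) trigger a restart from a perturbed
#' quantile-based split.
#'
#' @param x Numeric sample, length >= 3k.
#' @param k Number of components.
#' @param restarts Number of random restarts (the best likelihood wins).
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @return A `ln_fit` object with `estimates` (named `pi1..`, `mu1..`,
#'   `sigma1..`), `loglik`, information criteria, `converged`, plus
#'   `loglik_trace` of the final EM run and `responsibilities`.
#' @export
fit_normal_mixture <- function(x, k = 2, restarts = 5, max_iter = 500,
                               tol = 1e-10) {
  n <- length(x)
  if (n < 3 * k) stop("need at least 3k observations", call. = FALSE)
  sdx <- sd(x)
  best <- NULL
  for (r in 0:restarts) {
    # quantile split initialization, perturbed on restarts
    qs <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    mu <- if (r == 0) qs else qs + rnorm(k, 0, sdx / 4)
    sig <- rep(sdx / k, k)
    w <- rep(1 / k, k)
    trace <- numeric(0)
    ok <- TRUE
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      logd <- vapply(seq_len(k),
                     function(j) log(w[j]) + dnorm(x, mu[j], sig[j], log = TRUE),
                     numeric(n))
      m <- apply(logd, 1, max)
      ll <- sum(m + log(rowSums(exp(logd - m))))
      trace <- c(trace, ll)
      resp <- exp(logd - m - log(rowSums(exp(logd - m))))
      nk <- colSums(resp)
      w <- nk / n
      mu <- colSums(resp * x) / nk
      sig <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
      if (any(!is.finite(sig)) || any(sig < 1e-8 * sdx)) { ok <- FALSE; break }
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    if (!ok) next
    logd <- vapply(seq_len(k),
                   function(j) log(w[j]) + dnorm(x, mu[j], sig[j], log = TRUE),
                   numeric(n))
    m <- apply(logd, 1, max)
    ll <- sum(m + log(rowSums(exp(logd - m))))
    conv <- length(trace) < max_iter
    if (is.null(best) || ll > best$ll) {
      best <- list(w = w, mu = mu, sig = sig, ll = ll, trace = c(trace, ll),
                   conv = conv, r = r,
                   resp = exp(logd - m - log(rowSums(exp(logd - m)))))
    }
  }
  if (is.null(best))
    stop("EM degenerated in every restart", call. = FALSE)
  ord <- order(best$mu)
  est <- c(setNames(best$w[ord][-k], paste0("pi", seq_len(k - 1))),
           setNames(best$mu[ord], paste0("mu", seq_len(k))),
           setNames(best$sig[ord], paste0("sigma", seq_len(k))))
  make_fit_result(sprintf("%d-component normal mixture", k), est,
                  setNames(rep(NA_real_, length(est)), names(est)),
                  best$ll, n, as.integer(3 * k - 1), best$conv, best$r,
                  extra = list(loglik_trace = best$trace,
                               responsibilities = best$resp[, ord, drop = FALSE]))
}
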