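test_that("LN log-likelihood equals the summed log-density and the normal form", {
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(50, runif(1, -3, 3), runif(1, 0.5, 3))
    lam <- runif(1, 0.2, 4); mu <- runif(1, -2, 2); s <- runif(1, 0.5, 2)
    expect_equal(ln_loglik(x, lam, mu, s),
                 sum(dln(x, lam, mu, s, log = TRUE)), tolerance = 1e-10)
    expect_equal(skewln_loglik(x, lam, mu, s, alpha = 2.3),
                 sum(dskewln(x, lam, mu, s, 2.3, log = TRUE)),
                 tolerance = 1e-10)
  }
  x <- rnorm(40, 1, 2)
  expect_equal(ln_loglik(x, 1, 1, 2),
               -20 * log(2 * pi * 4) - sum((x - 1)^2) / 8,
               tolerance = 1e-10)
  expect_error(ln_loglik(numeric(0), 1), "empty")
})

test_that("starting values: moments exactly, lam0 near 1 for normal data", {
  set.seed(5)
  x <- rnorm(20000, 3, 2)
  iv <- ln_initial_values(x)
  expect_identical(iv$mu0, mean(x))
  expect_identical(iv$sigma0, sd(x))
  # under normality t_i = logit(Phi(z_i)) is exactly standard logistic,
  # whose SD is pi/sqrt(3), so lam0 -> 1
  expect_equal(iv$lam0, 1, tolerance = 0.05)
  # affine invariance of the shape start
  iv2 <- ln_initial_values(7 - 3 * x)
  expect_equal(iv2$lam0, iv$lam0, tolerance = 1e-12)
  expect_error(ln_initial_values(rep(2, 10)), "constant")
})

test_that("fit_ln recovers parameters and nests the normal model", {
  set.seed(14)
  x <- rln(5000, lam = 1.5, mu = 2, sigma = 1)
  f <- fit_ln(x)
  expect_true(f$converged)
  expect_false(f$boundary)
  expect_lt(f$gradient_norm, 1e-5)
  truth <- c(lam = 1.5, mu = 2, sigma = 1)
  expect_true(all(abs(f$estimates - truth) < 3 * f$std_errors))
  expect_equal(f$loglik, ln_loglik(x, f$estimates[1], f$estimates[2],
                                   f$estimates[3]))
  # information criteria identities
  expect_equal(f$aic, 2 * 3 - 2 * f$loglik)
  expect_equal(f$aicc, f$aic + 2 * 3 * 4 / (f$n - 4))
  expect_equal(f$bic, 3 * log(f$n) - 2 * f$loglik)

  # pure normal data: the LN fit can only do at least as well
  set.seed(15)
  z <- rnorm(400, 5, 2)
  fz <- fit_ln(z)
  mu_hat <- mean(z); s_hat <- sqrt(mean((z - mu_hat)^2))
  normal_ll <- sum(dnorm(z, mu_hat, s_hat, log = TRUE))
  expect_gte(fz$loglik, normal_ll - 1e-6)
})

test_that("fit_skew_ln recovers parameters and nests fit_ln", {
  set.seed(5)
  x <- rskewln(5000, lam = 2, mu = 0, sigma = 1, alpha = 3)
  f <- fit_skew_ln(x)
  expect_true(f$converged)
  truth <- c(lam = 2, mu = 0, sigma = 1, alpha = 3)
  expect_true(all(abs(f$estimates - truth) < 3 * f$std_errors))

  set.seed(6)
  y <- rln(400, 1.2, 1, 0.5)
  f_ln <- fit_ln(y)
  f_fixed <- fit_skew_ln(y, fix_alpha = TRUE)
  expect_equal(unname(f_fixed$estimates[c("lam", "mu", "sigma")]),
               unname(f_ln$estimates))
  f_free <- fit_skew_ln(y)
  expect_gte(f_free$loglik, f_ln$loglik - 1e-6)
})

test_that("boundary probe separates divergent ridges from interior MLEs", {
  # this draw is a known divergent case: its profile likelihood increases
  # monotonically along the lam -> Inf (logistic-limit) ridge
  set.seed(11)
  x <- rln(70, 1.5, 2, 1)
  f <- fit_ln(x)
  expect_true(f$boundary)
  # confirm the flag against the likelihood itself: pushing lam up by e^2
  # (rescaling sigma along the ridge) does not lose log-likelihood
  lam_hat <- f$estimates[["lam"]]
  up <- optim(c(f$estimates[["mu"]], log(f$estimates[["sigma"]]) + 2),
              function(q) -ln_loglik(x, lam_hat * exp(2), q[1], exp(q[2])),
              method = "Nelder-Mead", control = list(reltol = 1e-12))
  expect_gt(-up$value, f$loglik - 0.01)

  set.seed(78)
  y <- rln(400, 0.4, 0, 1)   # strongly bimodal: clearly interior MLE
  g <- fit_ln(y)
  expect_false(g$boundary)
  expect_lt(abs(g$estimates[["lam"]] - 0.4), 0.25)
})

test_that("K-S statistic: forced value, bounds, sampling consistency", {
  n <- 20
  x <- qln((1:n - 0.5) / n, 2)
  expect_equal(ks_statistic(x, function(q) pln(q, 2)), 0.5 / n)
  set.seed(4)
  y <- rln(10000, 0.3)
  D <- ks_statistic(y, function(q) pln(q, 0.3))
  expect_lt(D, 0.02)
  expect_gte(D, 0)
  # a terrible fit still yields D <= 1
  expect_lte(ks_statistic(y, function(q) pnorm(q, 50, 0.1)), 1)
})

test_that("normal-mixture EM: monotone trace, recovery, mclust agreement", {
  set.seed(9)
  x <- c(rnorm(300, 0, 1), rnorm(200, 6, 1.5))
  f <- fit_normal_mixture(x)
  expect_true(all(diff(f$loglik_trace) > -1e-8))
  expect_lt(abs(f$estimates[["mu1"]] - 0), 0.2)
  expect_lt(abs(f$estimates[["mu2"]] - 6), 0.3)
  expect_equal(f$loglik,
               sum(log(f$estimates[["pi1"]] *
                         dnorm(x, f$estimates[["mu1"]], f$estimates[["sigma1"]]) +
                       (1 - f$estimates[["pi1"]]) *
                         dnorm(x, f$estimates[["mu2"]], f$estimates[["sigma2"]]))))
  # independent EM implementation as oracle
  suppressPackageStartupMessages(library(mclust))
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(f$loglik, mc$loglik, tolerance = 1e-3)

  # single-cluster data: mixture still at least matches one normal
  set.seed(10)
  z <- rnorm(200, 1, 1)
  fz <- fit_normal_mixture(z)
  one_ll <- sum(dnorm(z, mean(z), sqrt(mean((z - mean(z))^2)), log = TRUE))
  expect_gte(fz$loglik, one_ll - 1e-6)
})
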