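test_that("logistic-G CDF matches direct arithmetic and reduces at lam = 1", {
  # u = 0.5 is the symmetry point for every shape
  for (lam in c(0.3, 1, 2, 7)) expect_equal(logistic_g_cdf(0.5, lam), 0.5)
  # lam = 1 is the identity
  u <- seq(0.01, 0.99, by = 0.07)
  expect_equal(logistic_g_cdf(u, 1), u)
  # 0.75^2 / (0.75^2 + 0.25^2) = 0.5625 / 0.625
  expect_equal(logistic_g_cdf(0.75, 2), 0.9)
  expect_true(all(diff(logistic_g_cdf(u, 0.4)) > 0))
  expect_error(logistic_g_cdf(0.5, -1), "lam")
  expect_error(logistic_g_cdf(1.2, 2), "\\[0, 1\\]")
})

test_that("logistic-G quantile inverts the CDF through the baseline", {
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(logistic_g_quantile(0.5, qnorm, 3.7), qnorm(0.5))
  expect_equal(logistic_g_quantile(p, qnorm, 1), qnorm(p))
  for (lam in c(0.3, 1, 3)) {
    x <- logistic_g_quantile(p, qnorm, lam)
    expect_equal(logistic_g_cdf(pnorm(x), lam), p, tolerance = 1e-10)
  }
  expect_error(logistic_g_quantile(0, qnorm, 1), "\\(0, 1\\)")
})

test_that("LN CDF: median at mu, normal reduction, symmetry identity", {
  expect_equal(pln(2, lam = 0.5, mu = 2, sigma = 3), 0.5)
  expect_equal(pln(2, lam = 4, mu = 2, sigma = 0.1), 0.5)
  x <- seq(-4, 4, by = 0.25)
  expect_equal(pln(x, lam = 1), pnorm(x), tolerance = 1e-12)
  for (lam in c(0.3, 2)) for (d in c(0.5, 1, 3)) {
    expect_equal(pln(5 + d, lam, 5, 1.3) + pln(5 - d, lam, 5, 1.3), 1,
                 tolerance = 1e-12)
  }
  # log-scale evaluation holds up far into the tails
  expect_true(is.finite(pln(-40, lam = 3, log.p = TRUE)))
  expect_lt(pln(-40, lam = 3, log.p = TRUE), -1000)
  expect_error(pln(0, lam = -2), "lam")
})

test_that("LN density is symmetric, normalized, and normal at lam = 1", {
  expect_equal(dln(0, 1, 0, 1, log = TRUE), dnorm(0, log = TRUE))
  x <- seq(-4, 4, by = 0.5)
  expect_equal(dln(x, 1), dnorm(x), tolerance = 1e-12)
  set.seed(1)
  d <- runif(20, 0, 6)
  for (lam in c(0.2, 0.5, 3)) {
    expect_equal(dln(1 + d, lam, 1, 2, log = TRUE),
                 dln(1 - d, lam, 1, 2, log = TRUE))
  }
  for (lam in c(0.2, 0.5, 1, 3)) {
    expect_equal(integrate(dln, -40, 40, lam = lam, rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6)
  }
})

test_that("LN quantile inverts the CDF and reduces at lam = 1", {
  expect_equal(qln(0.5, lam = 0.7, mu = -3, sigma = 2), -3)
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(qln(p, 1, 2, 1.5), 2 + 1.5 * qnorm(p), tolerance = 1e-12)
  for (lam in c(0.3, 1, 2.5)) {
    expect_equal(pln(qln(p, lam, 1, 2), lam, 1, 2), p, tolerance = 1e-10)
  }
  expect_error(qln(1, lam = 1), "\\(0, 1\\)")
})

test_that("LN sampling is reproducible and KS-consistent with the CDF", {
  set.seed(7); a <- rln(100, 2, 1, 3)
  set.seed(7); b <- rln(100, 2, 1, 3)
  expect_identical(a, b)
  for (lam in c(0.3, 1, 2)) {
    set.seed(42)
    x <- rln(10000, lam, mu = 2, sigma = 1)
    expect_lt(ks_statistic(x, function(q) pln(q, lam, 2, 1)), 0.02)
    expect_lt(abs(median(x) - 2), 3 * IQR(x) / sqrt(10000))
  }
  expect_error(rln(0, 1), "positive")
})

test_that("skew-LN reduces to LN, power-normal and normal", {
  x <- seq(-3, 5, by = 0.5)
  expect_equal(pskewln(x, lam = 1.7, mu = 1, alpha = 1), pln(x, 1.7, 1))
  expect_equal(pskewln(x, lam = 1, alpha = 2.5), pnorm(x)^2.5,
               tolerance = 1e-12)
  expect_equal(pskewln(x, lam = 1, alpha = 1), pnorm(x), tolerance = 1e-12)
  expect_equal(dskewln(x, 2.2, 0.5, 1.1, alpha = 1, log = TRUE),
               dln(x, 2.2, 0.5, 1.1, log = TRUE))
})

test_that("skew-LN density integrates to 1 and differentiates the CDF", {
  for (lam in c(0.5, 2)) for (alpha in c(0.5, 3)) {
    expect_equal(
      integrate(dskewln, -40, 40, lam = lam, alpha = alpha,
                rel.tol = 1e-9)$value,
      1, tolerance = 1e-6)
  }
  # central difference of the CDF vs the density
  x <- seq(-3, 3, by = 0.25); h <- 1e-5
  num <- (pskewln(x + h, 0.8, alpha = 2.5) -
            pskewln(x - h, 0.8, alpha = 2.5)) / (2 * h)
  expect_equal(num, dskewln(x, 0.8, alpha = 2.5), tolerance = 1e-6)
})

test_that("skew-LN quantile and sampling round-trip", {
  expect_equal(qskewln(0.5, 1.4, mu = 7, alpha = 1), 7)
  # p = 0.5^alpha maps back to the LN median
  for (alpha in c(0.4, 1, 3.7)) {
    expect_equal(qskewln(0.5^alpha, 2, mu = 1, alpha = alpha), 1,
                 tolerance = 1e-12)
  }
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(pskewln(qskewln(p, 0.7, alpha = 2.5), 0.7, alpha = 2.5), p,
               tolerance = 1e-8)
  set.seed(3); a <- rskewln(50, 2, 0, 1, 3)
  set.seed(3); b <- rskewln(50, 2, 0, 1, 3)
  expect_identical(a, b)
  set.seed(8)
  x <- rskewln(10000, 1.6, 2, 0.5, 2.4)
  expect_lt(ks_statistic(x, function(q) pskewln(q, 1.6, 2, 0.5, 2.4)), 0.02)
  # alpha = lam = 1 draws are plain normal
  set.seed(9)
  z <- rskewln(20000, 1, 3, 2, 1)
  expect_lt(abs(mean(z) - 3), 4 * 2 / sqrt(20000))
  expect_lt(abs(sd(z) - 2), 0.06)
})

test_that("mode finder matches a brute-force grid and the lam regimes", {
  m <- ln_modes(lam = 2, mu = 3, sigma = 1)
  expect_false(m$is_bimodal)
  expect_equal(m$modes, 3)
  m2 <- ln_modes(lam = 0.3)
  expect_true(m2$is_bimodal)
  expect_equal(length(m2$modes), 2L)
  expect_equal(m2$modes[1], -m2$modes[2], tolerance = 1e-8)
  # mu is a local minimum between the two modes
  expect_lt(dln(0, 0.3, log = TRUE), dln(m2$modes[1], 0.3, log = TRUE))

  # brute-force argmax oracle on a dense grid
  zg <- seq(-8, 8, length.out = 1e5)
  for (lam in c(0.3, 0.8, 2)) {
    dens <- dln(zg, lam)
    top <- zg[which.max(dens)]
    mm <- ln_modes(lam)
    expect_lt(min(abs(mm$modes - top)), 2 * (zg[2] - zg[1]))
  }

  for (lam in c(0.6, 0.8, 1, 2, 5, 10)) {
    expect_false(ln_modes(lam)$is_bimodal)
  }
  for (lam in c(0.1, 0.2, 0.3, 0.4)) {
    mm <- ln_modes(lam, mu = 5, sigma = 2)
    expect_true(mm$is_bimodal)
    expect_equal(mean(mm$modes), 5, tolerance = 1e-7)
  }
})

test_that("moments: binomial assembly matches independent oracles", {
  expect_equal(ln_moment(0, 3)$value, 1)
  expect_equal(ln_moment(1, 2, mu = 5, sigma = 3)$value, 5, tolerance = 1e-9)
  expect_equal(ln_moment(2, 1)$value, 1, tolerance = 1e-9)
  # odd central moments vanish
  for (r in c(1, 3, 5)) {
    expect_equal(ln_moment(r, 0.7)$value, 0, tolerance = 1e-8)
  }
  expect_equal(ln_moment(1, 2)$xi[2], 0, tolerance = 1e-8)
  # quantile-integral oracle: E[X^2] = int_0^1 Q(p)^2 dp
  q2 <- integrate(function(p) qln(p, 0.5)^2, 0, 1, rel.tol = 1e-10)$value
  expect_equal(ln_moment(2, 0.5)$value, q2, tolerance = 1e-8)
  # Monte-Carlo oracle for E[X^3] at (lam, mu, sigma) = (2, 1, 2)
  set.seed(99)
  x <- rln(1e6, 2, 1, 2)
  mc_se <- sd(x^3) / sqrt(1e6)
  expect_lt(abs(ln_moment(3, 2, 1, 2)$value - mean(x^3)), 3 * mc_se)
  expect_error(ln_moment(1.5, 1), "nonnegative integer")
})

test_that("tail ratio is symmetric and stabilizes for large |z|", {
  expect_equal(ln_tail_ratio(8, 0.7), ln_tail_ratio(-8, 0.7))
  for (lam in c(0.5, 1, 3)) {
    lr8 <- log(ln_tail_ratio(8, lam))
    lr10 <- log(ln_tail_ratio(10, lam))
    expect_lt(abs(lr10 - lr8), 0.05 * abs(lr8))
  }
  # lam = 1 reduces to the normal where the ratio is exactly 1/sqrt(2*pi)
  expect_equal(log(ln_tail_ratio(9, 1)), -log(sqrt(2 * pi)))
  # lam > 1: tails fall faster than the normal
  expect_lt(dln(6, 3, log = TRUE), dnorm(6, log = TRUE))
})
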