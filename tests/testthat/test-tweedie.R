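# Compound Poisson-gamma distribution: reparameterization, series density,
# sampling, unit deviance.

test_that("compound Poisson form matches the closed-form map and its mean
           identity", {
  cp <- to_compound_poisson(tweedie_params(1, 1, 1.5))
  expect_equal(cp$lam, 2)
  expect_equal(cp$shape, 1)
  expect_equal(cp$scale, 0.5)
  set.seed(11)
  for (i in 1:100) {
    mu <- runif(1, 0.05, 50); phi <- runif(1, 0.05, 4)
    p <- runif(1, 1.01, 1.99)
    cp <- suppressWarnings(to_compound_poisson(tweedie_params(mu, phi, p)))
    expect_lt(abs(cp$lam * cp$shape * cp$scale - mu), 1e-10)
  }
})

test_that("parameter validation rejects p outside (1,2) and warns near the
           boundary", {
  expect_error(tweedie_params(1, 1, 2), "p must lie")
  expect_error(tweedie_params(1, 1, 0.5), "p must lie")
  expect_error(tweedie_params(-1, 1, 1.5), "mu")
  expect_error(tweedie_params(1, 0, 1.5), "phi")
  expect_warning(to_compound_poisson(tweedie_params(1, 1, 1.9999)), "boundary")
  expect_warning(to_compound_poisson(tweedie_params(1, 1, 1.0001)), "boundary")
})

test_that("zero mass is exp(-lam) and matches Monte-Carlo zero frequency", {
  tw <- tweedie_params(1, 1, 1.5)
  expect_equal(tweedie_log_density(0, tw), -2)
  n <- 2e5
  s <- tweedie_sample(tw, n, seed = 101)
  p0 <- exp(-2)
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(s == 0) - p0), 3 * se)
})

test_that("series density equals the brute-force convolution oracle", {
  for (pars in list(c(2, 0.5, 1.3), c(0.3, 1.2, 1.7), c(10, 0.1, 1.15))) {
    tw <- tweedie_params(pars[1], pars[2], pars[3])
    cp <- suppressWarnings(to_compound_poisson(tw))
    y <- seq(0.05, 10 * pars[1], length.out = 40)
    ld <- tweedie_log_density(y, tw)
    oracle <- vapply(y, function(yy) {
      j <- 1:5000
      lt <- dpois(j, cp$lam, log = TRUE) +
        dgamma(yy, shape = j * cp$shape, scale = cp$scale, log = TRUE)
      m <- max(lt)
      m + log(sum(exp(lt - m)))
    }, 0)
    expect_lt(max(abs(expm1(ld - oracle))), 1e-8)
  }
})

test_that("series density agrees with an independent implementation (mgcv)", {
  skip_if_not_installed("mgcv")
  y <- c(0.01, 0.3, 1, 2.7, 8, 30)
  for (pars in list(c(2, 0.5, 1.3), c(1, 1, 1.5), c(5, 2, 1.8))) {
    ld <- tweedie_log_density(y, tweedie_params(pars[1], pars[2], pars[3]))
    ref <- mgcv::ldTweedie(y, mu = pars[1], p = pars[3], phi = pars[2])[, 1]
    expect_equal(ld, ref, tolerance = 1e-10)
  }
})

test_that("density plus zero mass integrates to one", {
  tw <- tweedie_params(2, 0.7, 1.4)
  # substitute y = exp(u) to tame the possible integrable singularity at 0
  f <- function(u) exp(tweedie_log_density(exp(u), tw) + u)
  total <- stats::integrate(f, -40, log(400), rel.tol = 1e-10)$value +
    exp(tweedie_log_density(0, tw))
  expect_lt(abs(total - 1), 1e-6)
})

test_that("negative observations are rejected and the density handles
           vector mu", {
  tw <- tweedie_params(c(1, 2, 4), 0.5, 1.4)
  expect_error(tweedie_log_density(-0.1, tweedie_params(1, 1, 1.5)),
               "non-negative")
  ld <- tweedie_log_density(c(1, 1, 1), tw)
  one <- vapply(c(1, 2, 4), function(m)
    tweedie_log_density(1, tweedie_params(m, 0.5, 1.4)), 0)
  expect_equal(ld, one)
})

test_that("sampling is reproducible and matches the moment identities", {
  tw <- tweedie_params(3, 0.6, 1.35)
  s1 <- tweedie_sample(tw, 1000, seed = 5)
  s2 <- tweedie_sample(tw, 1000, seed = 5)
  expect_identical(s1, s2)
  n <- 3e5
  s <- tweedie_sample(tw, n, seed = 6)
  v_target <- 0.6 * 3^1.35
  se_mean <- sqrt(v_target / n)
  expect_lt(abs(mean(s) - 3), 4 * se_mean)
  m2 <- s - mean(s)
  se_var <- sqrt((mean(m2^4) - mean(m2^2)^2) / n)
  expect_lt(abs(var(s) - v_target), 4 * se_var)
})

test_that("unit deviance: zero at the mean, known value at y = 0, positive
           elsewhere, consistent with density ratios", {
  expect_equal(tweedie_unit_deviance(3, 3, 1.5), 0)
  expect_equal(tweedie_unit_deviance(3, 3, 1.2), 0)
  expect_equal(tweedie_unit_deviance(0, 1, 1.5), 4)
  set.seed(8)
  y <- runif(50, 0.1, 20); mu <- runif(50, 0.1, 20)
  d <- tweedie_unit_deviance(y, mu, 1.4)
  expect_true(all(d[abs(y - mu) > 1e-12] > 0))
  # EDM identity: f(y; mu, phi) = a(y, phi) exp(-d(y, mu)/(2 phi)) implies
  # d(y, mu2) - d(y, mu1) = 2 phi [log f(y; mu1) - log f(y; mu2)] exactly
  phi <- 0.8; p <- 1.3
  y0 <- 2.7; mu1 <- 1.5; mu2 <- 6
  lhs <- tweedie_unit_deviance(y0, mu2, p) - tweedie_unit_deviance(y0, mu1, p)
  rhs <- 2 * phi * (tweedie_log_density(y0, tweedie_params(mu1, phi, p)) -
                      tweedie_log_density(y0, tweedie_params(mu2, phi, p)))
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_error(tweedie_unit_deviance(1, 1, 2.5), "p must lie")
})

test_that("log density is continuous in p at fixed y", {
  y0 <- 2.5
  for (p0 in c(1.05, 1.3, 1.6, 1.95)) {
    h <- 1e-8
    f1 <- tweedie_log_density(y0, tweedie_params(2, 0.7, p0))
    f2 <- tweedie_log_density(y0, tweedie_params(2, 0.7, p0 + h))
    expect_lt(abs(f2 - f1), 1e-6)
  }
})
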