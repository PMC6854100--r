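# Data model: normalization, the two mean structures, likelihood and prior.

test_that("covariate normalization z-scores with the population sd and
           records the scaling", {
  y <- matrix(c(1, 2, 3, 2, 1, 4), 3, 2)
  pan <- toy_panel(y)
  pan$x_site[, "northing"] <- c(1, 2, 3)
  nm <- normalize_covariates(pan)
  expect_equal(nm$panel$x_site[, "northing"],
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  sc <- nm$scaling
  expect_equal(sc$sd[sc$name == "northing"], sqrt(2 / 3), tolerance = 1e-9)
  # habitat factor passes through untouched
  expect_equal(nm$panel$x_site[, "habitat"], pan$x_site[, "habitat"],
               ignore_attr = TRUE)
  # idempotence on an already-standardized column
  z <- c(-1, 0, 1) * sqrt(3 / 2)
  pan2 <- toy_panel(y)
  pan2$x_site[, "easting"] <- z
  nm2 <- normalize_covariates(pan2)
  expect_equal(nm2$panel$x_site[, "easting"], z, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(nm2$scaling$sd[nm2$scaling$name == "easting"], 1,
               tolerance = 1e-9)
})

test_that("a constant covariate fails with its name in the message", {
  pan <- toy_panel(matrix(1:6, 3, 2))
  pan$v_time[, , "sparrowhawk"] <- 2
  expect_error(normalize_covariates(pan), "sparrowhawk")
})

test_that("standard means: null coefficients give flat trajectories and a
           constant covariate gives exact geometric growth", {
  pan <- random_panel(n = 3, T = 5)
  st <- toy_state(3, mu0 = c(2, 10, 40))
  st$gamma_dd <- 0
  mu <- means_standard(st, pan)
  expect_equal(mu, matrix(c(2, 10, 40), 3, 5), ignore_attr = TRUE)
  # v identically 1 after scaling, gamma = log 2 on one covariate
  pan2 <- pan
  pan2$v_time[] <- 0
  pan2$v_time[, , 1] <- 1
  st$gamma <- c(log(2), 0, 0)
  mu2 <- means_standard(st, pan2)
  expect_equal(mu2, outer(c(2, 10, 40), 2^(1:5)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("standard means match an independent R recursion including
           centred density dependence", {
  pan <- random_panel(n = 3, T = 4, seed = 21)
  set.seed(22)
  st <- toy_state(3, gamma = rnorm(3, 0, 0.05), gamma_dd = -0.04,
                  eps = rnorm(3, 0, 0.1), mu0 = c(3, 8, 20))
  mu <- means_standard(st, pan)
  for (i in 1:3) {
    lm_prev <- log(st$mu0[i])
    for (t in 1:4) {
      lm_cur <- lm_prev + sum(pan$v_time[i, t, ] * st$gamma) +
        st$gamma_dd * (exp(lm_prev) / pan$dd_ref - 1) + st$eps[i]
      expect_equal(log(mu[i, t]), lm_cur, tolerance = 1e-12)
      lm_prev <- lm_cur
    }
  }
  # telescoping identity without density dependence
  st$gamma_dd <- 0
  mu <- means_standard(st, pan)
  for (i in 1:3) {
    rhs <- sum(pan$v_time[i, , ] %*% st$gamma) + 4 * st$eps[i]
    expect_equal(log(mu[i, 4]) - log(st$mu0[i]), rhs, tolerance = 1e-10)
  }
})

test_that("standard means error on divergent states", {
  pan <- random_panel(n = 2, T = 30)
  st <- toy_state(2, eps = c(3, 0), mu0 = c(5, 5), gamma_dd = 0)
  expect_error(means_standard(st, pan), "divergent")
})

test_that("change means: baseline year anchors at mu0, no covariate change
           gives a constant mean, and a doubled covariate scales by
           2^gamma", {
  T <- 5
  y <- matrix(rep(c(4, 7), T), 2, T)
  v <- array(1, c(2, T, 3),
             dimnames = list(NULL, NULL,
                             c("sparrowhawk", "collared_dove", "frost_days")))
  pan <- normalize_covariates(toy_panel(y, v = NULL))$panel
  pan$v_time_raw[] <- 1  # no change anywhere
  spec <- model_spec("change")
  st <- toy_state(2, eps = c(0.3, -0.2), mu0 = c(4, 7), gamma_dd = 0,
                  gamma = c(0.5, -0.2, 0.1))
  mu <- means_change(st, pan, spec)
  expect_equal(mu[, 1], c(4, 7))                       # augmented baseline
  expect_equal(mu[1, 2:T], rep(exp(0.3), T - 1))       # constant after
  expect_equal(mu[2, 2:T], rep(exp(-0.2), T - 1))
  # predator covariate doubles (with the +1 offset) from year 2 on
  pan$v_time_raw[, , "sparrowhawk"] <- 1
  pan$v_time_raw[, 2:T, "sparrowhawk"] <- 3  # (3+1)/(1+1) = 2
  st$gamma <- c(-0.0325, 0, 0)
  st$eps <- c(0, 0)
  mu <- means_change(st, pan, spec)
  expect_equal(mu[1, 3], 2^-0.0325, tolerance = 1e-12)
  expect_equal(100 * (1 - mu[1, 3]), 2.2, tolerance = 0.05)
  # gamma = 0: identical across years regardless of covariates
  st$gamma <- c(0, 0, 0)
  mu <- means_change(st, pan, spec)
  expect_true(all(abs(mu[, 2:T] - 1) < 1e-14))
})

test_that("log likelihood is the sum of cell densities over observed cells
           only", {
  y <- matrix(c(1.2, NA, 0, 4.5, 2.2, NA, NA, 3.3, 0.4), 3, 3)
  pan <- normalize_covariates(toy_panel(y))$panel
  spec <- model_spec("standard")
  st <- toy_state(3, gamma = c(0.01, -0.02, 0.01), gamma_dd = -0.01,
                  eps = c(0.05, -0.02, 0), mu0 = c(2, 3, 1), phi = 0.8,
                  p = 1.4)
  ll <- log_likelihood(st, pan, spec)
  mu <- means_standard(st, pan, spec)
  oracle <- 0
  for (i in 1:3) for (t in 1:3) if (!is.na(y[i, t]))
    oracle <- oracle + tweedie_log_density(
      y[i, t], tweedie_params(mu[i, t], st$phi, st$p))
  expect_equal(ll, oracle, tolerance = 1e-10)
  # single observed cell: mask everything else
  pan1 <- normalize_covariates(toy_panel(matrix(c(2.5, 1, 1, 1), 2, 2)))$panel
  pan1$obs[] <- FALSE
  pan1$obs[1, 1] <- TRUE
  st1 <- toy_state(2, mu0 = c(3, 3), gamma_dd = 0)
  ll1 <- log_likelihood(st1, pan1, spec)
  mu1 <- means_standard(st1, pan1, spec)
  expect_equal(ll1, tweedie_log_density(2.5, tweedie_params(mu1[1, 1], 1, 1.5)))
  # fully masked panel contributes nothing
  ep <- empty_panel()
  ep$normalized <- TRUE
  expect_equal(log_likelihood(st1, ep, spec), 0)
})

test_that("excluding a covariate and zeroing its coefficient give identical
           likelihoods", {
  pan <- random_panel(n = 4, T = 5, seed = 31)
  spec <- model_spec("standard")
  st_in <- toy_state(4, gamma = c(0, 0.02, -0.01), mu0 = rep(5, 4),
                     gamma_dd = -0.02)
  st_out <- st_in
  st_out$inc_gamma <- c(0L, 1L, 1L)
  expect_identical(log_likelihood(st_in, pan, spec),
                   log_likelihood(st_out, pan, spec))
})

test_that("log prior: support violations signal -Inf and the in-support
           value matches a hand-summed closed form", {
  spec <- model_spec("standard")
  st <- toy_state(2, alpha = 0.05, beta = c(0.02, -0.01, 0.03),
                  gamma = c(-0.04, 0.01, 0.02), gamma_dd = -0.05,
                  eps = c(0, 0), sigma2 = 0.4, phi = 2, p = 1.3,
                  mu0 = c(10, 150))
  st_bad <- st; st_bad$mu0[2] <- 250
  expect_identical(log_prior(st_bad, spec), -Inf)
  st_bad2 <- st; st_bad2$gamma_dd <- 0.1
  expect_identical(log_prior(st_bad2, spec), -Inf)
  st_bad3 <- st; st_bad3$phi <- 7
  expect_identical(log_prior(st_bad3, spec), -Inf)
  hand <- dnorm(0.05, 0, 0.1, log = TRUE) +
    sum(dnorm(c(0.02, -0.01, 0.03), 0, 0.1, log = TRUE)) +
    sum(dnorm(c(-0.04, 0.01, 0.02), 0, 0.1, log = TRUE)) +
    log(2) + dnorm(-0.05, 0, 0.1, log = TRUE) +
    log(1 / 5) + log(1 / 2) + 2 * log(1 / 200) +
    0.001 * log(0.001) - lgamma(0.001) - 1.001 * log(0.4) - 0.001 / 0.4 +
    7 * log(0.5)
  expect_equal(log_prior(st, spec), hand, tolerance = 1e-10)
})

test_that("panel CSV round-trips through the long format", {
  sim <- simulate_panel(synthetic_truth(n_site = 6, T = 5, seed = 9,
                                        mu0_band = c(1, 10)))
  f <- tempfile(fileext = ".csv")
  write_panel_csv(sim$panel, f)
  back <- read_panel_csv(f)
  expect_equal(dim(back$y), dim(sim$panel$y))
  expect_equal(sum(back$obs), sum(sim$panel$obs))
  # align site order before comparing
  ord <- match(sim$panel$site_ids, back$site_ids)
  expect_equal(back$y[ord, ], sim$panel$y, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(back$v_time[ord, , "frost_days"],
               sim$panel$v_time[, , "frost_days"], ignore_attr = TRUE)
  expect_error(read_panel_csv(textConnection("a,b\n1,2")))
})

test_that("panel validation enforces the documented invariants", {
  y <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_error(toy_panel(y, habitat = c(0, 1)), "habitat")
  y_neg <- y; y_neg[1, 1] <- -1
  expect_error(toy_panel(y_neg), "non-negative")
  y_all_na <- y; y_all_na[1, ] <- NA
  expect_error(toy_panel(y_all_na), "at least one observed year")
})
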