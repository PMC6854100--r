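#' Chain configuration
#'
#' Iteration counts default per formulation to the run lengths the two
#' model forms need: the standard formulation mixes quickly (20,000
#' iterations, 5,000 burn-in is conservative), while the change
#' formulation needs far longer (100,000 iterations, 60,000 burn-in).
#'
#' @param n_iter total iterations (`NULL` = formulation default).
#' @param n_burn burn-in iterations discarded (`NULL` = formulation
#'   default); must be smaller than `n_iter`.
#' @param seed integer RNG seed; every source of randomness in the chain
#'   flows from it.
#' @param proposal_scales optional named list overriding the default
#'   random-walk scales (`eps`, `mu0`, `gamma`, `gamma_dd`, `phi`, `p`).
#' @param adapt adapt proposal scales during burn-in only (target
#'   acceptance 0.2-0.4), frozen afterwards so detailed balance holds for
#'   the retained draws.
#' @param thin keep every `thin`-th post-burn-in draw (default 1 = all).
#' @return object of class `chain_config`.
#' @export
chain_config <- function(n_iter = NULL, n_burn = NULL, seed = 1,
                         proposal_scales = NULL, adapt = TRUE, thin = 1L) {
  if (!is.null(n_iter) && !is.null(n_burn) && n_burn >= n_iter)
    stop("n_burn must be smaller than n_iter")
  structure(list(n_iter = n_iter, n_burn = n_burn, seed = as.integer(seed),
                 proposal_scales = proposal_scales, adapt = isTRUE(adapt),
                 thin = as.integer(thin)),
            class = "chain_config")
}

.default_scales <- function(k_gamma) {
  list(eps = 0.05, mu0 = 2, gamma = rep(0.005, k_gamma), gamma_dd = 0.005,
       phi = 0.1, p = 0.1, gamma_rc = rep(0.02, k_gamma), shear = 0.05)
}

.resolve_config <- function(config, formulation) {
  if (is.null(config)) config <- chain_config()
  if (is.null(config$n_iter))
    config$n_iter <- if (formulation == "standard") 20000L else 100000L
  if (is.null(config$n_burn))
    config$n_burn <- if (formulation == "standard") 5000L else 60000L
  if (config$n_burn >= config$n_iter) stop("n_burn must be smaller than n_iter")
  config
}

# preprocessed fit context shared by all block updates
.prepare <- function(panel, spec) {
  stopifnot(inherits(panel, "obs_panel"), inherits(spec, "model_spec"))
  if (!panel$normalized)
    stop("normalize the panel (normalize_covariates) before fitting")
  prep <- list(y = panel$y, obs = panel$obs, x = panel$x_site,
               v = panel$v_time, first = panel$first, last = panel$last,
               dd_ref = panel$dd_ref, n = nrow(panel$y), T = ncol(panel$y),
               K = dim(panel$v_time)[3],
               gamma_names = dimnames(panel$v_time)[[3]],
               beta_names = colnames(panel$x_site),
               any_obs = any(panel$obs),
               no_obs = rowSums(panel$obs) == 0L)
  if (spec$formulation == "change") prep$lr <- change_logratios(panel)
  # Per-site decomposition used by the gamma recentering move: a change
  # delta in gamma_k perturbs site i's log mean at year t by
  # delta * C_ikt (cumulative covariate under the standard recursion, the
  # log-ratio itself under the change form).  Regressing C_ikt on the
  # within-window year index splits that into a level part (absorbable by
  # log mu0) and a slope part (absorbable by eps).
  rc_a <- matrix(0, prep$n, prep$K)
  rc_b <- matrix(0, prep$n, prep$K)
  for (i in seq_len(prep$n)) {
    f <- prep$first[i]; l <- prep$last[i]
    if (is.na(f)) next
    if (spec$formulation == "standard") {
      w <- l - f + 1
      m <- matrix(prep$v[i, f:l, ], nrow = w)
      Ck <- apply(m, 2, cumsum)
      if (w == 1) Ck <- matrix(Ck, 1)
      x <- seq_len(w)
      if (length(x) > 1) {
        b <- as.vector(stats::cov(x, Ck)) / stats::var(x)
        a <- colMeans(Ck) - b * mean(x)
      } else {
        b <- Ck[1, ]; a <- rep(0, prep$K)
      }
      rc_a[i, ] <- a; rc_b[i, ] <- b
    } else {
      ff <- min(f + 1L, l)
      rc_b[i, ] <- if (l > ff) colMeans(prep$lr[i, ff:l, ]) else prep$lr[i, ff, ]
    }
  }
  prep$rc_a <- rc_a
  prep$rc_b <- rc_b
  # mean within-window year index, for the per-site slope/level shear
  prep$xbar <- ifelse(is.na(prep$first), 0,
                      (prep$last - prep$first) / 2 + 1)
  prep
}

.lmu_prep <- function(st, prep, spec) {
  if (spec$formulation == "standard") {
    gdd <- if (spec$include_density_dependence) st$gamma_dd else 0
    cpp_means_standard(log(st$mu0), st$eps, st$gamma, gdd, prep$v,
                       prep$first, prep$last, prep$dd_ref)
  } else {
    cpp_means_change(log(st$mu0), st$eps, st$gamma, prep$lr,
                     prep$first, prep$last)
  }
}

.make_cache <- function(st, prep, spec) {
  lmu <- .lmu_prep(st, prep, spec)
  sll <- if (prep$any_obs)
    cpp_site_loglik(prep$y, prep$obs, lmu, st$phi, st$p)
  else numeric(prep$n)
  list(lmu = lmu, sll = sll, ll = sum(sll))
}

.eps_prior_mean <- function(st, prep)
  st$alpha + as.vector(prep$x %*% (st$beta * st$inc_beta))

.reflect <- function(x, lo, hi) {
  r <- hi - lo
  x <- (x - lo) %% (2 * r)
  lo + ifelse(x > r, 2 * r - x, x)
}

# ---- Metropolis blocks ------------------------------------------------------
# Each returns list(st, cache, acc = accepted/attempted).  All randomness is
# drawn from R's RNG so chains are reproducible from a single seed.

.blk_eps <- function(st, cache, prep, spec, s) {
  prop <- st$eps + stats::rnorm(prep$n) * s
  st2 <- st; st2$eps <- prop
  lmu_p <- .lmu_prep(st2, prep, spec)
  sll_p <- if (prep$any_obs)
    cpp_site_loglik(prep$y, prep$obs, lmu_p, st$phi, st$p)
  else numeric(prep$n)
  m <- .eps_prior_mean(st, prep); sd <- sqrt(st$sigma2)
  logr <- (sll_p - cache$sll) +
    stats::dnorm(prop, m, sd, log = TRUE) - stats::dnorm(st$eps, m, sd, log = TRUE)
  logr[!is.finite(logr)] <- -Inf
  if (s == 0) logr[] <- 0  # degenerate proposal: state unchanged, accepted
  acc <- log(stats::runif(prep$n)) < logr
  if (any(acc)) {
    st$eps[acc] <- prop[acc]
    cache$lmu[acc, ] <- lmu_p[acc, ]
    cache$sll[acc] <- sll_p[acc]
    cache$ll <- sum(cache$sll)
  }
  if (any(prep$no_obs)) {
    # a site with no observed cells has its prior as full conditional:
    # draw it exactly (Gibbs) instead of walking
    k <- sum(prep$no_obs)
    st$eps[prep$no_obs] <- stats::rnorm(k, m[prep$no_obs], sd)
  }
  list(st = st, cache = cache,
       acc = if (all(prep$no_obs)) 1 else mean(acc[!prep$no_obs]))
}

.blk_mu0 <- function(st, cache, prep, spec, s, priors) {
  prop <- .reflect(st$mu0 + stats::rnorm(prep$n) * s,
                   priors$mu0_min, priors$mu0_max)
  st2 <- st; st2$mu0 <- prop
  lmu_p <- .lmu_prep(st2, prep, spec)
  sll_p <- if (prep$any_obs)
    cpp_site_loglik(prep$y, prep$obs, lmu_p, st$phi, st$p)
  else numeric(prep$n)
  logr <- sll_p - cache$sll
  logr[!is.finite(logr)] <- -Inf
  if (s == 0) logr[] <- 0
  acc <- log(stats::runif(prep$n)) < logr
  if (any(acc)) {
    st$mu0[acc] <- prop[acc]
    cache$lmu[acc, ] <- lmu_p[acc, ]
    cache$sll[acc] <- sll_p[acc]
    cache$ll <- sum(cache$sll)
  }
  if (any(prep$no_obs))
    st$mu0[prep$no_obs] <- stats::runif(sum(prep$no_obs),
                                        priors$mu0_min, priors$mu0_max)
  list(st = st, cache = cache,
       acc = if (all(prep$no_obs)) 1 else mean(acc[!prep$no_obs]))
}

.blk_gamma <- function(st, cache, prep, spec, s, prop_cov = NULL,
                       lambda = 1) {
  idx <- which(st$inc_gamma == 1L)
  if (!length(idx)) return(list(st = st, cache = cache, acc = NA_real_))
  prop <- st$gamma
  if (!is.null(prop_cov)) {
    # adaptive joint proposal along the learned posterior covariance
    R <- tryCatch(chol(prop_cov[idx, idx, drop = FALSE] +
                         diag(1e-12, length(idx))),
                  error = function(e) NULL)
    step <- if (is.null(R)) stats::rnorm(length(idx)) * s[idx]
            else lambda * drop(stats::rnorm(length(idx)) %*% R)
    prop[idx] <- prop[idx] + step
  } else
    prop[idx] <- prop[idx] + stats::rnorm(length(idx)) * s[idx]
  st2 <- st; st2$gamma <- prop
  lmu_p <- .lmu_prep(st2, prep, spec)
  sll_p <- if (prep$any_obs)
    cpp_site_loglik(prep$y, prep$obs, lmu_p, st$phi, st$p)
  else numeric(prep$n)
  ll_p <- sum(sll_p)
  sd0 <- spec$priors$coef_sd
  logr <- ll_p - cache$ll +
    sum(stats::dnorm(prop[idx], 0, sd0, log = TRUE)) -
    sum(stats::dnorm(st$gamma[idx], 0, sd0, log = TRUE))
  if (all(s[idx] == 0)) logr <- 0
  acc <- is.finite(logr) && log(stats::runif(1)) < logr
  if (acc) {
    st$gamma <- prop
    cache <- list(lmu = lmu_p, sll = sll_p, ll = ll_p)
  }
  list(st = st, cache = cache, acc = as.numeric(acc))
}

# Recentering move: a shear along the gamma_k / site-effect / anchor ridge
# that plain random walks cross slowly:
#   gamma_k -> gamma_k + delta
#   eps_i   -> eps_i   - delta * b_ik      (slope compensation)
#   mu0_i   -> mu0_i * exp(-delta * a_ik)  (level compensation)
# with (a, b) the per-site least-squares split computed in .prepare.  The
# map is linear in (gamma, eps, log mu0); in the stored mu0 coordinate its
# Jacobian is exp(-delta * sum_i a_ik), included in the ratio.
.blk_gamma_rc <- function(st, cache, prep, spec, s, k) {
  if (st$inc_gamma[k] == 0L)
    return(list(st = st, cache = cache, acc = NA_real_))
  delta <- stats::rnorm(1) * s[k]
  prop_g <- st$gamma
  prop_g[k] <- prop_g[k] + delta
  prop_e <- st$eps - delta * prep$rc_b[, k]
  prop_m <- st$mu0 * exp(-delta * prep$rc_a[, k])
  pr <- spec$priors
  if (any(prop_m < pr$mu0_min | prop_m > pr$mu0_max))
    return(list(st = st, cache = cache, acc = 0))
  st2 <- st; st2$gamma <- prop_g; st2$eps <- prop_e; st2$mu0 <- prop_m
  lmu_p <- .lmu_prep(st2, prep, spec)
  sll_p <- if (prep$any_obs)
    cpp_site_loglik(prep$y, prep$obs, lmu_p, st$phi, st$p)
  else numeric(prep$n)
  ll_p <- sum(sll_p)
  sd0 <- pr$coef_sd
  m <- .eps_prior_mean(st, prep); sdev <- sqrt(st$sigma2)
  logr <- ll_p - cache$ll +
    stats::dnorm(prop_g[k], 0, sd0, log = TRUE) -
    stats::dnorm(st$gamma[k], 0, sd0, log = TRUE) +
    sum(stats::dnorm(prop_e, m, sdev, log = TRUE)) -
    sum(stats::dnorm(st$eps, m, sdev, log = TRUE)) -
    delta * sum(prep$rc_a[, k])
  if (s[k] == 0) logr <- 0
  acc <- is.finite(logr) && log(stats::runif(1)) < logr
  if (acc) {
    st$gamma <- prop_g; st$eps <- prop_e; st$mu0 <- prop_m
    cache <- list(lmu = lmu_p, sll = sll_p, ll = ll_p)
  }
  list(st = st, cache = cache, acc = as.numeric(acc))
}

# Per-site slope/level shear: eps_i -> eps_i + delta_i with
# log mu0_i -> log mu0_i - delta_i * xbar_i (xbar_i = mean within-window
# year index), which trades a site's growth rate against its anchor while
# leaving the trajectory's midpoint fixed.  Site-separable; Jacobian in
# the stored mu0 coordinate is exp(-delta_i * xbar_i).
.blk_site_shear <- function(st, cache, prep, spec, s) {
  delta <- stats::rnorm(prep$n) * s
  prop_e <- st$eps + delta
  prop_m <- st$mu0 * exp(-delta * prep$xbar)
  pr <- spec$priors
  bad <- prop_m < pr$mu0_min | prop_m > pr$mu0_max
  st2 <- st; st2$eps <- prop_e; st2$mu0 <- pmin(pmax(prop_m, pr$mu0_min),
                                                pr$mu0_max)
  lmu_p <- .lmu_prep(st2, prep, spec)
  sll_p <- if (prep$any_obs)
    cpp_site_loglik(prep$y, prep$obs, lmu_p, st$phi, st$p)
  else numeric(prep$n)
  m <- .eps_prior_mean(st, prep); sdev <- sqrt(st$sigma2)
  logr <- (sll_p - cache$sll) +
    stats::dnorm(prop_e, m, sdev, log = TRUE) -
    stats::dnorm(st$eps, m, sdev, log = TRUE) -
    delta * prep$xbar
  logr[bad | !is.finite(logr)] <- -Inf
  if (s == 0) logr[] <- 0
  acc <- log(stats::runif(prep$n)) < logr
  acc[prep$no_obs] <- FALSE
  if (any(acc)) {
    st$eps[acc] <- prop_e[acc]
    st$mu0[acc] <- prop_m[acc]
    cache$lmu[acc, ] <- lmu_p[acc, ]
    cache$sll[acc] <- sll_p[acc]
    cache$ll <- sum(cache$sll)
  }
  list(st = st, cache = cache,
       acc = if (all(prep$no_obs)) 1 else mean(acc[!prep$no_obs]))
}

.blk_gdd <- function(st, cache, prep, spec, s) {
  if (!spec$include_density_dependence || st$inc_dd == 0L)
    return(list(st = st, cache = cache, acc = NA_real_))
  prop <- st$gamma_dd + stats::rnorm(1) * s
  if (s == 0) prop <- st$gamma_dd
  if (prop > 0)
    return(list(st = st, cache = cache, acc = 0))
  st2 <- st; st2$gamma_dd <- prop
  lmu_p <- .lmu_prep(st2, prep, spec)
  sll_p <- if (prep$any_obs)
    cpp_site_loglik(prep$y, prep$obs, lmu_p, st$phi, st$p)
  else numeric(prep$n)
  ll_p <- sum(sll_p)
  sd0 <- spec$priors$coef_sd
  logr <- ll_p - cache$ll +
    stats::dnorm(prop, 0, sd0, log = TRUE) -
    stats::dnorm(st$gamma_dd, 0, sd0, log = TRUE)
  if (s == 0) logr <- 0
  acc <- is.finite(logr) && log(stats::runif(1)) < logr
  if (acc) {
    st$gamma_dd <- prop
    cache <- list(lmu = lmu_p, sll = sll_p, ll = ll_p)
  }
  list(st = st, cache = cache, acc = as.numeric(acc))
}

.blk_tw <- function(st, cache, prep, spec, s_phi, s_p) {
  pr <- spec$priors
  lo <- 1 + pr$p_eps; hi <- 2 - pr$p_eps
  phi_p <- exp(log(st$phi) + stats::rnorm(1) * s_phi)
  w0 <- (st$p - lo) / (hi - lo)
  z_p <- stats::qlogis(w0) + stats::rnorm(1) * s_p
  wp <- stats::plogis(z_p)
  p_p <- lo + wp * (hi - lo)
  if (s_phi == 0 && s_p == 0) { phi_p <- st$phi; p_p <- st$p; wp <- w0 }
  if (phi_p > pr$phi_max)
    return(list(st = st, cache = cache, acc = 0))
  sll_p <- if (prep$any_obs)
    cpp_site_loglik(prep$y, prep$obs, cache$lmu, phi_p, p_p)
  else numeric(prep$n)
  ll_p <- sum(sll_p)
  logr <- ll_p - cache$ll +
    (log(phi_p) - log(st$phi)) +                     # log-walk Jacobian
    (log(wp * (1 - wp)) - log(w0 * (1 - w0)))        # logit-walk Jacobian
  if (s_phi == 0 && s_p == 0) logr <- 0
  acc <- is.finite(logr) && log(stats::runif(1)) < logr
  if (acc) {
    st$phi <- phi_p; st$p <- p_p
    cache$sll <- sll_p; cache$ll <- ll_p
  }
  list(st = st, cache = cache, acc = as.numeric(acc))
}

# ---- Reversible-jump toggles -----------------------------------------------
# Birth proposes the coefficient from its prior, so prior and proposal
# cancel and the acceptance ratio reduces to the likelihood ratio times the
# prior odds of inclusion.

.rj_beta_k <- function(st, prep, spec, k) {
  sd0 <- spec$priors$coef_sd
  q <- spec$inclusion_prior
  sdev <- sqrt(st$sigma2)
  lp_eps <- function(beta, inc) {
    m <- st$alpha + as.vector(prep$x %*% (beta * inc))
    sum(stats::dnorm(st$eps, m, sdev, log = TRUE))
  }
  inc2 <- st$inc_beta; b2 <- st$beta
  if (st$inc_beta[k] == 1L) {           # death
    inc2[k] <- 0L; b2[k] <- 0
    logr <- lp_eps(b2, inc2) - lp_eps(st$beta, st$inc_beta) + log((1 - q) / q)
  } else {                              # birth
    inc2[k] <- 1L; b2[k] <- stats::rnorm(1, 0, sd0)
    logr <- lp_eps(b2, inc2) - lp_eps(st$beta, st$inc_beta) + log(q / (1 - q))
  }
  if (is.finite(logr) && log(stats::runif(1)) < logr) {
    st$beta <- b2; st$inc_beta <- inc2
    accepted <- TRUE
  } else accepted <- FALSE
  list(st = st, accepted = accepted)
}

.rj_gamma_k <- function(st, cache, prep, spec, k) {
  sd0 <- spec$priors$coef_sd
  q <- spec$inclusion_prior
  g2 <- st$gamma; inc2 <- st$inc_gamma
  if (st$inc_gamma[k] == 1L) {
    inc2[k] <- 0L; g2[k] <- 0
    lodds <- log((1 - q) / q)
  } else {
    inc2[k] <- 1L; g2[k] <- stats::rnorm(1, 0, sd0)
    lodds <- log(q / (1 - q))
  }
  st2 <- st; st2$gamma <- g2
  lmu_p <- .lmu_prep(st2, prep, spec)
  sll_p <- if (prep$any_obs)
    cpp_site_loglik(prep$y, prep$obs, lmu_p, st$phi, st$p)
  else numeric(prep$n)
  ll_p <- sum(sll_p)
  logr <- ll_p - cache$ll + lodds
  if (is.finite(logr) && log(stats::runif(1)) < logr) {
    st$gamma <- g2; st$inc_gamma <- inc2
    cache <- list(lmu = lmu_p, sll = sll_p, ll = ll_p)
  }
  list(st = st, cache = cache)
}

.rj_dd <- function(st, cache, prep, spec) {
  sd0 <- spec$priors$coef_sd
  q <- spec$inclusion_prior
  if (st$inc_dd == 1L) {
    g2 <- 0; inc2 <- 0L; lodds <- log((1 - q) / q)
  } else {
    g2 <- -abs(stats::rnorm(1, 0, sd0)); inc2 <- 1L; lodds <- log(q / (1 - q))
  }
  st2 <- st; st2$gamma_dd <- g2
  lmu_p <- .lmu_prep(st2, prep, spec)
  sll_p <- if (prep$any_obs)
    cpp_site_loglik(prep$y, prep$obs, lmu_p, st$phi, st$p)
  else numeric(prep$n)
  ll_p <- sum(sll_p)
  logr <- ll_p - cache$ll + lodds
  if (is.finite(logr) && log(stats::runif(1)) < logr) {
    st$gamma_dd <- g2; st$inc_dd <- inc2
    cache <- list(lmu = lmu_p, sll = sll_p, ll = ll_p)
  }
  list(st = st, cache = cache)
}

# ---- Gibbs block ------------------------------------------------------------

#' Gibbs update of the hierarchical-centering hyperparameters
#'
#' Under hierarchical centering the site effects satisfy
#' \eqn{\varepsilon_i \sim N(\alpha + x_i^T \beta, \sigma^2)}, so given the
#' current site effects, `(alpha, beta)` have a joint normal full
#' conditional (a known-variance normal linear model of `eps` on the site
#' covariates with N(0, 0.01) priors) and `sigma2` an inverse-gamma full
#' conditional.  Both are drawn exactly, which is what makes the centred
#' parameterization mix well.
#'
#' @param eps current site-effect vector.
#' @param x_site normalized site covariate matrix (n x 3).
#' @param priors see [default_priors()].
#' @param sigma2 current random-effect variance (used for the coefficient
#'   draw; `sigma2` itself is then redrawn given the new coefficients).
#' @param inc_beta 0/1 inclusion indicators; excluded columns are dropped
#'   from the design and their coefficients stay zero.
#' @return list with `alpha`, `beta` (length 3) and `sigma2`.
#' @export
gibbs_update_hypers <- function(eps, x_site, priors = default_priors(),
                                sigma2 = 1, inc_beta = rep(1L, ncol(x_site))) {
  n <- length(eps)
  X <- cbind(intercept = 1, x_site[, inc_beta == 1L, drop = FALSE])
  k <- ncol(X)
  A <- crossprod(X) / sigma2 + diag(1 / priors$coef_sd^2, k)
  R <- tryCatch(chol(A), error = function(e)
    stop("singular design: included site covariates are collinear"))
  m <- backsolve(R, backsolve(R, crossprod(X, eps) / sigma2, transpose = TRUE))
  draw <- as.vector(m + backsolve(R, stats::rnorm(k)))
  beta <- numeric(ncol(x_site))
  names(beta) <- colnames(x_site)
  beta[inc_beta == 1L] <- draw[-1]
  resid <- eps - as.vector(X %*% draw)
  sigma2_new <- 1 / stats::rgamma(1, shape = priors$sigma2_shape + n / 2,
                                  rate = priors$sigma2_rate + sum(resid^2) / 2)
  sigma2_new <- min(max(sigma2_new, priors$sigma2_min), priors$sigma2_max)
  list(alpha = draw[1], beta = beta, sigma2 = sigma2_new)
}

# ---- Exported single-move wrappers -----------------------------------------

#' Random-walk Metropolis update of one parameter block
#'
#' Applies one Metropolis-within-Gibbs move to the named block: plain
#' normal walks for the site effects and (included) time-covariate
#' coefficients, a sign-constrained walk for the density-dependence
#' coefficient, a log-scale walk for `phi` with a logit-type walk for `p`
#' inside its computable range (the `tw` block), and a reflected walk in
#' \[0, 200\] for the pre-survey means.  Proposals producing invalid states
#' are rejected, never raised.  A zero proposal scale leaves the state
#' unchanged with the move counted as accepted.
#'
#' @param state a [parameter_state()].
#' @param block one of `"eps"`, `"mu0"`, `"gamma"`, `"gamma_dd"`, `"tw"`.
#' @param panel a normalized [observation_panel()].
#' @param spec a [model_spec()].
#' @param scales optional named list of proposal scales.
#' @return the updated state, with attribute `acceptance` (the block's
#'   acceptance fraction for this call).
#' @export
mh_update_block <- function(state, block = c("eps", "mu0", "gamma",
                                             "gamma_dd", "tw"),
                            panel, spec, scales = NULL) {
  block <- match.arg(block)
  prep <- .prepare(panel, spec)
  sc <- .default_scales(prep$K)
  if (!is.null(scales)) sc[names(scales)] <- scales
  cache <- .make_cache(state, prep, spec)
  res <- switch(block,
    eps = .blk_eps(state, cache, prep, spec, sc$eps),
    mu0 = .blk_mu0(state, cache, prep, spec, sc$mu0, spec$priors),
    gamma = .blk_gamma(state, cache, prep, spec, sc$gamma),
    gamma_dd = .blk_gdd(state, cache, prep, spec, sc$gamma_dd),
    tw = .blk_tw(state, cache, prep, spec, sc$phi, sc$p))
  out <- res$st
  class(out) <- "parameter_state"
  attr(out, "acceptance") <- res$acc
  out
}

#' Reversible-jump toggle of one covariate
#'
#' Proposes flipping the inclusion indicator of a selectable covariate: a
#' birth move draws the coefficient from its prior (so prior and proposal
#' cancel and the acceptance ratio is the likelihood ratio times the prior
#' inclusion odds); a death move zeroes it.  The intercept is never
#' toggled.  Site-covariate toggles only involve the site-effect
#' regression, time-covariate and density-dependence toggles the full
#' panel likelihood.
#'
#' @param state a [parameter_state()].
#' @param covariate index (over `northing`, `easting`, `habitat`, the
#'   time-varying covariates, then `density_dependence`) or the covariate
#'   name.
#' @inheritParams mh_update_block
#' @return the updated state.
#' @export
rj_toggle <- function(state, covariate, panel, spec) {
  prep <- .prepare(panel, spec)
  sel <- c(prep$beta_names, prep$gamma_names,
           if (spec$include_density_dependence) "density_dependence")
  if (is.character(covariate)) covariate <- match(covariate, sel)
  if (is.na(covariate) || covariate < 1 || covariate > length(sel))
    stop("unknown selectable covariate")
  cache <- .make_cache(state, prep, spec)
  nb <- length(prep$beta_names)
  if (covariate <= nb) {
    res <- .rj_beta_k(state, prep, spec, covariate)
  } else if (covariate <= nb + prep$K) {
    res <- .rj_gamma_k(state, cache, prep, spec, covariate - nb)
  } else {
    res <- .rj_dd(state, cache, prep, spec)
  }
  out <- res$st
  class(out) <- "parameter_state"
  out
}

# ---- Chain driver -----------------------------------------------------------

.init_state <- function(prep, spec) {
  site_mean <- vapply(seq_len(prep$n), function(i) {
    yi <- prep$y[i, prep$obs[i, ]]
    if (length(yi)) mean(yi) else 5
  }, 0)
  mu0 <- pmin(pmax(site_mean, 0.5), 190)
  parameter_state(
    n_site = prep$n, k_gamma = prep$K, alpha = 0, beta = numeric(3),
    gamma = numeric(prep$K),
    gamma_dd = if (spec$include_density_dependence) -0.01 else 0,
    eps = numeric(prep$n), sigma2 = 0.01, phi = 1, p = 1.5, mu0 = mu0,
    inc_beta = rep(1L, 3), inc_gamma = rep(1L, prep$K), inc_dd = 1L)
}

#' Run the Metropolis-within-Gibbs / reversible-jump sampler
#'
#' One sweep per iteration: exact Gibbs draws of `(alpha, beta, sigma2)`
#' given the site effects, Metropolis blocks for the site effects,
#' pre-survey means, time-covariate coefficients, density dependence and
#' the Tweedie `(phi, p)` pair, and (when `spec$select`) one
#' reversible-jump toggle per selectable covariate.  Proposal scales adapt
#' during burn-in only.  Chains are exactly reproducible from
#' `config$seed`.
#'
#' @param panel a normalized [observation_panel()].
#' @param spec a [model_spec()].
#' @param config a [chain_config()]; `NULL` uses the formulation defaults.
#' @param init optional initial [parameter_state()].
#' @param quiet suppress the per-1,000-iteration acceptance-rate log.
#' @return object of class `tw_chain`: post-burn-in samples, the inclusion
#'   trace, per-block acceptance rates, and the log-posterior trace.
#' @export
run_chain <- function(panel, spec, config = NULL, init = NULL, quiet = TRUE) {
  config <- .resolve_config(config, spec$formulation)
  prep <- .prepare(panel, spec)
  if (prep$n < 2)
    stop("at least 2 sites are required (random-effect variance is ",
         "unidentifiable from a single site)")
  set.seed(config$seed)
  st <- if (is.null(init)) .init_state(prep, spec) else init
  if (!spec$select) {
    st$inc_beta <- rep(1L, 3); st$inc_gamma <- rep(1L, prep$K)
    st$inc_dd <- if (spec$include_density_dependence) 1L else 0L
  }
  sc <- .default_scales(prep$K)
  if (!is.null(config$proposal_scales))
    sc[names(config$proposal_scales)] <- config$proposal_scales
  cache <- .make_cache(st, prep, spec)
  if (!is.finite(cache$ll))
    stop("initial state has non-finite log likelihood; ",
         "check the panel for invalid values")
  n_iter <- config$n_iter; n_burn <- config$n_burn; thin <- max(1L, config$thin)
  keep_iters <- seq.int(n_burn + thin, n_iter, by = thin)
  n_keep <- length(keep_iters)
  if (n_keep < 1L) stop("no post-burn-in draws would be kept")
  has_dd <- spec$include_density_dependence
  sel_names <- c(prep$beta_names, prep$gamma_names,
                 if (has_dd) "density_dependence")
  S <- list(alpha = numeric(n_keep),
            beta = matrix(0, n_keep, 3, dimnames = list(NULL, prep$beta_names)),
            gamma = matrix(0, n_keep, prep$K,
                           dimnames = list(NULL, prep$gamma_names)),
            gamma_dd = numeric(n_keep), sigma2 = numeric(n_keep),
            phi = numeric(n_keep), p = numeric(n_keep),
            eps = matrix(0, n_keep, prep$n),
            mu0 = matrix(0, n_keep, prep$n))
  inc_trace <- matrix(0L, n_keep, length(sel_names),
                      dimnames = list(NULL, sel_names))
  lp_trace <- numeric(n_keep)
  blocks <- c("eps", "mu0", "shear", "gamma", "gamma_rc", "gamma_dd", "tw")
  acc_tot <- stats::setNames(numeric(7), blocks)
  try_tot <- stats::setNames(numeric(7), blocks)
  acc_win <- acc_tot; try_win <- try_tot
  keep_ptr <- 0L
  gamma_hist <- matrix(0, n_burn, prep$K)
  gamma_cov <- NULL       # learned joint proposal covariance (frozen after
  lambda_gamma <- 1       # burn-in, preserving detailed balance)
  for (it in seq_len(n_iter)) {
    g <- gibbs_update_hypers(st$eps, prep$x, spec$priors, st$sigma2,
                             st$inc_beta)
    st$alpha <- g$alpha; st$beta <- unname(g$beta); st$sigma2 <- g$sigma2
    if (spec$select)
      for (k in 1:3) {
        r <- .rj_beta_k(st, prep, spec, k)
        st <- r$st
      }
    r <- .blk_eps(st, cache, prep, spec, sc$eps)
    st <- r$st; cache <- r$cache
    acc_win["eps"] <- acc_win["eps"] + r$acc; try_win["eps"] <- try_win["eps"] + 1
    r <- .blk_mu0(st, cache, prep, spec, sc$mu0, spec$priors)
    st <- r$st; cache <- r$cache
    acc_win["mu0"] <- acc_win["mu0"] + r$acc; try_win["mu0"] <- try_win["mu0"] + 1
    r <- .blk_site_shear(st, cache, prep, spec, sc$shear)
    st <- r$st; cache <- r$cache
    acc_win["shear"] <- acc_win["shear"] + r$acc
    try_win["shear"] <- try_win["shear"] + 1
    r <- .blk_gamma(st, cache, prep, spec, sc$gamma, gamma_cov, lambda_gamma)
    st <- r$st; cache <- r$cache
    if (!is.na(r$acc)) {
      acc_win["gamma"] <- acc_win["gamma"] + r$acc
      try_win["gamma"] <- try_win["gamma"] + 1
    }
    # recentering cycles over the covariates, one per sweep
    k_rc <- (it - 1L) %% prep$K + 1L
    r <- .blk_gamma_rc(st, cache, prep, spec, sc$gamma_rc, k_rc)
    st <- r$st; cache <- r$cache
    if (!is.na(r$acc)) {
      acc_win["gamma_rc"] <- acc_win["gamma_rc"] + r$acc
      try_win["gamma_rc"] <- try_win["gamma_rc"] + 1
    }
    if (it <= n_burn) {
      gamma_hist[it, ] <- st$gamma
      if (config$adapt && it >= 500L && it %% 100L == 0L) {
        lo <- max(1L, it - 2000L)
        C <- stats::cov(gamma_hist[lo:it, , drop = FALSE])
        if (all(is.finite(C)) && all(diag(C) > 0))
          gamma_cov <- C * (2.38^2 / prep$K)
      }
    }
    if (has_dd) {
      r <- .blk_gdd(st, cache, prep, spec, sc$gamma_dd)
      st <- r$st; cache <- r$cache
      if (!is.na(r$acc)) {
        acc_win["gamma_dd"] <- acc_win["gamma_dd"] + r$acc
        try_win["gamma_dd"] <- try_win["gamma_dd"] + 1
      }
    }
    r <- .blk_tw(st, cache, prep, spec, sc$phi, sc$p)
    st <- r$st; cache <- r$cache
    acc_win["tw"] <- acc_win["tw"] + r$acc; try_win["tw"] <- try_win["tw"] + 1
    if (spec$select) {
      for (k in seq_len(prep$K)) {
        r <- .rj_gamma_k(st, cache, prep, spec, k)
        st <- r$st; cache <- r$cache
      }
      if (has_dd) {
        r <- .rj_dd(st, cache, prep, spec)
        st <- r$st; cache <- r$cache
      }
    }
    if (!is.finite(cache$ll)) {
      stop("chain diverged at iteration ", it,
           ": non-finite log likelihood; state: phi=", format(st$phi),
           " p=", format(st$p), " sigma2=", format(st$sigma2))
    }
    # burn-in-only scale adaptation toward acceptance 0.2-0.4
    if (config$adapt && it <= n_burn && it %% 50L == 0L) {
      rate <- ifelse(try_win > 0, acc_win / pmax(try_win, 1), NA)
      adj <- function(s, r) {
        if (is.na(r)) s
        else if (r > 0.4) s * exp(0.15)
        else if (r < 0.2) s * exp(-0.15)
        else s
      }
      sc$eps <- adj(sc$eps, rate["eps"])
      sc$mu0 <- min(adj(sc$mu0, rate["mu0"]), 50)
      sc$shear <- adj(sc$shear, rate["shear"])
      sc$gamma <- vapply(sc$gamma, adj, 0, r = rate["gamma"])
      lambda_gamma <- adj(lambda_gamma, rate["gamma"])
      sc$gamma_rc <- vapply(sc$gamma_rc, adj, 0, r = rate["gamma_rc"])
      sc$gamma_dd <- adj(sc$gamma_dd, rate["gamma_dd"])
      sc$phi <- adj(sc$phi, rate["tw"])
      sc$p <- adj(sc$p, rate["tw"])
      acc_tot <- acc_tot + acc_win; try_tot <- try_tot + try_win
      acc_win[] <- 0; try_win[] <- 0
    }
    if (!quiet && it %% 1000L == 0L) {
      rate <- (acc_tot + acc_win) / pmax(try_tot + try_win, 1)
      message(sprintf("iter %d | ll %.1f | acc %s", it, cache$ll,
                      paste(sprintf("%s=%.2f", blocks, rate), collapse = " ")))
    }
    if (it > n_burn && (it - n_burn) %% thin == 0L) {
      keep_ptr <- keep_ptr + 1L
      S$alpha[keep_ptr] <- st$alpha
      S$beta[keep_ptr, ] <- st$beta * st$inc_beta
      S$gamma[keep_ptr, ] <- st$gamma * st$inc_gamma
      S$gamma_dd[keep_ptr] <- st$gamma_dd * st$inc_dd
      S$sigma2[keep_ptr] <- st$sigma2
      S$phi[keep_ptr] <- st$phi
      S$p[keep_ptr] <- st$p
      S$eps[keep_ptr, ] <- st$eps
      S$mu0[keep_ptr, ] <- st$mu0
      inc_trace[keep_ptr, ] <- c(st$inc_beta, st$inc_gamma,
                                 if (has_dd) st$inc_dd)
      lp_trace[keep_ptr] <- cache$ll + log_prior(st, spec, prep$x)
    }
  }
  acc_tot <- acc_tot + acc_win; try_tot <- try_tot + try_win
  structure(list(samples = S, inclusion_trace = inc_trace,
                 acceptance_rates = acc_tot / pmax(try_tot, 1),
                 log_posterior_trace = lp_trace, config = config,
                 spec = spec, n_site = prep$n,
                 cov_names = sel_names, final_scales = sc,
                 final_state = st),
            class = "tw_chain")
}

#' @export
print.tw_chain <- function(x, ...) {
  cat("Tweedie panel chain (", x$spec$formulation, " formulation): ",
      length(x$samples$alpha), " retained draws, ", x$n_site, " sites\n",
      sep = "")
  cat("  acceptance: ",
      paste(sprintf("%s=%.2f", names(x$acceptance_rates),
                    x$acceptance_rates), collapse = "  "), "\n", sep = "")
  invisible(x)
}

# ---- Bayes factors and summaries -------------------------------------------

#' Bayes factor from a posterior inclusion probability
#'
#' `BF = [q/(1-q)] / [r/(1-r)]`, the posterior odds of inclusion divided by
#' the prior odds.  With the default prior probability 0.5 the Bayes factor
#' equals the posterior odds, and a value greater than 3 is read as
#' positive evidence for the covariate.  `q = 1` maps to `Inf` (rendered
#' as ">10" in printed tables).
#'
#' @param inclusion_probability posterior inclusion probability in \[0, 1\].
#' @param prior_probability prior inclusion probability in (0, 1).
#' @return positive Bayes factor, possibly `Inf`.
#' @export
bayes_factor <- function(inclusion_probability, prior_probability = 0.5) {
  q <- inclusion_probability; r <- prior_probability
  if (any(q < 0 | q > 1)) stop("inclusion probability must lie in [0, 1]")
  if (any(r <= 0 | r >= 1)) stop("prior probability must lie strictly in (0, 1)")
  ifelse(q == 1, Inf, (q / (1 - q)) / (r / (1 - r)))
}

.fmt_bf <- function(bf) {
  ifelse(is.na(bf), "-", ifelse(bf > 10, ">10", sprintf("%.4g", bf)))
}

#' Summarize a chain
#'
#' Model-averaged posterior means (excluded coefficients count as zero),
#' posterior inclusion probabilities, Bayes factors with the BF > 3
#' significance flag, and posterior means with 95% credible intervals for
#' the always-present parameters.
#'
#' @param chain a `tw_chain` from [run_chain()].
#' @param level credible-interval level.
#' @return object of class `tw_summary` with data.frames `covariates` and
#'   `parameters`.
#' @export
summarize_chain <- function(chain, level = 0.95) {
  stopifnot(inherits(chain, "tw_chain"))
  S <- chain$samples
  if (!length(S$alpha)) stop("chain has no retained draws")
  a <- (1 - level) / 2
  qs <- function(v) unname(stats::quantile(v, c(a, 1 - a)))
  has_dd <- chain$spec$include_density_dependence
  draws <- S$beta
  draws <- cbind(draws, S$gamma)
  if (has_dd) {
    draws <- cbind(draws, S$gamma_dd)
    colnames(draws)[ncol(draws)] <- "density_dependence"
  }
  incp <- colMeans(chain$inclusion_trace)
  bf <- bayes_factor(incp, chain$spec$inclusion_prior)
  ci <- apply(draws, 2, qs)
  covariates <- data.frame(
    name = colnames(draws),
    posterior_mean = colMeans(draws),
    lower = ci[1, ], upper = ci[2, ],
    inclusion_probability = incp,
    bayes_factor = bf,
    significant = bf > 3,
    row.names = NULL)
  pm <- rbind(alpha = c(mean(S$alpha), qs(S$alpha)),
              sigma2 = c(mean(S$sigma2), qs(S$sigma2)),
              phi = c(mean(S$phi), qs(S$phi)),
              p = c(mean(S$p), qs(S$p)))
  parameters <- data.frame(name = rownames(pm), posterior_mean = pm[, 1],
                           lower = pm[, 2], upper = pm[, 3], row.names = NULL)
  structure(list(covariates = covariates, parameters = parameters,
                 n_draws = length(S$alpha),
                 formulation = chain$spec$formulation),
            class = "tw_summary")
}

#' @export
summary.tw_chain <- function(object, ...) summarize_chain(object, ...)

#' @export
print.tw_summary <- function(x, ...) {
  cat("Posterior summary (", x$formulation, " formulation, ", x$n_draws,
      " draws)\n\nCovariates (model-averaged; BF > 3 flagged):\n", sep = "")
  cv <- x$covariates
  cv$bayes_factor <- .fmt_bf(cv$bayes_factor)
  cv$posterior_mean <- sprintf("%.4f", cv$posterior_mean)
  print(cv[, c("name", "posterior_mean", "inclusion_probability",
               "bayes_factor", "significant")], row.names = FALSE)
  cat("\nAlways-present parameters:\n")
  pm <- x$parameters
  pm$posterior_mean <- sprintf("%.4f", pm$posterior_mean)
  pm$lower <- sprintf("%.4f", pm$lower); pm$upper <- sprintf("%.4f", pm$upper)
  print(pm, row.names = FALSE)
  invisible(x)
}
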