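#' Default prior settings
#'
#' Priors used by both model formulations: N(0, 0.01) (variance 0.01, sd
#' 0.1) on regression coefficients of normalized covariates, a half-normal
#' HN(0, 0.01) on the magnitude of the (negative) density-dependence
#' coefficient, U\[0, 5\] on the Tweedie dispersion, U\[0, 2\] on the index
#' (confined to (1 + 1e-3, 2 - 1e-3) inside the sampler, where the
#' compound Poisson-gamma density exists and is computable),
#' InvGamma(0.001, 0.001) (shape-rate) on the random-effect variance, and
#' U\[0, 200\] on each site's augmented pre-survey mean.
#'
#' @param coef_sd prior sd of regression coefficients (default 0.1,
#'   i.e. variance 0.01).
#' @param phi_max upper bound of the uniform dispersion prior.
#' @param sigma2_shape,sigma2_rate inverse-gamma hyperparameters.
#' @param mu0_max upper bound of the uniform prior on pre-survey means.
#' @param p_eps half-width by which p is kept off the (1, 2) boundary.
#' @param mu0_min tiny positive floor for the pre-survey mean walk (its log
#'   enters the recursion; measure-zero truncation of U\[0, 200\]).
#' @param sigma2_min,sigma2_max bounds at which the inverse-gamma variance
#'   sampler is truncated.  InvGamma(0.001, 0.001) is so diffuse that
#'   roughly half of its mass lies beyond the range of double-precision
#'   numbers (its median is near 1e298), so untruncated draws overflow;
#'   with any data the posterior never approaches these bounds.
#' @return named list of hyperparameters.
#' @export
default_priors <- function(coef_sd = 0.1, phi_max = 5, sigma2_shape = 0.001,
                           sigma2_rate = 0.001, mu0_max = 200, p_eps = 1e-3,
                           mu0_min = 1e-3, sigma2_min = 1e-12,
                           sigma2_max = 1e12) {
  list(coef_sd = coef_sd, phi_max = phi_max, sigma2_shape = sigma2_shape,
       sigma2_rate = sigma2_rate, mu0_max = mu0_max, p_eps = p_eps,
       mu0_min = mu0_min, sigma2_min = sigma2_min, sigma2_max = sigma2_max)
}

#' Model specification
#'
#' Chooses the mean structure and what is selectable.  The `standard`
#' formulation models the log ratio of consecutive expected means as a
#' linear function of the time-varying covariates, optional negative
#' density dependence, and a site effect; the `change` formulation models
#' log abundance as a linear function of log covariate ratios relative to
#' each site's first observed year.  Density dependence is never part of
#' the change formulation.
#'
#' @param formulation `"standard"` or `"change"`.
#' @param include_density_dependence logical; standard formulation only.
#' @param priors see [default_priors()].
#' @param inclusion_prior prior inclusion probability for each selectable
#'   covariate (in (0, 1)); with the default 0.5 the Bayes factor equals
#'   the posterior odds of inclusion.
#' @param select logical; run reversible-jump moves over covariate
#'   inclusion.  With `FALSE` every covariate stays in the model (used for
#'   pure parameter-recovery runs).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(formulation = c("standard", "change"),
                       include_density_dependence = NULL,
                       priors = default_priors(), inclusion_prior = 0.5,
                       select = TRUE) {
  formulation <- match.arg(formulation)
  if (is.null(include_density_dependence))
    include_density_dependence <- formulation == "standard"
  if (formulation == "change" && include_density_dependence)
    stop("the change formulation never includes density dependence")
  if (inclusion_prior <= 0 || inclusion_prior >= 1)
    stop("inclusion_prior must lie in (0, 1)")
  structure(list(formulation = formulation,
                 include_density_dependence = include_density_dependence,
                 priors = priors, inclusion_prior = inclusion_prior,
                 select = select),
            class = "model_spec")
}

#' One MCMC parameter state
#'
#' Collects every sampled quantity: intercept `alpha`, site-covariate
#' coefficients `beta` (northing, easting, habitat), time-covariate
#' coefficients `gamma`, non-positive density-dependence coefficient
#' `gamma_dd`, site random effects `eps`, random-effect variance `sigma2`,
#' Tweedie `phi` and `p`, augmented pre-survey means `mu0`, and binary
#' inclusion indicators.  Under hierarchical centering `alpha` and `beta`
#' act through the mean of `eps` rather than through the observation means
#' directly.  Excluded coefficients are held at exactly zero.
#'
#' @param n_site number of sites.
#' @param k_gamma number of time-varying covariates.
#' @param alpha,beta,gamma,gamma_dd,eps,sigma2,phi,p,mu0 initial values.
#' @param inc_beta,inc_gamma,inc_dd 0/1 inclusion indicators.
#' @return object of class `parameter_state`.
#' @export
parameter_state <- function(n_site, k_gamma = 3, alpha = 0,
                            beta = numeric(3), gamma = numeric(k_gamma),
                            gamma_dd = 0, eps = numeric(n_site),
                            sigma2 = 0.01, phi = 1, p = 1.5,
                            mu0 = rep(10, n_site),
                            inc_beta = rep(1L, 3), inc_gamma = rep(1L, k_gamma),
                            inc_dd = 1L) {
  st <- list(alpha = alpha, beta = beta, gamma = gamma, gamma_dd = gamma_dd,
             eps = eps, sigma2 = sigma2, phi = phi, p = p, mu0 = mu0,
             inc_beta = as.integer(inc_beta), inc_gamma = as.integer(inc_gamma),
             inc_dd = as.integer(inc_dd))
  validate_state(st)
  structure(st, class = "parameter_state")
}

validate_state <- function(st) {
  stopifnot(length(st$beta) == 3L, length(st$eps) == length(st$mu0))
  if (st$sigma2 <= 0) stop("sigma2 must be positive")
  if (st$gamma_dd > 0) stop("gamma_dd must be non-positive")
  if (any(st$mu0 < 0 | st$mu0 > 200)) stop("mu0 must lie in [0, 200]")
  if (st$phi <= 0) stop("phi must be positive")
  if (st$p <= 1 || st$p >= 2) stop("p must lie in (1, 2)")
  if (any(st$beta[st$inc_beta == 0L] != 0) ||
      any(st$gamma[st$inc_gamma == 0L] != 0) ||
      (st$inc_dd == 0L && st$gamma_dd != 0))
    stop("excluded coefficients must be exactly zero")
  invisible(st)
}

# log-ratio array for the change formulation: log((v+1)/(v_first+1))
# relative to each site's first observed year (+1 offset keeps zero counts
# finite and preserves "no change -> 0")
change_logratios <- function(panel) {
  v <- if (!is.null(panel$v_time_raw)) panel$v_time_raw else panel$v_time
  if (any(v < 0)) stop("change formulation needs non-negative raw covariates")
  n <- dim(v)[1]; T <- dim(v)[2]; K <- dim(v)[3]
  lr <- array(0, dim(v), dimnames = dimnames(v))
  lv <- log(v + 1)
  for (i in seq_len(n)) {
    f <- panel$first[i]
    if (is.na(f)) next
    lr[i, , ] <- lv[i, , ] - matrix(lv[i, f, ], T, K, byrow = TRUE)
  }
  lr
}

# internal log-mean matrices (NA outside each site's first..last window)
.lmu_matrix <- function(state, panel, spec) {
  if (any(state$mu0 <= 0))
    stop("mu0 must be strictly positive to anchor the log-mean recursion")
  if (spec$formulation == "standard") {
    gdd <- if (spec$include_density_dependence) state$gamma_dd else 0
    cpp_means_standard(log(state$mu0), state$eps, state$gamma, gdd,
                       panel$v_time, panel$first, panel$last, panel$dd_ref)
  } else {
    lr <- attr(panel, "lr_cache")
    if (is.null(lr)) lr <- change_logratios(panel)
    cpp_means_change(log(state$mu0), state$eps, state$gamma, lr,
                     panel$first, panel$last)
  }
}

.check_divergence <- function(lmu, panel) {
  bad <- is.na(lmu) & panel$obs
  if (any(bad))
    stop("divergent state: |log mu| exceeded 50 at ", sum(bad),
         " observed site-year(s)")
  lmu
}

#' Expected means under the standard formulation
#'
#' Runs the multiplicative recursion
#' \deqn{\log \mu_{it} = \log \mu_{i,t-1} + v_{it}^T \gamma +
#'   \gamma_{DD}\, (\mu_{i,t-1}/\bar y - 1) + \varepsilon_i}
#' from each site's augmented pre-survey mean \eqn{\mu_{i0}}, through
#' unobserved interior years, up to its last observed year.  The lagged
#' expected count is scaled by the panel's fixed reference count `dd_ref`
#' and centred, so the density-dependence coefficient lives on the same
#' (centred, unit-ish) scale as the normalized covariates and stays
#' uncorrelated with the intercept.
#'
#' @param state a [parameter_state()].
#' @param panel a normalized [observation_panel()].
#' @param spec a [model_spec()] (standard formulation).
#' @return matrix (n_site x T) of positive means, `NA` outside each site's
#'   observation window.
#' @export
means_standard <- function(state, panel, spec = model_spec("standard")) {
  stopifnot(inherits(panel, "obs_panel"), spec$formulation == "standard")
  if (!panel$normalized) stop("normalize the panel before computing means")
  exp(.check_divergence(.lmu_matrix(state, panel, spec), panel))
}

#' Expected means under the change-change formulation
#'
#' For years after each site's first observed year,
#' \deqn{\log \mu_{it} = \log(v_{it}/v_{i,\mathrm{first}})^T \gamma +
#'   \varepsilon'_i,}
#' with the covariate ratios computed on the raw scale with a +1 offset
#' (counts can be zero) and \eqn{\varepsilon'_i \sim N(\alpha + x_i^T\beta,
#' \sigma^2)} by hierarchical centering.  The first observed year's mean is
#' the site's augmented baseline `mu0`.
#'
#' @inheritParams means_standard
#' @return matrix (n_site x T) of positive means.
#' @export
means_change <- function(state, panel, spec = model_spec("change")) {
  stopifnot(inherits(panel, "obs_panel"), spec$formulation == "change")
  if (!panel$normalized) stop("normalize the panel before computing means")
  exp(.check_divergence(.lmu_matrix(state, panel, spec), panel))
}

#' Panel log likelihood
#'
#' Sum of the Tweedie log density over observed site-years only; missing
#' site-years contribute nothing, and a panel with every cell masked has
#' log likelihood zero.
#'
#' @inheritParams means_standard
#' @param spec a [model_spec()].
#' @return scalar log likelihood.
#' @export
log_likelihood <- function(state, panel, spec) {
  stopifnot(inherits(panel, "obs_panel"), inherits(spec, "model_spec"))
  if (!panel$normalized) stop("normalize the panel before evaluating")
  if (state$phi <= 0 || state$p <= 1 || state$p >= 2)
    stop("invalid Tweedie parameters: need phi > 0 and p in (1, 2)")
  if (!any(panel$obs)) return(0)
  lmu <- .check_divergence(.lmu_matrix(state, panel, spec), panel)
  sum(cpp_site_loglik(panel$y, panel$obs, lmu, state$phi, state$p))
}

#' Joint log prior density
#'
#' Sums the log prior over every parameter in the state: normal priors on
#' the intercept and included coefficients, the negative half-normal on the
#' density-dependence coefficient, uniforms on `phi`, `p` (restricted to
#' the computable index range) and each `mu0`, the inverse-gamma on
#' `sigma2`, the hierarchically centred normal on the site effects, and
#' independent Bernoulli inclusion indicators.  States outside the prior
#' support return `-Inf` (signalled, not an error).
#'
#' @param state a [parameter_state()] (or plain list with the same fields).
#' @param spec a [model_spec()].
#' @param x_site optional normalized site covariate matrix; when supplied
#'   the site-effect term N(alpha + x beta, sigma2) is included.
#' @return scalar log prior density (possibly `-Inf`).
#' @export
log_prior <- function(state, spec, x_site = NULL) {
  pr <- spec$priors
  st <- state
  if (st$sigma2 <= 0 || st$phi <= 0 || st$phi > pr$phi_max) return(-Inf)
  if (st$p <= 1 + pr$p_eps || st$p >= 2 - pr$p_eps) return(-Inf)
  if (any(st$mu0 < 0 | st$mu0 > pr$mu0_max)) return(-Inf)
  if (spec$include_density_dependence && st$gamma_dd > 0) return(-Inf)
  lp <- stats::dnorm(st$alpha, 0, pr$coef_sd, log = TRUE)
  inc_b <- st$inc_beta == 1L
  inc_g <- st$inc_gamma == 1L
  if (any(inc_b))
    lp <- lp + sum(stats::dnorm(st$beta[inc_b], 0, pr$coef_sd, log = TRUE))
  if (any(inc_g))
    lp <- lp + sum(stats::dnorm(st$gamma[inc_g], 0, pr$coef_sd, log = TRUE))
  if (spec$include_density_dependence && st$inc_dd == 1L)
    lp <- lp + log(2) + stats::dnorm(st$gamma_dd, 0, pr$coef_sd, log = TRUE)
  lp <- lp - log(pr$phi_max)   # U[0, phi_max]
  lp <- lp - log(2)            # U[0, 2] on p (restricted support)
  lp <- lp - length(st$mu0) * log(pr$mu0_max)
  a <- pr$sigma2_shape; b <- pr$sigma2_rate
  lp <- lp + a * log(b) - lgamma(a) - (a + 1) * log(st$sigma2) - b / st$sigma2
  q <- spec$inclusion_prior
  n_inc <- sum(st$inc_beta) + sum(st$inc_gamma) +
    if (spec$include_density_dependence) st$inc_dd else 0L
  n_sel <- length(st$inc_beta) + length(st$inc_gamma) +
    if (spec$include_density_dependence) 1L else 0L
  lp <- lp + n_inc * log(q) + (n_sel - n_inc) * log(1 - q)
  if (!is.null(x_site)) {
    m <- st$alpha + as.vector(x_site %*% (st$beta * st$inc_beta))
    lp <- lp + sum(stats::dnorm(st$eps, m, sqrt(st$sigma2), log = TRUE))
  }
  lp
}
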