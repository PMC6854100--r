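#' Deviance discrepancy
#'
#' The discrepancy statistic for posterior-predictive checking: the
#' dispersion-scaled total Tweedie deviance
#' \deqn{D(y; \theta) = \sum_{it \in \mathrm{obs}}
#'   d(y_{it}, \mu_{it}(\theta)) / \phi,}
#' summed over observed site-years only.  It is zero when every mean equals
#' its observation exactly.
#'
#' @param state a [parameter_state()] (or list with the same fields).
#' @param panel a normalized [observation_panel()].
#' @param spec a [model_spec()].
#' @return non-negative scalar.
#' @export
deviance_discrepancy <- function(state, panel, spec) {
  stopifnot(inherits(panel, "obs_panel"))
  if (!any(panel$obs)) return(0)
  lmu <- .check_divergence(.lmu_matrix(state, panel, spec), panel)
  o <- panel$obs
  sum(tweedie_unit_deviance(panel$y[o], exp(lmu[o]), state$p)) / state$phi
}

.state_from_draw <- function(chain, j) {
  S <- chain$samples
  list(alpha = S$alpha[j], beta = S$beta[j, ], gamma = S$gamma[j, ],
       gamma_dd = S$gamma_dd[j], eps = S$eps[j, ], sigma2 = S$sigma2[j],
       phi = S$phi[j], p = S$p[j], mu0 = S$mu0[j, ],
       inc_beta = rep(1L, 3), inc_gamma = rep(1L, ncol(S$gamma)),
       inc_dd = 1L)
}

#' Posterior-predictive Bayesian p-value
#'
#' For each retained draw, a replicate panel is simulated from the Tweedie
#' observation model at that draw's means on the observed missingness mask
#' (no imputation of unobserved site-years), and the deviance discrepancy
#' is computed for both the observed and the replicate data.  The Bayesian
#' p-value is the fraction of draws whose replicate discrepancy is at least
#' the observed one; values outside \[0.025, 0.975\] signal poor fit.
#'
#' @param chain a `tw_chain` from [run_chain()].
#' @param panel the normalized [observation_panel()] the chain was fitted to.
#' @param spec the [model_spec()] used for the fit.
#' @param seed integer seed for the replicate draws.
#' @param n_draws maximum number of posterior draws to use (evenly thinned).
#' @param keep_pairs store the (observed, replicate) discrepancy pairs.
#' @return object of class `gof_result` with fields `p_value`,
#'   `n_draws_used` and optionally `discrepancy_pairs`.
#' @export
bayesian_pvalue <- function(chain, panel, spec, seed = 1, n_draws = 500,
                            keep_pairs = FALSE) {
  stopifnot(inherits(chain, "tw_chain"), inherits(panel, "obs_panel"))
  n_avail <- length(chain$samples$alpha)
  if (n_avail < 1) stop("chain has no retained draws")
  use <- unique(round(seq(1, n_avail, length.out = min(n_draws, n_avail))))
  if (length(use) < 100)
    warning("fewer than 100 usable draws (", length(use),
            "); the Bayesian p-value will be noisy")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  o <- panel$obs
  y_obs <- panel$y[o]
  D_obs <- numeric(length(use)); D_rep <- numeric(length(use))
  for (jj in seq_along(use)) {
    st <- .state_from_draw(chain, use[jj])
    lmu <- .check_divergence(.lmu_matrix(st, panel, spec), panel)
    mu <- exp(lmu[o])
    D_obs[jj] <- sum(tweedie_unit_deviance(y_obs, mu, st$p)) / st$phi
    y_rep <- tweedie_sample(tweedie_params(mu, st$phi, st$p), length(mu))
    D_rep[jj] <- sum(tweedie_unit_deviance(y_rep, mu, st$p)) / st$phi
  }
  structure(list(p_value = mean(D_rep >= D_obs),
                 n_draws_used = length(use),
                 discrepancy_pairs = if (keep_pairs) cbind(observed = D_obs,
                                                           replicate = D_rep)),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  flag <- if (x$p_value < 0.025 || x$p_value > 0.975)
    " [outside 0.025-0.975: evidence of poor fit]" else ""
  cat(sprintf("Bayesian p-value: %.4f (%d draws)%s\n", x$p_value,
              x$n_draws_used, flag))
  invisible(x)
}
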