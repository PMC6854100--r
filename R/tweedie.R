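#' Tweedie compound Poisson-gamma parameters
#'
#' Bundles the mean/dispersion/index triple \eqn{(\mu, \phi, p)} of a Tweedie
#' distribution with variance \eqn{\phi \mu^p}.  Only the compound
#' Poisson-gamma branch \eqn{1 < p < 2} is supported: a Poisson number of
#' gamma summands, giving a continuous distribution on \eqn{(0, \infty)}
#' with a discrete mass at zero.  This is the observation model for averaged
#' winter count data, which are non-negative, right-skewed and contain exact
#' zeros.
#'
#' @param mu positive mean.
#' @param phi positive dispersion.
#' @param p index parameter, strictly inside (1, 2).
#' @return An object of class `tweedie_params`.
#' @examples
#' tw <- tweedie_params(mu = 2, phi = 0.5, p = 1.3)
#' to_compound_poisson(tw)
#' @export
tweedie_params <- function(mu, phi, p) {
  stopifnot(is.numeric(mu), is.numeric(phi), is.numeric(p),
            length(phi) == 1L, length(p) == 1L)
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be positive")
  if (!is.finite(phi) || phi <= 0) stop("phi must be positive")
  if (!is.finite(p) || p <= 1 || p >= 2)
    stop("index p must lie strictly inside (1, 2)")
  structure(list(mu = mu, phi = phi, p = p), class = "tweedie_params")
}

#' @export
print.tweedie_params <- function(x, ...) {
  cat("Tweedie(mu = ", format(x$mu), ", phi = ", format(x$phi),
      ", p = ", format(x$p), ")\n", sep = "")
  invisible(x)
}

#' Compound Poisson-gamma reparameterization
#'
#' Maps \eqn{(\mu, \phi, p)} to the generative form: a Poisson rate
#' \eqn{\lambda = \mu^{2-p} / (\phi (2-p))} of gamma summands with shape
#' \eqn{(2-p)/(p-1)} and scale \eqn{\phi (p-1) \mu^{p-1}}.  The implied mean
#' `lam * shape * scale` equals `mu` exactly; `exp(-lam)` is the probability
#' of an exact zero.
#'
#' As \eqn{p \to 2} the gamma shape diverges and as \eqn{p \to 1} the number
#' of summands does; a warning is issued within `1e-3` of either boundary.
#'
#' @param params a [tweedie_params()] object.
#' @return list with elements `lam`, `shape`, `scale`.
#' @export
to_compound_poisson <- function(params) {
  stopifnot(inherits(params, "tweedie_params"))
  p <- params$p
  if (p < 1 + 1e-3 || p > 2 - 1e-3)
    warning("index p within 1e-3 of the (1,2) boundary; ",
            "compound Poisson form is numerically fragile there")
  list(lam   = params$mu^(2 - p) / (params$phi * (2 - p)),
       shape = (2 - p) / (p - 1),
       scale = params$phi * (p - 1) * params$mu^(p - 1))
}

#' Tweedie log density
#'
#' Evaluates the log density of the compound Poisson-gamma Tweedie
#' distribution.  For `y = 0` this is the log point mass `-lam`; for `y > 0`
#' the density is computed by summing the series over the latent Poisson
#' count, truncated adaptively around its maximal term so that the dropped
#' tail is far below `1e-12` of the retained sum.  Non-convergence raises an
#' error rather than silently truncating.
#'
#' @param y non-negative numeric vector.
#' @param params a [tweedie_params()] object; `mu` may be a vector recycled
#'   against `y`.
#' @return numeric vector of log densities.
#' @examples
#' tw <- tweedie_params(1, 1, 1.5)
#' tweedie_log_density(0, tw)  # log P(Y = 0) = -2
#' @export
tweedie_log_density <- function(y, params) {
  stopifnot(inherits(params, "tweedie_params"))
  if (any(y < 0, na.rm = TRUE)) stop("y must be non-negative")
  n <- max(length(y), length(params$mu))
  y <- rep_len(y, n)
  lmu <- rep_len(log(params$mu), n)
  cpp_tw_logdens(as.numeric(y), lmu, params$phi, params$p)
}

#' Sample from a Tweedie distribution
#'
#' Draws via the generative mechanism: `N ~ Poisson(lam)` gamma summands,
#' whose sum is a single gamma variate with shape `N * shape` (zero when
#' `N = 0`).
#'
#' @param params a [tweedie_params()] object (`mu` may be a vector; it is
#'   recycled to length `n`).
#' @param n number of draws.
#' @param seed optional integer; when supplied the caller's RNG state is
#'   saved and restored, so the draw is reproducible and side-effect free.
#' @return numeric vector of `n` non-negative draws.
#' @export
tweedie_sample <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "tweedie_params"), n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  cp <- suppressWarnings(to_compound_poisson(params))
  mu <- rep_len(params$mu, n)
  lam <- rep_len(cp$lam, n)
  scl <- rep_len(cp$scale, n)
  N <- stats::rpois(n, lam)
  y <- numeric(n)
  pos <- N > 0L
  if (any(pos))
    y[pos] <- stats::rgamma(sum(pos), shape = N[pos] * cp$shape,
                            scale = scl[pos])
  y
}

#' Tweedie unit deviance
#'
#' The unit deviance of the Tweedie family for \eqn{1 < p < 2}:
#' \deqn{d(y, \mu) = 2\left( \frac{y^{2-p}}{(1-p)(2-p)} -
#'   \frac{y \mu^{1-p}}{1-p} + \frac{\mu^{2-p}}{2-p} \right),}
#' finite at `y = 0` (where it equals \eqn{2 \mu^{2-p} / (2-p)}), zero at
#' `y = mu`, and positive elsewhere.  Summed over cells and scaled by the
#' dispersion it is the discrepancy statistic used for posterior-predictive
#' goodness of fit.
#'
#' @param y non-negative observations.
#' @param mu positive means (recycled).
#' @param p index in (1, 2).
#' @return non-negative numeric vector.
#' @export
tweedie_unit_deviance <- function(y, mu, p) {
  if (p <= 1 || p >= 2) stop("index p must lie in (1, 2)")
  if (any(y < 0, na.rm = TRUE)) stop("y must be non-negative")
  if (any(mu <= 0, na.rm = TRUE)) stop("mu must be positive")
  2 * (y^(2 - p) / ((1 - p) * (2 - p)) - y * mu^(1 - p) / (1 - p) +
         mu^(2 - p) / (2 - p))
}
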