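#' Generate a survey design skeleton
#'
#' Emulates the structure of a long-running volunteer feeding-station
#' survey: a fixed number of concurrently active sites, an average annual
#' turnover under which retiring sites are replaced by new ones nearby
#' with the same habitat class, and time-varying covariates defined for
#' every site and year (weather and predator indices exist whether or not
#' a site was surveyed that year).  Defaults follow the surveyed
#' conditions this generator emulates: 174 active sites per year over 36
#' years with 8% annual turnover.
#'
#' Covariate processes are deliberately simple but realistic: winter
#' ground-frost days as a year-level AR(1) around 50 days plus site-level
#' noise (integer, clipped to \[0, 183\]); predator (sparrowhawk) counts as
#' small Poisson counts around a site rate with a rising national trend;
#' pseudo-predator (collared dove) counts likewise with a steeper rise.
#'
#' @param n_site number of sites active in each year.
#' @param T number of years (at least 3).
#' @param turnover_rate expected fraction of active sites replaced each
#'   year, in \[0, 0.5\].
#' @param urban_fraction probability a site is suburban/urban (+1).
#' @param seed integer seed; the skeleton is a deterministic function of
#'   the arguments.
#' @param covariate_pars optional overrides for the covariate processes
#'   (see Details in the package vignette).
#' @return list of class `panel_design` with the active-site mask, site
#'   covariates and time-varying covariate array over all distinct sites.
#' @export
generate_design <- function(n_site = 174, T = 36, turnover_rate = 0.08,
                            urban_fraction = 0.5, seed = 1,
                            covariate_pars = list()) {
  if (n_site < 2) stop("n_site must be at least 2")
  if (T < 3) stop("T must be at least 3")
  if (turnover_rate < 0 || turnover_rate > 0.5)
    stop("turnover_rate must lie in [0, 0.5]")
  cp <- utils::modifyList(list(
    frost_mean = 50, frost_ar = 0.5, frost_year_sd = 8, frost_site_sd = 5,
    hawk_start = 0.6, hawk_end = 1.6, hawk_site_sd = 0.35,
    dove_start = 0.8, dove_end = 3.0, dove_site_sd = 0.35), covariate_pars)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  coords <- cbind(northing = stats::runif(n_site, 0, 1000),
                  easting = stats::runif(n_site, 0, 1000))
  habitat <- ifelse(stats::runif(n_site) < urban_fraction, 1, -1)
  active_ids <- seq_len(n_site)
  start_year <- rep(1L, n_site)
  end_year <- rep(NA_integer_, n_site)
  for (t in 2:T) {
    k <- stats::rbinom(1, length(active_ids), turnover_rate)
    if (k > 0) {
      out <- sample(seq_along(active_ids), k)
      retiring <- active_ids[out]
      end_year[retiring] <- t - 1L
      # replacements: similar location and habitat to the site they replace
      new_coords <- coords[retiring, , drop = FALSE] +
        matrix(stats::rnorm(2 * k, 0, 30), k, 2)
      new_coords <- pmin(pmax(new_coords, 0), 1000)
      coords <- rbind(coords, new_coords)
      habitat <- c(habitat, habitat[retiring])
      new_ids <- nrow(coords) - k + seq_len(k)
      start_year <- c(start_year, rep(t, k))
      end_year <- c(end_year, rep(NA_integer_, k))
      active_ids[out] <- new_ids
    }
  }
  end_year[is.na(end_year)] <- T
  n_tot <- nrow(coords)
  active <- matrix(FALSE, n_tot, T)
  for (i in seq_len(n_tot)) active[i, start_year[i]:end_year[i]] <- TRUE
  # frost: shared year process + site offsets
  fy <- numeric(T)
  fy[1] <- cp$frost_mean + stats::rnorm(1, 0, cp$frost_year_sd)
  for (t in 2:T)
    fy[t] <- cp$frost_mean + cp$frost_ar * (fy[t - 1] - cp$frost_mean) +
      stats::rnorm(1, 0, cp$frost_year_sd)
  frost <- outer(stats::rnorm(n_tot, 0, cp$frost_site_sd), rep(1, T)) +
    outer(rep(1, n_tot), fy) + matrix(stats::rnorm(n_tot * T, 0, 3), n_tot, T)
  frost <- pmin(pmax(round(frost), 0), 183)
  trend_counts <- function(start, end, site_sd) {
    national <- seq(start, end, length.out = T) *
      exp(stats::rnorm(T, 0, 0.08))
    site_fac <- exp(stats::rnorm(n_tot, 0, site_sd))
    rate <- outer(site_fac, national)
    matrix(stats::rpois(n_tot * T, rate), n_tot, T)
  }
  hawk <- trend_counts(cp$hawk_start, cp$hawk_end, cp$hawk_site_sd)
  dove <- trend_counts(cp$dove_start, cp$dove_end, cp$dove_site_sd)
  v <- array(c(hawk, dove, frost), c(n_tot, T, 3),
             dimnames = list(NULL, NULL,
                             c("sparrowhawk", "collared_dove", "frost_days")))
  structure(list(site_ids = paste0("S", seq_len(n_tot)), years = seq_len(T),
                 active = active, x_site = cbind(coords, habitat = habitat),
                 v_time = v, n_site_active = n_site,
                 turnover_rate = turnover_rate, seed = seed),
            class = "panel_design")
}

#' Bundle generating truth for a synthetic panel
#'
#' Collects the design settings and the generating parameter values so
#' that a panel can be regenerated bit-exactly and fitted estimates
#' compared against truth.  Default effect sizes sit in the range typical
#' of fitted garden-bird models (coefficients of a few hundredths on
#' normalized covariates, index p around 1.3, dispersion around 0.5).
#'
#' @param n_site,T,turnover_rate,urban_fraction,covariate_pars design
#'   settings passed to [generate_design()].
#' @param alpha,beta,gamma,gamma_dd,sigma2,phi,p generating parameters
#'   (`beta` over northing/easting/habitat, `gamma` over the time-varying
#'   covariates as normalized by the fit; `gamma_dd` must be
#'   non-positive and is ignored under the change formulation).
#' @param mu0_band range from which pre-survey means are drawn uniformly;
#'   sub-interval of the \[0, 200\] prior support chosen to avoid
#'   degenerate all-zero series.
#' @param formulation `"standard"` or `"change"` generative mean structure.
#' @param seed integer seed.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_site = 174, T = 36, turnover_rate = 0.08,
                            urban_fraction = 0.5, covariate_pars = list(),
                            alpha = -0.02, beta = c(-0.01, -0.01, -0.005),
                            gamma = c(-0.05, 0.01, 0.02), gamma_dd = -0.03,
                            sigma2 = 0.005, phi = 0.5, p = 1.3,
                            mu0_band = c(2, 50),
                            formulation = c("standard", "change"), seed = 1) {
  formulation <- match.arg(formulation)
  if (gamma_dd > 0) stop("gamma_dd must be non-positive")
  if (p <= 1 || p >= 2) stop("p must lie in (1, 2)")
  if (mu0_band[1] <= 0 || mu0_band[2] > 200 || diff(mu0_band) <= 0)
    stop("mu0_band must be an increasing interval inside (0, 200]")
  structure(list(n_site = n_site, T = T, turnover_rate = turnover_rate,
                 urban_fraction = urban_fraction,
                 covariate_pars = covariate_pars, alpha = alpha, beta = beta,
                 gamma = gamma, gamma_dd = gamma_dd, sigma2 = sigma2,
                 phi = phi, p = p, mu0_band = mu0_band,
                 formulation = formulation, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Simulate an observation panel from known truth
#'
#' Draws site effects from the hierarchically centred normal, pre-survey
#' means uniformly from `truth$mu0_band`, propagates expected means
#' forward through the chosen mean structure (on the covariates exactly as
#' the fit will normalize them), and draws observed counts from the
#' Tweedie observation model at active site-years.  Regenerating with the
#' same truth reproduces the panel bit-exactly.
#'
#' @param truth a [synthetic_truth()].
#' @return list with elements `panel` (an unnormalized
#'   [observation_panel()] ready for fitting) and `truth` (the input
#'   augmented with the realized site effects and pre-survey means).
#' @export
simulate_panel <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  des <- generate_design(truth$n_site, truth$T, truth$turnover_rate,
                         truth$urban_fraction, truth$seed,
                         truth$covariate_pars)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(truth$seed + 1L)
  n <- nrow(des$x_site); T <- length(des$years)
  dd_ref <- mean(truth$mu0_band)
  # normalize covariates exactly as the fit will (population z-scores)
  zs <- function(z) (z - mean(z)) / sqrt(mean((z - mean(z))^2))
  xn <- des$x_site
  xn[, "northing"] <- zs(xn[, "northing"])
  xn[, "easting"] <- zs(xn[, "easting"])
  vn <- des$v_time
  for (k in 1:3) vn[, , k] <- zs(as.vector(vn[, , k]))
  eps <- stats::rnorm(n, truth$alpha + as.vector(xn %*% truth$beta),
                      sqrt(truth$sigma2))
  mu0 <- stats::runif(n, truth$mu0_band[1], truth$mu0_band[2])
  first <- apply(des$active, 1L, function(a) which(a)[1L])
  last <- apply(des$active, 1L, function(a) max(which(a)))
  if (truth$formulation == "standard") {
    lmu <- cpp_means_standard(log(mu0), eps, truth$gamma, truth$gamma_dd,
                              vn, first, last, dd_ref)
  } else {
    fake <- list(v_time_raw = des$v_time, first = first)
    lr <- change_logratios(fake)
    lmu <- cpp_means_change(log(mu0), eps, truth$gamma, lr, first, last)
  }
  if (any(is.na(lmu) & des$active))
    stop("divergent synthetic means (|log mu| > 50): use smaller effects ",
         "or a shorter horizon")
  y <- matrix(NA_real_, n, T)
  act <- which(des$active)
  mu_act <- exp(lmu[act])
  y[act] <- tweedie_sample(tweedie_params(mu_act, truth$phi, truth$p),
                           length(act))
  panel <- observation_panel(y, des$years, des$site_ids, des$x_site,
                             des$v_time, dd_ref = dd_ref)
  truth$eps <- eps
  truth$mu0 <- mu0
  truth$design <- des
  list(panel = panel, truth = truth)
}
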