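# Shared fixture builders: tiny panels and states constructed in code.

# small fully-specified panel with hand-controllable observations
toy_panel <- function(y, v = NULL, habitat = NULL, years = NULL,
                      dd_ref = NULL) {
  y <- as.matrix(y)
  n <- nrow(y); T <- ncol(y)
  if (is.null(years)) years <- seq_len(T)
  if (is.null(habitat)) habitat <- rep(c(-1, 1), length.out = n)
  x <- cbind(northing = seq(100, 900, length.out = n),
             easting = seq(900, 100, length.out = n),
             habitat = habitat)
  if (is.null(v)) {
    set.seed(42)
    v <- array(c(matrix(rpois(n * T, 1), n, T),
                 matrix(rpois(n * T, 2), n, T),
                 matrix(sample(20:80, n * T, TRUE), n, T)),
               c(n, T, 3),
               dimnames = list(NULL, NULL, c("sparrowhawk", "collared_dove",
                                             "frost_days")))
  }
  observation_panel(y, years, paste0("S", seq_len(n)), x, v, dd_ref = dd_ref)
}

# a panel in which no cell is observed (flat likelihood); bypasses the
# every-site-observed validation deliberately
empty_panel <- function(n = 2, T = 4) {
  p <- toy_panel(matrix(1, n, T))
  p$y[] <- NA_real_
  p$obs[] <- FALSE
  p$first <- rep(NA_integer_, n)
  p$last <- rep(NA_integer_, n)
  p
}

# normalized small random panel with strictly positive observations
random_panel <- function(n = 3, T = 4, seed = 7) {
  set.seed(seed)
  y <- matrix(rgamma(n * T, shape = 4, scale = 2), n, T)
  normalize_covariates(toy_panel(y))$panel
}

toy_state <- function(n, k = 3, ...) parameter_state(n_site = n, k_gamma = k, ...)
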