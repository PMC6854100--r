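#' Site-by-year observation panel
#'
#' Container for a panel of averaged winter counts: one row per site, one
#' column per year, `NA` marking site-years without observation.  Site-level
#' covariates are northing, easting and a rural (-1) / suburban-urban (+1)
#' habitat factor; time-varying covariates (by default predator count,
#' pseudo-predator count and ground-frost days) are carried for every
#' site-year, including years in which the count itself was not observed --
#' the mean recursion propagates through unobserved years and needs them.
#'
#' @param y numeric matrix (n_site x T) of non-negative values, `NA` where
#'   unobserved.
#' @param years integer vector of length T.
#' @param site_ids character/integer vector of length n_site.
#' @param x_site numeric matrix (n_site x 3) with columns `northing`,
#'   `easting`, `habitat` (habitat coded -1 rural / +1 suburban-urban).
#' @param v_time numeric array (n_site x T x K) of time-varying covariates;
#'   third dimension named (default `sparrowhawk`, `collared_dove`,
#'   `frost_days`).
#' @param dd_ref positive reference count used to scale the lagged expected
#'   count in the density-dependence term; defaults to the overall mean of
#'   the observed values.
#' @param validate logical; check invariants (non-negative observations,
#'   habitat in {-1, +1}, every site observed at least once, frost days in
#'   \[0, 183\]).
#' @return An object of class `obs_panel`.
#' @export
observation_panel <- function(y, years, site_ids, x_site, v_time,
                              dd_ref = NULL, validate = TRUE) {
  y <- as.matrix(y)
  x_site <- as.matrix(x_site)
  n <- nrow(y); T <- ncol(y)
  stopifnot(length(years) == T, length(site_ids) == n,
            nrow(x_site) == n, ncol(x_site) == 3L,
            length(dim(v_time)) == 3L,
            dim(v_time)[1] == n, dim(v_time)[2] == T)
  if (is.null(colnames(x_site)))
    colnames(x_site) <- c("northing", "easting", "habitat")
  if (is.null(dimnames(v_time)[[3]]))
    dimnames(v_time)[[3]] <- c("sparrowhawk", "collared_dove",
                               "frost_days")[seq_len(dim(v_time)[3])]
  obs <- !is.na(y)
  if (validate) {
    if (any(y[obs] < 0)) stop("observed counts must be non-negative")
    if (!all(x_site[, "habitat"] %in% c(-1, 1)))
      stop("habitat must be coded -1 (rural) / +1 (suburban-urban)")
    if (any(rowSums(obs) < 1L))
      stop("every site must have at least one observed year")
    if ("frost_days" %in% dimnames(v_time)[[3]]) {
      fd <- v_time[, , "frost_days"]
      if (any(fd < 0 | fd > 183, na.rm = TRUE))
        stop("frost_days must lie within [0, 183]")
    }
    if (any(!is.finite(v_time))) stop("time-varying covariates must be finite")
  }
  first <- apply(obs, 1L, function(o) if (any(o)) which(o)[1L] else NA_integer_)
  last <- apply(obs, 1L, function(o) if (any(o)) max(which(o)) else NA_integer_)
  if (is.null(dd_ref)) {
    dd_ref <- if (any(obs)) mean(y[obs]) else 1
    if (!is.finite(dd_ref) || dd_ref <= 0) dd_ref <- 1
  }
  structure(list(site_ids = site_ids, years = as.integer(years), y = y,
                 obs = obs, x_site = x_site, v_time = v_time,
                 first = as.integer(first), last = as.integer(last),
                 dd_ref = dd_ref, normalized = FALSE, scaling = NULL,
                 v_time_raw = NULL),
            class = "obs_panel")
}

#' @export
print.obs_panel <- function(x, ...) {
  cat("Observation panel: ", nrow(x$y), " sites x ", ncol(x$y), " years (",
      min(x$years), "-", max(x$years), "), ", sum(x$obs),
      " observed site-years\n", sep = "")
  zf <- mean(x$y[x$obs] == 0)
  cat("  zero fraction ", sprintf("%.3f", zf), "; covariates: ",
      paste(dimnames(x$v_time)[[3]], collapse = ", "),
      if (x$normalized) " [normalized]" else "", "\n", sep = "")
  invisible(x)
}

#' Read a panel from long-format CSV
#'
#' Expected columns: `site_id`, `year`, `y` (empty for missing),
#' `northing`, `easting`, `habitat`, plus one column per time-varying
#' covariate (default `sparrowhawk`, `collared_dove`, `frost_days`).
#'
#' @param path CSV file path.
#' @param tv_names names of the time-varying covariate columns.
#' @return An [observation_panel()].
#' @export
read_panel_csv <- function(path,
                           tv_names = c("sparrowhawk", "collared_dove",
                                        "frost_days")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "year", "y", "northing", "easting", "habitat", tv_names)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("panel CSV missing column(s): ", paste(miss, collapse = ", "))
  sites <- unique(d$site_id)
  years <- sort(unique(d$year))
  n <- length(sites); T <- length(years)
  si <- match(d$site_id, sites); ti <- match(d$year, years)
  idx <- cbind(si, ti)
  y <- matrix(NA_real_, n, T)
  y[idx] <- suppressWarnings(as.numeric(d$y))
  x_site <- matrix(NA_real_, n, 3,
                   dimnames = list(NULL, c("northing", "easting", "habitat")))
  fr <- !duplicated(si)
  x_site[si[fr], ] <- as.matrix(d[fr, c("northing", "easting", "habitat")])
  v <- array(NA_real_, c(n, T, length(tv_names)),
             dimnames = list(NULL, NULL, tv_names))
  for (k in seq_along(tv_names)) {
    vk <- matrix(NA_real_, n, T)
    vk[idx] <- d[[tv_names[k]]]
    # covariates must cover all site-years the recursion passes through;
    # fill interior gaps by per-site carry-forward of the nearest value
    vk <- t(apply(vk, 1L, .fill_locf))
    v[, , k] <- vk
  }
  observation_panel(y, years, sites, x_site, v)
}

.fill_locf <- function(z) {
  if (!anyNA(z)) return(z)
  ok <- which(!is.na(z))
  if (!length(ok)) return(rep(0, length(z)))
  idx <- findInterval(seq_along(z), ok)
  idx[idx == 0L] <- 1L
  z[ok][idx]
}

#' Write a panel to long-format CSV
#'
#' Inverse of [read_panel_csv()]; rows are emitted for every site-year a
#' covariate is defined, with `y` left empty where unobserved.
#'
#' @param panel an [observation_panel()] (unnormalized).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "obs_panel"))
  if (panel$normalized)
    stop("write the raw panel, not a normalized one")
  n <- nrow(panel$y); T <- ncol(panel$y)
  si <- rep(seq_len(n), T); ti <- rep(seq_len(T), each = n)
  d <- data.frame(site_id = panel$site_ids[si], year = panel$years[ti],
                  y = as.vector(panel$y),
                  northing = panel$x_site[si, "northing"],
                  easting = panel$x_site[si, "easting"],
                  habitat = panel$x_site[si, "habitat"])
  for (k in dimnames(panel$v_time)[[3]]) d[[k]] <- as.vector(panel$v_time[, , k])
  d <- d[order(d$site_id, d$year), ]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Normalize panel covariates
#'
#' Centres and scales the continuous covariates to unit variance: northing
#' and easting across sites, each time-varying covariate across all
#' site-years.  The +/-1 habitat factor is already on unit scale and passes
#' through untouched.  The raw time-varying covariates are retained on the
#' panel (the change-change formulation needs them for its log ratios), and
#' the per-covariate means and standard deviations are returned for
#' back-transformation of fitted coefficients to per-unit scale.
#'
#' @param panel an [observation_panel()].
#' @return list with elements `panel` (normalized) and `scaling`
#'   (data.frame with columns `name`, `mean`, `sd`).
#' @export
normalize_covariates <- function(panel) {
  stopifnot(inherits(panel, "obs_panel"))
  if (panel$normalized) stop("panel is already normalized")
  sc <- list()
  zscore <- function(z, name) {
    m <- mean(z); s <- sqrt(mean((z - m)^2))  # population sd
    if (!is.finite(s) || s == 0)
      stop("covariate '", name, "' is constant and cannot be normalized")
    sc[[name]] <<- c(mean = m, sd = s)
    (z - m) / s
  }
  x <- panel$x_site
  x[, "northing"] <- zscore(x[, "northing"], "northing")
  x[, "easting"] <- zscore(x[, "easting"], "easting")
  sc[["habitat"]] <- c(mean = 0, sd = 1)
  v_raw <- panel$v_time
  v <- v_raw
  for (k in dimnames(v)[[3]]) v[, , k] <- zscore(as.vector(v[, , k]), k)
  out <- panel
  out$x_site <- x
  out$v_time <- v
  out$v_time_raw <- v_raw
  out$normalized <- TRUE
  out$scaling <- data.frame(name = names(sc),
                            mean = vapply(sc, `[[`, 0, "mean"),
                            sd = vapply(sc, `[[`, 0, "sd"),
                            row.names = NULL)
  list(panel = out, scaling = out$scaling)
}
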