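#' Configuration for a synthetic river landscape
#'
#' Describes a rectangular study region with sites scattered uniformly at
#' random, an altitude surface rising with latitude, and a set of
#' environmental driver fields. Each driver is a deterministic linear trend
#' in altitude and latitude plus a spatially autocorrelated Gaussian residual
#' field with exponential covariance (correlation length `sac_range`).
#'
#' The default drivers mirror the covariates used in large-scale river
#' invasion studies, organised in the four classical groups:
#' Geography (`altitude`, `slope`), Climate (`temperature`, `precipitation`,
#' `drought`), Human factors (`eutrophication`, `human_footprint`,
#' `livestock_density`, `fragmentation`) and Land use (`artificial`,
#' `agricultural`, `forest`). Units are metres, percent slope, degrees C,
#' mm/year, days, index scores and percent cover respectively. Lowland areas
#' are warmer, drier, more eutrophic and more farmed than the uplands, the
#' gradient structure such surveys typically face.
#'
#' @param n_sites number of sampling sites (>= 2)
#' @param extent width and height of the region in km
#' @param sac_range correlation length (km) of the residual fields (> 0)
#' @param altitude_profile `c(max, exponent)`: altitude = max * (lat/height)^exponent
#' @param driver_gradients named list, one `c(intercept, altitude, lat)` per
#'   driver: value = intercept + altitude * alt_m + lat * northing_km + residual
#' @param noise_sd named numeric, marginal standard deviation of each
#'   driver's spatially correlated residual field (`altitude` entry included)
#' @param clamp named list of `c(lo, hi)` ranges applied after noise
#' @param seed integer seed; the same config and seed reproduce the landscape
#'   bit for bit
#' @return an object of class `landscape_config`
#' @export
landscape_config <- function(n_sites = 400,
                             extent = c(200, 200),
                             sac_range = 40,
                             altitude_profile = c(max = 1200, exponent = 1.5),
                             driver_gradients = NULL,
                             noise_sd = NULL,
                             clamp = NULL,
                             seed = 1L) {
  .check(length(n_sites) == 1 && n_sites >= 2, "n_sites must be >= 2")
  .check(length(extent) == 2 && all(extent > 0), "extent must be two positive lengths (km)")
  .check(length(sac_range) == 1 && sac_range > 0, "sac_range must be > 0")

  grads <- list(
    slope            = c(intercept = 1,    altitude = 0.012,    lat = 0),
    temperature      = c(intercept = 16,   altitude = -0.0065,  lat = 0),
    precipitation    = c(intercept = 600,  altitude = 0.6,      lat = 0),
    drought          = c(intercept = 35,   altitude = -0.012,   lat = 0),
    eutrophication   = c(intercept = 60,   altitude = -0.04,    lat = 0),
    human_footprint  = c(intercept = 28,   altitude = -0.015,   lat = 0),
    livestock_density = c(intercept = 60,  altitude = -0.035,   lat = 0),
    fragmentation    = c(intercept = 0.15, altitude = 3e-4,     lat = 0),
    artificial       = c(intercept = 12,   altitude = -0.006,   lat = 0),
    agricultural     = c(intercept = 55,   altitude = -0.03,    lat = 0),
    forest           = c(intercept = 20,   altitude = 0.035,    lat = 0)
  )
  if (!is.null(driver_gradients)) grads[names(driver_gradients)] <- driver_gradients

  sds <- c(altitude = 100, slope = 2, temperature = 1, precipitation = 90,
           drought = 5, eutrophication = 12, human_footprint = 6,
           livestock_density = 20, fragmentation = 0.12, artificial = 4,
           agricultural = 12, forest = 10)
  if (!is.null(noise_sd)) sds[names(noise_sd)] <- noise_sd

  cl <- list(altitude = c(0, Inf), slope = c(0, Inf), drought = c(0, Inf),
             eutrophication = c(0, 100), human_footprint = c(0, 50),
             livestock_density = c(0, Inf), fragmentation = c(0, 0.97),
             artificial = c(0, 100), agricultural = c(0, 100),
             forest = c(0, 100))
  if (!is.null(clamp)) cl[names(clamp)] <- clamp

  structure(list(n_sites = as.integer(n_sites), extent = extent,
                 sac_range = sac_range, altitude_profile = altitude_profile,
                 driver_gradients = grads, noise_sd = sds, clamp = cl,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' Simulate a Gaussian random field with exponential covariance
#'
#' Draws one realisation of a zero-mean Gaussian field at the given
#' coordinates, with covariance `sd^2 * exp(-d / range)` for inter-point
#' distance `d`. Uses a Cholesky factor of the covariance matrix, so it is
#' intended for up to a few thousand points.
#'
#' @param coords 2-column matrix of coordinates (km)
#' @param range correlation length (km), > 0
#' @param sd marginal standard deviation
#' @param nugget small variance added to the diagonal for numerical stability
#' @return numeric vector, one value per row of `coords`
#' @export
simulate_grf <- function(coords, range, sd = 1, nugget = 1e-8) {
  .check(range > 0, "range must be > 0")
  n <- nrow(coords)
  if (sd == 0) return(numeric(n))
  D <- .distmat(coords)
  C <- sd^2 * exp(-D / range)
  diag(C) <- diag(C) + nugget
  L <- chol(C)
  drop(crossprod(L, rnorm(n)))
}

#' Generate a synthetic site table
#'
#' Places sites uniformly in the configured extent and evaluates altitude and
#' every configured driver at each site: a deterministic gradient in altitude
#' and latitude plus a spatially autocorrelated Gaussian residual
#' (exponential covariance, correlation length `config$sac_range`). Setting a
#' driver's `noise_sd` to zero makes it an exact deterministic function of
#' the coordinates.
#'
#' @param config a [landscape_config()]
#' @return a data.frame (class `site_table`) with `site_id`, `x`, `y`
#'   (km), `altitude` (m) and one column per driver; the config and its hash
#'   are attached as attributes
#' @export
generate_landscape <- function(config = landscape_config()) {
  .check(inherits(config, "landscape_config"), "config must be a landscape_config")
  set.seed(config$seed)
  n <- config$n_sites
  w <- config$extent[1]; h <- config$extent[2]
  x <- runif(n, 0, w)
  y <- runif(n, 0, h)
  coords <- cbind(x, y)

  noise <- function(nm) {
    s <- config$noise_sd[[nm]]
    if (is.null(s) || s == 0) numeric(n) else simulate_grf(coords, config$sac_range, s)
  }
  clamp <- function(nm, v) {
    r <- config$clamp[[nm]]
    if (is.null(r)) v else pmin(pmax(v, r[1]), r[2])
  }

  ap <- config$altitude_profile
  altitude <- clamp("altitude", ap[["max"]] * (y / h)^ap[["exponent"]] + noise("altitude"))

  out <- data.frame(site_id = sprintf("s%04d", seq_len(n)), x = x, y = y,
                    altitude = altitude, stringsAsFactors = FALSE)
  for (nm in names(config$driver_gradients)) {
    g <- config$driver_gradients[[nm]]
    v <- g[["intercept"]] + g[["altitude"]] * altitude + g[["lat"]] * y + noise(nm)
    out[[nm]] <- clamp(nm, v)
  }
  attr(out, "config") <- config
  attr(out, "config_hash") <- .config_hash(config)
  class(out) <- c("site_table", "data.frame")
  out
}
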