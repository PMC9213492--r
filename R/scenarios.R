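#' Synthetic study with invasion planted on eutrophication and temperature
#'
#' A calibrated test bed with known ground truth: the landscape gives
#' eutrophication and temperature substantial spatially structured variation
#' that is only loosely tied to altitude, exotic species' niches depend on
#' those two drivers alone (eutrophication the stronger axis, mirroring the
#' typical dominance of nutrient pressure over climate in lowland invasion),
#' and native species prefer the opposite ends of both gradients. The
#' per-site invasion degree therefore rises with eutrophication and
#' temperature and carries no direct dependence on the remaining drivers,
#' which are present as decoy predictors.
#'
#' @param seed integer seed
#' @param n_sites number of sites
#' @param n_native,n_exotic species pool composition
#' @return list: `sites` (site table), `community`, `response` (data.frame
#'   with `invasion_degree`), `X` (driver matrix, coordinates excluded),
#'   `coords`
#' @export
scenario_planted <- function(seed = 1L, n_sites = 400, n_native = 18,
                             n_exotic = 7) {
  cfg <- landscape_config(
    n_sites = n_sites, seed = seed,
    driver_gradients = list(
      eutrophication = c(intercept = 55, altitude = -0.015, lat = 0),
      temperature    = c(intercept = 16, altitude = -0.004, lat = 0)),
    noise_sd = c(eutrophication = 25, temperature = 3))
  sites <- generate_landscape(cfg)
  pool <- generate_species_pool(
    n_native, n_exotic, seed = seed + 1000L,
    niche_vars = c("temperature", "eutrophication"),
    native_opt = list(temperature = c(8, 13), eutrophication = c(5, 35)),
    exotic_opt = list(temperature = c(17, 21), eutrophication = c(72, 95)),
    breadth = c(temperature = 5, eutrophication = 20))
  comm <- sample_communities(sites, pool, seed = seed + 2000L, dispersion = 0.3)
  deg <- invasion_degree(comm)
  deg <- deg[match(sites$site_id, deg$site_id), ]
  deg$invasion_degree[is.na(deg$invasion_degree)] <- 0
  drivers <- setdiff(names(sites), c("site_id", "x", "y"))
  list(sites = sites, community = comm,
       response = data.frame(site_id = sites$site_id,
                             invasion_degree = deg$invasion_degree),
       X = as.matrix(sites[, drivers]),
       coords = as.matrix(sites[, c("x", "y")]))
}

#' Synthetic regression data with spatially autocorrelated residuals
#'
#' A response driven by one real predictor plus a smooth Gaussian random
#' field in the residuals — the situation in which a model of the drivers
#' alone leaves significant spatial autocorrelation, and the
#' Voronoi-neighborhood autocovariate should absorb it.
#'
#' @param seed integer seed
#' @param n_sites number of sites
#' @param sac_sd standard deviation of the residual spatial field
#' @param noise_sd standard deviation of the unstructured noise
#' @return list: `X` (drivers), `y`, `coords`
#' @export
scenario_sac <- function(seed = 1L, n_sites = 300, sac_sd = 1, noise_sd = 0.3) {
  cfg <- landscape_config(n_sites = n_sites, seed = seed)
  sites <- generate_landscape(cfg)
  coords <- as.matrix(sites[, c("x", "y")])
  set.seed(seed + 500L)
  field <- simulate_grf(coords, range = 50, sd = sac_sd)
  eu <- as.numeric(scale(sites$eutrophication))
  y <- 1.0 * eu + field + rnorm(n_sites, 0, noise_sd)
  drivers <- setdiff(names(sites), c("site_id", "x", "y"))
  list(X = as.matrix(sites[, drivers]), y = y, coords = coords)
}
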