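#' Generate a pool of native and exotic fish species
#'
#' Each species gets a Gaussian niche (optimum and breadth) on a set of
#' niche-defining drivers, a body-size class and a maximum expected
#' abundance. Exotic species are biased — configurably — towards low-altitude,
#' warm, eutrophic conditions, the trait syndrome shared by most successful
#' freshwater invaders of lowland river stretches; natives span the full
#' gradients.
#'
#' @param n_native,n_exotic non-negative species counts
#' @param seed integer seed
#' @param niche_vars drivers that define the niches
#' @param native_opt,exotic_opt named list of `c(lo, hi)` uniform ranges for
#'   niche optima per niche variable
#' @param breadth named vector of niche breadths (sd of the Gaussian
#'   response, same units as the driver)
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of the
#'   maximum expected abundance (individuals per standardised survey)
#' @return data.frame (class `species_pool`), one row per species, with
#'   columns `species`, `origin`, `body_size_class`, `max_abundance` and
#'   `opt_*` / `breadth_*` per niche variable
#' @export
generate_species_pool <- function(n_native, n_exotic, seed = 1L,
                                  niche_vars = c("altitude", "temperature", "eutrophication"),
                                  native_opt = list(altitude = c(0, 1200),
                                                    temperature = c(7, 16),
                                                    eutrophication = c(5, 55)),
                                  exotic_opt = list(altitude = c(0, 350),
                                                    temperature = c(12, 20),
                                                    eutrophication = c(45, 95)),
                                  breadth = c(altitude = 300, temperature = 4,
                                              eutrophication = 25),
                                  abundance_meanlog = log(60),
                                  abundance_sdlog = 0.6) {
  .check(n_native >= 0 && n_exotic >= 0, "species counts must be >= 0")
  set.seed(seed)
  n <- n_native + n_exotic
  origin <- rep(c("native", "exotic"), c(n_native, n_exotic))
  pool <- data.frame(
    species = sprintf("sp_%s_%02d", substr(origin, 1, 3),
                      c(seq_len(n_native), seq_len(n_exotic))[seq_len(max(n, 0))]),
    origin = origin,
    body_size_class = if (n > 0) sample(c("small", "medium", "large"), n, replace = TRUE)
                      else character(0),
    max_abundance = rlnorm(n, abundance_meanlog, abundance_sdlog),
    stringsAsFactors = FALSE
  )
  for (v in niche_vars) {
    r_nat <- native_opt[[v]]; r_exo <- exotic_opt[[v]]
    opt <- c(runif(n_native, r_nat[1], r_nat[2]), runif(n_exotic, r_exo[1], r_exo[2]))
    pool[[paste0("opt_", v)]] <- opt
    br <- breadth[[v]] * exp(rnorm(n, 0, 0.15))
    .check(all(br > 0), "niche breadths must be positive")
    pool[[paste0("breadth_", v)]] <- br
  }
  attr(pool, "niche_vars") <- niche_vars
  class(pool) <- c("species_pool", "data.frame")
  pool
}

#' Default abundance breakpoints for ordinal field abundance classes
#'
#' Upper abundance bounds of classes 1 to 5 (class 5 is open-ended). The
#' original field protocol's bins are not reproduced here; these geometric
#' bins (1–2, 3–10, 11–50, 51–200, > 200 individuals) are a documented,
#' fully configurable stand-in.
#'
#' @param upper upper bounds of classes 1..4 (class 5 unbounded)
#' @param presence_threshold realized abundance below this records class 0
#' @return list with `upper` and `presence_threshold`
#' @export
moyle_breaks <- function(upper = c(2, 10, 50, 200), presence_threshold = 0.5) {
  .check(length(upper) == 4 && all(diff(upper) > 0) && all(upper > 0),
         "upper must be 4 increasing positive bounds")
  list(upper = upper, presence_threshold = presence_threshold)
}

#' Classify a continuous abundance into an ordinal abundance class 0-5
#' @param abundance nonnegative realized abundance
#' @param breaks a [moyle_breaks()] configuration
#' @return integer vector of classes 0..5
#' @export
classify_moyle <- function(abundance, breaks = moyle_breaks()) {
  .check(all(abundance >= 0), "abundance must be nonnegative")
  # class bins are upper-inclusive: (0, u1], (u1, u2], ..., (u4, Inf)
  cls <- findInterval(abundance, breaks$upper, left.open = TRUE) + 1L
  cls[abundance < breaks$presence_threshold] <- 0L
  as.integer(cls)
}

#' Sample fish communities over a site table
#'
#' For every site and species, the expected abundance is the species'
#' maximum abundance times a Gaussian niche response over the niche-defining
#' drivers. Realized abundance multiplies in gamma-distributed
#' (negative-binomial-style, mean 1) overdispersion noise, and is then
#' recorded as an ordinal abundance class via the configured breakpoints —
#' the same lossy discretisation a field survey applies.
#'
#' @param sites a `site_table` from [generate_landscape()]
#' @param pool a `species_pool` from [generate_species_pool()]
#' @param seed integer seed
#' @param dispersion variance of the multiplicative gamma noise (0 = off)
#' @param breaks a [moyle_breaks()] configuration
#' @param keep_absences if TRUE, class-0 rows are kept in the output
#' @return long data.frame (class `community_sample`): `site_id`, `species`,
#'   `origin`, `body_size_class`, `moyle_class`; the total number of sampled
#'   sites is attached as attribute `n_sites`
#' @export
sample_communities <- function(sites, pool, seed = 1L, dispersion = 0.4,
                               breaks = moyle_breaks(), keep_absences = FALSE) {
  .check(nrow(sites) > 0 && nrow(pool) > 0, "sites and pool must be non-empty")
  set.seed(seed)
  niche_vars <- attr(pool, "niche_vars")
  .check(all(niche_vars %in% names(sites)),
         "sites lack the pool's niche-defining driver columns")
  n_sites <- nrow(sites); n_sp <- nrow(pool)

  res <- vector("list", n_sp)
  for (k in seq_len(n_sp)) {
    logresp <- rep(0, n_sites)
    for (v in niche_vars) {
      opt <- pool[[paste0("opt_", v)]][k]
      br <- pool[[paste0("breadth_", v)]][k]
      logresp <- logresp - 0.5 * ((sites[[v]] - opt) / br)^2
    }
    lambda <- pool$max_abundance[k] * exp(logresp)
    noise <- if (dispersion > 0)
      rgamma(n_sites, shape = 1 / dispersion, scale = dispersion) else 1
    ab <- lambda * noise
    res[[k]] <- data.frame(site_id = sites$site_id,
                           species = pool$species[k],
                           origin = pool$origin[k],
                           body_size_class = pool$body_size_class[k],
                           moyle_class = classify_moyle(ab, breaks),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (!keep_absences) out <- out[out$moyle_class > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sites") <- n_sites
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("community_sample", "data.frame")
  out
}
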