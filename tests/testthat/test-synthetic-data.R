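test_that("zero-noise landscapes are exact deterministic functions of coordinates", {
  nm <- c("altitude", "slope", "temperature", "precipitation", "drought",
          "eutrophication", "human_footprint", "livestock_density",
          "fragmentation", "artificial", "agricultural", "forest")
  cfg <- landscape_config(n_sites = 50, seed = 7,
                          noise_sd = setNames(rep(0, length(nm)), nm))
  L <- generate_landscape(cfg)
  alt_expected <- 1200 * (L$y / 200)^1.5
  expect_equal(L$altitude, alt_expected, tolerance = 1e-12)
  expect_equal(L$temperature, 16 - 0.0065 * L$altitude, tolerance = 1e-12)
  expect_equal(L$precipitation, 600 + 0.6 * L$altitude, tolerance = 1e-12)
})

test_that("landscape generation is deterministic under a fixed seed", {
  cfg <- landscape_config(n_sites = 60, seed = 42)
  expect_identical(as.data.frame(generate_landscape(cfg)),
                   as.data.frame(generate_landscape(cfg)))
  cfg2 <- landscape_config(n_sites = 60, seed = 43)
  expect_false(identical(generate_landscape(cfg)$x, generate_landscape(cfg2)$x))
})

test_that("landscape rejects degenerate configuration", {
  expect_error(landscape_config(n_sites = 1), "n_sites")
  expect_error(landscape_config(sac_range = 0), "sac_range")
  expect_error(landscape_config(sac_range = -3), "sac_range")
})

test_that("generated fields carry detectable positive spatial autocorrelation", {
  cfg <- landscape_config(n_sites = 400, extent = c(200, 200), sac_range = 50,
                          seed = 5)
  L <- generate_landscape(cfg)
  coords <- cbind(L$x, L$y)
  set.seed(99)
  field <- simulate_grf(coords, range = 50, sd = 1)
  W <- voronoi_weights(coords)
  m <- morans_i(field, W, method = "permutation", nperm = 999,
                alternative = "greater")
  expect_gt(m$I, 0)
  expect_lt(m$p, 0.05)
  # and essentially none when the correlation length is tiny
  set.seed(99)
  white <- simulate_grf(coords, range = 1e-6, sd = 1)
  m0 <- morans_i(white, W, method = "permutation", nperm = 499,
                 alternative = "greater")
  expect_gt(m0$p, 0.01)
})

test_that("species pool respects counts and the exotic lowland bias", {
  expect_equal(nrow(generate_species_pool(0, 0)), 0)
  pool <- generate_species_pool(5, 3, seed = 2)
  expect_equal(nrow(pool), 8)
  expect_equal(sum(pool$origin == "exotic"), 3)
  expect_true(all(pool[, grep("^breadth_", names(pool))] > 0))
  # Monte-Carlo over seeds: exotic altitude optima sit lower than natives'
  diffs <- vapply(1:100, function(s) {
    p <- generate_species_pool(6, 6, seed = s)
    mean(p$opt_altitude[p$origin == "exotic"]) -
      mean(p$opt_altitude[p$origin == "native"])
  }, numeric(1))
  expect_lt(mean(diffs), 0)
})

test_that("community sampling honours niches, noise and discretisation", {
  cfg <- landscape_config(n_sites = 40, seed = 3)
  L <- generate_landscape(cfg)
  pool <- generate_species_pool(2, 1, seed = 3)
  # a species infinitely far from every site is absent everywhere
  pool$opt_altitude[1] <- 1e9
  comm <- sample_communities(L, pool, seed = 1, keep_absences = TRUE)
  expect_true(all(comm$moyle_class[comm$species == pool$species[1]] == 0L))
  # with noise off, a site at a species' exact optimum attains the top class
  pool2 <- generate_species_pool(0, 1, seed = 4)
  pool2$max_abundance <- 1000
  site1 <- L[1, ]
  for (v in attr(pool2, "niche_vars")) pool2[[paste0("opt_", v)]] <- site1[[v]]
  comm2 <- sample_communities(site1, pool2, seed = 1, dispersion = 0,
                              keep_absences = TRUE)
  expect_equal(comm2$moyle_class, 5L)
})

test_that("a low-altitude exotic produces altitude-declining invasion degree", {
  cfg <- landscape_config(n_sites = 400, seed = 11)
  L <- generate_landscape(cfg)
  pool <- generate_species_pool(6, 1, seed = 11)
  pool$opt_altitude[pool$origin == "exotic"] <- 0
  pool$breadth_altitude[pool$origin == "exotic"] <- 250
  comm <- sample_communities(L, pool, seed = 11)
  deg <- invasion_degree(comm)
  alt <- L$altitude[match(deg$site_id, L$site_id)]
  ct <- suppressWarnings(stats::cor.test(deg$invasion_degree, alt,
                                         method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("moyle classification maps abundance through the configured bins", {
  br <- moyle_breaks()
  expect_equal(classify_moyle(c(0, 0.4, 1, 2, 3, 10, 11, 200, 201, 1e6), br),
               c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 4L, 5L, 5L))
  expect_error(moyle_breaks(upper = c(5, 4, 3, 2)), "increasing")
})

test_that("barrier generation follows the category and Poisson structure", {
  net <- dendritic_network(4, 30, 0.7)
  expect_equal(nrow(generate_barriers(net, 0, seed = 1)), 0)
  b1 <- generate_barriers(net, 0.2, category_probs = c(1, 0, 0, 0), seed = 1)
  expect_true(all(b1$category == 1L))
  expect_error(generate_barriers(net, 0.1, category_probs = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
  # offsets stay inside their reach
  b <- generate_barriers(net, 0.3, seed = 2)
  len <- net$edges$length_km[match(b$edge_id, net$edges$edge_id)]
  expect_true(all(b$offset_km >= 0 & b$offset_km <= len))
  # counts are Poisson(density * length): 99% interval over repeated seeds
  lambda <- 0.1 * net$total_length
  counts <- vapply(1:200, function(s) nrow(generate_barriers(net, 0.1, seed = s)),
                   numeric(1))
  inside <- mean(counts >= qpois(0.005, lambda) & counts <= qpois(0.995, lambda))
  expect_gte(inside, 0.95)
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 200))
})

test_that("every generator is reproducible bit for bit under its seed", {
  net <- dendritic_network(3, 25, 0.7)
  expect_identical(generate_barriers(net, 0.2, seed = 9),
                   generate_barriers(net, 0.2, seed = 9))
  expect_identical(generate_species_pool(4, 4, seed = 9),
                   generate_species_pool(4, 4, seed = 9))
  L <- generate_landscape(landscape_config(n_sites = 30, seed = 9))
  p <- generate_species_pool(3, 2, seed = 9)
  expect_identical(sample_communities(L, p, seed = 9),
                   sample_communities(L, p, seed = 9))
  expect_identical(network_sites(net, 10, seed = 9),
                   network_sites(net, 10, seed = 9))
})
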