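test_that("livestock units apply the standard weights linearly", {
  expect_equal(livestock_units(0, 0, 0, 0), 0)
  expect_equal(livestock_units(poultry = 100), 1)  # 100 poultry = one cattle
  expect_equal(livestock_units(100, 10, 20, 4), 15)
  # linearity
  expect_equal(livestock_units(10, 2, 3, 4) + livestock_units(5, 1, 0, 2),
               livestock_units(15, 3, 3, 6))
  expect_error(livestock_units(cattle = -1), ">= 0")
})

test_that("reachable barriers match a Dijkstra oracle on a dendritic network", {
  net <- dendritic_network(2, 8, 0.8)
  # no barriers
  s <- list(edge_id = 1, offset_km = 3)
  empty <- generate_barriers(net, 0, seed = 1)
  expect_equal(nrow(reachable_barriers(s, net, empty)), 0)
  # single barrier 5 km away on the same reach
  one <- data.frame(barrier_id = 1L, edge_id = 1L, offset_km = 8 - 0 ,
                    category = 2L)
  one$offset_km <- 8  # at the downstream node of the 8-km outlet reach
  s0 <- list(edge_id = 1, offset_km = 3)
  rb <- reachable_barriers(s0, net, one, cutoff = 10)
  expect_equal(rb$distance_km, 5)
  # several barriers across the tree vs the independent shortest-path oracle
  set.seed(77)
  b6 <- generate_barriers(net, 0.15, seed = 77)
  expect_gte(nrow(b6), 4)
  for (site in list(list(edge_id = 1, offset_km = 2),
                    list(edge_id = 4, offset_km = 3.1))) {
    for (cut in c(5, 10, 25)) {
      rb <- reachable_barriers(site, net, b6, cutoff = cut)
      d_oracle <- vapply(seq_len(nrow(b6)), function(i)
        oracle_network_distance(net, site$edge_id, site$offset_km,
                                b6$edge_id[i], b6$offset_km[i]), numeric(1))
      expect_setequal(rb$barrier_id, b6$barrier_id[d_oracle <= cut])
      expect_equal(sort(rb$distance_km), sort(d_oracle[d_oracle <= cut]),
                   tolerance = 1e-9)
    }
  }
  expect_error(reachable_barriers(list(edge_id = 99, offset_km = 0), net, b6),
               "not on the network")
})

test_that("fragmentation index is bounded, monotone and matches closed form", {
  expect_equal(fragmentation_index(integer(0), numeric(0)), 0)
  expect_equal(fragmentation_index(4, 1), (2 / pi) * atan(4), tolerance = 1e-12)
  expect_equal(round(fragmentation_index(4, 1), 3), 0.844)
  set.seed(5)
  for (rep in 1:50) {
    k <- sample(1:8, 1)
    cats <- sample(1:4, k, replace = TRUE)
    d <- runif(k, 0, 10)
    fi <- fragmentation_index(cats, d)
    expect_true(fi >= 0 && fi < 1)
    # raising a category never decreases the index
    j <- sample(k, 1)
    cats2 <- cats; cats2[j] <- min(cats2[j] + 1, 4)
    expect_gte(fragmentation_index(cats2, d), fi)
    # pushing a barrier away never increases it
    d2 <- d; d2[j] <- d2[j] + 1
    expect_lte(fragmentation_index(cats, d2), fi)
  }
  # approaches 1 as the barrier load diverges; zero distance floored at eps
  expect_gt(fragmentation_index(rep(4, 50), rep(0.01, 50)), 0.999)
  expect_lt(fragmentation_index(4, 0), 1)
})

test_that("barrier summary combines count, mean distance and index", {
  net <- dendritic_network(1, 10, 1)
  b <- data.frame(barrier_id = 1:2, edge_id = c(1L, 1L),
                  offset_km = c(2, 9), category = c(1L, 4L))
  s <- list(edge_id = 1, offset_km = 5)
  bs <- barrier_summary(s, net, b, cutoff = 10)
  expect_equal(unname(bs["n_reachable"]), 2)
  expect_equal(unname(bs["mean_distance"]), mean(c(3, 4)))
  expect_equal(unname(bs["index"]),
               (2 / pi) * atan(1 / 3 + 4 / 4), tolerance = 1e-12)
})

test_that("IDW interpolation is exact at samples and recovers smooth fields", {
  one <- data.frame(x = 3, y = 4, value = 7)
  q <- data.frame(x = runif(10), y = runif(10))
  expect_equal(interpolate_idw(one, q), rep(7, 10))
  set.seed(8)
  samples <- data.frame(x = runif(100, 0, 100), y = runif(100, 0, 100))
  samples$value <- 2 + 0.05 * samples$x - 0.03 * samples$y  # linear field
  expect_equal(interpolate_idw(samples, samples[12, c("x", "y")]),
               samples$value[12])
  sites <- data.frame(x = runif(50, 10, 90), y = runif(50, 10, 90))
  truth <- 2 + 0.05 * sites$x - 0.03 * sites$y
  est <- interpolate_idw(samples, sites, power = 2)
  rmse <- sqrt(mean((est - truth)^2))
  expect_lt(rmse, 0.05 * diff(range(samples$value)))
  expect_error(interpolate_idw(samples[0, ], sites), "at least one")
})

test_that("radius aggregation equals brute-force enumeration", {
  set.seed(9)
  pts <- data.frame(x = runif(200, 0, 50), y = runif(200, 0, 50),
                    value = rnorm(200))
  site <- list(x = 25, y = 25)
  inside <- (pts$x - 25)^2 + (pts$y - 25)^2 <= 100
  expect_equal(aggregate_radius(pts, site, 10, "mean"), mean(pts$value[inside]))
  expect_equal(aggregate_radius(pts, site, 10, "min"), min(pts$value[inside]))
  expect_equal(aggregate_radius(pts, site, 10, "max"), max(pts$value[inside]))
  expect_equal(aggregate_radius(pts, site, 10, "sum-density"),
               sum(pts$value[inside]) / (pi * 100))
  # uniform field: mean is the constant; lone peak: max finds it
  pts$value <- 3.5
  expect_equal(aggregate_radius(pts, site, 10, "mean"), 3.5)
  pts$value[which(inside)[1]] <- 99
  expect_equal(aggregate_radius(pts, site, 10, "max"), 99)
  expect_warning(agg <- aggregate_radius(pts, list(x = 1e6, y = 1e6), 10, "mean"),
                 "no points")
  expect_true(is.na(agg))
})

test_that("eutrophication proxy scores clean water high and is monotone", {
  pristine <- data.frame(oxygen_saturation = 100, bod = 1, cod = 5, nh4 = 0.03,
                         no3 = 0.3, total_p = 0.02, e_coli = 100)
  expect_equal(eutrophication_proxy(pristine), 100)
  # worsening any single parameter never increases the score
  for (p in names(pristine)) {
    worse <- pristine
    worse[[p]] <- if (p == "oxygen_saturation") 60 else worse[[p]] * 10
    expect_lte(eutrophication_proxy(worse), eutrophication_proxy(pristine))
  }
  # identical stations score identically; fully missing stations are NA
  two <- rbind(pristine, pristine)
  expect_equal(eutrophication_proxy(two)[1], eutrophication_proxy(two)[2])
  missing <- pristine; missing[1, ] <- NA
  expect_true(is.na(eutrophication_proxy(missing)))
  half <- pristine; half$bod <- NA
  expect_false(is.na(eutrophication_proxy(half)))
})
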