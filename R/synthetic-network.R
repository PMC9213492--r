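#' Build a synthetic dendritic river network
#'
#' A binary branching tree: one outlet reach that splits recursively for
#' `n_levels` levels, headwater reaches shrinking geometrically. No real
#' hydrography is shipped; this topology is enough to exercise along-network
#' distance and barrier reachability.
#'
#' @param n_levels number of bifurcation levels (>= 0; 0 = one reach)
#' @param base_length length (km) of the outlet reach
#' @param length_decay multiplicative length factor per level
#' @return list of class `river_network`: `edges` data.frame
#'   (`edge_id`, `from`, `to`, `length_km`) and the total length
#' @export
dendritic_network <- function(n_levels = 4, base_length = 30, length_decay = 0.7) {
  .check(n_levels >= 0 && base_length > 0 && length_decay > 0,
         "n_levels >= 0 and positive lengths required")
  edges <- data.frame(edge_id = integer(), from = integer(), to = integer(),
                      length_km = numeric())
  node_counter <- 1L  # node 1 is the outlet
  tips <- data.frame(node = 1L, level = 0L)
  eid <- 0L
  for (lev in 0:n_levels) {
    len <- base_length * length_decay^lev
    new_tips <- list()
    for (i in seq_len(nrow(tips))) {
      n_children <- if (lev == 0) 1L else 2L
      for (ch in seq_len(n_children)) {
        node_counter <- node_counter + 1L
        eid <- eid + 1L
        edges <- rbind(edges, data.frame(edge_id = eid, from = tips$node[i],
                                         to = node_counter, length_km = len))
        new_tips[[length(new_tips) + 1L]] <- data.frame(node = node_counter,
                                                        level = lev + 1L)
      }
    }
    tips <- do.call(rbind, new_tips)
  }
  structure(list(edges = edges, total_length = sum(edges$length_km)),
            class = "river_network")
}

#' @export
print.river_network <- function(x, ...) {
  cat("river_network:", nrow(x$edges), "reaches,",
      round(x$total_length, 1), "km total\n")
  invisible(x)
}

#' Place migration barriers on a river network
#'
#' Barriers fall as a Poisson process of the given density along each reach,
#' and are assigned one of 4 categories — 1 small jump, 2 high jump, 3 minor
#' dam, 4 major dam — with the given probabilities.
#'
#' @param network a [dendritic_network()] (or any `river_network`)
#' @param density_per_km expected barriers per km (>= 0)
#' @param category_probs probabilities over the 4 categories, summing to 1
#' @param seed integer seed
#' @return data.frame of class `barrier_set`: `barrier_id`, `edge_id`,
#'   `offset_km` (from the reach's upstream `from` node), `category`
#' @export
generate_barriers <- function(network, density_per_km,
                              category_probs = c(0.4, 0.3, 0.2, 0.1),
                              seed = 1L) {
  .check(inherits(network, "river_network"), "network must be a river_network")
  .check(density_per_km >= 0, "density_per_km must be >= 0")
  .check(length(category_probs) == 4 && all(category_probs >= 0) &&
           abs(sum(category_probs) - 1) < 1e-8,
         "category_probs must be 4 nonnegative values summing to 1")
  set.seed(seed)
  ed <- network$edges
  counts <- rpois(nrow(ed), density_per_km * ed$length_km)
  idx <- rep(seq_len(nrow(ed)), counts)
  n <- length(idx)
  out <- data.frame(
    barrier_id = seq_len(n),
    edge_id = ed$edge_id[idx],
    offset_km = runif(n) * ed$length_km[idx],
    category = if (n > 0) sample(1:4, n, replace = TRUE, prob = category_probs)
               else integer(0)
  )
  class(out) <- c("barrier_set", "data.frame")
  out
}

#' Place survey sites at random positions along a river network
#' @param network a `river_network`
#' @param n number of sites
#' @param seed integer seed
#' @return data.frame with `site_id`, `edge_id`, `offset_km`
#' @export
network_sites <- function(network, n, seed = 1L) {
  .check(inherits(network, "river_network") && n >= 1, "need a network and n >= 1")
  set.seed(seed)
  ed <- network$edges
  pick <- sample(seq_len(nrow(ed)), n, replace = TRUE,
                 prob = ed$length_km / sum(ed$length_km))
  data.frame(site_id = sprintf("ns%03d", seq_len(n)),
             edge_id = ed$edge_id[pick],
             offset_km = runif(n) * ed$length_km[pick])
}
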