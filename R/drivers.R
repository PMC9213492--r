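#' Livestock units from animal counts
#'
#' Standard conversion combining farmed animals into one pressure variable:
#' poultry 0.01, cattle 1, sheep 0.1, pigs 0.5.
#'
#' @param poultry,cattle,sheep,pigs nonnegative counts (vectorised)
#' @return livestock units (LSU)
#' @export
livestock_units <- function(poultry = 0, cattle = 0, sheep = 0, pigs = 0) {
  .check(all(c(poultry, cattle, sheep, pigs) >= 0), "animal counts must be >= 0")
  0.01 * poultry + 1 * cattle + 0.1 * sheep + 0.5 * pigs
}

#' Along-network distance between two positions on a river network
#' @noRd
.network_distance <- function(network, g, node_dist, e1, o1, e2, o2) {
  ed <- network$edges
  r1 <- ed[ed$edge_id == e1, ]; r2 <- ed[ed$edge_id == e2, ]
  d <- Inf
  if (e1 == e2) d <- abs(o1 - o2)
  ends1 <- c(r1$from, r1$to); off1 <- c(o1, r1$length_km - o1)
  ends2 <- c(r2$from, r2$to); off2 <- c(o2, r2$length_km - o2)
  for (a in 1:2) for (b in 1:2) {
    dd <- off1[a] + node_dist[as.character(ends1[a]), as.character(ends2[b])] + off2[b]
    if (dd < d) d <- dd
  }
  d
}

#' Barriers reachable from a site along the river network
#'
#' Returns every barrier whose along-network distance from the site — in any
#' direction, upstream or downstream — does not exceed the cutoff. Distances
#' are shortest paths through the network geometry.
#'
#' @param site list or one-row data.frame with `edge_id` and `offset_km`
#' @param network a `river_network`
#' @param barriers a `barrier_set`
#' @param cutoff search radius along the network, km (default 10)
#' @return data.frame `barrier_id`, `category`, `distance_km`, sorted by
#'   distance; zero rows when nothing is reachable
#' @export
reachable_barriers <- function(site, network, barriers, cutoff = 10) {
  .check(inherits(network, "river_network"), "network must be a river_network")
  .check(all(c("edge_id", "offset_km") %in% names(site)),
         "site must carry edge_id and offset_km (snapped to the network)")
  ed <- network$edges
  .check(site$edge_id %in% ed$edge_id, "site is not on the network")
  len <- ed$length_km[ed$edge_id == site$edge_id]
  .check(site$offset_km >= 0 && site$offset_km <= len,
         "site offset outside its reach")

  nodes <- sort(unique(c(ed$from, ed$to)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$from), to = as.character(ed$to)),
    directed = FALSE, vertices = data.frame(name = as.character(nodes)))
  node_dist <- igraph::distances(g, weights = ed$length_km)

  if (nrow(barriers) == 0)
    return(data.frame(barrier_id = integer(), category = integer(),
                      distance_km = numeric()))
  d <- vapply(seq_len(nrow(barriers)), function(i)
    .network_distance(network, g, node_dist,
                      site$edge_id, site$offset_km,
                      barriers$edge_id[i], barriers$offset_km[i]), numeric(1))
  keep <- which(d <= cutoff)
  out <- data.frame(barrier_id = barriers$barrier_id[keep],
                    category = barriers$category[keep],
                    distance_km = d[keep])
  out[order(out$distance_km), , drop = FALSE]
}

#' River habitat fragmentation index
#'
#' A bounded score of the migration barriers reachable from a site:
#' `(2/pi) * atan( sum_b category_b / distance_b )`, which is 0 with no
#' reachable barrier, grows with barrier category (1 small jump .. 4 major
#' dam), shrinks with along-network distance (km), and approaches — but never
#' reaches — 1 as the barrier load diverges. A barrier sitting on the site
#' itself has its distance floored at `eps` to keep the sum finite.
#'
#' @param categories integer barrier categories in 1..4
#' @param distances_km positive along-network distances (km)
#' @param eps distance floor (km) for barriers at the site
#' @return a value in `[0, 1)`
#' @export
fragmentation_index <- function(categories, distances_km, eps = 0.01) {
  .check(length(categories) == length(distances_km),
         "categories and distances must have equal length")
  if (length(categories) == 0) return(0)
  .check(all(categories %in% 1:4), "categories must be integers 1..4")
  .check(all(distances_km >= 0), "distances must be nonnegative")
  d <- pmax(distances_km, eps)
  (2 / pi) * atan(sum(categories / d))
}

#' Summarise barrier pressure at a site
#'
#' The three fragmentation variables used as invasion drivers: the count of
#' reachable barriers within the cutoff, their mean along-network distance,
#' and the bounded fragmentation index.
#'
#' @inheritParams reachable_barriers
#' @param eps distance floor passed to [fragmentation_index()]
#' @return named numeric `c(n_reachable, mean_distance, index)`;
#'   `mean_distance` is NA when no barrier is reachable
#' @export
barrier_summary <- function(site, network, barriers, cutoff = 10, eps = 0.01) {
  rb <- reachable_barriers(site, network, barriers, cutoff)
  c(n_reachable = nrow(rb),
    mean_distance = if (nrow(rb)) mean(rb$distance_km) else NA_real_,
    index = fragmentation_index(rb$category, rb$distance_km, eps))
}

#' Inverse-distance-weighted interpolation of point samples
#'
#' Deterministic IDW estimate of a scalar field at query sites: a weighted
#' mean of the `k` nearest sample values with weights `1/d^power` (the
#' usual local form; `k = Inf` gives global IDW). Exact at sample locations
#' (a query within `tol` of a sample returns that sample's value).
#'
#' @param samples data.frame with `x`, `y`, `value`
#' @param sites data.frame with `x`, `y` query coordinates
#' @param power IDW exponent (default 2)
#' @param k number of nearest samples used per query (default 12)
#' @param tol coincidence tolerance in coordinate units
#' @return numeric vector of interpolated values, one per query site
#' @export
interpolate_idw <- function(samples, sites, power = 2, k = 12, tol = 1e-9) {
  .check(nrow(samples) >= 1, "need at least one sample point")
  .check(all(c("x", "y", "value") %in% names(samples)), "samples need x, y, value")
  .check(k >= 1, "k must be >= 1")
  vapply(seq_len(nrow(sites)), function(i) {
    dx <- samples$x - sites$x[i]; dy <- samples$y - sites$y[i]
    d <- sqrt(dx * dx + dy * dy)
    hit <- which(d <= tol)
    if (length(hit)) return(mean(samples$value[hit]))
    use <- if (is.finite(k) && k < length(d)) order(d)[seq_len(k)]
           else seq_along(d)
    w <- 1 / d[use]^power
    sum(w * samples$value[use]) / sum(w)
  }, numeric(1))
}

#' Aggregate a point field within a radius of a site
#'
#' Computes a summary of field values at fine points falling within
#' `radius_km` of the site. `"sum-density"` divides the sum by the disc area
#' (per km^2), the density form used for pressure variables so that they do
#' not scale with the aggregation area.
#'
#' @param points data.frame with `x`, `y`, `value`
#' @param site list or one-row data.frame with `x`, `y`
#' @param radius_km aggregation radius (> 0), default 10
#' @param stat one of `"mean"`, `"min"`, `"max"`, `"sum-density"`
#' @return the statistic, or NA (with a warning) when no point falls inside
#' @export
aggregate_radius <- function(points, site, radius_km = 10,
                             stat = c("mean", "min", "max", "sum-density")) {
  stat <- match.arg(stat)
  .check(radius_km > 0, "radius_km must be > 0")
  dx <- points$x - site$x; dy <- points$y - site$y
  v <- points$value[dx * dx + dy * dy <= radius_km^2]
  if (length(v) == 0) {
    warning("no points within ", radius_km, " km of site; returning NA")
    return(NA_real_)
  }
  switch(stat,
         mean = mean(v), min = min(v), max = max(v),
         `sum-density` = sum(v) / (pi * radius_km^2))
}

#' Default quality breakpoints for the eutrophication proxy
#'
#' Per water-quality parameter, the `best` (pristine) and `worst` values of a
#' linear 100-to-0 quality subscore. Oxygen saturation is scored on its
#' absolute deviation from 100 % saturation; E. coli on log10 counts.
#' Concentrations in mg/L; the bounds bracket typical lowland-river ranges.
#'
#' @return named list of `c(best, worst)` pairs
#' @export
eutrophication_breakpoints <- function() {
  list(oxygen_saturation = c(best = 0, worst = 60),   # |saturation - 100|
       bod = c(best = 1, worst = 15),
       cod = c(best = 5, worst = 50),
       nh4 = c(best = 0.03, worst = 3),
       no3 = c(best = 0.3, worst = 10),
       total_p = c(best = 0.02, worst = 0.6),
       e_coli = c(best = 2, worst = 4.7))             # log10 CFU / 100 mL
}

#' Composite eutrophication proxy from water-quality parameters
#'
#' Scores 7 nutrient-related parameters (oxygen saturation, BOD, COD, NH4,
#' NO3, total P, E. coli) per station: each parameter maps linearly to a
#' 0-100 quality subscore between its configured pristine (`best` = 100) and
#' degraded (`worst` = 0) breakpoints; the station index is the mean of the
#' available subscores. Orientation: high proxy = clean water / low
#' eutrophication. Missing parameters are skipped; a station with all 7
#' missing gets NA.
#'
#' @param params data.frame with columns `oxygen_saturation` (%), `bod`,
#'   `cod`, `nh4`, `no3`, `total_p` (mg/L), `e_coli` (CFU/100 mL)
#' @param breakpoints a [eutrophication_breakpoints()] list
#' @return numeric index per station (0 = degraded, 100 = pristine)
#' @export
eutrophication_proxy <- function(params, breakpoints = eutrophication_breakpoints()) {
  need <- names(eutrophication_breakpoints())
  .check(all(need %in% names(params)),
         paste("params must have columns:", paste(need, collapse = ", ")))
  sub <- sapply(need, function(p) {
    v <- params[[p]]
    if (p == "oxygen_saturation") v <- abs(v - 100)
    if (p == "e_coli") v <- log10(pmax(v, 1))
    b <- breakpoints[[p]]
    s <- 100 * (b[["worst"]] - v) / (b[["worst"]] - b[["best"]])
    pmin(pmax(s, 0), 100)
  })
  sub <- matrix(sub, nrow = nrow(params))
  rowMeans(sub, na.rm = TRUE) * ifelse(rowSums(!is.na(sub)) > 0, 1, NA)
}
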