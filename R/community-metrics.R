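#' Default weight table mapping abundance class and body size to abundance
#'
#' Field surveys record each species' abundance as an ordinal class 0-5;
#' converting classes to a body-mass-corrected abundance requires a class
#' midpoint and a body-size weight. The original bins are not public, so the
#' package ships a documented default — geometric class midpoints times size
#' weights 1 / 2 / 4 — and every metric accepts any positive table that is
#' strictly increasing in class within a size.
#'
#' @param class_midpoints abundance midpoints of classes 1..5 (increasing, > 0)
#' @param size_weights named positive weights per body-size class
#' @return list of class `moyle_weights`
#' @export
moyle_weight_table <- function(class_midpoints = c(1.5, 6.5, 30, 125, 400),
                               size_weights = c(small = 1, medium = 2, large = 4)) {
  .check(length(class_midpoints) == 5 && all(class_midpoints > 0) &&
           all(diff(class_midpoints) > 0),
         "class_midpoints must be 5 increasing positive values")
  .check(all(size_weights > 0) && !is.null(names(size_weights)),
         "size_weights must be named and positive")
  structure(list(class_midpoints = class_midpoints, size_weights = size_weights),
            class = "moyle_weights")
}

#' Convert ordinal abundance classes to body-mass-corrected abundance
#'
#' Abundance = class midpoint x body-size weight; class 0 (absent) maps to 0
#' for every size.
#'
#' @param moyle_class integer classes in 0..5
#' @param body_size_class labels present in `weights$size_weights`
#' @param weights a [moyle_weight_table()]
#' @return numeric abundance vector
#' @export
moyle_to_abundance <- function(moyle_class, body_size_class,
                               weights = moyle_weight_table()) {
  .check(inherits(weights, "moyle_weights"), "weights must be a moyle_weight_table")
  .check(all(moyle_class %in% 0:5), "moyle_class must be in 0..5")
  .check(all(body_size_class %in% names(weights$size_weights)),
         "unknown body_size_class value")
  mid <- c(0, weights$class_midpoints)[moyle_class + 1L]
  mid * unname(weights$size_weights[body_size_class])
}

#' Attach body-mass-corrected abundance to community records
#' @param records long-format community records (`site_id`, `species`,
#'   `origin`, `moyle_class`, `body_size_class`)
#' @param weights a [moyle_weight_table()]
#' @return `records` with an `abundance` column
#' @export
add_abundance <- function(records, weights = moyle_weight_table()) {
  need <- c("site_id", "species", "origin", "moyle_class", "body_size_class")
  .check(all(need %in% names(records)),
         paste("records must have columns:", paste(need, collapse = ", ")))
  records$abundance <- moyle_to_abundance(records$moyle_class,
                                          records$body_size_class, weights)
  records
}

#' Per-site invasion degree
#'
#' The share of a site's total (body-mass-corrected) community abundance
#' contributed by exotic species: 0 for an all-native community, 1 for an
#' all-exotic one. A site whose records sum to zero abundance has no defined
#' community and is reported as `NA`, never as 0.
#'
#' @param records community records; an `abundance` column is computed with
#'   `weights` if absent
#' @param weights a [moyle_weight_table()]
#' @return data.frame `site_id`, `invasion_degree`
#' @export
invasion_degree <- function(records, weights = moyle_weight_table()) {
  if (is.null(records$abundance)) records <- add_abundance(records, weights)
  .check(all(records$origin %in% c("native", "exotic")),
         "origin must be 'native' or 'exotic'")
  tot <- tapply(records$abundance, records$site_id, sum)
  exo <- tapply(records$abundance * (records$origin == "exotic"),
                records$site_id, sum)
  deg <- ifelse(tot > 0, exo / tot, NA_real_)
  data.frame(site_id = names(tot), invasion_degree = as.numeric(deg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-site relative abundance of one species
#'
#' The share of each site's total abundance held by `species` (0 where
#' absent, NA for empty sites). The species-level analogue of the invasion
#' degree, used as the response when modelling single invaders.
#'
#' @inheritParams invasion_degree
#' @param species one species label
#' @return data.frame `site_id`, `relative_abundance`
#' @export
species_share <- function(records, species, weights = moyle_weight_table()) {
  if (is.null(records$abundance)) records <- add_abundance(records, weights)
  tot <- tapply(records$abundance, records$site_id, sum)
  sp <- tapply(records$abundance * (records$species == species),
               records$site_id, sum)
  data.frame(site_id = names(tot),
             relative_abundance = as.numeric(ifelse(tot > 0, sp / tot, NA_real_)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Colonization and prevalence of one species
#'
#' Colonization is the percentage of all sampled sites where the species is
#' present; prevalence is its average relative abundance (%) in the fish
#' community over the sites where it is present. A species absent everywhere
#' has colonization 0 and undefined (NA) prevalence.
#'
#' @inheritParams invasion_degree
#' @param species one species label
#' @param n_sites total number of sampled sites; defaults to the records'
#'   `n_sites` attribute, else the number of distinct non-empty sites
#' @return named numeric `c(colonization, prevalence)` in percent
#' @export
colonization_prevalence <- function(records, species, n_sites = NULL,
                                    weights = moyle_weight_table()) {
  if (is.null(records$abundance)) records <- add_abundance(records, weights)
  if (is.null(n_sites)) n_sites <- attr(records, "n_sites")
  tot <- tapply(records$abundance, records$site_id, sum)
  occupied <- names(tot)[tot > 0]
  if (is.null(n_sites)) n_sites <- length(occupied)
  .check(n_sites > 0, "total site count must be positive")

  rec_sp <- records[records$species == species & records$abundance > 0, , drop = FALSE]
  present_sites <- unique(rec_sp$site_id)
  colonization <- 100 * length(present_sites) / n_sites
  if (length(present_sites) == 0) return(c(colonization = 0, prevalence = NA_real_))
  sp_ab <- tapply(rec_sp$abundance, rec_sp$site_id, sum)
  prevalence <- mean(100 * sp_ab / tot[names(sp_ab)])
  c(colonization = colonization, prevalence = unname(prevalence))
}

#' Invasiveness index and ranking of exotic species
#'
#' For every exotic species, index = colonization x prevalence (both in
#' percent, so the index lies in 0..10000). Species are ranked by descending
#' index; ties break by descending colonization, then species label.
#'
#' @inheritParams colonization_prevalence
#' @param exotic_species labels to rank; defaults to all species recorded
#'   with origin `"exotic"`
#' @return data.frame (class `invasiveness_table`): `rank`, `species`,
#'   `index`, `colonization`, `prevalence`
#' @export
invasiveness_rank <- function(records, exotic_species = NULL, n_sites = NULL,
                              weights = moyle_weight_table()) {
  if (is.null(records$abundance)) records <- add_abundance(records, weights)
  if (is.null(exotic_species))
    exotic_species <- sort(unique(records$species[records$origin == "exotic"]))
  .check(length(exotic_species) >= 1, "need at least one exotic species")

  rows <- lapply(exotic_species, function(sp) {
    cp <- colonization_prevalence(records, sp, n_sites = n_sites, weights = weights)
    data.frame(species = sp, colonization = cp[["colonization"]],
               prevalence = cp[["prevalence"]],
               index = if (cp[["colonization"]] == 0) 0
                       else cp[["colonization"]] * cp[["prevalence"]],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$index, -tab$colonization, tab$species)
  tab <- tab[ord, c("species", "index", "colonization", "prevalence")]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  class(tab) <- c("invasiveness_table", "data.frame")
  tab
}
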