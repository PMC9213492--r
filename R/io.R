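#' Write a table of points as a GeoJSON FeatureCollection
#'
#' Each row becomes a Point feature; all non-coordinate columns are carried
#' as properties.
#'
#' @param df data.frame containing the coordinate columns
#' @param path output file
#' @param coords names of the x and y columns
#' @export
write_geojson_points <- function(df, path, coords = c("x", "y")) {
  .check(all(coords %in% names(df)), "coordinate columns missing")
  props <- df[, setdiff(names(df), coords), drop = FALSE]
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df[[coords[1]]][i], df[[coords[2]]][i])),
         properties = as.list(props[i, , drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection of points into a data.frame
#' @param path GeoJSON file
#' @param coords names given to the coordinate columns
#' @return data.frame with coordinates and feature properties
#' @export
read_geojson_points <- function(path, coords = c("x", "y")) {
  gj <- jsonlite::read_json(path)
  .check(identical(gj$type, "FeatureCollection"), "not a FeatureCollection")
  rows <- lapply(gj$features, function(f) {
    .check(identical(f$geometry$type, "Point"), "only Point features supported")
    xy <- unlist(f$geometry$coordinates)
    c(setNames(as.list(xy[1:2]), coords), f$properties)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Read a long-format community CSV
#'
#' Expected columns: `site_id`, `species`, `origin`, `moyle_class`,
#' `body_size_class`.
#'
#' @param path CSV file
#' @param n_sites total number of sampled sites (attached as attribute);
#'   defaults to the number of distinct site_ids in the file
#' @return data.frame of class `community_sample`
#' @export
read_community_csv <- function(path, n_sites = NULL) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "species", "origin", "moyle_class", "body_size_class")
  .check(all(need %in% names(rec)),
         paste("community CSV must have columns:", paste(need, collapse = ", ")))
  attr(rec, "n_sites") <- if (is.null(n_sites)) length(unique(rec$site_id))
                          else as.integer(n_sites)
  class(rec) <- c("community_sample", "data.frame")
  rec
}

#' Write a community sample to CSV (long format)
#' @param records a `community_sample`
#' @param path output CSV
#' @export
write_community_csv <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
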