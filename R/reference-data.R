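#' Published top-10 invasiveness ranking for Italian freshwater fish
#'
#' The printed national ranking of the ten most invasive freshwater fish
#' species in Italy — rank, invasiveness index, colonization (% of sampled
#' sites with presence) and prevalence (average % of the fish community
#' where present), all rounded to two decimals as published. Shipped as a
#' worked example: the invasiveness index should equal colonization times
#' prevalence, up to the rounding of the printed inputs.
#'
#' @return data.frame with `rank`, `species`, `common_name`, `index`,
#'   `colonization`, `prevalence`
#' @export
italy_top10 <- function() {
  read.csv(system.file("extdata", "italy_top10_invasiveness.csv",
                       package = "fishinv"), stringsAsFactors = FALSE)
}
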