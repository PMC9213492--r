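#' Configuration for the end-to-end analysis pipeline
#'
#' Wires the stages together: simulate a study (or load one), compute the
#' community invasion metrics, assemble the driver table, fit the boosted
#' tree protocol for the overall invasion degree and the top-N invaders,
#' and run the variation partitioning and redundancy analysis. Geographic
#' coordinates are never used as predictors — they proxy the very drivers
#' under study.
#'
#' @param seed global seed; stage seeds derive from it
#' @param stages subset of `c("simulate", "metrics", "brt", "varpart", "rda")`
#' @param landscape a [landscape_config()] (its seed is overridden by `seed`)
#' @param n_native,n_exotic species pool composition for the simulate stage
#' @param brt a [brt_config()]
#' @param top_n how many top-ranked invaders get a species-level BRT model
#' @param groups named list mapping the four driver groups to driver columns
#' @param vif_threshold collinearity screening cutoff for varpart/RDA
#' @param n_perm_varpart,n_perm_rda permutation counts of the two test
#'   families
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("simulate", "metrics", "brt",
                                       "varpart", "rda"),
                            landscape = landscape_config(),
                            n_native = 18, n_exotic = 7,
                            brt = brt_config(),
                            top_n = 10,
                            groups = list(
                              Geography = c("altitude", "slope"),
                              Climate = c("temperature", "precipitation", "drought"),
                              Human = c("eutrophication", "human_footprint",
                                        "livestock_density", "fragmentation"),
                              Landuse = c("artificial", "agricultural", "forest")),
                            vif_threshold = 8,
                            n_perm_varpart = 999, n_perm_rda = 499) {
  structure(list(seed = as.integer(seed), stages = stages,
                 landscape = landscape, n_native = n_native,
                 n_exotic = n_exotic, brt = brt, top_n = top_n,
                 groups = groups, vif_threshold = vif_threshold,
                 n_perm_varpart = n_perm_varpart, n_perm_rda = n_perm_rda),
            class = "pipeline_config")
}

#' Run the invasion analysis pipeline
#'
#' Executes the enabled stages in order and, when `out_dir` is given, writes
#' the machine-readable outputs: sites GeoJSON, community and driver CSVs,
#' the per-site invasion-degree and invasiveness ranking CSVs, a JSON report
#' per boosted-tree model, the variation-partitioning fractions CSV with
#' permutation p-values and Euler-Venn areas JSON, the RDA score CSVs and
#' axis-test JSON, and a manifest carrying the config hash. Identical config
#' and seed reproduce identical outputs.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created); NULL for no files
#' @param community optional pre-existing `community_sample` (skips the
#'   simulate stage's community)
#' @param sites optional pre-existing site table with driver columns
#' @param quiet suppress progress messages
#' @return list of class `pipeline_result` with each stage's objects
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         community = NULL, sites = NULL, quiet = FALSE) {
  .check(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  say <- function(...) if (!quiet) message(...)
  hash <- .config_hash(config)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(name, writer) if (!is.null(out_dir)) {
    writer(file.path(out_dir, name)); name
  } else NULL
  manifest <- list(config_hash = hash, seed = config$seed, files = character())
  res <- list(config = config, config_hash = hash)

  if ("simulate" %in% config$stages && (is.null(sites) || is.null(community))) {
    say("stage simulate: landscape + species pool + communities")
    lc <- config$landscape; lc$seed <- config$seed
    if (is.null(sites)) sites <- generate_landscape(lc)
    if (is.null(community)) {
      pool <- generate_species_pool(config$n_native, config$n_exotic,
                                    seed = config$seed + 1000L)
      community <- sample_communities(sites, pool, seed = config$seed + 2000L)
      res$pool <- pool
    }
    manifest$files <- c(manifest$files,
      emit("sites.geojson", function(p) write_geojson_points(as.data.frame(sites), p)),
      emit("community.csv", function(p) write_community_csv(community, p)))
  }
  .check(!is.null(sites) && !is.null(community),
         "need sites and community (enable the simulate stage or supply them)")
  res$sites <- sites; res$community <- community

  driver_cols <- setdiff(names(sites), c("site_id", "x", "y"))
  X <- as.matrix(as.data.frame(sites)[, driver_cols])
  rownames(X) <- sites$site_id
  coords <- as.matrix(as.data.frame(sites)[, c("x", "y")])
  manifest$files <- c(manifest$files,
    emit("drivers.csv", function(p)
      write.csv(data.frame(site_id = sites$site_id, X), p, row.names = FALSE)))

  if ("metrics" %in% config$stages) {
    say("stage metrics: invasion degree + invasiveness ranking")
    deg <- invasion_degree(community)
    rank_tab <- invasiveness_rank(community)
    res$invasion_degree <- deg
    res$invasiveness <- rank_tab
    manifest$files <- c(manifest$files,
      emit("invasion_degree.csv", function(p) write.csv(deg, p, row.names = FALSE)),
      emit("invasiveness.csv", function(p)
        write.csv(as.data.frame(rank_tab), p, row.names = FALSE)))
  }

  y_deg <- NULL
  if (any(c("brt", "varpart", "rda") %in% config$stages)) {
    deg <- if (!is.null(res$invasion_degree)) res$invasion_degree
           else invasion_degree(community)
    y_deg <- deg$invasion_degree[match(sites$site_id, deg$site_id)]
    y_deg[is.na(y_deg)] <- 0
  }

  if ("brt" %in% config$stages) {
    say("stage brt: overall invasion degree")
    cfg_b <- config$brt; cfg_b$seed <- config$seed
    res$brt_overall <- run_brt_pipeline(X, y_deg, coords, cfg_b)
    manifest$files <- c(manifest$files,
      emit("brt_overall.json", function(p) .write_brt_json(res$brt_overall, hash, p)))
    if (config$top_n > 0) {
      rk <- if (!is.null(res$invasiveness)) res$invasiveness
            else invasiveness_rank(community)
      top <- head(rk$species, config$top_n)
      res$brt_species <- lapply(setNames(top, top), function(sp) {
        say("stage brt: species ", sp)
        ysp <- species_share(community, sp)
        yv <- ysp$relative_abundance[match(sites$site_id, ysp$site_id)]
        yv[is.na(yv)] <- 0
        if (sd(yv) == 0) return(NULL)
        run_brt_pipeline(X, yv, coords, cfg_b)
      })
      for (sp in names(res$brt_species)) if (!is.null(res$brt_species[[sp]]))
        manifest$files <- c(manifest$files,
          emit(paste0("brt_", gsub("[^A-Za-z0-9]", "_", sp), ".json"),
               function(p) .write_brt_json(res$brt_species[[sp]], hash, p)))
    }
  }

  groups_X <- NULL
  if (any(c("varpart", "rda") %in% config$stages)) {
    groups_X <- lapply(config$groups, function(cols) {
      cols <- intersect(cols, colnames(X))
      vf <- vif_filter(X[, cols, drop = FALSE], config$vif_threshold)
      vf$X
    })
  }

  if ("varpart" %in% config$stages) {
    say("stage varpart: 4-group variation partitioning")
    res$varpart <- variation_partition(y_deg, groups_X,
                                       n_perm = config$n_perm_varpart,
                                       seed = config$seed)
    manifest$files <- c(manifest$files,
      emit("varpart_fractions.csv", function(p)
        write.csv(res$varpart$fractions, p, row.names = FALSE)),
      emit("varpart.json", function(p)
        jsonlite::write_json(list(config_hash = hash,
                                  full_adj_r2 = res$varpart$full_adj_r2,
                                  residual = res$varpart$residual,
                                  unique_p = as.list(res$varpart$unique_p),
                                  venn_areas = venn_areas(res$varpart)),
                             p, auto_unbox = TRUE, digits = NA)))
  }

  if ("rda" %in% config$stages) {
    say("stage rda: top invaders ~ drivers")
    rk <- if (!is.null(res$invasiveness)) res$invasiveness
          else invasiveness_rank(community)
    top <- head(rk$species[rk$index > 0], config$top_n)
    Y <- vapply(top, function(sp) {
      sh <- species_share(community, sp)
      v <- sh$relative_abundance[match(sites$site_id, sh$site_id)]
      v[is.na(v)] <- 0
      v
    }, numeric(nrow(sites)))
    Xr <- do.call(cbind, groups_X)
    res$rda <- rda_fit(Y, Xr)
    res$rda_axes <- rda_axis_test(res$rda, n_perm = config$n_perm_rda,
                                  seed = config$seed,
                                  max_axes = min(4, length(res$rda$eigenvalues)))
    manifest$files <- c(manifest$files,
      emit("rda_species_scores.csv", function(p)
        write.csv(data.frame(species = rownames(res$rda$species_scores),
                             res$rda$species_scores), p, row.names = FALSE)),
      emit("rda_site_scores.csv", function(p)
        write.csv(data.frame(site_id = sites$site_id, res$rda$wa_scores),
                  p, row.names = FALSE)),
      emit("rda_biplot_scores.csv", function(p)
        write.csv(data.frame(driver = rownames(res$rda$biplot_scores),
                             res$rda$biplot_scores), p, row.names = FALSE)),
      emit("rda_axis_tests.json", function(p)
        jsonlite::write_json(list(config_hash = hash,
                                  adj_r2 = res$rda$adj_r2,
                                  proportion = as.list(res$rda$proportion),
                                  axes = res$rda_axes),
                             p, auto_unbox = TRUE, digits = NA)))
  }

  if (!is.null(out_dir)) {
    manifest$files <- manifest$files[!vapply(manifest$files, is.null, logical(1))]
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(res) <- "pipeline_result"
  res
}

#' @noRd
.write_brt_json <- function(br, hash, path) {
  jsonlite::write_json(
    list(config_hash = hash,
         selected_variables = br$selected_variables,
         vi = as.list(br$vi), direction = as.list(br$direction),
         cv_r2 = br$cv_r2, sac_used = br$sac_used,
         sac_share = br$sac_share, sac_cv_r2_gain = br$sac_cv_r2_gain,
         moran_initial = if (!is.null(br$moran_initial))
           list(I = br$moran_initial$I, p = br$moran_initial$p),
         moran_final = if (!is.null(br$moran_final))
           list(I = br$moran_final$I, p = br$moran_final$p),
         log = br$log),
    path, auto_unbox = TRUE, digits = NA)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Invasion analysis pipeline (config hash", x$config_hash, ")\n")
  if (!is.null(x$invasiveness)) {
    cat("Top invaders:\n")
    print(utils::head(as.data.frame(x$invasiveness), 5))
  }
  if (!is.null(x$brt_overall)) print(x$brt_overall)
  if (!is.null(x$varpart))
    cat("Variation partitioning full adjusted R^2:",
        round(x$varpart$full_adj_r2, 4), "\n")
  if (!is.null(x$rda))
    cat("RDA axis 1 explains", round(100 * x$rda$proportion[1], 2),
        "% of variance\n")
  invisible(x)
}
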