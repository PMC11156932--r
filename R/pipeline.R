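# End-to-end orchestration: configuration, stage chaining, per-stage count
# bookkeeping, gridded spatial summaries and deterministic output tables.

#' Pipeline configuration
#'
#' Collects every analysis threshold with its default, plus either a
#' synthetic-ocean configuration or paths to atlas/profile CSVs.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading files.
#' @param atlas_path,profiles_path Input CSVs (ignored when `synthetic` is
#'   given).
#' @param alpha Classification significance level (default 0.05).
#' @param min_lifespan Minimum eddy lifespan in days (default 14).
#' @param min_seabed Minimum seabed depth in metres (default 1000).
#' @param ribbon_factor Control-ribbon outer limit in effective radii
#'   (default 2).
#' @param control_guard Exclude control points inside neighboring eddies?
#' @param trapping_definition `"U_over_c"` or `"distance_over_speed"`.
#' @param period_handling `"stratified"` or `"pooled"` (NASC tests).
#' @param drop_unknown_seabed Drop profiles without seabed depth?
#' @param cell_degrees Grid cell size for the spatial summary (default 3).
#' @param grid_variable Classification variable feeding the grid summary.
#' @param seed Master seed (defaults to the synthetic config's seed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            atlas_path = NULL, profiles_path = NULL,
                            alpha = 0.05,
                            min_lifespan = 14,
                            min_seabed = 1000,
                            ribbon_factor = 2,
                            control_guard = TRUE,
                            trapping_definition = "U_over_c",
                            period_handling = "stratified",
                            drop_unknown_seabed = FALSE,
                            cell_degrees = 3,
                            grid_variable = "nasc_epipelagic",
                            seed = NULL) {
  if (is.null(synthetic) && (is.null(atlas_path) || is.null(profiles_path))) {
    stop("either a synthetic config or both input paths are required")
  }
  if (is.null(seed)) {
    seed <- if (!is.null(synthetic)) synthetic$seed else 1
  }
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Representative position of each sampled eddy
#'
#' The mean of the eddy's inside-profile positions (longitudes normalized to
#' `[-180, 180)`; adequate for the regional track extents handled here).
#'
#' @param profiles Prepared profile table.
#' @param collocation Collocation table.
#' @return Tibble: `eddy_id`, `lon`, `lat`.
#' @export
eddy_positions <- function(profiles, collocation) {
  sel <- collocation$relation == "inside" & !is.na(collocation$eddy_id)
  x <- dplyr::inner_join(collocation[sel, c("profile_id", "eddy_id")],
                         profiles[, c("profile_id", "lon", "lat")],
                         by = "profile_id")
  dplyr::summarise(dplyr::group_by(x, .data$eddy_id),
                   lon = normalize_lon(mean(.data$lon)),
                   lat = mean(.data$lat), .groups = "drop")
}

#' Six-characteristic table for sampled eddies
#'
#' Assembles, per retained eddy: amplitude, trapping, effective area (each
#' averaged over the eddy's records on the days it was sampled inside), the
#' relative SST and chlorophyll anomalies from the anomaly stage, and the
#' eddy age at observation (mean inside-sampling date minus first
#' detection).
#'
#' @param atlas Atlas tibble with a `trapping` column.
#' @param profiles Prepared profile table.
#' @param collocation Collocation table.
#' @param anomaly_summary Per-eddy anomaly summary.
#' @return Tibble: `eddy_id`, `amplitude_m`, `trapping`,
#'   `effective_area_km2`, `sst_anomaly`, `chl_anomaly`, `age_days`.
#' @export
build_eddy_characteristics <- function(atlas, profiles, collocation,
                                       anomaly_summary) {
  stopifnot("trapping" %in% names(atlas))
  sel <- collocation$relation == "inside" & !is.na(collocation$eddy_id)
  x <- dplyr::inner_join(collocation[sel, c("profile_id", "eddy_id")],
                         profiles[, c("profile_id", "time")],
                         by = "profile_id")
  x$date <- as.Date(x$time)
  rows <- list()
  for (eid in unique(anomaly_summary$eddy_id)) {
    dates <- x$date[x$eddy_id == eid]
    rec <- atlas[atlas$eddy_id == eid & atlas$date %in% dates, , drop = FALSE]
    if (nrow(rec) == 0) rec <- atlas[atlas$eddy_id == eid, , drop = FALSE]
    mean_date <- mean(dates)
    rows[[length(rows) + 1]] <- tibble::tibble(
      eddy_id = eid,
      amplitude_m = mean(rec$amplitude_m),
      trapping = mean(rec$trapping[is.finite(rec$trapping)]),
      effective_area_km2 = mean(rec$effective_area_km2),
      age_days = as.numeric(mean_date - rec$first_detection_date[1])
    )
  }
  chars <- dplyr::bind_rows(rows)
  dplyr::left_join(chars,
                   anomaly_summary[, c("eddy_id", "sst_anomaly", "chl_anomaly")],
                   by = "eddy_id")
}

#' Gridded percentage of significant eddies
#'
#' Bins each eddy's representative position onto a regular
#' `cell_degrees`-degree grid (cell origins at −180° longitude, −90°
#' latitude) and reports, per occupied cell, the number of eddies and the
#' percentage with a significant effect (increase and decrease combined).
#' The latitudinal marginal distribution is emitted alongside.
#'
#' @param results One classification row per eddy (a single variable):
#'   `eddy_id`, `outcome`.
#' @param positions Tibble `eddy_id`, `lon`, `lat` (see [eddy_positions()]).
#' @param cell_degrees Cell size in degrees (default 3).
#' @return List: `cells` (tibble `lon_bin`, `lat_bin` — west/south cell
#'   edges —, `n_eddies`, `n_significant`, `pct_significant`) and
#'   `latitudinal` (per latitude band).
#' @export
summarize_grid <- function(results, positions, cell_degrees = 3) {
  x <- dplyr::inner_join(results[, c("eddy_id", "outcome")], positions,
                         by = "eddy_id")
  x$significant <- x$outcome %in% c("increase", "decrease")
  x$lon_bin <- floor((normalize_lon(x$lon) + 180) / cell_degrees) *
    cell_degrees - 180
  x$lat_bin <- floor((x$lat + 90) / cell_degrees) * cell_degrees - 90
  cells <- dplyr::summarise(
    dplyr::group_by(x, .data$lon_bin, .data$lat_bin),
    n_eddies = dplyr::n(),
    n_significant = sum(.data$significant),
    pct_significant = 100 * mean(.data$significant),
    .groups = "drop"
  )
  latitudinal <- dplyr::summarise(
    dplyr::group_by(x, .data$lat_bin),
    n_eddies = dplyr::n(),
    n_significant = sum(.data$significant),
    pct_significant = 100 * mean(.data$significant),
    .groups = "drop"
  )
  list(cells = cells, latitudinal = latitudinal)
}

#' Run the full eddy–forage-fauna pipeline
#'
#' Chains atlas preparation (lifespan filter, trapping metric), acoustic
#' preparation (twilight and shelf filters), collocation, the retention
#' rule, per-eddy anomalies, per-eddy classification, proportion summaries,
#' characteristic comparisons and the gridded spatial summary. The manifest
#' records the count entering and surviving each filter stage. Identical
#' configuration (including seed) reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List of stage outputs: `atlas`, `truth` (synthetic runs),
#'   `profiles`, `collocation`, `sampled`, `anomalies`, `classification`,
#'   `proportions`, `characteristics`, `comparisons`, `grid`, `aggregate`,
#'   `manifest`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$synthetic)) {
    sim <- generate_eddy_atlas(config$synthetic)
    atlas_raw <- sim$atlas
    truth <- sim$truth
    track <- generate_track(config$synthetic)
    gen <- generate_profiles(track, atlas_raw, truth, config$synthetic)
    profiles_raw <- gen$profiles
  } else {
    atlas_raw <- read_atlas(config$atlas_path)
    profiles_raw <- read_profiles_csv(config$profiles_path)
  }
  atlas <- filter_lifespan(atlas_raw, config$min_lifespan)
  atlas <- compute_trapping(atlas, definition = config$trapping_definition)
  profiles <- prepare_profiles(profiles_raw, min_seabed = config$min_seabed,
                               drop_unknown_seabed = config$drop_unknown_seabed)
  collocation <- collocate_profiles(profiles, atlas,
                                    guard = config$control_guard,
                                    ribbon_factor = config$ribbon_factor)
  sampled <- build_sampled_eddies(collocation)
  anomalies <- compute_eddy_anomalies(profiles, collocation, sampled, atlas)
  classification <- classify_eddies(profiles, collocation, sampled, atlas,
                                    alpha = config$alpha,
                                    period_handling = config$period_handling)
  proportions <- if (nrow(classification) > 0) {
    summarize_proportions(classification, anomalies$summary)
  } else NULL
  characteristics <- if (nrow(anomalies$summary) > 0) {
    build_eddy_characteristics(atlas, profiles, collocation,
                               anomalies$summary)
  } else NULL
  epi <- classification[classification$variable == "nasc_epipelagic", ,
                        drop = FALSE]
  comparisons <- if (nrow(epi) > 0) {
    compare_characteristics(epi, characteristics, alpha = config$alpha)
  } else NULL
  positions <- eddy_positions(profiles, collocation)
  grid_rows <- classification[classification$variable == config$grid_variable, ,
                              drop = FALSE]
  grid <- if (nrow(grid_rows) > 0) {
    summarize_grid(grid_rows, positions, config$cell_degrees)
  } else NULL
  aggregate <- if (nrow(anomalies$bins) > 0) {
    aggregate_anomalies(anomalies$bins, "polarity")
  } else NULL
  manifest <- tibble::tibble(
    stage = c("atlas_records", "atlas_records_lifespan_ok", "eddies",
              "eddies_lifespan_ok", "profiles", "profiles_prepared",
              "profiles_inside", "profiles_control", "eddies_sampled",
              "eddies_retained"),
    count = c(nrow(atlas_raw), nrow(atlas),
              dplyr::n_distinct(atlas_raw$eddy_id),
              dplyr::n_distinct(atlas$eddy_id),
              nrow(profiles_raw), nrow(profiles),
              sum(collocation$relation == "inside"),
              sum(collocation$relation == "control"),
              nrow(sampled), sum(sampled$retained))
  )
  list(atlas = atlas, truth = truth, profiles = profiles,
       collocation = collocation, sampled = sampled, anomalies = anomalies,
       classification = classification, proportions = proportions,
       characteristics = characteristics, comparisons = comparisons,
       grid = grid, aggregate = aggregate, manifest = manifest,
       config = config)
}

#' Write the pipeline's output tables
#'
#' Writes every tabular stage output as CSV with deterministic number
#' formatting (see [write_table_csv()]), so identical runs produce
#' byte-identical files.
#'
#' @param result Output of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(x, name) {
    if (is.null(x) || nrow(x) == 0) return(invisible(NULL))
    p <- file.path(dir, name)
    write_table_csv(x, p)
    paths <<- c(paths, p)
  }
  put(result$collocation, "collocation.csv")
  put(result$sampled, "sampled_eddies.csv")
  put(result$anomalies$bins, "eddy_anomaly_bins.csv")
  put(result$anomalies$summary, "eddy_anomaly_summary.csv")
  put(result$classification, "classification.csv")
  put(result$proportions, "proportions.csv")
  put(result$characteristics, "characteristics.csv")
  if (!is.null(result$comparisons)) {
    put(result$comparisons$tests, "comparison_tests.csv")
    put(result$comparisons$quartiles, "comparison_quartiles.csv")
  }
  if (!is.null(result$grid)) {
    put(result$grid$cells, "grid_cells.csv")
    put(result$grid$latitudinal, "grid_latitudinal.csv")
  }
  put(result$aggregate, "aggregate_anomaly.csv")
  put(result$manifest, "manifest.csv")
  invisible(paths)
}
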