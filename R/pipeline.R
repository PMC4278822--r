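#' Pipeline configuration
#'
#' Paths and options for an end-to-end [run_pipeline()] call.  A config can
#' also be loaded from YAML with [read_pipeline_config()].
#'
#' @param bundles Character vector of bundle directories.
#' @param checklist Path to the checklist CSV.
#' @param layers Named character vector/list of GeoJSON paths; `ecoregion`
#'   and `country` are mandatory, `hotspot` optional.
#' @param out_dir Output directory (created if needed).
#' @param raster Optional NPP raster directory.
#' @param offshore_threshold_m Escalation distance for offshore flags.
#' @param expected_clades Optional named list (by study) of
#'   `c(rank, name)` pairs declaring expected clades.
#' @param near_miss_weight Partial credit for near misses (default 0.5).
#' @param seed Seed recorded in the run summary.
#' @param strict Treat warnings as errors when deciding the exit status.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(bundles, checklist, layers, out_dir,
                            raster = NULL, offshore_threshold_m = 10000,
                            expected_clades = NULL, near_miss_weight = 0.5,
                            seed = 1, strict = FALSE) {
  structure(list(bundles = bundles, checklist = checklist,
                 layers = as.list(layers), out_dir = out_dir,
                 raster = raster,
                 offshore_threshold_m = offshore_threshold_m,
                 expected_clades = expected_clades,
                 near_miss_weight = near_miss_weight,
                 seed = as.integer(seed), strict = strict),
            class = "pipeline_config")
}

#' @param path YAML file (for `read_pipeline_config`).
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_with("ecocollate_config_error", "the yaml package is required")
  }
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full collation pipeline
#'
#' Stages, in order: read and assemble the bundles; validate (including the
#' GIS country check; a run with error-severity issues stops here);
#' resolve taxonomy against the checklist; build the curation review queue;
#' annotate sites against the region layers and flag offshore sites;
#' write the site extract; write coverage tables (latitudinal bands, biome,
#' hotspot) and species counts.  Every stage logs record counts; outputs
#' are CSV files plus a machine-readable JSON run summary in `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with `status` (`"ok"` or
#'   `"validation_failed"`), the final database and output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  summary <- list(seed = config$seed, stages = list())

  say("assemble: reading %d bundle(s)", length(config$bundles))
  bundles <- lapply(config$bundles, read_bundle)
  db <- assemble_database(bundles)
  summary$stages$assemble <- list(
    sources = nrow(db$sources), studies = nrow(db$studies),
    sites = nrow(db$sites), taxa = nrow(db$taxa),
    measurements = nrow(db$measurements))
  say("assemble: %d studies, %d sites, %d measurements",
      nrow(db$studies), nrow(db$sites), nrow(db$measurements))

  layers <- list()
  for (nm in names(config$layers)) {
    layers[[nm]] <- read_geojson_layer(config$layers[[nm]], nm)
  }
  issues <- validate_database(db, countries = layers$country)
  paths$issues <- file.path(out_dir, "issues.csv")
  summary$stages$validate <- list(
    issues = nrow(issues),
    errors = sum(issues$severity == "error"),
    warnings = sum(issues$severity == "warning"))
  say("validate: %d issue(s), %d error(s)", nrow(issues),
      sum(issues$severity == "error"))
  blocking <- sum(issues$severity == "error") > 0 ||
    (config$strict && sum(issues$severity == "warning") > 0)
  if (blocking) {
    write_issues(issues, paths$issues)
    summary$status <- "validation_failed"
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    say("pipeline aborted: validation failed")
    return(invisible(list(status = "validation_failed", db = db,
                          issues = issues, paths = paths)))
  }

  cl <- read_checklist(config$checklist)
  clades <- NULL
  if (!is.null(config$expected_clades)) {
    clades <- lapply(config$expected_clades, function(x) {
      clade_constraint(x[[1]], x[[2]])
    })
  }
  db <- resolve_taxonomy(db, cl, constraints = clades)
  queue <- build_review_queue(db, expected_clades = clades)
  paths$review_queue <- file.path(out_dir, "review_queue.csv")
  readr::write_csv(queue, paths$review_queue, na = "")
  summary$stages$resolve <- list(
    taxa = nrow(db$taxa),
    unmatched = sum(db$taxa$resolution_mode == "unmatched"),
    review_queue = nrow(queue))
  say("resolve: %d taxa, %d unmatched, %d queued for review",
      nrow(db$taxa), sum(db$taxa$resolution_mode == "unmatched"),
      nrow(queue))

  db <- annotate_sites(db, layers)
  offshore <- flag_offshore_sites(db, config$offshore_threshold_m)
  issues <- rbind(issues, offshore)
  write_issues(issues, paths$issues)
  summary$stages$annotate <- list(
    sites = nrow(db$sites), offshore = nrow(offshore))
  say("annotate: %d site(s), %d offshore flag(s)", nrow(db$sites),
      nrow(offshore))

  extract <- site_extract(db)
  paths$site_extract <- file.path(out_dir, "site_extract.csv")
  write_site_extract(extract, paths$site_extract)
  say("extract: %d row(s)", nrow(extract))

  raster <- if (!is.null(config$raster)) read_npp_raster(config$raster)
            else NULL
  lat_cov <- latitudinal_coverage(db, raster = raster)
  paths$latitudinal_coverage <- file.path(out_dir,
                                          "latitudinal_coverage.csv")
  readr::write_csv(lat_cov, paths$latitudinal_coverage, na = "")
  for (cat in c("biome", "hotspot")) {
    tab <- coverage_table(db, cat)
    p <- file.path(out_dir, sprintf("coverage_%s.csv", cat))
    paths[[paste0("coverage_", cat)]] <- p
    readr::write_csv(tab, p, na = "")
  }
  counts <- count_species(db)
  paths$species_counts <- file.path(out_dir, "species_counts.csv")
  readr::write_csv(counts$by_group, paths$species_counts, na = "")
  summary$stages$summarize <- list(species_total = counts$total)
  say("summarize: estimated %d species", counts$total)

  summary$status <- "ok"
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(status = "ok", db = db, issues = issues,
                 extract = extract, species = counts, paths = paths))
}
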