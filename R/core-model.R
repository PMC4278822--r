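#' Survey bundle constructor
#'
#' A bundle is the unit of data capture: one data source together with its
#' studies, sites, taxon list and site-by-taxon measurement matrix.  Bundles
#' are what [assemble_database()] consumes and what [read_bundle()] /
#' [write_bundle()] exchange with disk (a directory of UTF-8 CSV files:
#' `source.csv`, `studies.csv`, `sites.csv`, `taxa.csv`, `matrix.csv`).
#'
#' Field-level values (coordinates, dates, times since conversion) are held
#' verbatim as entered; they are parsed leniently at assembly and checked by
#' [validate_database()], so that a malformed coordinate becomes a validation
#' issue rather than a read failure.
#'
#' @param source One-row data frame: `source_id`, `bibliographic_citation`,
#'   `declared_countries` (semicolon-separated country names, or the literal
#'   `"Multiple countries"`), `provenance_kind`.
#' @param studies Data frame: `study_id`, `source_id`, `sampling_method`,
#'   `effort_unit`, `metric_type` (abundance/occurrence/species_richness).
#' @param sites Data frame of site rows (see [read_bundle()] for columns).
#' @param taxa Data frame: `taxon_id`, `study_id`, `name_entered`.
#' @param matrix Data frame, sites as rows and taxa as columns, first column
#'   `site_id`; empty cells are `NA`.
#' @return A `survey_bundle`.
#' @export
survey_bundle <- function(source, studies, sites, taxa, matrix) {
  structure(
    list(source = tibble::as_tibble(source),
         studies = tibble::as_tibble(studies),
         sites = tibble::as_tibble(sites),
         taxa = tibble::as_tibble(taxa),
         matrix = as.data.frame(matrix, check.names = FALSE)),
    class = "survey_bundle")
}

.METRIC_TYPES <- c("abundance", "occurrence", "species_richness")
.PROVENANCE_KINDS <- c("journal article", "unpublished", "internet database",
                       "thesis", "report", "other")

assembly_error <- function(msg, ...) {
  stop_with("ecocollate_assembly_error", msg, ...)
}

parse_coord_lenient <- function(x) {
  vapply(as.character(x), function(v) {
    if (is_blank(v)) return(NA_real_)
    tryCatch(parse_angle(v), error = function(e) NA_real_)
  }, numeric(1), USE.NAMES = FALSE)
}

# Strict ISO-8601 calendar parse; NA when malformed or not a real date.
parse_date_lenient <- function(x) {
  out <- rep(as.Date(NA), length(x))
  x <- as.character(x)
  ok <- !is_blank(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  for (i in which(ok)) {
    p <- as.integer(strsplit(x[i], "-")[[1]])
    if (p[2] >= 1 && p[2] <= 12 && p[3] >= 1 &&
        p[3] <= days_in_month(p[1], p[2])) {
      out[i] <- as.Date(x[i])
    }
  }
  out
}

parse_tsc_lenient <- function(x) {
  vapply(as.character(x), function(v) {
    if (is_blank(v)) return(NA_real_)
    tryCatch(parse_time_since_conversion(v),
             error = function(e) {
               # keep plain negatives so the validator can flag them
               if (grepl("^\\s*-[0-9.]+\\s*$", v)) as.numeric(v) else NA_real_
             })
  }, numeric(1), USE.NAMES = FALSE)
}

#' Interpret empty cells of a site-by-taxon matrix
#'
#' Received matrices often contain empty cells.  When every filled cell is
#' non-zero, blanks are interpreted as zeros (the taxon was looked for and
#' not found).  When any filled cell is zero, blanks instead mean the taxon
#' was not looked for at that site and stay missing.  The rule is applied
#' per study matrix.  The operation is idempotent.
#'
#' @param m Numeric matrix (or data frame) with `NA` for empty cells.
#' @return Numeric matrix with blanks resolved to 0 or left `NA`.
#' @examples
#' interpret_matrix_blanks(rbind(c(1, 2), c(NA, 3)))  # blank -> 0
#' interpret_matrix_blanks(rbind(c(0, 2), c(NA, 3)))  # blank stays NA
#' @export
interpret_matrix_blanks <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  filled <- !is.na(m)
  if (any(m[filled] < 0)) {
    stop_with("ecocollate_validation_error",
              "negative measurement value in matrix")
  }
  if (any(filled) && all(m[filled] != 0)) {
    m[!filled] <- 0
  }
  m
}

#' Assemble study bundles into a survey database
#'
#' Checks structural invariants (referential integrity, two or more sites
#' per study, unique identifiers, recognised metric types), interprets blank
#' matrix cells per study via [interpret_matrix_blanks()], converts entered
#' field text into typed columns (keeping the verbatim `*_entered` text for
#' validation), and maps the patch-area sentinel (-1 = unknown but large)
#' into an explicit tri-state.  Bundles that fail a structural invariant are
#' rejected with an error naming the offending record; field-level problems
#' are left for [validate_database()].
#'
#' @param bundles A `survey_bundle` or list of them.
#' @return A `survey_database`: list of tibbles `sources`, `studies`,
#'   `sites`, `taxa`, `measurements`, plus a `curation_log`.
#' @export
assemble_database <- function(bundles) {
  if (inherits(bundles, "survey_bundle")) bundles <- list(bundles)
  stopifnot(length(bundles) >= 1)

  sources <- list(); studies <- list(); sites <- list()
  taxa <- list(); meas <- list()

  for (b in bundles) {
    stopifnot(inherits(b, "survey_bundle"))
    src <- b$source
    if (nrow(src) != 1 || is_blank(src$source_id)) {
      assembly_error("each bundle needs exactly one source with a source_id")
    }
    if (all(is_blank(src$declared_countries))) {
      assembly_error("source %s: declared_countries is empty", src$source_id)
    }
    if (!is_blank(src$provenance_kind) &&
        !src$provenance_kind %in% .PROVENANCE_KINDS) {
      assembly_error("source %s: unknown provenance_kind '%s'",
                     src$source_id, src$provenance_kind)
    }
    st <- b$studies
    if (nrow(st) < 1) assembly_error("source %s: bundle has no studies",
                                     src$source_id)
    bad <- st$source_id != src$source_id
    if (any(bad)) {
      assembly_error("study %s references unknown source %s",
                     st$study_id[bad][1], st$source_id[bad][1])
    }
    if (anyDuplicated(st$study_id)) {
      assembly_error("duplicate study_id %s",
                     st$study_id[duplicated(st$study_id)][1])
    }
    bad <- !st$metric_type %in% .METRIC_TYPES
    if (any(bad)) {
      assembly_error("study %s: unknown metric_type '%s'",
                     st$study_id[bad][1], st$metric_type[bad][1])
    }
    si <- b$sites
    if (any(!si$study_id %in% st$study_id)) {
      off <- si$site_id[!si$study_id %in% st$study_id][1]
      assembly_error("site %s references unknown study", off)
    }
    n_per <- table(si$study_id)
    few <- st$study_id[!st$study_id %in% names(n_per)[n_per >= 2]]
    if (length(few)) {
      assembly_error("study %s has fewer than two sites", few[1])
    }
    dup <- duplicated(si[, c("study_id", "site_id")])
    if (any(dup)) {
      assembly_error("duplicate site_id %s within study %s",
                     si$site_id[dup][1], si$study_id[dup][1])
    }
    if (anyDuplicated(si$site_id)) {
      assembly_error("site_id %s is reused across studies in source %s",
                     si$site_id[duplicated(si$site_id)][1], src$source_id)
    }
    tx <- b$taxa
    if (any(!tx$study_id %in% st$study_id)) {
      assembly_error("taxon %s references unknown study",
                     tx$taxon_id[!tx$study_id %in% st$study_id][1])
    }
    if (anyDuplicated(tx$taxon_id)) {
      assembly_error("duplicate taxon_id %s",
                     tx$taxon_id[duplicated(tx$taxon_id)][1])
    }

    mx <- b$matrix
    if (ncol(mx) < 1 || names(mx)[1] != "site_id") {
      assembly_error("source %s: matrix must have site_id as first column",
                     src$source_id)
    }
    if (any(!mx$site_id %in% si$site_id)) {
      assembly_error("measurement references unknown site %s",
                     mx$site_id[!mx$site_id %in% si$site_id][1])
    }
    mx_taxa <- names(mx)[-1]
    if (any(!mx_taxa %in% tx$taxon_id)) {
      assembly_error("measurement references unknown taxon %s",
                     mx_taxa[!mx_taxa %in% tx$taxon_id][1])
    }

    # per-study blank interpretation, then long-format measurements
    for (sid in st$study_id) {
      s_sites <- si$site_id[si$study_id == sid]
      s_taxa <- tx$taxon_id[tx$study_id == sid]
      s_taxa <- s_taxa[s_taxa %in% mx_taxa]
      rows <- which(mx$site_id %in% s_sites)
      if (!length(rows) || !length(s_taxa)) next
      sub <- as.matrix(mx[rows, s_taxa, drop = FALSE])
      storage.mode(sub) <- "double"
      sub <- interpret_matrix_blanks(sub)
      metric <- st$metric_type[st$study_id == sid]
      if (metric == "occurrence") {
        obs <- sub[!is.na(sub)]
        if (any(!obs %in% c(0, 1))) {
          assembly_error("study %s: occurrence values must be 0 or 1", sid)
        }
      }
      meas[[length(meas) + 1]] <- tibble::tibble(
        study_id = sid,
        site_id = rep(mx$site_id[rows], times = length(s_taxa)),
        taxon_id = rep(s_taxa, each = length(rows)),
        value = as.vector(sub))
    }

    sources[[length(sources) + 1]] <- tibble::tibble(
      source_id = src$source_id,
      bibliographic_citation = src$bibliographic_citation %||% NA_character_,
      declared_countries = list(trimws(strsplit(
        as.character(src$declared_countries), ";")[[1]])),
      provenance_kind = src$provenance_kind %||% NA_character_)
    studies[[length(studies) + 1]] <- tibble::tibble(
      study_id = st$study_id, source_id = st$source_id,
      sampling_method = st$sampling_method %||% NA_character_,
      effort_unit = st$effort_unit %||% NA_character_,
      metric_type = st$metric_type)
    sites[[length(sites) + 1]] <- normalize_sites(si)
    taxa[[length(taxa) + 1]] <- tibble::tibble(
      taxon_id = tx$taxon_id, study_id = tx$study_id,
      name_entered = tx$name_entered)
  }

  sources <- do.call(rbind, sources)
  if (anyDuplicated(sources$source_id)) {
    assembly_error("duplicate source_id %s",
                   sources$source_id[duplicated(sources$source_id)][1])
  }
  db <- structure(
    list(sources = sources,
         studies = do.call(rbind, studies),
         sites = do.call(rbind, sites),
         taxa = do.call(rbind, taxa),
         measurements = if (length(meas)) do.call(rbind, meas) else
           tibble::tibble(study_id = character(), site_id = character(),
                          taxon_id = character(), value = double()),
         curation_log = tibble::tibble(taxon_id = character(),
                                       old_query = character(),
                                       new_query = character(),
                                       reason = character())),
    class = "survey_database", annotated = FALSE, resolved = FALSE)
  db
}

# Typed site table from raw entered text; verbatim text kept alongside.
normalize_sites <- function(si) {
  get_col <- function(nm) {
    if (!nm %in% names(si)) return(rep(NA_character_, nrow(si)))
    x <- as.character(si[[nm]])
    x[is_blank(x)] <- NA_character_   # "" and NA are both "not given"
    x
  }
  patch_raw <- suppressWarnings(as.numeric(get_col("patch_area")))
  tibble::tibble(
    site_id = si$site_id,
    study_id = si$study_id,
    site_name = if ("site_name" %in% names(si)) si$site_name else si$site_id,
    latitude = parse_coord_lenient(get_col("latitude")),
    longitude = parse_coord_lenient(get_col("longitude")),
    latitude_entered = get_col("latitude"),
    longitude_entered = get_col("longitude"),
    habitat_description = get_col("habitat_description"),
    land_use = get_col("land_use"),
    use_intensity = get_col("use_intensity"),
    fragmentation_layout = get_col("fragmentation_layout"),
    patch_area_m2 = ifelse(!is.na(patch_raw) & patch_raw >= 0,
                           patch_raw, NA_real_),
    patch_area_state = ifelse(
      is.na(patch_raw), "unknown",
      ifelse(patch_raw == -1, "unknown_large", "known")),
    max_linear_extent = suppressWarnings(
      as.numeric(get_col("max_linear_extent"))),
    start_date = parse_date_lenient(get_col("start_date")),
    end_date = parse_date_lenient(get_col("end_date")),
    start_entered = get_col("start_date"),
    end_entered = get_col("end_date"),
    date_resolution = get_col("date_resolution"),
    effort = suppressWarnings(as.numeric(get_col("effort"))),
    time_since_conversion = parse_tsc_lenient(get_col("time_since_conversion")),
    time_since_conversion_entered = get_col("time_since_conversion"),
    block = get_col("block"))
}

#' @export
print.survey_database <- function(x, ...) {
  cat(sprintf(
    "<survey_database> %d source(s), %d studies, %d sites, %d taxa, %d measurements\n",
    nrow(x$sources), nrow(x$studies), nrow(x$sites), nrow(x$taxa),
    nrow(x$measurements)))
  cat(sprintf("  annotated: %s; taxonomy resolved: %s\n",
              isTRUE(attr(x, "annotated")), isTRUE(attr(x, "resolved"))))
  invisible(x)
}

#' Site-level extract of the database
#'
#' One row per site carrying the predominant land use, use intensity,
#' fragmentation layout, coordinates, sampling dates, country, biogeographic
#' realm, ecoregion, biome, biodiversity hotspot, the taxonomic group studied
#' and the number of (non-missing) measurements taken, plus identifiers.
#' Requires the database to be annotated ([annotate_sites()]) and its
#' taxonomy resolved ([resolve_taxonomy()]).
#'
#' @param db An annotated, resolved `survey_database`.
#' @return A tibble with a fixed, documented column order (see
#'   [write_site_extract()]).
#' @export
site_extract <- function(db) {
  stopifnot(inherits(db, "survey_database"))
  if (!isTRUE(attr(db, "annotated"))) {
    stop_with("ecocollate_state_error",
              "database is not annotated; run annotate_sites() first")
  }
  if (!isTRUE(attr(db, "resolved"))) {
    stop_with("ecocollate_state_error",
              "taxonomy is not resolved; run resolve_taxonomy() first")
  }
  s <- db$sites
  n_meas <- table(db$measurements$site_id[!is.na(db$measurements$value)])
  group <- setNames(db$studies$lowest_common_name, db$studies$study_id)
  tibble::tibble(
    source_id = setNames(db$studies$source_id,
                         db$studies$study_id)[s$study_id],
    study_id = s$study_id,
    site_id = s$site_id,
    site_name = s$site_name,
    land_use = s$land_use,
    use_intensity = s$use_intensity,
    fragmentation_layout = s$fragmentation_layout,
    latitude = s$latitude,
    longitude = s$longitude,
    start_date = s$start_date,
    end_date = s$end_date,
    date_resolution = s$date_resolution,
    country = s$country,
    biogeographic_realm = s$realm,
    ecoregion = s$ecoregion,
    biome = s$biome,
    hotspot = s$hotspot,
    taxonomic_group = unname(group[s$study_id]),
    n_measurements = as.integer(ifelse(is.na(match(s$site_id, names(n_meas))),
                                       0L, n_meas[s$site_id])))
}
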