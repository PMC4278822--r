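# CSV dialect: UTF-8, comma-separated, quoted fields, mandatory header row,
# ISO-8601 dates (resolution in its own column).  BOM-prefixed files are
# accepted (readr strips the BOM).

read_csv_strict <- function(path, required = NULL) {
  if (!file.exists(path)) {
    stop_with("ecocollate_parse_error", "file not found: %s", path)
  }
  df <- suppressWarnings(readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs)) {
    stop_with("ecocollate_parse_error", "%s: malformed row at line %d (%s)",
              path, probs$row[1] + 1L, probs$expected[1])
  }
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_with("ecocollate_parse_error", "%s: missing column(s) %s", path,
              paste(miss, collapse = ", "))
  }
  df
}

#' Read / write a study bundle directory
#'
#' A bundle directory holds five UTF-8 CSV files: `source.csv`,
#' `studies.csv`, `sites.csv`, `taxa.csv` and `matrix.csv` (sites as rows,
#' taxa as columns, first column `site_id`, empty cells for blanks).
#'
#' @param path Bundle directory.
#' @return `read_bundle()`: a [survey_bundle()]; `write_bundle()`: the path,
#'   invisibly.
#' @export
read_bundle <- function(path) {
  src <- read_csv_strict(file.path(path, "source.csv"),
                         c("source_id", "declared_countries"))
  st <- read_csv_strict(file.path(path, "studies.csv"),
                        c("study_id", "source_id", "metric_type"))
  si <- read_csv_strict(file.path(path, "sites.csv"),
                        c("site_id", "study_id"))
  tx <- read_csv_strict(file.path(path, "taxa.csv"),
                        c("taxon_id", "study_id", "name_entered"))
  mx <- read_csv_strict(file.path(path, "matrix.csv"), "site_id")
  for (j in seq_along(mx)[-1]) mx[[j]] <- suppressWarnings(
    as.numeric(mx[[j]]))
  survey_bundle(src, st, si, tx, mx)
}

#' @param bundle A [survey_bundle()] (for `write_bundle`).
#' @rdname read_bundle
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "survey_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$source, file.path(path, "source.csv"), na = "")
  readr::write_csv(bundle$studies, file.path(path, "studies.csv"), na = "")
  readr::write_csv(bundle$sites, file.path(path, "sites.csv"), na = "")
  readr::write_csv(bundle$taxa, file.path(path, "taxa.csv"), na = "")
  readr::write_csv(bundle$matrix, file.path(path, "matrix.csv"), na = "")
  invisible(path)
}

#' Read / write a checklist CSV
#'
#' Columns: `entry_id`, `name`, `rank`, `status`, `accepted_ref`, the
#' classification columns `kingdom` ... `infraspecies`, and optionally
#' `common_names` (pipe-separated), which is expanded into common-name
#' entries pointing at the row's accepted entry.
#'
#' @param path CSV file path.
#' @return `read_checklist()`: a [checklist()].
#' @export
read_checklist <- function(path) {
  df <- read_csv_strict(path, c("entry_id", "name", "rank", "status"))
  if (!"accepted_ref" %in% names(df)) df$accepted_ref <- NA_character_
  extra <- list()
  if ("common_names" %in% names(df)) {
    cn_col <- df$common_names
    df$common_names <- NULL
    has <- which(!is_blank(cn_col))
    for (i in has) {
      for (cn in strsplit(cn_col[i], "\\|")[[1]]) {
        r <- df[i, ]
        r$entry_id <- paste0(r$entry_id, "_cn", length(extra) + 1L)
        r$name <- trimws(cn)
        r$status <- "common_name"
        r$accepted_ref <- df$accepted_ref[i] %||% df$entry_id[i]
        if (is_blank(r$accepted_ref)) r$accepted_ref <- df$entry_id[i]
        extra[[length(extra) + 1L]] <- r
      }
    }
    if (length(extra)) df <- rbind(df, do.call(rbind, extra))
  }
  checklist(df)
}

#' @param cl A [checklist()] (for `write_checklist`).
#' @rdname read_checklist
#' @export
write_checklist <- function(cl, path) {
  out <- as.data.frame(cl)[, c("entry_id", "name", "rank", "status",
                               "accepted_ref", rank_ladder())]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read / write a region layer as GeoJSON
#'
#' Reads a WGS84 GeoJSON FeatureCollection of Polygon/MultiPolygon features
#' (the dialect the fixture generators emit); feature properties become the
#' attribute map.  This is a reader for that narrow dialect, not a general
#' GeoJSON implementation.
#'
#' @param path GeoJSON file.
#' @param layer_name Name for the layer.
#' @return `read_geojson_layer()`: a [region_layer()].
#' @export
read_geojson_layer <- function(path, layer_name) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop_with("ecocollate_parse_error",
              "%s: expected a FeatureCollection", path)
  }
  ring_mat <- function(coords) {
    do.call(rbind, lapply(coords, function(pt) {
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
    }))
  }
  feats <- lapply(gj$features, function(f) {
    g <- f$geometry
    polys <- switch(
      g$type,
      Polygon = list(lapply(g$coordinates, ring_mat)),
      MultiPolygon = lapply(g$coordinates, function(p) {
        lapply(p, ring_mat)
      }),
      stop_with("ecocollate_parse_error",
                "%s: unsupported geometry type '%s'", path, g$type))
    list(attributes = f$properties, polygons = polys)
  })
  region_layer(layer_name, feats)
}

#' @param layer A [region_layer()] (for `write_geojson_layer`).
#' @rdname read_geojson_layer
#' @export
write_geojson_layer <- function(layer, path) {
  stopifnot(inherits(layer, "region_layer"))
  feats <- lapply(layer$features, function(f) {
    coords <- lapply(f$polygons, function(poly) {
      lapply(poly, function(ring) {
        lapply(seq_len(nrow(ring)), function(i) {
          list(ring[i, 1], ring[i, 2])
        })
      })
    })
    if (length(coords) == 1) {
      geom <- list(type = "Polygon", coordinates = coords[[1]])
    } else {
      geom <- list(type = "MultiPolygon", coordinates = coords)
    }
    list(type = "Feature", properties = f$attributes, geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ESRI-ASCII-style plain-text grid, one file per month.
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize)
}

write_ascii_grid <- function(m, xll, yll, cellsize, path, nodata = -9999) {
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %g", xll), sprintf("yllcorner %g", yll),
           sprintf("cellsize %g", cellsize),
           sprintf("NODATA_value %g", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a monthly NPP raster directory
#'
#' Twelve ESRI-ASCII-style grids `npp_01.asc` ... `npp_12.asc` (mean daily
#' NPP in g C m^-2 day^-1) and an optional `mask.asc` of terrestrial
#' fractions.
#'
#' @param path Directory.
#' @return `read_npp_raster()`: an [npp_raster()].
#' @export
read_npp_raster <- function(path) {
  grids <- lapply(1:12, function(m) {
    read_ascii_grid(file.path(path, sprintf("npp_%02d.asc", m)))
  })
  g1 <- grids[[1]]
  vals <- array(NA_real_, c(nrow(g1$values), ncol(g1$values), 12))
  for (m in 1:12) vals[, , m] <- grids[[m]]$values
  mask_path <- file.path(path, "mask.asc")
  mask <- if (file.exists(mask_path)) read_ascii_grid(mask_path)$values
          else NULL
  npp_raster(vals, xll = g1$xll, yll = g1$yll, cellsize = g1$cellsize,
             mask = mask)
}

#' @param raster An [npp_raster()] (for `write_npp_raster`).
#' @rdname read_npp_raster
#' @export
write_npp_raster <- function(raster, path) {
  stopifnot(inherits(raster, "npp_raster"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (m in 1:12) {
    write_ascii_grid(raster$values[, , m], raster$xll, raster$yll,
                     raster$cellsize,
                     file.path(path, sprintf("npp_%02d.asc", m)))
  }
  write_ascii_grid(raster$mask, raster$xll, raster$yll, raster$cellsize,
                   file.path(path, "mask.asc"))
  invisible(path)
}

#' Write the site extract CSV
#'
#' Fixed column order: source_id, study_id, site_id, site_name, land_use,
#' use_intensity, fragmentation_layout, latitude, longitude, start_date,
#' end_date, date_resolution, country, biogeographic_realm, ecoregion,
#' biome, hotspot, taxonomic_group, n_measurements.
#'
#' @param extract Output of [site_extract()].
#' @param path CSV path.
#' @export
write_site_extract <- function(extract, path) {
  readr::write_csv(extract, path, na = "")
  invisible(path)
}

#' Write validation issues as CSV
#'
#' Columns: code, severity, record_ref, message.
#'
#' @param issues Issue tibble from [validate_database()].
#' @param path CSV path.
#' @export
write_issues <- function(issues, path) {
  readr::write_csv(issues, path, na = "")
  invisible(path)
}
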