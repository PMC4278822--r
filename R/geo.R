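#' Construct a region layer
#'
#' A layer of attributed polygons in WGS84 used for biogeographic annotation:
#' ecoregion/biome/realm, country/UN region/UN subregion, or biodiversity
#' hotspots.  Each feature is a list with an `attributes` named list and a
#' `polygons` element: a list of polygons, each a list of rings (the first
#' ring the outer boundary, subsequent rings holes), each ring an n x 2
#' (lon, lat) matrix closed on itself.  Polygons crossing the antimeridian
#' are rejected.
#'
#' @param layer_name Layer name, e.g. `"ecoregion"`.
#' @param features List of features as described above.
#' @return A `region_layer`.
#' @export
region_layer <- function(layer_name, features) {
  for (f in features) {
    if (is.null(f$attributes) || !length(f$attributes)) {
      stop_with("ecocollate_config_error",
                "layer %s: every feature needs a non-empty attribute map",
                layer_name)
    }
    for (poly in f$polygons) {
      for (ring in poly) {
        if (any(abs(diff(ring[, 1])) > 180)) {
          stop_with("ecocollate_config_error",
                    "layer %s: antimeridian-crossing polygons are not supported",
                    layer_name)
        }
      }
    }
  }
  structure(list(layer_name = layer_name, features = features),
            class = "region_layer")
}

#' @export
print.region_layer <- function(x, ...) {
  cat(sprintf("<region_layer> '%s': %d feature(s)\n",
              x$layer_name, length(x$features)))
  invisible(x)
}

#' Rectangular feature helper
#'
#' Convenience constructor for an axis-aligned rectangular feature, the
#' building block of the fixture region layers.
#'
#' @param xmin,ymin,xmax,ymax Longitude/latitude bounds in degrees.
#' @param attributes Named list of feature attributes.
#' @return A feature suitable for [region_layer()].
#' @export
rect_feature <- function(xmin, ymin, xmax, ymax, attributes) {
  ring <- cbind(c(xmin, xmax, xmax, xmin, xmin),
                c(ymin, ymin, ymax, ymax, ymin))
  list(attributes = attributes, polygons = list(list(ring)))
}

# Even-odd containment with boundary counted as inside.
point_in_feature <- function(feature, point) {
  for (poly in feature$polygons) {
    outer <- poly[[1]]
    pos <- sp::point.in.polygon(point[1], point[2], outer[, 1], outer[, 2])
    if (pos == 0) next
    if (pos >= 2) return(TRUE)        # on the outer boundary
    inside <- TRUE
    for (hole in poly[-1]) {
      hp <- sp::point.in.polygon(point[1], point[2], hole[, 1], hole[, 2])
      if (hp == 1) { inside <- FALSE; break }
    }
    if (inside) return(TRUE)
  }
  FALSE
}

# Great-circle distance (m) from a point to one boundary segment.  Edges
# are straight lines in lon/lat space (consistent with the planar
# containment test); the minimum along the edge is located by a coarse scan
# refined with a ternary search.
point_segment_distance <- function(p, a, b) {
  f <- function(t) {
    gc_distance(p, cbind(a[1] + t * (b[1] - a[1]),
                         a[2] + t * (b[2] - a[2])))
  }
  ts <- seq(0, 1, length.out = 33)
  d <- f(ts)
  i <- which.min(d)
  lo <- ts[max(i - 1L, 1L)]
  hi <- ts[min(i + 1L, 33L)]
  for (k in 1:45) {
    m1 <- lo + (hi - lo) / 3
    m2 <- hi - (hi - lo) / 3
    if (f(m1) < f(m2)) hi <- m2 else lo <- m1
  }
  unname(f((lo + hi) / 2))
}

feature_boundary_distance <- function(feature, point) {
  best <- Inf
  for (poly in feature$polygons) {
    for (ring in poly) {
      for (i in seq_len(nrow(ring) - 1)) {
        d <- point_segment_distance(point, ring[i, ], ring[i + 1, ])
        if (d < best) best <- d
      }
    }
  }
  best
}

#' Match a point to the nearest feature of a layer
#'
#' Points inside a feature match it with distance zero; points outside match
#' the feature with the smallest great-circle distance to its boundary, and
#' that distance is reported.  Exact ties are broken by feature order.
#'
#' @param layer A [region_layer()].
#' @param point `c(longitude, latitude)` in decimal degrees.
#' @return List with `attributes` (named list) and `distance` (meters, 0
#'   when inside).
#' @export
match_nearest <- function(layer, point) {
  stopifnot(inherits(layer, "region_layer"))
  if (!length(layer$features)) {
    stop_with("ecocollate_config_error", "layer '%s' is empty",
              layer$layer_name)
  }
  for (f in layer$features) {
    if (point_in_feature(f, point)) {
      return(list(attributes = f$attributes, distance = 0))
    }
  }
  best <- NULL; best_d <- Inf
  for (f in layer$features) {
    d <- feature_boundary_distance(f, point)
    # strict improvement beyond numerical noise: exact ties keep the
    # earlier feature, making the tie-break deterministic by layer order
    if (d < best_d - 1e-6) { best_d <- d; best <- f }
  }
  list(attributes = best$attributes, distance = best_d)
}

#' Match a point strictly within a layer
#'
#' Exact containment only — no nearest-polygon fallback.  Used for
#' biodiversity hotspots, where a site just outside a hotspot is genuinely
#' not in it.  Boundary points count as inside.
#'
#' @inheritParams match_nearest
#' @return The containing feature's attributes, or `NULL`.
#' @export
match_within <- function(layer, point) {
  stopifnot(inherits(layer, "region_layer"))
  for (f in layer$features) {
    if (point_in_feature(f, point)) return(f$attributes)
  }
  NULL
}

#' Annotate sites with biogeographic attributes
#'
#' Each site gains its ecoregion, biome and biogeographic realm (nearest
#' ecoregion polygon, with distance), country, UN region and UN subregion
#' (nearest country polygon, with distance), and hotspot (exact containment
#' only; `NA` outside all hotspots).  The operation is idempotent.
#'
#' @param db A `survey_database`.
#' @param layers Named list with mandatory `ecoregion` and `country`
#'   [region_layer()]s and an optional `hotspot` layer.
#' @return The annotated database (attribute `annotated` set).
#' @export
annotate_sites <- function(db, layers) {
  stopifnot(inherits(db, "survey_database"))
  for (need in c("ecoregion", "country")) {
    if (is.null(layers[[need]]) || !length(layers[[need]]$features)) {
      stop_with("ecocollate_config_error",
                "mandatory layer '%s' is missing or empty", need)
    }
  }
  s <- db$sites
  n <- nrow(s)
  eco <- bio <- realm <- ctry <- ureg <- usub <- hot <-
    rep(NA_character_, n)
  d_eco <- d_ctry <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(s$latitude[i]) || is.na(s$longitude[i])) next
    if (abs(s$latitude[i]) > 90 || abs(s$longitude[i]) > 180) next
    p <- c(s$longitude[i], s$latitude[i])
    m <- match_nearest(layers$ecoregion, p)
    eco[i] <- m$attributes$ecoregion %||% NA_character_
    bio[i] <- m$attributes$biome %||% NA_character_
    realm[i] <- m$attributes$realm %||% NA_character_
    d_eco[i] <- m$distance
    m <- match_nearest(layers$country, p)
    ctry[i] <- m$attributes$country %||% NA_character_
    ureg[i] <- m$attributes$un_region %||% NA_character_
    usub[i] <- m$attributes$un_subregion %||% NA_character_
    d_ctry[i] <- m$distance
    if (!is.null(layers$hotspot)) {
      h <- match_within(layers$hotspot, p)
      if (!is.null(h)) hot[i] <- h$hotspot %||% NA_character_
    }
  }
  s$ecoregion <- eco; s$biome <- bio; s$realm <- realm
  s$ecoregion_distance_m <- d_eco
  s$country <- ctry; s$un_region <- ureg; s$un_subregion <- usub
  s$country_distance_m <- d_ctry
  s$hotspot <- hot
  db$sites <- s
  attr(db, "annotated") <- TRUE
  db
}

#' Latitude of a study
#'
#' A study's latitude is the median of its sites' latitudes (the mean of the
#' central two for even site counts).
#'
#' @param db A `survey_database`.
#' @param study_id Optional single study; when `NULL`, all studies.
#' @return A number, or a tibble (`study_id`, `latitude`) for all studies.
#' @export
study_latitude <- function(db, study_id = NULL) {
  one <- function(sid) {
    lat <- db$sites$latitude[db$sites$study_id == sid]
    lat <- lat[!is.na(lat)]
    if (!length(lat)) {
      stop_with("ecocollate_argument_error",
                "study %s has no sites with coordinates", sid)
    }
    median(lat)
  }
  if (!is.null(study_id)) return(one(study_id))
  tibble::tibble(study_id = db$studies$study_id,
                 latitude = vapply(db$studies$study_id, one, numeric(1)))
}

band_index <- function(lat, width, lower = -90, upper = 90) {
  i <- floor((lat - lower) / width) + 1
  nmax <- ceiling((upper - lower) / width)
  pmin(i, nmax)  # top band is closed
}

band_label <- function(i, width, lower = -90) {
  lo <- lower + (i - 1) * width
  sprintf("[%g, %g)", lo, lo + width)
}

#' Latitudinal coverage in fixed-width bands
#'
#' The percentage of studies, sites and samples in bands of latitude
#' (default five degrees).  Studies are assigned to the band containing
#' their [study_latitude()]; sites and samples (non-missing measurements) to
#' the band of their site.  Bands are half-open `[lower, upper)` with the
#' northernmost band closed.  Optionally adds the percentage of terrestrial
#' area per band (closed-form spherical band areas, see [cell_area()]) and
#' of total net primary production from an NPP raster.
#'
#' @param db Annotated `survey_database`.
#' @param band_width Band width in degrees (default 5).
#' @param raster Optional [npp_raster()] for a `percent_tnpp` column.
#' @param area Add a `percent_area` column (default `TRUE`).
#' @return Tibble of coverage rows (only occupied bands are listed, plus
#'   every band occupied by area/TNPP when those columns are requested).
#' @export
latitudinal_coverage <- function(db, band_width = 5, raster = NULL,
                                 area = TRUE) {
  stopifnot(inherits(db, "survey_database"))
  nb <- ceiling(180 / band_width)
  st_lat <- study_latitude(db)
  st_band <- band_index(st_lat$latitude, band_width)
  site_band <- band_index(db$sites$latitude, band_width)
  names(site_band) <- db$sites$site_id
  m <- db$measurements[!is.na(db$measurements$value), ]
  samp_band <- site_band[m$site_id]

  tab <- function(idx, n) {
    t <- tabulate(idx[!is.na(idx)], nbins = nb)
    if (n == 0) rep(0, nb) else 100 * t / n
  }
  out <- tibble::tibble(
    band = band_label(seq_len(nb), band_width),
    percent_studies = tab(st_band, nrow(st_lat)),
    percent_sites = tab(site_band, sum(!is.na(site_band))),
    percent_samples = tab(samp_band, sum(!is.na(samp_band))))
  if (area) {
    lows <- -90 + (seq_len(nb) - 1) * band_width
    a <- vapply(lows, function(lo) {
      cell_area(lo, min(band_width, 90 - lo), lon_width = 360)
    }, numeric(1))
    out$percent_area <- 100 * a / sum(a)
  }
  if (!is.null(raster)) {
    tn <- total_npp(raster, by = "band", band_width = band_width)
    v <- rep(0, nb)
    v[tn$band_index] <- tn$tnpp_g_c
    out$percent_tnpp <- if (sum(v) > 0) 100 * v / sum(v) else v
  }
  keep <- out$percent_studies > 0 | out$percent_sites > 0 |
    out$percent_samples > 0
  if (area) keep <- keep | rep(TRUE, nb)
  out[keep, ]
}

#' Coverage table for an annotation category
#'
#' Per category (biome, realm, ecoregion, country, UN region/subregion or
#' hotspot): the percentage of studies, sites and samples.  A study counts
#' in every category any of its sites touches, so the studies column can sum
#' to more than 100 across overlapping categories; sites and samples
#' partition, so those columns sum to 100.  Sites outside all hotspots fall
#' in a `"None"` row.  Optional columns: percent of terrestrial area (from
#' an attributed polygon layer plus the total land area) and percent of
#' total net primary production (from an NPP raster zoned by the layer).
#'
#' @param db Annotated `survey_database`.
#' @param category Annotation column name, e.g. `"biome"`, `"hotspot"`.
#' @param area_layer Optional [region_layer()] whose features carry
#'   `category` among their attributes; used for the area column.
#' @param land_area_km2 Total land area for the area denominator; defaults
#'   to the summed area of `area_layer`.
#' @param raster Optional [npp_raster()] (zoned by `area_layer`).
#' @return Tibble of coverage rows sorted by category.
#' @export
coverage_table <- function(db, category, area_layer = NULL,
                           land_area_km2 = NULL, raster = NULL) {
  stopifnot(inherits(db, "survey_database"))
  if (!isTRUE(attr(db, "annotated"))) {
    stop_with("ecocollate_state_error",
              "database is not annotated; run annotate_sites() first")
  }
  s <- db$sites
  if (!category %in% names(s)) {
    stop_with("ecocollate_argument_error",
              "unknown annotation category '%s'", category)
  }
  cat_val <- s[[category]]
  cat_val[is.na(cat_val)] <- "None"
  cats <- sort(unique(cat_val))

  site_count <- table(factor(cat_val, levels = cats))
  study_pairs <- unique(data.frame(study = s$study_id, cat = cat_val))
  study_count <- table(factor(study_pairs$cat, levels = cats))
  m <- db$measurements[!is.na(db$measurements$value), ]
  samp_cat <- cat_val[match(m$site_id, s$site_id)]
  samp_count <- table(factor(samp_cat, levels = cats))

  out <- tibble::tibble(
    category = cats,
    percent_studies = 100 * as.vector(study_count) / nrow(db$studies),
    percent_sites = 100 * as.vector(site_count) / nrow(s),
    percent_samples = if (nrow(m)) 100 * as.vector(samp_count) / nrow(m)
                      else 0)
  if (!is.null(area_layer)) {
    areas <- setNames(rep(0, length(cats)), cats)
    total_feature_area <- 0
    for (f in area_layer$features) {
      a <- 0
      for (poly in f$polygons) {
        a <- a + geosphere::areaPolygon(poly[[1]][-nrow(poly[[1]]), ]) / 1e6
        for (hole in poly[-1]) {
          a <- a - geosphere::areaPolygon(hole[-nrow(hole), ]) / 1e6
        }
      }
      total_feature_area <- total_feature_area + a
      nm <- f$attributes[[category]]
      if (!is.null(nm) && nm %in% cats) areas[nm] <- areas[nm] + a
    }
    land <- land_area_km2 %||% total_feature_area
    if ("None" %in% cats) areas["None"] <- max(land - total_feature_area, 0)
    out$percent_area <- 100 * as.vector(areas) / land
  }
  if (!is.null(raster) && !is.null(area_layer)) {
    tn <- total_npp(raster, by = "region", regions = area_layer,
                    attribute = category)
    v <- setNames(rep(0, length(cats)), cats)
    common <- intersect(tn$category, cats)
    v[common] <- tn$tnpp_g_c[match(common, tn$category)]
    out$percent_tnpp <- if (sum(tn$tnpp_g_c) > 0)
      100 * as.vector(v) / sum(tn$tnpp_g_c) else 0
  }
  out
}

#' Area of a longitude-latitude cell on the sphere
#'
#' Closed-form spherical band formula `R^2 * dlambda * (sin(phi2) -
#' sin(phi1))` with R = 6371.0088 km, where `latitude` is the cell's
#' southern edge.
#'
#' @param latitude Southern edge latitude in degrees (|lat| <= 90).
#' @param resolution_degrees Cell height in degrees.
#' @param lon_width Cell width in degrees (defaults to the resolution).
#' @return Area in km^2.
#' @export
cell_area <- function(latitude, resolution_degrees,
                      lon_width = resolution_degrees) {
  stopifnot(all(abs(latitude) <= 90))
  phi1 <- latitude * pi / 180
  phi2 <- pmin(latitude + resolution_degrees, 90) * pi / 180
  .EARTH_RADIUS_KM^2 * (lon_width * pi / 180) * (sin(phi2) - sin(phi1))
}

#' Construct a gridded monthly NPP raster
#'
#' Twelve monthly layers of mean daily net primary production
#' (g C m^-2 day^-1) on a regular lon/lat grid, with an optional terrestrial
#' fraction mask (default 1 everywhere).  Rows run north to south as in
#' ESRI ASCII grids.
#'
#' @param values 3-D array `[nrow, ncol, 12]`, `NA` for missing cells.
#' @param xll,yll Coordinates of the grid's lower-left corner (degrees).
#' @param cellsize Cell size in degrees.
#' @param mask Optional `[nrow, ncol]` matrix of terrestrial fractions.
#' @return An `npp_raster`.
#' @export
npp_raster <- function(values, xll, yll, cellsize, mask = NULL) {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == 12)
  if (is.null(mask)) mask <- matrix(1, dim(values)[1], dim(values)[2])
  stopifnot(all(dim(mask) == dim(values)[1:2]))
  if (any(values[!is.na(values)] < 0)) {
    stop_with("ecocollate_argument_error", "NPP values must be >= 0")
  }
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, mask = mask),
            class = "npp_raster")
}

# Cell-center coordinates; row 1 is the northernmost row.
raster_cell_centers <- function(r) {
  nr <- dim(r$values)[1]; nc <- dim(r$values)[2]
  lon <- r$xll + (seq_len(nc) - 0.5) * r$cellsize
  lat <- r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize
  list(lon = lon, lat = lat)
}

.MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Total net primary production per region or latitudinal band
#'
#' For each cell, the monthly total is the mean daily NPP times the number
#' of days in the month (non-leap year) times the cell's terrestrial area in
#' m^2; annual TNPP is the sum of the twelve months; a region's TNPP is the
#' sum over its member cells (missing cells contribute zero).  Cells are
#' assigned to regions by their center.
#'
#' @param raster An [npp_raster()].
#' @param by `"band"` (five-degree latitudinal belts by default) or
#'   `"region"` (zones from a polygon layer).
#' @param band_width Band width in degrees when `by = "band"`.
#' @param regions [region_layer()] when `by = "region"`.
#' @param attribute Feature attribute naming the zone when `by = "region"`.
#' @return Tibble with the zone (`band`/`band_index` or `category`) and
#'   `tnpp_g_c` (g C yr^-1).
#' @export
total_npp <- function(raster, by = c("band", "region"), band_width = 5,
                      regions = NULL, attribute = NULL) {
  stopifnot(inherits(raster, "npp_raster"))
  by <- match.arg(by)
  ctr <- raster_cell_centers(raster)
  nr <- dim(raster$values)[1]; nc <- dim(raster$values)[2]

  # annual g C m^-2 per cell
  annual <- matrix(0, nr, nc)
  for (mth in 1:12) {
    v <- raster$values[, , mth]
    v[is.na(v)] <- 0
    annual <- annual + v * .MONTH_DAYS[mth]
  }
  # cell terrestrial area in m^2 (area depends on latitude row only)
  row_area <- cell_area(ctr$lat - raster$cellsize / 2, raster$cellsize) * 1e6
  cell_tnpp <- annual * raster$mask * row_area

  if (by == "band") {
    bi <- band_index(ctr$lat, band_width)
    per_band <- tapply(rowSums(cell_tnpp), bi, sum)
    idx <- as.integer(names(per_band))
    return(tibble::tibble(band = band_label(idx, band_width),
                          band_index = idx,
                          tnpp_g_c = as.vector(per_band)))
  }
  if (is.null(regions) || is.null(attribute)) {
    stop_with("ecocollate_argument_error",
              "by = 'region' needs a regions layer and an attribute name")
  }
  acc <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (cell_tnpp[i, j] == 0) next
      attrs <- match_within(regions, c(ctr$lon[j], ctr$lat[i]))
      zone <- if (is.null(attrs)) "None" else
        (attrs[[attribute]] %||% "None")
      acc[[zone]] <- (acc[[zone]] %||% 0) + cell_tnpp[i, j]
    }
  }
  tibble::tibble(category = names(acc), tnpp_g_c = unlist(acc, use.names = FALSE))
}
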