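#' Validation rule catalogue
#'
#' Codes emitted by [validate_database()] and the geographic checks, with
#' their fixed severities.  Severity `error` blocks a pipeline run; `warning`
#' and `review` do not (unless running strict).
#'
#' @return Tibble with columns `code` and `severity`.
#' @export
validation_rules <- function() {
  tibble::tribble(
    ~code, ~severity,
    "MISSING_MANDATORY",        "error",
    "NEGATIVE_CONVERSION_TIME", "error",
    "COORDINATE_OUT_OF_RANGE",  "error",
    "BAD_ANGLE",                "error",
    "INVALID_DATE",             "error",
    "DUPLICATE_SITE_NAME",      "error",
    "DUPLICATE_TAXON_NAME",     "error",
    "COUNTRY_MISMATCH",         "error",
    "OFFSHORE_SITE",            "review",
    "OFFSHORE_SITE_FAR",        "warning")
}

# Mandatory fields per record type (ids are enforced at assembly).
mandatory_fields <- function() {
  list(
    sites = c("latitude_entered", "longitude_entered", "start_entered",
              "end_entered", "land_use", "use_intensity"),
    studies = c("metric_type", "effort_unit"))
}

issue <- function(code, record_ref, message) {
  sev <- validation_rules()
  tibble::tibble(code = code,
                 severity = sev$severity[match(code, sev$code)],
                 record_ref = record_ref, message = message)
}

empty_issues <- function() {
  tibble::tibble(code = character(), severity = character(),
                 record_ref = character(), message = character())
}

#' Parse a coordinate angle literal to decimal degrees
#'
#' Accepts plain decimal degrees (passed through) and
#' degrees-minutes-seconds literals such as `"1° 30' S"`, computing
#' degrees + minutes/60 + seconds/3600 and negating for southern/western
#' hemisphere markers.  Minutes and seconds must lie in \[0, 60): a latitude
#' entered as `"1° 61'"` is an error, which is how such slips are caught
#' at validation.
#'
#' @param text Coordinate string.
#' @return Decimal degrees.
#' @examples
#' parse_angle("1° 30' S")  # -1.5
#' @export
parse_angle <- function(text) {
  txt <- trimws(as.character(text))
  if (!nzchar(txt)) stop_with("ecocollate_format_error", "empty coordinate")
  if (grepl("^[-+]?[0-9]+(\\.[0-9]+)?$", txt)) return(as.numeric(txt))

  hemi <- 1
  hm <- regmatches(txt, regexpr("[NSEWnsew]$", txt))
  if (length(hm) && nzchar(hm)) {
    if (toupper(hm) %in% c("S", "W")) hemi <- -1
    txt <- trimws(sub("[NSEWnsew]$", "", txt))
  }
  neg <- grepl("^-", txt)
  if (neg) { hemi <- hemi * -1; txt <- sub("^-", "", txt) }

  num <- "([0-9]+(?:\\.[0-9]+)?)"
  pat <- paste0("^", num, "\\s*[°ºd:]", # degrees
                "(?:\\s*", num, "\\s*['′’m:])?",  # minutes
                "(?:\\s*", num, "\\s*[\"″”s])?\\s*$")
  m <- regmatches(txt, regexec(pat, txt))[[1]]
  if (!length(m)) {
    stop_with("ecocollate_format_error", "cannot parse coordinate '%s'", text)
  }
  deg <- as.numeric(m[2])
  mins <- if (nzchar(m[3])) as.numeric(m[3]) else 0
  secs <- if (nzchar(m[4])) as.numeric(m[4]) else 0
  if (mins >= 60 || secs >= 60) {
    stop_with("ecocollate_angle_error",
              "minutes/seconds out of range in '%s'", text)
  }
  hemi * (deg + mins / 60 + secs / 3600)
}

#' Validate an assembled survey database
#'
#' Runs the lower-level rule set: mandatory-field presence, non-negative
#' time since conversion, coordinate range, angle-literal sanity (e.g. a
#' latitude of `"1° 61'"`), real-calendar date validity (e.g. a 32nd of
#' January), duplicated site names within a study and duplicated taxon names
#' within a study.  When a `countries` layer is supplied the GIS country
#' consistency check ([check_country_consistency()]) is included.
#' Issues, not errors, are the output; an empty result means all implemented
#' rules pass.
#'
#' @param db A `survey_database`.
#' @param countries Optional country [region_layer()] for the consistency
#'   check.
#' @return Tibble of issues: `code`, `severity`, `record_ref`, `message`.
#' @export
validate_database <- function(db, countries = NULL) {
  stopifnot(inherits(db, "survey_database"))
  out <- list(empty_issues())
  s <- db$sites
  ref <- sprintf("site:%s/%s", s$study_id, s$site_id)

  # mandatory fields
  for (fld in mandatory_fields()$sites) {
    miss <- is_blank(s[[fld]])
    if (any(miss)) {
      out[[length(out) + 1]] <- issue(
        "MISSING_MANDATORY", ref[miss],
        sprintf("site field '%s' is missing",
                sub("_entered$", "", fld)))
    }
  }
  for (fld in mandatory_fields()$studies) {
    miss <- is_blank(db$studies[[fld]])
    if (any(miss)) {
      out[[length(out) + 1]] <- issue(
        "MISSING_MANDATORY", sprintf("study:%s", db$studies$study_id[miss]),
        sprintf("study field '%s' is missing", fld))
    }
  }

  # negative time since conversion
  neg <- !is.na(s$time_since_conversion) & s$time_since_conversion < 0
  if (any(neg)) {
    out[[length(out) + 1]] <- issue(
      "NEGATIVE_CONVERSION_TIME", ref[neg],
      sprintf("time since conversion is negative (%s)",
              s$time_since_conversion[neg]))
  }

  # angle sanity and coordinate range, on the entered text
  for (axis in c("latitude", "longitude")) {
    entered <- s[[paste0(axis, "_entered")]]
    lim <- if (axis == "latitude") 90 else 180
    for (i in seq_along(entered)) {
      if (is_blank(entered[i])) next
      val <- tryCatch(parse_angle(entered[i]), error = function(e) e)
      if (inherits(val, "error")) {
        out[[length(out) + 1]] <- issue(
          "BAD_ANGLE", ref[i],
          sprintf("%s '%s' is not a valid angle", axis, entered[i]))
      } else if (abs(val) > lim) {
        out[[length(out) + 1]] <- issue(
          "COORDINATE_OUT_OF_RANGE", ref[i],
          sprintf("%s %s outside [-%d, %d]", axis, val, lim, lim))
      }
    }
  }

  # calendar dates
  for (end in c("start", "end")) {
    entered <- s[[paste0(end, "_entered")]]
    parsed <- s[[paste0(end, "_date")]]
    bad <- !is_blank(entered) & is.na(parsed)
    if (any(bad)) {
      out[[length(out) + 1]] <- issue(
        "INVALID_DATE", ref[bad],
        sprintf("%s date '%s' is not a real calendar date",
                end, entered[bad]))
    }
  }

  # duplicate site names within a study (one issue per duplicated name)
  key <- paste(s$study_id, s$site_name, sep = "\r")
  dup_keys <- unique(key[duplicated(key) & !is_blank(s$site_name)])
  for (k in dup_keys) {
    first <- which(key == k)[1]
    out[[length(out) + 1]] <- issue(
      "DUPLICATE_SITE_NAME", ref[first],
      sprintf("site name '%s' duplicated within study %s",
              s$site_name[first], s$study_id[first]))
  }

  # duplicate taxon names within a study
  tx <- db$taxa
  tkey <- paste(tx$study_id, tx$name_entered, sep = "\r")
  dup_keys <- unique(tkey[duplicated(tkey) & !is_blank(tx$name_entered)])
  for (k in dup_keys) {
    first <- which(tkey == k)[1]
    out[[length(out) + 1]] <- issue(
      "DUPLICATE_TAXON_NAME",
      sprintf("taxon:%s/%s", tx$study_id[first], tx$taxon_id[first]),
      sprintf("taxon name '%s' duplicated within study %s",
              tx$name_entered[first], tx$study_id[first]))
  }

  # country consistency (higher-level check)
  if (!is.null(countries)) {
    declared <- declared_countries_by_study(db)
    for (i in seq_len(nrow(s))) {
      if (is.na(s$latitude[i]) || is.na(s$longitude[i])) next
      if (abs(s$latitude[i]) > 90 || abs(s$longitude[i]) > 180) next
      res <- check_country_consistency(
        s[i, ], declared[[s$study_id[i]]], countries)
      if (!is.null(res)) out[[length(out) + 1]] <- res
    }
  }

  do.call(rbind, out)
}

declared_countries_by_study <- function(db) {
  by_source <- setNames(db$sources$declared_countries, db$sources$source_id)
  setNames(by_source[db$studies$source_id], db$studies$study_id)
}

#' GIS country-consistency check for one site
#'
#' The site's coordinates are matched to the nearest country polygon; the
#' check passes when the matched country equals one of the countries declared
#' for the source, or when the declaration is the literal
#' `"Multiple countries"`.  Mismatches usually indicate swapped or
#' mis-assembled coordinates.
#'
#' @param site One site row (with numeric `latitude`, `longitude`).
#' @param declared Character vector of declared country names.
#' @param countries Country [region_layer()] whose features carry a
#'   `country` attribute.
#' @return `NULL` on pass, otherwise a one-row issue tibble with code
#'   `COUNTRY_MISMATCH` carrying both names.
#' @export
check_country_consistency <- function(site, declared, countries) {
  if (!length(countries$features)) {
    stop_with("ecocollate_config_error", "country layer is empty")
  }
  if ("Multiple countries" %in% declared) return(NULL)
  m <- match_nearest(countries, c(site$longitude, site$latitude))
  matched <- m$attributes$country
  if (fold_name(matched) %in% fold_name(declared)) return(NULL)
  issue("COUNTRY_MISMATCH",
        sprintf("site:%s/%s", site$study_id, site$site_id),
        sprintf("GIS-matched country '%s' does not match declared '%s'",
                matched, paste(declared, collapse = "; ")))
}

#' Suggest coordinate transforms for a country-mismatched site
#'
#' Coordinate mistakes typically are latitude/longitude swapped, a dropped
#' sign on one axis, or both.  For a site that failed
#' [check_country_consistency()], each candidate transform (swap, negate
#' latitude, negate longitude, negate both) is evaluated against the country
#' layer; transforms whose result lands in a declared country (within
#' `tolerance_m` of its boundary, 0 by default) are returned, ordered by
#' distance.  The database is never mutated.
#'
#' @inheritParams check_country_consistency
#' @param tolerance_m Accept candidates up to this far outside the declared
#'   country's polygon (for coarse coastal polygons).
#' @return Tibble of candidates: `transform`, `latitude`, `longitude`,
#'   `matched_country`, `distance_m`; empty when nothing lands in a declared
#'   country (including when the precondition does not hold).
#' @export
suggest_coordinate_fixes <- function(site, declared, countries,
                                     tolerance_m = 0) {
  lat <- site$latitude; lon <- site$longitude
  cands <- list(
    swap = c(lat, lon),
    negate_latitude = c(lon, -lat),
    negate_longitude = c(-lon, lat),
    negate_both = c(-lon, -lat))
  rows <- list()
  for (nm in names(cands)) {
    p <- cands[[nm]]
    if (abs(p[2]) > 90 || abs(p[1]) > 180) next
    m <- match_nearest(countries, p)
    if (fold_name(m$attributes$country) %in% fold_name(declared) &&
        m$distance <= tolerance_m) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        transform = nm, latitude = p[2], longitude = p[1],
        matched_country = m$attributes$country, distance_m = m$distance)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(transform = character(), latitude = double(),
                          longitude = double(), matched_country = character(),
                          distance_m = double()))
  }
  out <- do.call(rbind, rows)
  out[order(out$distance_m), ]
}

#' Flag sites lying outside all country polygons
#'
#' Global GIS layers are coarse at local scales, so coastal or island sites
#' can fall slightly outside the relevant polygon.  Sites with a nonzero
#' nearest-country distance are flagged for review; beyond `threshold`
#' meters the flag escalates to a warning.  Requires annotation distances
#' (run [annotate_sites()] first).
#'
#' @param db Annotated `survey_database`.
#' @param threshold Escalation distance in meters (default 10 km).
#' @return Tibble of `OFFSHORE_SITE` / `OFFSHORE_SITE_FAR` issues.
#' @export
flag_offshore_sites <- function(db, threshold = 10000) {
  stopifnot(inherits(db, "survey_database"))
  if (!isTRUE(attr(db, "annotated"))) {
    stop_with("ecocollate_state_error",
              "database is not annotated; run annotate_sites() first")
  }
  s <- db$sites
  off <- which(!is.na(s$country_distance_m) & s$country_distance_m > 0)
  if (!length(off)) return(empty_issues())
  code <- ifelse(s$country_distance_m[off] > threshold,
                 "OFFSHORE_SITE_FAR", "OFFSHORE_SITE")
  issue(code, sprintf("site:%s/%s", s$study_id[off], s$site_id[off]),
        sprintf("site is %.0f m outside the nearest country polygon (%s)",
                s$country_distance_m[off], s$country[off]))
}
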