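#' Land-use, intensity and fragmentation vocabularies
#'
#' The site ontology uses six predominant land-use classes derived from the
#' Representative Concentration Pathways harmonized land-use classes (primary
#' vegetation, secondary vegetation, cropland, pasture, urban) plus plantation
#' forest, with "Cannot decide" for sites lacking information.  Secondary
#' vegetation carries a successional stage (young, intermediate, mature, or
#' indeterminate when the stage is unknown).  Use intensity is minimal, light
#' or intense, again with "Cannot decide".  Fragmentation layout is one of
#' five classes describing a site's position relative to habitat patches.
#'
#' @return Character vector of the canonical labels, in serialization order.
#' @name ontology
NULL

#' @rdname ontology
#' @export
land_use_classes <- function() {
  c("Primary vegetation", "Secondary vegetation", "Cropland", "Pasture",
    "Urban", "Plantation forest", "Cannot decide")
}

#' @rdname ontology
#' @export
secondary_stages <- function() {
  c("young", "intermediate", "mature", "indeterminate")
}

#' @rdname ontology
#' @export
use_intensities <- function() {
  c("Minimal use", "Light use", "Intense use", "Cannot decide")
}

#' @rdname ontology
#' @export
fragmentation_layouts <- function() {
  c("Well within unfragmented habitat",
    "Within unfragmented habitat, at or near its edge",
    "Within a remnant patch",
    "Representative part of a fragmented landscape",
    "Part of the matrix surrounding remnant patches")
}

#' Construct a predominant land-use value
#'
#' @param class One of [land_use_classes()].
#' @param stage Successional stage, required iff `class` is
#'   `"Secondary vegetation"`; one of [secondary_stages()].
#' @return An object of class `land_use` with fields `class` and `stage`.
#' @examples
#' land_use("Secondary vegetation", "mature")
#' @export
land_use <- function(class, stage = NULL) {
  class <- match.arg(class, land_use_classes())
  if (class == "Secondary vegetation") {
    if (is.null(stage)) stage <- "indeterminate"
    stage <- match.arg(stage, secondary_stages())
  } else if (!is.null(stage)) {
    stop_with("ecocollate_argument_error",
              "stage is only meaningful for secondary vegetation")
  }
  structure(list(class = class, stage = stage), class = "land_use")
}

#' @export
print.land_use <- function(x, ...) {
  cat(land_use_label(x), "\n")
  invisible(x)
}

#' Serialize / parse land-use labels
#'
#' `land_use_label()` renders a `land_use` as the canonical label used in the
#' site extract, e.g. `"Secondary vegetation (mature)"`;
#' `parse_land_use()` inverts it.
#'
#' @param x A `land_use` object (for `land_use_label`) or a label string
#'   (for `parse_land_use`).
#' @return A label string, or a `land_use` object.
#' @export
land_use_label <- function(x) {
  stopifnot(inherits(x, "land_use"))
  if (is.null(x$stage)) x$class else sprintf("%s (%s)", x$class, x$stage)
}

#' @rdname land_use_label
#' @export
parse_land_use <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec("^(.*?)\\s*\\((\\w+)\\)$", x))[[1]]
  if (length(m) == 3) land_use(m[2], m[3]) else land_use(x)
}

#' Near-miss relation for predominant land use
#'
#' Two differing land-use classifications are a "near miss" (and receive
#' partial credit in repeatability scoring) in exactly four pre-specified
#' cases: primary vegetation versus mature secondary vegetation; adjacent
#' secondary stages (young-intermediate, intermediate-mature); indeterminate
#' secondary versus any other secondary stage; and "Cannot decide" versus any
#' other class.  The relation is symmetric and irreflexive.
#'
#' @param a,b `land_use` objects; must differ.
#' @return `TRUE` or `FALSE`.
#' @examples
#' near_miss_land_use(land_use("Primary vegetation"),
#'                    land_use("Secondary vegetation", "mature"))
#' @export
near_miss_land_use <- function(a, b) {
  stopifnot(inherits(a, "land_use"), inherits(b, "land_use"))
  if (identical(unclass(a), unclass(b))) {
    stop_with("ecocollate_argument_error",
              "near misses are defined only for differing classifications")
  }
  if (a$class == "Cannot decide" || b$class == "Cannot decide") return(TRUE)
  sec <- "Secondary vegetation"
  if (a$class == "Primary vegetation" && b$class == sec) {
    return(identical(b$stage, "mature"))
  }
  if (b$class == "Primary vegetation" && a$class == sec) {
    return(identical(a$stage, "mature"))
  }
  if (a$class == sec && b$class == sec) {
    if (a$stage == "indeterminate" || b$stage == "indeterminate") return(TRUE)
    ord <- c(young = 1L, intermediate = 2L, mature = 3L)
    return(abs(ord[[a$stage]] - ord[[b$stage]]) == 1L)
  }
  FALSE
}

#' Near-miss relation for use intensity
#'
#' Differing intensity scores are near misses when they are adjacent
#' (minimal-light or light-intense) or when either is "Cannot decide".
#'
#' @param a,b Intensity labels from [use_intensities()]; must differ.
#' @return `TRUE` or `FALSE`.
#' @export
near_miss_intensity <- function(a, b) {
  a <- match.arg(a, use_intensities())
  b <- match.arg(b, use_intensities())
  if (a == b) {
    stop_with("ecocollate_argument_error",
              "near misses are defined only for differing classifications")
  }
  if (a == "Cannot decide" || b == "Cannot decide") return(TRUE)
  ord <- c("Minimal use" = 1L, "Light use" = 2L, "Intense use" = 3L)
  abs(ord[[a]] - ord[[b]]) == 1L
}

#' Build a date interval from possibly coarse date parts
#'
#' Authors report sampling dates at day, month or year precision.  The
#' interval stores the earliest possible start date and the latest possible
#' end date at the finest resolution available on both ends: a month-only
#' start snaps to the first day of the month, a month-only end to the last
#' day of the month (leap-year aware); year-only ends snap analogously to
#' 1 January and 31 December.
#'
#' @param year,month,day Start-date parts (`month`/`day` may be `NA`).
#' @param end_year,end_month,end_day End-date parts.
#' @return A `date_interval` with fields `start` (Date), `end` (Date) and
#'   `resolution` (`"day"`, `"month"` or `"year"`).
#' @examples
#' make_date_interval(2007, 6, NA, 2007, 8, NA)  # June-August 2007
#' @export
make_date_interval <- function(year, month = NA, day = NA,
                               end_year, end_month = NA, end_day = NA) {
  part_ok <- function(y, m, d) {
    if (is.na(y)) stop_with("ecocollate_date_error", "year is mandatory")
    if (!is.na(d) && is.na(m)) {
      stop_with("ecocollate_date_error", "day given without month")
    }
    if (!is.na(m) && (m < 1 || m > 12)) {
      stop_with("ecocollate_date_error", "invalid month %s", m)
    }
    if (!is.na(d) && (d < 1 || d > days_in_month(y, m))) {
      stop_with("ecocollate_date_error", "invalid day %s-%s-%s", y, m, d)
    }
  }
  part_ok(year, month, day)
  part_ok(end_year, end_month, end_day)
  res <- if (!is.na(day) && !is.na(end_day)) "day"
         else if (!is.na(month) && !is.na(end_month)) "month"
         else "year"
  start <- switch(res,
    day   = as.Date(sprintf("%04d-%02d-%02d", year, month, day)),
    month = as.Date(sprintf("%04d-%02d-01", year, month)),
    year  = as.Date(sprintf("%04d-01-01", year)))
  end <- switch(res,
    day   = as.Date(sprintf("%04d-%02d-%02d", end_year, end_month, end_day)),
    month = as.Date(sprintf("%04d-%02d-%02d", end_year, end_month,
                            days_in_month(end_year, end_month))),
    year  = as.Date(sprintf("%04d-12-31", end_year)))
  if (start > end) {
    stop_with("ecocollate_date_error", "start date %s is after end date %s",
              start, end)
  }
  structure(list(start = start, end = end, resolution = res),
            class = "date_interval")
}

#' @export
print.date_interval <- function(x, ...) {
  cat(sprintf("[%s, %s] (resolution: %s)\n", x$start, x$end, x$resolution))
  invisible(x)
}

#' Parse a reported time since land-use conversion
#'
#' Plain numbers are taken at face value; ranges (`"10-20 years"`) store the
#' midpoint; open-ended reports (`"greater than N years"`, `"at least N
#' years"`, `"> N"`) store N x 1.25.
#'
#' @param text Reported value as text (a plain number is also accepted).
#' @return Time since conversion in years.
#' @examples
#' parse_time_since_conversion("at least 20 years")  # 25
#' parse_time_since_conversion("10-20 years")        # 15
#' @export
parse_time_since_conversion <- function(text) {
  txt <- tolower(trimws(as.character(text)))
  txt <- sub("\\s*(years?|yrs?)\\s*$", "", txt)
  num <- "[0-9]+(?:\\.[0-9]+)?"
  out <- if (grepl(paste0("^(greater than|at least|more than|>=?|≥)\\s*",
                          num, "$"), txt)) {
    1.25 * as.numeric(regmatches(txt, regexpr(num, txt)))
  } else if (grepl(paste0("^", num, "\\s*(–|—|-|to)\\s*", num, "$"),
                   txt)) {
    ends <- as.numeric(regmatches(txt, gregexpr(num, txt))[[1]])
    mean(ends)
  } else if (grepl(paste0("^-?", num, "$"), txt)) {
    as.numeric(txt)
  } else {
    stop_with("ecocollate_format_error",
              "cannot parse time since conversion: '%s'", text)
  }
  if (out < 0) {
    stop_with("ecocollate_argument_error",
              "time since conversion is negative: '%s'", text)
  }
  out
}

#' Maximum linear extent of sampling
#'
#' The greatest linear distance encompassed by sampling at a site: the length
#' of a transect (two points), the maximum pairwise great-circle distance of
#' a set of sampling points, or 0 for a single point.  Distances use a
#' spherical Earth of radius 6371.0088 km.
#'
#' @param points A two-column matrix or data frame of (longitude, latitude)
#'   in decimal degrees WGS84.
#' @return Extent in meters.
#' @export
max_linear_extent <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2 || nrow(pts) < 1) {
    stop_with("ecocollate_argument_error",
              "points must be an n x 2 (lon, lat) matrix with n >= 1")
  }
  if (nrow(pts) == 1) return(0)
  d <- geosphere::distm(pts, fun = gc_distance)
  max(d)
}
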