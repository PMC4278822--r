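`%||%` <- function(a, b) if (is.null(a)) b else a

#' Taxonomic rank ladder
#'
#' The fixed rank ladder used throughout name resolution, ordered from the
#' most inclusive (kingdom) to the least (infraspecies).
#'
#' @return Character vector of rank names.
#' @export
rank_ladder <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus",
    "species", "infraspecies")
}

# Case-insensitive, diacritic-folded key used for all name matching.
fold_name <- function(x) {
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  tolower(trimws(x))
}

is_blank <- function(x) {
  is.na(x) | !nzchar(trimws(as.character(x)))
}

# Derive an independent pseudo-random stream seed from a master seed and a
# stable label, so adding a generator never shifts existing outputs.
stream_seed <- function(master, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(master) * 1009 + h) %% 2147483647)
}

with_stream_seed <- function(master, label, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(stream_seed(master, label))
  expr
}

stop_with <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ecocollate_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

days_in_month <- function(year, month) {
  lengths <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- lengths[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  ifelse(month == 2L & leap, 29L, d)
}

# Haversine great-circle distance in meters on the package sphere.
gc_distance <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = .EARTH_RADIUS_M)
}
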