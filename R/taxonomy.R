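.TAXON_STATUSES <- c("accepted", "synonym", "ambiguous_synonym",
                     "misapplied", "common_name")

#' Construct a taxonomic checklist
#'
#' An authoritative name list modeled on the Catalogue of Life Annual
#' Checklist: every entry has a name, a rank, a status (accepted, synonym,
#' ambiguous synonym, misapplied, or common name), a pointer to its accepted
#' entry and a classification down to its rank.  Accepted entries point to
#' themselves; every non-accepted entry must point to an accepted one.
#'
#' @param entries Data frame with columns `entry_id`, `name`, `rank`,
#'   `status`, `accepted_ref` and the classification columns
#'   `kingdom` ... `infraspecies` (missing ranks `NA`).
#' @return A `checklist` (tibble subclass with a folded `name_key` column).
#' @export
checklist <- function(entries) {
  e <- tibble::as_tibble(entries)
  need <- c("entry_id", "name", "rank", "status", "accepted_ref")
  if (!all(need %in% names(e))) {
    stop_with("ecocollate_argument_error",
              "checklist needs columns: %s", paste(need, collapse = ", "))
  }
  for (r in rank_ladder()) if (!r %in% names(e)) e[[r]] <- NA_character_
  bad <- !e$status %in% .TAXON_STATUSES
  if (any(bad)) {
    stop_with("ecocollate_argument_error", "unknown status '%s'",
              e$status[bad][1])
  }
  acc <- e$status == "accepted"
  e$accepted_ref[acc] <- e$entry_id[acc]
  tgt <- match(e$accepted_ref, e$entry_id)
  if (any(is.na(tgt)) || any(e$status[tgt] != "accepted")) {
    stop_with("ecocollate_argument_error",
              "every accepted_ref must resolve to an accepted entry")
  }
  e$name_key <- fold_name(e$name)
  class(e) <- c("checklist", class(e))
  e
}

# Named rank -> name vector for one checklist/pool row, NA ranks dropped.
classification_of <- function(row) {
  v <- unlist(row[rank_ladder()])
  v <- setNames(as.character(v), rank_ladder())
  v[!is.na(v)]
}

#' Clade constraint for name resolution
#'
#' Restricts checklist searches to one clade, e.g. kingdom Animalia for
#' cross-kingdom homonyms such as *Bellardia*, *Dracaena* and *Ficus*, or
#' family Carabidae for a study of carabid beetles.
#'
#' @param rank A rank from [rank_ladder()].
#' @param name The clade name at that rank.
#' @return A `clade_constraint`.
#' @export
clade_constraint <- function(rank, name) {
  rank <- match.arg(rank, rank_ladder())
  structure(list(rank = rank, name = name), class = "clade_constraint")
}

unmatched_resolution <- function() {
  structure(list(matched_entry = NA_character_, rank = NA_character_,
                 name = NA_character_, classification = character(0),
                 mode = "unmatched"),
            class = "resolution")
}

#' @export
print.resolution <- function(x, ...) {
  if (x$mode == "unmatched") {
    cat("<resolution> unmatched\n")
  } else {
    cat(sprintf("<resolution> %s '%s' (%s)\n", x$rank, x$name, x$mode))
  }
  invisible(x)
}

#' Parse an entered taxon name to a putative Latin binomial
#'
#' Grammar: the first token, when a capitalized word, is the genus; the
#' second token is kept as the specific epithet iff it is all lowercase and
#' not an open-nomenclature qualifier (sp, spp, cf, aff, gr, nr, indet);
#' parsing stops at a qualifier, a capitalized token (an authority), a
#' parenthesis or a digit.  Every input is treated as a scientific name, so
#' common names parse nonsensically ("Black and White Casqued Hornbill"
#' parses to "Black and") — such results are caught later in curation.
#'
#' @param name_entered Name as given by the data provider.
#' @return The parsed name (genus, or genus + epithet).
#' @examples
#' parse_taxon_name("Ancistrocerus trifasciatus Müll.")  # drops authority
#' parse_taxon_name("Bracon sp. 1")                           # "Bracon"
#' @export
parse_taxon_name <- function(name_entered) {
  txt <- trimws(as.character(name_entered))
  if (!nzchar(txt)) {
    stop_with("ecocollate_format_error", "empty taxon name")
  }
  tokens <- strsplit(txt, "\\s+")[[1]]
  qualifiers <- c("sp", "spp", "cf", "aff", "gr", "nr", "indet")
  is_qualifier <- function(tok) tolower(sub("\\.$", "", tok)) %in% qualifiers
  stops_parse <- function(tok) {
    grepl("[()0-9]", tok) || grepl("^[[:upper:]]", tok) || is_qualifier(tok)
  }
  out <- tokens[1]
  if (length(tokens) >= 2) {
    tok2 <- tokens[2]
    if (!stops_parse(tok2) &&
        grepl("^[[:lower:]à-ÿ-]+$", tok2)) {
      out <- paste(out, tok2)
    }
  }
  out
}

#' Resolve a query name against a checklist
#'
#' Search is by name (scientific or common), case-insensitive and
#' diacritic-folded; fuzzy matching is deliberately not attempted (typo
#' repair is a curation task).  With an optional [clade_constraint()] only
#' records in that clade are considered.  Then: (a) if the results contain
#' exactly one distinct accepted name — directly, or via the accepted-name
#' pointers of synonyms/common names — that accepted entry is the
#' resolution; (b) with zero or two-plus distinct accepted names, the
#' resolution is the lowest rank whose name is shared by all results'
#' classifications (so the homonym genus *Notiophilus*, accepted in two
#' beetle families, resolves to order Coleoptera); (c) with no results the
#' name is unmatched — a value, not an error.
#'
#' @param cl A [checklist()].
#' @param query Query name.
#' @param constraint Optional [clade_constraint()].
#' @return A `resolution`: `matched_entry`, `rank`, `name`,
#'   `classification`, and `mode` (`accepted_direct`, `accepted_via_status`,
#'   `lowest_common_rank`, `unmatched`).
#' @export
resolve_name <- function(cl, query, constraint = NULL) {
  stopifnot(inherits(cl, "checklist"))
  hits <- cl[cl$name_key == fold_name(query), , drop = FALSE]
  if (!is.null(constraint)) {
    stopifnot(inherits(constraint, "clade_constraint"))
    keep <- !is.na(hits[[constraint$rank]]) &
      fold_name(hits[[constraint$rank]]) == fold_name(constraint$name)
    hits <- hits[keep, , drop = FALSE]
  }
  if (!nrow(hits)) return(unmatched_resolution())

  accepted_ids <- unique(hits$accepted_ref)
  if (length(accepted_ids) == 1) {
    acc <- cl[cl$entry_id == accepted_ids, ]
    mode <- if (any(hits$status == "accepted")) "accepted_direct"
            else "accepted_via_status"
    return(structure(
      list(matched_entry = acc$entry_id, rank = acc$rank, name = acc$name,
           classification = classification_of(acc), mode = mode),
      class = "resolution"))
  }
  maps <- lapply(seq_len(nrow(hits)),
                 function(i) classification_of(hits[i, ]))
  lc <- lowest_common_classification(maps)
  if (is.null(lc)) return(unmatched_resolution())
  ladder <- rank_ladder()
  keep <- ladder[seq_len(match(lc$rank, ladder))]
  cls <- maps[[1]][intersect(keep, names(maps[[1]]))]
  structure(list(matched_entry = NA_character_, rank = lc$rank,
                 name = lc$name, classification = cls,
                 mode = "lowest_common_rank"),
            class = "resolution")
}

#' Lowest classification common to a set of results
#'
#' Classifications are lineage paths down the rank ladder; the lowest
#' common level is the deepest rank before the lineages diverge.  Walking
#' from kingdom downward, a rank where every map carries the same name
#' extends the common lineage; a rank missing from every map is skipped
#' (coarse checklists omit intermediate ranks); the first rank where the
#' maps differ — or where only some maps have a value — ends the walk.
#' Names alone do not count: two homonym genera in different families share
#' the genus name but diverge at family, so their lowest common level is
#' the order, as the nomenclatural violation demands.
#'
#' @param classifications Non-empty list of named rank-to-name vectors
#'   sharing the [rank_ladder()].
#' @return List with `rank` and `name`, or `NULL` when the maps do not agree
#'   even at kingdom.
#' @export
lowest_common_classification <- function(classifications) {
  if (!length(classifications)) {
    stop_with("ecocollate_argument_error",
              "need at least one classification")
  }
  best <- NULL
  for (rk in rank_ladder()) {
    vals <- vapply(classifications,
                   function(m) if (rk %in% names(m)) m[[rk]] else
                     NA_character_,
                   character(1))
    if (all(is.na(vals))) next        # rank absent everywhere: skip
    if (anyNA(vals) || length(unique(vals)) > 1) break  # divergence
    best <- list(rank = rk, name = vals[[1]])
  }
  best
}

#' Resolve every taxon of a database against a checklist
#'
#' Each taxon name is parsed ([parse_taxon_name()]); the query name is the
#' parsed name unless a curation override applies; the query is resolved
#' ([resolve_name()]) under any per-study clade constraint.  The taxa table
#' gains the parsed/query names, the resolution columns, the resolved
#' classification, the best-guess binomial and the higher taxonomic group.
#' Each study gains the lowest classification common to its resolved taxa.
#'
#' @param db A `survey_database`.
#' @param cl A [checklist()].
#' @param constraints Optional named list (by `study_id`) of
#'   [clade_constraint()]s.
#' @return The database with resolved taxonomy (attribute `resolved` set).
#' @export
resolve_taxonomy <- function(db, cl, constraints = NULL) {
  stopifnot(inherits(db, "survey_database"), inherits(cl, "checklist"))
  tx <- db$taxa
  n <- nrow(tx)
  if (!"query_name" %in% names(tx)) tx$query_name <- NA_character_
  tx$parsed_name <- vapply(tx$name_entered, parse_taxon_name, character(1),
                           USE.NAMES = FALSE)
  tx$query_name <- ifelse(is.na(tx$query_name), tx$parsed_name,
                          tx$query_name)
  tx$matched_entry <- tx$resolved_rank <- tx$resolved_name <-
    rep(NA_character_, n)
  tx$resolution_mode <- rep("unmatched", n)
  for (rk in rank_ladder()) tx[[rk]] <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- resolve_name(cl, tx$query_name[i],
                        constraints[[tx$study_id[i]]])
    tx$matched_entry[i] <- res$matched_entry
    tx$resolved_rank[i] <- res$rank
    tx$resolved_name[i] <- res$name
    tx$resolution_mode[i] <- res$mode
    for (rk in names(res$classification)) {
      tx[[rk]][i] <- res$classification[[rk]]
    }
  }
  tx$best_guess_binomial <- best_guess_binomial(
    tx$resolved_rank, tx$resolved_name, tx$parsed_name)
  tx$higher_group <- vapply(seq_len(n), function(i) {
    higher_group(classification_of(tx[i, ]))
  }, character(1))
  db$taxa <- tx

  # study-level lowest common taxon
  st <- db$studies
  st$lowest_common_rank <- st$lowest_common_name <- NA_character_
  for (j in seq_len(nrow(st))) {
    rows <- which(tx$study_id == st$study_id[j] &
                    tx$resolution_mode != "unmatched")
    if (!length(rows)) next
    maps <- lapply(rows, function(i) classification_of(tx[i, ]))
    lc <- lowest_common_classification(maps)
    if (!is.null(lc)) {
      st$lowest_common_rank[j] <- lc$rank
      st$lowest_common_name[j] <- lc$name
    }
  }
  db$studies <- st
  attr(db, "resolved") <- TRUE
  db
}

#' Build the taxon curation review queue
#'
#' Flags, with criterion codes: `UNMATCHED` — taxa with no checklist record;
#' `COARSE_RESOLUTION` — taxa resolved above species whose entered name
#' looks like a Latin binomial or a common name; `INCONSISTENT` — the same
#' parsed name resolving to different checklist entries in different
#' studies; `IMPLAUSIBLE_CLADE` — studies whose lowest common taxon is not
#' within the declared expected clade (e.g. a bird study resolving to
#' kingdom Animalia instead of class Aves, the signature of an uncurated
#' bird-code collision).
#'
#' @param db A resolved `survey_database`.
#' @param expected_clades Optional named list (by `study_id`) of
#'   [clade_constraint()]s declaring each study's expected clade.
#' @return Tibble: `criterion`, `study_id`, `taxon_id`, `detail`.
#' @export
build_review_queue <- function(db, expected_clades = NULL) {
  stopifnot(inherits(db, "survey_database"))
  if (!isTRUE(attr(db, "resolved"))) {
    stop_with("ecocollate_state_error",
              "taxonomy is not resolved; run resolve_taxonomy() first")
  }
  tx <- db$taxa
  out <- list(tibble::tibble(criterion = character(), study_id = character(),
                             taxon_id = character(), detail = character()))
  row <- function(criterion, study_id, taxon_id, detail) {
    tibble::tibble(criterion = criterion, study_id = study_id,
                   taxon_id = taxon_id, detail = detail)
  }
  un <- tx$resolution_mode == "unmatched"
  if (any(un)) {
    out[[length(out) + 1]] <- row(
      "UNMATCHED", tx$study_id[un], tx$taxon_id[un],
      sprintf("no checklist record for '%s'", tx$query_name[un]))
  }
  # Morphospecies ("Bracon sp. 1") parse to a bare genus and are expected
  # to resolve high; a parsed two-word binomial resolving above species is
  # the suspicious case.
  species_level <- tx$resolved_rank %in% c("species", "infraspecies")
  binomial_like <- vapply(strsplit(tx$parsed_name, " "), length,
                          integer(1)) >= 2
  coarse <- !un & !species_level & binomial_like
  if (any(coarse)) {
    out[[length(out) + 1]] <- row(
      "COARSE_RESOLUTION", tx$study_id[coarse], tx$taxon_id[coarse],
      sprintf("'%s' resolved only to %s %s", tx$name_entered[coarse],
              tx$resolved_rank[coarse], tx$resolved_name[coarse]))
  }
  matched <- !is.na(tx$matched_entry)
  for (pn in unique(tx$parsed_name[matched])) {
    rows <- which(matched & tx$parsed_name == pn)
    if (length(unique(tx$matched_entry[rows])) > 1 &&
        length(unique(tx$study_id[rows])) > 1) {
      out[[length(out) + 1]] <- row(
        "INCONSISTENT", tx$study_id[rows], tx$taxon_id[rows],
        sprintf("parsed name '%s' resolves to different entries across studies",
                pn))
    }
  }
  if (!is.null(expected_clades)) {
    st <- db$studies
    for (sid in names(expected_clades)) {
      cc <- expected_clades[[sid]]
      j <- match(sid, st$study_id)
      if (is.na(j)) next
      rows <- which(tx$study_id == sid & tx$resolution_mode != "unmatched")
      ok <- FALSE
      if (length(rows)) {
        maps <- lapply(rows, function(i) classification_of(tx[i, ]))
        lc <- lowest_common_classification(maps)
        if (!is.null(lc)) {
          at_rank <- vapply(maps, function(m) {
            cc$rank %in% names(m) && fold_name(m[[cc$rank]]) ==
              fold_name(cc$name)
          }, logical(1))
          ok <- all(at_rank)
        }
      }
      if (!ok) {
        out[[length(out) + 1]] <- row(
          "IMPLAUSIBLE_CLADE", sid, NA_character_,
          sprintf("lowest common taxon of study %s (%s %s) is not within expected %s %s",
                  sid, st$lowest_common_rank[j] %||% NA,
                  st$lowest_common_name[j] %||% NA, cc$rank, cc$name))
      }
    }
  }
  do.call(rbind, out)
}

#' Apply a curation change to one taxon and re-resolve it
#'
#' Curation replaces the query name (never the entered or parsed name),
#' records the reason in the curation log, and reruns resolution.  The step
#' may be repeated; each change appends a log row.
#'
#' @param db A resolved `survey_database`.
#' @param taxon_id The taxon to curate.
#' @param new_query Replacement query name.
#' @param reason Non-empty reason for the change.
#' @param cl The [checklist()] to re-resolve against.
#' @param constraint Optional [clade_constraint()] for the re-query.
#' @return The updated database.
#' @export
apply_curation <- function(db, taxon_id, new_query, reason, cl,
                           constraint = NULL) {
  stopifnot(inherits(db, "survey_database"))
  if (is_blank(reason)) {
    stop_with("ecocollate_argument_error", "curation reason must be given")
  }
  i <- match(taxon_id, db$taxa$taxon_id)
  if (is.na(i)) {
    stop_with("ecocollate_argument_error", "unknown taxon_id '%s'", taxon_id)
  }
  old <- db$taxa$query_name[i]
  db$taxa$query_name[i] <- new_query
  res <- resolve_name(cl, new_query, constraint)
  db$taxa$matched_entry[i] <- res$matched_entry
  db$taxa$resolved_rank[i] <- res$rank
  db$taxa$resolved_name[i] <- res$name
  db$taxa$resolution_mode[i] <- res$mode
  for (rk in rank_ladder()) {
    db$taxa[[rk]][i] <- if (rk %in% names(res$classification))
      res$classification[[rk]] else NA_character_
  }
  db$taxa$best_guess_binomial[i] <- best_guess_binomial(
    res$rank, res$name, db$taxa$parsed_name[i])
  db$taxa$higher_group[i] <- higher_group(res$classification)
  db$curation_log <- rbind(
    db$curation_log,
    tibble::tibble(taxon_id = taxon_id, old_query = old,
                   new_query = new_query, reason = reason))
  db
}

#' Expand a four-letter bird code against a species pool
#'
#' Binomial-derived codes are the first two letters of the genus plus the
#' first two of the specific epithet (ACBA for *Accipiter badius*).  Pool
#' members whose derived code equals the query are the candidates: one
#' candidate resolves to that species; several resolve to the lowest
#' classification common to all matches (codes collide); none is unmatched.
#'
#' @param code Four-letter alphabetic code.
#' @param pool Data frame of candidate species: column `name` (binomial)
#'   plus classification columns `kingdom` ... `species`.
#' @return A `resolution`.
#' @export
expand_bird_code <- function(code, pool) {
  if (!grepl("^[[:alpha:]]{4}$", code)) {
    stop_with("ecocollate_format_error",
              "bird code must be four letters, got '%s'", code)
  }
  pool <- tibble::as_tibble(pool)
  if (!nrow(pool)) {
    stop_with("ecocollate_argument_error", "species pool is empty")
  }
  for (r in rank_ladder()) if (!r %in% names(pool)) pool[[r]] <- NA_character_
  words <- strsplit(pool$name, "\\s+")
  derived <- vapply(words, function(w) {
    if (length(w) < 2) return(NA_character_)
    toupper(paste0(substr(w[1], 1, 2), substr(w[2], 1, 2)))
  }, character(1))
  hits <- which(!is.na(derived) & derived == toupper(code))
  if (!length(hits)) return(unmatched_resolution())
  if (length(hits) == 1) {
    row <- pool[hits, ]
    cls <- classification_of(row)
    if (!"species" %in% names(cls)) cls <- c(cls, species = row$name)
    return(structure(
      list(matched_entry = NA_character_, rank = "species", name = row$name,
           classification = cls, mode = "accepted_direct"),
      class = "resolution"))
  }
  maps <- lapply(hits, function(i) {
    cls <- classification_of(pool[i, ])
    if (!"species" %in% names(cls)) cls <- c(cls, species = pool$name[i])
    cls
  })
  lc <- lowest_common_classification(maps)
  if (is.null(lc)) return(unmatched_resolution())
  ladder <- rank_ladder()
  keep <- ladder[seq_len(match(lc$rank, ladder))]
  structure(list(matched_entry = NA_character_, rank = lc$rank,
                 name = lc$name,
                 classification = maps[[1]][intersect(keep,
                                                      names(maps[[1]]))],
                 mode = "lowest_common_rank"),
            class = "resolution")
}

#' Best-guess binomial for joining to trait databases
#'
#' Rule cascade: the resolved name if the rank is species; the first two
#' words of the resolved name if the rank is infraspecies; the first two
#' words of the parsed name if the rank is above species (or unmatched) and
#' the parsed name has two or more words; empty otherwise.
#'
#' @param resolved_rank,resolved_name,parsed_name Vectors of the taxon's
#'   resolution rank/name and parsed name (`NA` rank means unmatched).
#' @return Character vector of binomials, `""` where no guess is possible.
#' @export
best_guess_binomial <- function(resolved_rank, resolved_name, parsed_name) {
  first_two <- function(x) {
    vapply(strsplit(x, "\\s+"), function(w) {
      if (length(w) >= 2) paste(w[1:2], collapse = " ") else ""
    }, character(1))
  }
  out <- character(length(parsed_name))
  resolved_name <- as.character(resolved_name)
  parsed_name <- as.character(parsed_name)
  rank <- as.character(resolved_rank)
  sp <- !is.na(rank) & rank == "species"
  inf <- !is.na(rank) & rank == "infraspecies"
  out[sp] <- resolved_name[sp]
  out[inf] <- first_two(resolved_name[inf])
  rest <- !sp & !inf
  out[rest] <- first_two(parsed_name[rest])
  out
}

#' Higher taxonomic grouping of a classification
#'
#' Taxonomic coverage is summarised with three rules applied in order:
#' (1) the order, when the class is Insecta or Entognatha; (2) the class,
#' when the phylum is Arthropoda (excluding those two classes), Chordata or
#' Tracheophyta; (3) otherwise the phylum.  So a bee groups as order
#' Hymenoptera, a wolf as class Mammalia, a snail as its phylum.  Returns
#' `"unplaced"` when the rank the rule needs is absent.
#'
#' @param classification Named rank-to-name vector.
#' @return Group name, or `"unplaced"`.
#' @export
higher_group <- function(classification) {
  cls <- classification
  get <- function(r) if (r %in% names(cls)) cls[[r]] else NA_character_
  klass <- get("class"); phylum <- get("phylum")
  if (!is.na(klass) && klass %in% c("Insecta", "Entognatha")) {
    ord <- get("order")
    return(if (is.na(ord)) "unplaced" else ord)
  }
  if (!is.na(phylum) &&
      phylum %in% c("Arthropoda", "Chordata", "Tracheophyta")) {
    return(if (is.na(klass)) "unplaced" else klass)
  }
  if (!is.na(phylum)) return(phylum)
  "unplaced"
}

#' Estimate the number of species in the database
#'
#' Taxa resolved at species or infraspecies level are counted once per
#' resolved name across the whole database.  Taxa resolved to higher ranks
#' (including unmatched names) are counted once per name per study — so
#' morphospecies such as *Eonycteris* sp. 1-3 reported by two studies count
#' as six, an inflation inherent in the names as provided.  Counts are
#' tallied by [higher_group()] (`"unplaced"` when no group applies).
#'
#' @param db A resolved `survey_database`.
#' @return List with `total` and `by_group` (tibble `higher_group`,
#'   `n_species`).
#' @export
count_species <- function(db) {
  stopifnot(inherits(db, "survey_database"))
  if (!isTRUE(attr(db, "resolved"))) {
    stop_with("ecocollate_state_error",
              "taxonomy is not resolved; run resolve_taxonomy() first")
  }
  tx <- db$taxa
  if (!nrow(tx)) {
    return(list(total = 0L,
                by_group = tibble::tibble(higher_group = character(),
                                          n_species = integer())))
  }
  species_level <- !is.na(tx$resolved_rank) &
    tx$resolved_rank %in% c("species", "infraspecies")
  key <- ifelse(species_level,
                paste0("name\r", tx$resolved_name),
                paste0("study\r", tx$study_id, "\r", tx$name_entered))
  first <- !duplicated(key)
  groups <- tx$higher_group[first]
  by_group <- tibble::tibble(
    higher_group = names(table(groups)),
    n_species = as.integer(table(groups)))
  by_group <- by_group[order(-by_group$n_species, by_group$higher_group), ]
  list(total = sum(first), by_group = by_group)
}

#' Roll up higher-group counts for comparison with described-species totals
#'
#' Applies the four fixed roll-ups used when comparing database counts with
#' published estimates of described species: Magnoliophyta = Magnoliopsida +
#' Liliopsida; Gymnosperms = Pinopsida + Gnetopsida; Ferns and allies =
#' Polypodiopsida + Lycopodiopsida + Psilotopsida + Equisetopsida +
#' Marattiopsida; Crustacea = Malacostraca.  Unlisted groups pass through.
#'
#' @param counts Named numeric vector, or tibble (`higher_group`,
#'   `n_species`) as from [count_species()].
#' @return Tibble (`group`, `n_species`).
#' @export
aggregate_group_counts <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- setNames(counts$n_species, counts$higher_group)
  }
  rollups <- list(
    "Magnoliophyta" = c("Magnoliopsida", "Liliopsida"),
    "Gymnosperms" = c("Pinopsida", "Gnetopsida"),
    "Ferns and allies" = c("Polypodiopsida", "Lycopodiopsida",
                           "Psilotopsida", "Equisetopsida", "Marattiopsida"),
    "Crustacea" = "Malacostraca")
  out <- list()
  consumed <- character(0)
  for (nm in names(rollups)) {
    members <- intersect(rollups[[nm]], names(counts))
    if (length(members)) {
      out[[nm]] <- sum(counts[members])
      consumed <- c(consumed, members)
    }
  }
  rest <- counts[setdiff(names(counts), consumed)]
  for (nm in names(rest)) out[[nm]] <- unname(rest[[nm]])
  tibble::tibble(group = names(out),
                 n_species = as.numeric(unlist(out, use.names = FALSE)))
}

#' Match best-guess binomials against a trait/attribute database
#'
#' Exact binomial matches are counted first; genus-level matches (the
#' binomial's genus equals the genus of some attribute-database record) are
#' counted only among binomials without a species match, and only when
#' genus matching is enabled.
#'
#' @param binomials Character vector of best-guess binomials (empty strings
#'   ignored).
#' @param attribute_names Character vector of binomials in the attribute
#'   database.
#' @param match_genus Enable genus-level matching (default `FALSE`).
#' @return List: `species_matches`, `genus_matches`, `total`.
#' @export
match_attribute_names <- function(binomials, attribute_names,
                                  match_genus = FALSE) {
  binomials <- binomials[!is_blank(binomials)]
  sp <- fold_name(binomials) %in% fold_name(attribute_names)
  genus_of <- function(x) vapply(strsplit(x, "\\s+"), `[`, character(1), 1)
  gn <- 0L
  if (match_genus && any(!sp)) {
    attr_genera <- fold_name(genus_of(attribute_names))
    gn <- sum(fold_name(genus_of(binomials[!sp])) %in% attr_genera)
  }
  list(species_matches = sum(sp), genus_matches = as.integer(gn),
       total = sum(sp) + as.integer(gn))
}
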