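#' Fixture generation specification
#'
#' Controls the deterministic synthetic-data generators.  The same spec and
#' seed always produce identical output; each generator draws from its own
#' pseudo-random stream derived from the master seed by a stable label, so
#' adding a generator never shifts existing outputs.
#'
#' @param seed Master seed (integer).
#' @param n_sources,studies_per_source,sites_per_study,taxa_per_study
#'   Survey-bundle sizes.
#' @param errors Named list of injection counts per validation code
#'   (`NEGATIVE_CONVERSION_TIME`, `BAD_ANGLE`, `INVALID_DATE`,
#'   `DUPLICATE_SITE_NAME`, `DUPLICATE_TAXON_NAME`,
#'   `COORDINATE_OUT_OF_RANGE`, `COUNTRY_MISMATCH`); empty for clean data.
#' @param checklist Shape of the generated checklist: `species_per_family`,
#'   `synonym_rate` (fraction of species given an off-name synonym),
#'   `same_name_synonym_clusters` (accepted name plus two synonym records
#'   under the same name), `homonym_pairs` (a genus accepted in two beetle
#'   families), `cross_kingdom` (a genus accepted in two kingdoms),
#'   `common_names`.
#' @param regions Region-grid shape: `bbox` (xmin, ymin, xmax, ymax),
#'   `eco_nx`, `eco_ny`, `country_nx`, `country_ny`, `hotspot_cells`,
#'   `npp_resolution` (degrees).
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1,
                         n_sources = 2, studies_per_source = 1,
                         sites_per_study = 6, taxa_per_study = 8,
                         errors = list(),
                         checklist = list(),
                         regions = list()) {
  cl_def <- list(species_per_family = 6, synonym_rate = 0.3,
                 same_name_synonym_clusters = 2, homonym_pairs = 1,
                 cross_kingdom = 1, common_names = 2)
  rg_def <- list(bbox = c(-40, -30, 40, 30), eco_nx = 4, eco_ny = 3,
                 country_nx = 2, country_ny = 2, hotspot_cells = 3,
                 npp_resolution = 5)
  structure(list(seed = as.integer(seed), n_sources = n_sources,
                 studies_per_source = studies_per_source,
                 sites_per_study = sites_per_study,
                 taxa_per_study = taxa_per_study,
                 errors = errors,
                 checklist = modifyList(cl_def, checklist),
                 regions = modifyList(rg_def, regions)),
            class = "fixture_spec")
}

# Deterministic synthetic family frame used by the checklist generator.
.FIXTURE_FAMILIES <- tibble::tribble(
  ~kingdom, ~phylum, ~class, ~order, ~family,
  "Animalia", "Arthropoda", "Insecta", "Coleoptera", "Carabidae",
  "Animalia", "Arthropoda", "Insecta", "Coleoptera", "Erirhinidae",
  "Animalia", "Arthropoda", "Insecta", "Hymenoptera", "Colletidae",
  "Animalia", "Chordata", "Aves", "Passeriformes", "Muscicapidae",
  "Animalia", "Chordata", "Mammalia", "Chiroptera", "Pteropodidae",
  "Plantae", "Tracheophyta", "Magnoliopsida", "Rosales", "Rosaceae",
  "Plantae", "Tracheophyta", "Liliopsida", "Poales", "Poaceae")

letter_tag <- function(i) {
  # deterministic lowercase tag: a, b, ..., z, aa, ab, ...
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k] - 1L
    s <- ""
    repeat {
      s <- paste0(letters[n %% 26L + 1L], s)
      n <- n %/% 26L - 1L
      if (n < 0) break
    }
    out[k] <- s
  }
  out
}

#' Generate a synthetic taxonomic checklist with ground truth
#'
#' Emits accepted species across a fixed synthetic family frame, plus the
#' structures name resolution has to cope with: off-name synonyms (resolved
#' via the accepted-name pointer), clusters of one accepted name and two
#' synonym records under the same name, homonym genera accepted in two
#' families of the same order (resolving to the order as the lowest common
#' rank), cross-kingdom homonym genera, and common-name entries.  The
#' expected resolution for every generated query is recorded alongside in
#' the `truth` attribute.
#'
#' @param spec A [fixture_spec()].
#' @return A [checklist()]; `attr(, "truth")` is a tibble of queries with
#'   expected modes/ranks/names.
#' @export
gen_checklist <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  p <- spec$checklist
  fams <- .FIXTURE_FAMILIES
  rows <- list(); truth <- list(); eid <- 0L
  new_id <- function() { eid <<- eid + 1L; sprintf("COL%04d", eid) }
  add_entry <- function(name, rank, status, accepted_ref, cls) {
    id <- new_id()
    r <- tibble::tibble(entry_id = id, name = name, rank = rank,
                        status = status,
                        accepted_ref = accepted_ref %||% id)
    for (rk in rank_ladder()) {
      r[[rk]] <- if (rk %in% names(cls)) cls[[rk]] else NA_character_
    }
    rows[[length(rows) + 1L]] <<- r
    id
  }
  add_truth <- function(query, mode, rank, name, constraint_rank = NA,
                        constraint_name = NA) {
    truth[[length(truth) + 1L]] <<- tibble::tibble(
      query = query, expected_mode = mode, expected_rank = rank,
      expected_name = name, constraint_rank = constraint_rank,
      constraint_name = constraint_name)
  }

  with_stream_seed(spec$seed, "checklist", {
    gi <- 0L
    for (f in seq_len(nrow(fams))) {
      frame <- as.list(fams[f, ])
      for (g in 1:2) {
        gi <- gi + 1L
        genus <- paste0("Genus", fams$family[f], letter_tag(g))
        g_cls <- c(frame, genus = genus)
        add_entry(genus, "genus", "accepted", NULL, g_cls)
        n_sp <- ceiling(p$species_per_family / 2)
        for (s in seq_len(n_sp)) {
          binom <- paste(genus, paste0("species", letter_tag(s)))
          cls <- c(g_cls, species = binom)
          acc <- add_entry(binom, "species", "accepted", NULL, cls)
          add_truth(binom, "accepted_direct", "species", binom)
          if (stats::runif(1) < p$synonym_rate) {
            syn_name <- paste(paste0("Oldgenus", letter_tag(gi)),
                              paste0("olim", letter_tag(s)))
            add_entry(syn_name, "species", "synonym", acc, cls)
            add_truth(syn_name, "accepted_via_status", "species", binom)
          }
        }
      }
    }
    all_rows <- do.call(rbind, rows)

    # one accepted plus two same-name synonym records
    sp_rows <- all_rows[all_rows$rank == "species" &
                          all_rows$status == "accepted", ]
    pick <- utils::head(sample(nrow(sp_rows)),
                        p$same_name_synonym_clusters)
    for (i in pick) {
      r <- sp_rows[i, ]
      cls <- classification_of(r)
      for (k in 1:2) {
        add_entry(r$name, "species", "synonym", r$entry_id, cls)
      }
      add_truth(r$name, "accepted_direct", "species", r$name)
    }

    # homonym genus accepted in two families of the same order
    for (h in seq_len(p$homonym_pairs)) {
      gname <- paste0("Homonymus", letter_tag(h))
      for (fam in c("Carabidae", "Erirhinidae")) {
        frame <- as.list(fams[fams$family == fam, ])
        add_entry(gname, "genus", "accepted", NULL, c(frame, genus = gname))
      }
      add_truth(gname, "lowest_common_rank", "order", "Coleoptera")
      add_truth(gname, "accepted_direct", "genus", gname,
                constraint_rank = "family", constraint_name = "Carabidae")
    }

    # cross-kingdom homonym genus
    for (h in seq_len(p$cross_kingdom)) {
      gname <- paste0("Ambiregnum", letter_tag(h))
      for (fam in c("Carabidae", "Rosaceae")) {
        frame <- as.list(fams[fams$family == fam, ])
        add_entry(gname, "genus", "accepted", NULL, c(frame, genus = gname))
      }
      add_truth(gname, "unmatched", NA_character_, NA_character_)
      add_truth(gname, "accepted_direct", "genus", gname,
                constraint_rank = "kingdom", constraint_name = "Plantae")
    }

    # common names pointing at bird species
    all_rows <- do.call(rbind, rows)
    birds <- all_rows[all_rows$status == "accepted" &
                        all_rows$rank == "species" &
                        !is.na(all_rows$class) & all_rows$class == "Aves", ]
    for (k in seq_len(min(p$common_names, nrow(birds)))) {
      r <- birds[k, ]
      cname <- paste("Fixture warbler", letter_tag(k))
      add_entry(cname, "species", "common_name", r$entry_id,
                classification_of(r))
      add_truth(cname, "accepted_via_status", "species", r$name)
    }
  })

  cl <- checklist(do.call(rbind, rows))
  attr(cl, "truth") <- do.call(rbind, truth)
  cl
}

.INJECTABLE <- c("NEGATIVE_CONVERSION_TIME", "BAD_ANGLE", "INVALID_DATE",
                 "DUPLICATE_SITE_NAME", "DUPLICATE_TAXON_NAME",
                 "COORDINATE_OUT_OF_RANGE", "COUNTRY_MISMATCH")

country_bbox <- function(regions, name) {
  for (f in regions$country$features) {
    if (f$attributes$country == name) {
      ring <- f$polygons[[1]][[1]]
      return(c(min(ring[, 1]), min(ring[, 2]), max(ring[, 1]),
               max(ring[, 2])))
    }
  }
  stop_with("ecocollate_argument_error", "unknown fixture country %s", name)
}

#' Generate synthetic study bundles with an injected-error ledger
#'
#' Builds clean, internally consistent study bundles (sites inside the
#' declared fixture country, valid dates and classifications, abundance
#' matrices), then injects the requested number of data-quality errors of
#' each kind — negative times since conversion, impossible angle literals,
#' a 32nd of January, duplicated site and taxon names, out-of-range
#' coordinates, and sites relocated to the wrong country — recording an
#' exact ledger of what was injected where.  With no injections the
#' validator returns an empty issue list on the output.
#'
#' @param spec A [fixture_spec()].
#' @param cl Optional [gen_checklist()] output supplying taxon names.
#' @param regions Optional [gen_regions()] output; generated from `spec`
#'   when absent.
#' @return List with `bundles` (list of [survey_bundle()]), `ledger`
#'   (tibble `code`, `record_ref`) and `regions`.
#' @export
gen_survey <- function(spec, cl = NULL, regions = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(regions)) regions <- gen_regions(spec)
  if (is.null(cl)) cl <- gen_checklist(spec)
  countries <- vapply(regions$country$features,
                      function(f) f$attributes$country, character(1))
  # each study samples one class, as real surveys do
  sp_pool <- cl[cl$rank == "species" & cl$status == "accepted", ]
  classes <- unique(sp_pool$class)

  bundles <- list(); ledger <- list()
  with_stream_seed(spec$seed, "survey", {
    for (b in seq_len(spec$n_sources)) {
      src_id <- sprintf("SRC%02d", b)
      country <- countries[(b - 1L) %% length(countries) + 1L]
      bb <- country_bbox(regions, country)
      inset <- 0.15 * c(bb[3] - bb[1], bb[4] - bb[2])
      source <- tibble::tibble(
        source_id = src_id,
        bibliographic_citation = sprintf("Fixture et al. (20%02d)", b),
        declared_countries = country,
        provenance_kind = "journal article")
      studies <- sites <- taxa <- list()
      mats <- list()
      for (st in seq_len(spec$studies_per_source)) {
        study_id <- sprintf("%s_S%d", src_id, st)
        studies[[st]] <- tibble::tibble(
          study_id = study_id, source_id = src_id,
          sampling_method = "pitfall traps",
          effort_unit = "trap nights", metric_type = "abundance")
        n_si <- spec$sites_per_study
        lu_pool <- c("Primary vegetation", "Secondary vegetation (young)",
                     "Secondary vegetation (mature)", "Cropland", "Pasture",
                     "Plantation forest", "Urban")
        site_tbl <- tibble::tibble(
          site_id = sprintf("%s_P%d", study_id, seq_len(n_si)),
          study_id = study_id,
          site_name = sprintf("Plot %d", seq_len(n_si)),
          latitude = sprintf("%.5f", stats::runif(
            n_si, bb[2] + inset[2], bb[4] - inset[2])),
          longitude = sprintf("%.5f", stats::runif(
            n_si, bb[1] + inset[1], bb[3] - inset[1])),
          habitat_description = "fixture habitat",
          land_use = sample(lu_pool, n_si, replace = TRUE),
          use_intensity = sample(c("Minimal use", "Light use",
                                   "Intense use"), n_si, replace = TRUE),
          fragmentation_layout = sample(fragmentation_layouts(), n_si,
                                        replace = TRUE),
          patch_area = as.character(
            sample(c("-1", "", "40000"), n_si, replace = TRUE)),
          max_linear_extent = sprintf("%.1f", stats::runif(n_si, 10, 500)),
          start_date = "2007-06-01", end_date = "2007-08-31",
          date_resolution = "month",
          effort = sprintf("%d", sample(10:40, n_si, replace = TRUE)),
          time_since_conversion = sample(
            c("", "7", "10-20 years", "at least 20 years"), n_si,
            replace = TRUE),
          block = "")
        n_tx <- spec$taxa_per_study
        klass <- classes[((b - 1L) * spec$studies_per_source + st - 1L) %%
                           length(classes) + 1L]
        class_names <- sp_pool$name[sp_pool$class == klass]
        n_named <- min(length(class_names), ceiling(n_tx * 0.75))
        named <- sample(class_names, n_named)
        morpho_genus <- sub(" .*", "", named[1])
        morpho <- sprintf("%s sp. %d", morpho_genus,
                          seq_len(n_tx - n_named))
        taxon_tbl <- tibble::tibble(
          taxon_id = sprintf("%s_T%d", study_id, seq_len(n_tx)),
          study_id = study_id,
          name_entered = c(named, morpho))
        m <- matrix(stats::rpois(n_si * n_tx, 2) + 1L, n_si, n_tx)
        mat <- data.frame(site_id = site_tbl$site_id, m,
                          check.names = FALSE)
        names(mat)[-1] <- taxon_tbl$taxon_id
        sites[[st]] <- site_tbl
        taxa[[st]] <- taxon_tbl
        mats[[st]] <- mat
      }
      sites <- do.call(rbind, sites)
      taxa <- do.call(rbind, taxa)
      mat <- Reduce(function(a, b) merge(a, b, by = "site_id",
                                         all = TRUE, sort = FALSE),
                    mats)
      bundles[[b]] <- survey_bundle(source, do.call(rbind, studies),
                                    sites, taxa, mat)
    }

    # error injection on distinct target sites
    counts <- spec$errors
    bad <- setdiff(names(counts), .INJECTABLE)
    if (length(bad)) {
      stop_with("ecocollate_argument_error",
                "cannot inject issue code '%s'", bad[1])
    }
    total <- sum(unlist(counts))
    if (total > 0) {
      all_sites <- do.call(rbind, lapply(bundles, function(x) {
        x$sites[, c("site_id", "study_id")]
      }))
      if (total > nrow(all_sites)) {
        stop_with("ecocollate_argument_error",
                  "more injections (%d) than sites (%d)", total,
                  nrow(all_sites))
      }
      targets <- all_sites[sample(nrow(all_sites), total), ]
      t_i <- 0L
      bundle_of_study <- function(study) {
        for (bi in seq_along(bundles)) {
          if (study %in% bundles[[bi]]$studies$study_id) return(bi)
        }
      }
      for (code in names(counts)) {
        for (rep_i in seq_len(counts[[code]])) {
          t_i <- t_i + 1L
          tgt <- targets[t_i, ]
          bi <- bundle_of_study(tgt$study_id)
          s <- bundles[[bi]]$sites
          row <- which(s$site_id == tgt$site_id)
          ref <- sprintf("site:%s/%s", tgt$study_id, tgt$site_id)
          if (code == "NEGATIVE_CONVERSION_TIME") {
            s$time_since_conversion[row] <- "-3"
          } else if (code == "BAD_ANGLE") {
            s$latitude[row] <- "1° 61'"
          } else if (code == "INVALID_DATE") {
            s$start_date[row] <- "2007-01-32"
          } else if (code == "COORDINATE_OUT_OF_RANGE") {
            s$latitude[row] <- "95.0"
          } else if (code == "COUNTRY_MISMATCH") {
            declared <- bundles[[bi]]$source$declared_countries
            other <- setdiff(countries, declared)[1]
            ob <- country_bbox(regions, other)
            s$latitude[row] <- sprintf("%.5f", (ob[2] + ob[4]) / 2)
            s$longitude[row] <- sprintf("%.5f", (ob[1] + ob[3]) / 2)
          } else if (code == "DUPLICATE_SITE_NAME") {
            in_study <- which(s$study_id == tgt$study_id)
            donor <- setdiff(in_study, row)[1]
            s$site_name[row] <- s$site_name[donor]
            first <- min(row, donor)
            ref <- sprintf("site:%s/%s", tgt$study_id, s$site_id[first])
          } else if (code == "DUPLICATE_TAXON_NAME") {
            tx <- bundles[[bi]]$taxa
            in_study <- which(tx$study_id == tgt$study_id)
            pair <- in_study[1:2]
            tx$name_entered[pair[2]] <- tx$name_entered[pair[1]]
            bundles[[bi]]$taxa <- tx
            ref <- sprintf("taxon:%s/%s", tgt$study_id,
                           tx$taxon_id[pair[1]])
          }
          bundles[[bi]]$sites <- s
          ledger[[length(ledger) + 1L]] <- tibble::tibble(
            code = code, record_ref = ref)
        }
      }
    }
  })
  list(bundles = bundles,
       ledger = if (length(ledger)) do.call(rbind, ledger) else
         tibble::tibble(code = character(), record_ref = character()),
       regions = regions)
}

#' Generate rectangular fixture region layers and an NPP raster
#'
#' A synthetic world on a lon/lat rectangle: a grid of ecoregions grouped
#' into biomes (by row) and realms (west/east half), a separate grid of
#' countries with UN regions/subregions, a hotspot layer covering a stated
#' number of ecoregion cells, and twelve monthly NPP grids following a
#' cosine-of-latitude profile with a mild seasonal cycle.  All areas are
#' computable in closed form (see [cell_area()]).
#'
#' @param spec A [fixture_spec()].
#' @return List with `ecoregion`, `country`, `hotspot` [region_layer()]s,
#'   an [npp_raster()] `raster` and the `bbox`.
#' @export
gen_regions <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  p <- spec$regions
  bb <- p$bbox
  grid_feats <- function(nx, ny, attr_fun) {
    w <- (bb[3] - bb[1]) / nx
    h <- (bb[4] - bb[2]) / ny
    feats <- list()
    k <- 0L
    for (r in seq_len(ny)) {
      for (c in seq_len(nx)) {
        k <- k + 1L
        x0 <- bb[1] + (c - 1) * w
        y0 <- bb[2] + (r - 1) * h
        feats[[k]] <- rect_feature(x0, y0, x0 + w, y0 + h,
                                   attr_fun(k, r, c, x0 + w / 2))
      }
    }
    feats
  }
  eco <- region_layer("ecoregion", grid_feats(
    p$eco_nx, p$eco_ny,
    function(k, r, c, xc) list(
      ecoregion = sprintf("Ecoregion %d", k),
      biome = sprintf("Biome %d", r),
      realm = if (xc < (bb[1] + bb[3]) / 2) "Realm West" else "Realm East")))
  ctry <- region_layer("country", grid_feats(
    p$country_nx, p$country_ny,
    function(k, r, c, xc) list(
      country = sprintf("Country %d", k),
      un_region = sprintf("Region %d", r),
      un_subregion = sprintf("Subregion %d", k))))
  hot_feats <- lapply(seq_len(min(p$hotspot_cells,
                                  length(eco$features))), function(k) {
    f <- eco$features[[k]]
    f$attributes <- list(hotspot = sprintf("Hotspot %d", k))
    f
  })
  hot <- region_layer("hotspot", hot_feats)

  res <- p$npp_resolution
  nc <- as.integer(round((bb[3] - bb[1]) / res))
  nr <- as.integer(round((bb[4] - bb[2]) / res))
  lat_ctr <- bb[2] + (nr - seq_len(nr) + 0.5) * res
  vals <- array(0, c(nr, nc, 12))
  for (m in 1:12) {
    prof <- pmax(cos(lat_ctr * pi / 180), 0) *
      (1 + 0.2 * sin(2 * pi * (m - 1) / 12))
    vals[, , m] <- matrix(prof, nr, nc)
  }
  raster <- npp_raster(vals, xll = bb[1], yll = bb[2], cellsize = res)
  list(ecoregion = eco, country = ctry, hotspot = hot, raster = raster,
       bbox = bb)
}

#' Generate paired ratings from a known joint distribution
#'
#' Samples rating pairs from a category-by-category joint probability table
#' and returns the analytic observed agreement, expected agreement and
#' kappa alongside, for recovery tests: with an identity table kappa is 1,
#' with independent margins it is 0.
#'
#' @param spec A [fixture_spec()] (supplies the seed).
#' @param confusion Square probability matrix with category dimnames,
#'   entries summing to 1.
#' @param n Number of items to sample.
#' @return A [paired_ratings()]; `attr(, "analytic")` holds `p_o`, `p_e`,
#'   `kappa`.
#' @export
gen_ratings <- function(spec, confusion, n) {
  stopifnot(inherits(spec, "fixture_spec"), is.matrix(confusion))
  if (abs(sum(confusion) - 1) > 1e-8 || any(confusion < 0)) {
    stop_with("ecocollate_argument_error",
              "confusion entries must be non-negative and sum to 1")
  }
  u <- rownames(confusion)
  if (is.null(u) || !identical(u, colnames(confusion))) {
    stop_with("ecocollate_argument_error",
              "confusion needs matching row/column category names")
  }
  k <- length(u)
  idx <- with_stream_seed(spec$seed, "ratings", {
    sample.int(k * k, n, replace = TRUE, prob = as.vector(confusion))
  })
  r1 <- u[(idx - 1L) %% k + 1L]
  r2 <- u[(idx - 1L) %/% k + 1L]
  out <- paired_ratings(r1, r2, universe = u)
  m1 <- rowSums(confusion); m2 <- colSums(confusion)
  p_o <- sum(diag(confusion))
  p_e <- sum(m1 * m2)
  attr(out, "analytic") <- list(
    p_o = p_o, p_e = p_e,
    kappa = if (p_e < 1) (p_o - p_e) / (1 - p_e) else 1)
  out
}
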