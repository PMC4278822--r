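# Shared in-code fixtures: a small hand-built checklist exercising every
# resolution structure, and a minimal bundle builder.

cls_row <- function(entry_id, name, rank, status, accepted_ref = NA, ...) {
  cls <- list(...)
  r <- data.frame(entry_id = entry_id, name = name, rank = rank,
                  status = status, accepted_ref = accepted_ref,
                  stringsAsFactors = FALSE)
  for (rk in rank_ladder()) {
    r[[rk]] <- if (rk %in% names(cls)) cls[[rk]] else NA_character_
  }
  r
}

tiny_checklist <- function() {
  spider <- list(kingdom = "Animalia", phylum = "Arthropoda",
                 class = "Arachnida", order = "Araneae",
                 family = "Salticidae", genus = "Euophrys",
                 species = "Euophrys frontalis")
  carab <- list(kingdom = "Animalia", phylum = "Arthropoda",
                class = "Insecta", order = "Coleoptera",
                family = "Carabidae", genus = "Notiophilus")
  weevil <- modifyList(carab, list(family = "Erirhinidae"))
  bee <- list(kingdom = "Animalia", phylum = "Arthropoda",
              class = "Insecta", order = "Hymenoptera",
              family = "Colletidae", genus = "Diphaglossa",
              species = "Diphaglossa gayi")
  bird <- list(kingdom = "Animalia", phylum = "Chordata", class = "Aves",
               order = "Accipitriformes", family = "Accipitridae",
               genus = "Accipiter", species = "Accipiter badius")
  bumble <- list(kingdom = "Animalia", phylum = "Arthropoda",
                 class = "Insecta", order = "Hymenoptera",
                 family = "Apidae", genus = "Bombus",
                 species = "Bombus pascuorum")
  plant_g <- list(kingdom = "Plantae", phylum = "Tracheophyta",
                  class = "Magnoliopsida", order = "Lamiales",
                  family = "Orobanchaceae", genus = "Bellardia")
  moth_g <- list(kingdom = "Animalia", phylum = "Arthropoda",
                 class = "Insecta", order = "Lepidoptera",
                 family = "Noctuidae", genus = "Bellardia")
  bat_g <- list(kingdom = "Animalia", phylum = "Chordata",
                class = "Mammalia", order = "Chiroptera",
                family = "Pteropodidae", genus = "Eonycteris")
  bug_g <- list(kingdom = "Animalia", phylum = "Arthropoda",
                class = "Insecta", order = "Hemiptera",
                family = "Pentatomidae", genus = "Tepa")
  rows <- rbind(
    do.call(cls_row, c(list("EF1", "Euophrys frontalis", "species",
                            "accepted"), spider)),
    do.call(cls_row, c(list("EF2", "Euophrys frontalis", "species",
                            "synonym", "EF1"), spider)),
    do.call(cls_row, c(list("EF3", "Euophrys frontalis", "species",
                            "synonym", "EF1"), spider)),
    do.call(cls_row, c(list("NO1", "Notiophilus", "genus", "accepted"),
                       carab)),
    do.call(cls_row, c(list("NO2", "Notiophilus", "genus", "accepted"),
                       modifyList(weevil, list(genus = "Notiophilus")))),
    do.call(cls_row, c(list("DG1", "Diphaglossa gayi", "species",
                            "accepted"), bee)),
    do.call(cls_row, c(list("AB1", "Accipiter badius", "species",
                            "accepted"), bird)),
    do.call(cls_row, c(list("AB2", "Shikra", "species", "common_name",
                            "AB1"), bird)),
    do.call(cls_row, c(list("BP1", "Bombus pascuorum", "species",
                            "accepted"), bumble)),
    do.call(cls_row, c(list("BL1", "Bellardia", "genus", "accepted"),
                       plant_g)),
    do.call(cls_row, c(list("BL2", "Bellardia", "genus", "accepted"),
                       moth_g)),
    do.call(cls_row, c(list("EO1", "Eonycteris", "genus", "accepted"),
                       bat_g)),
    do.call(cls_row, c(list("TP1", "Tepa", "genus", "accepted"), bug_g)))
  checklist(rows)
}

# Minimal bundle: one source, studies given as a named list
# study_id -> character vector of taxon names; each study gets
# `n_sites` sites with valid fields inside [0, 10] x [0, 10].
mini_bundle <- function(studies, source_id = "SRC1", n_sites = 2,
                        declared = "Testland", metric = "abundance",
                        lat = NULL, lon = NULL) {
  source <- data.frame(source_id = source_id,
                       bibliographic_citation = "Doe (2010)",
                       declared_countries = declared,
                       provenance_kind = "journal article")
  st <- data.frame(study_id = names(studies), source_id = source_id,
                   sampling_method = "transects", effort_unit = "m",
                   metric_type = metric)
  sites <- do.call(rbind, lapply(names(studies), function(sid) {
    data.frame(site_id = sprintf("%s_P%d", sid, seq_len(n_sites)),
               study_id = sid,
               site_name = sprintf("P%d", seq_len(n_sites)),
               latitude = if (is.null(lat))
                 sprintf("%.4f", seq(2, 8, length.out = n_sites)) else lat,
               longitude = if (is.null(lon))
                 sprintf("%.4f", seq(2, 8, length.out = n_sites)) else lon,
               habitat_description = "meadow",
               land_use = "Cropland", use_intensity = "Light use",
               fragmentation_layout = "Within a remnant patch",
               patch_area = "40000", max_linear_extent = "120",
               start_date = "2007-06-01", end_date = "2007-08-31",
               date_resolution = "month", effort = "100",
               time_since_conversion = "7", block = "")
  }))
  taxa <- do.call(rbind, lapply(names(studies), function(sid) {
    data.frame(taxon_id = sprintf("%s_T%d", sid,
                                  seq_along(studies[[sid]])),
               study_id = sid, name_entered = studies[[sid]])
  }))
  mx <- data.frame(site_id = sites$site_id)
  for (tid in taxa$taxon_id) mx[[tid]] <- 1
  # zero out cells for taxa not in the site's study
  for (i in seq_len(nrow(mx))) {
    sid <- sites$study_id[sites$site_id == mx$site_id[i]]
    other <- taxa$taxon_id[taxa$study_id != sid]
    for (tid in other) mx[[tid]][i] <- NA
  }
  survey_bundle(source, st, sites, taxa, mx)
}

# Single-country fixture world on [0,10] x [0,10] for annotation tests.
square_layers <- function() {
  eco <- region_layer("ecoregion", list(
    rect_feature(0, 0, 10, 5, list(ecoregion = "Eco South",
                                   biome = "Biome A",
                                   realm = "Realm X")),
    rect_feature(0, 5, 10, 10, list(ecoregion = "Eco North",
                                    biome = "Biome B",
                                    realm = "Realm X"))))
  ctry <- region_layer("country", list(
    rect_feature(0, 0, 10, 10, list(country = "Testland",
                                    un_region = "Region T",
                                    un_subregion = "Subregion T"))))
  hot <- region_layer("hotspot", list(
    rect_feature(0, 0, 5, 5, list(hotspot = "Hotspot SW"))))
  list(ecoregion = eco, country = ctry, hotspot = hot)
}

expect_issue_codes <- function(issues, codes) {
  expect_setequal(issues$code, codes)
}
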