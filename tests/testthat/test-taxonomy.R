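test_that("the parser extracts putative binomials the documented way", {
  expect_equal(parse_taxon_name("Ancistrocerus trifasciatus Müll."),
               "Ancistrocerus trifasciatus")
  expect_equal(parse_taxon_name("Black and White Casqued Hornbill"),
               "Black and")
  expect_equal(parse_taxon_name("Bracon sp. 1"), "Bracon")
  expect_equal(parse_taxon_name("Bracon spp."), "Bracon")
  expect_equal(parse_taxon_name("Euophrys cf. frontalis"), "Euophrys")
  expect_equal(parse_taxon_name("Carabidae"), "Carabidae")
  expect_equal(parse_taxon_name("Apis mellifera (Linnaeus, 1758)"),
               "Apis mellifera")
  expect_error(parse_taxon_name("  "), class = "ecocollate_format_error")
})

test_that("resolution picks the single accepted name among synonyms", {
  cl <- tiny_checklist()
  res <- resolve_name(cl, "Euophrys frontalis")
  expect_equal(res$mode, "accepted_direct")
  expect_equal(res$matched_entry, "EF1")
  expect_equal(res$rank, "species")
  expect_equal(res$classification[["family"]], "Salticidae")

  # via-status: a common name resolves to its accepted species
  res <- resolve_name(cl, "Shikra")
  expect_equal(res$mode, "accepted_via_status")
  expect_equal(res$name, "Accipiter badius")
})

test_that("homonym genera fall back to the lowest common rank", {
  cl <- tiny_checklist()
  res <- resolve_name(cl, "Notiophilus")
  expect_equal(res$mode, "lowest_common_rank")
  expect_equal(res$rank, "order")
  expect_equal(res$name, "Coleoptera")

  # clade constraint disambiguates
  res <- resolve_name(cl, "Notiophilus",
                      clade_constraint("family", "Carabidae"))
  expect_equal(res$mode, "accepted_direct")
  expect_equal(res$matched_entry, "NO1")

  # cross-kingdom homonym: no common rank at all -> unmatched
  res <- resolve_name(cl, "Bellardia")
  expect_equal(res$mode, "unmatched")
  res <- resolve_name(cl, "Bellardia",
                      clade_constraint("kingdom", "Plantae"))
  expect_equal(res$matched_entry, "BL1")
})

test_that("resolution with a single-entry checklist is the identity", {
  one <- checklist(cls_row("X1", "Solus unicus", "species", "accepted",
                           kingdom = "Animalia", genus = "Solus",
                           species = "Solus unicus"))
  res <- resolve_name(one, "Solus unicus")
  expect_equal(res$matched_entry, "X1")
  expect_equal(res$name, "Solus unicus")
  expect_equal(resolve_name(one, "Alius alter")$mode, "unmatched")
})

test_that("name matching is case-insensitive and diacritic-folded", {
  cl <- tiny_checklist()
  expect_equal(resolve_name(cl, "EUOPHRYS FRONTALIS")$matched_entry, "EF1")
  expect_equal(resolve_name(cl, "euophrys frontális")$matched_entry, "EF1")
})

test_that("lowest common classification agrees with a brute-force scan", {
  ladder <- rank_ladder()
  brute <- function(maps) {
    # independent oracle: compare full lineage path strings down to each
    # rank; the answer is the deepest rank whose paths coincide with no
    # missing value at that rank
    path <- function(m, k) {
      paste(sapply(ladder[1:k], function(r) {
        if (r %in% names(m)) m[[r]] else "~absent~"
      }), collapse = "/")
    }
    best <- NULL
    for (k in seq_along(ladder)) {
      vals <- sapply(maps, function(m) {
        if (ladder[k] %in% names(m)) m[[ladder[k]]] else NA_character_
      })
      paths <- sapply(maps, path, k = k)
      if (length(unique(paths)) == 1 && !anyNA(vals)) {
        best <- list(rank = ladder[k], name = vals[[1]])
      }
    }
    best
  }
  set.seed(12)
  pool <- replicate(6, NULL)
  random_map <- function() {
    depth <- sample(1:8, 1)
    v <- paste0("T", sample(1:3, depth, replace = TRUE), seq_len(depth))
    setNames(v, ladder[seq_len(depth)])
  }
  for (i in 1:1000) {
    maps <- list(random_map(), random_map())
    expect_identical(lowest_common_classification(maps), brute(maps))
  }
  expect_error(lowest_common_classification(list()),
               class = "ecocollate_argument_error")
})

test_that("constrained resolution always stays within the clade", {
  spec <- fixture_spec(seed = 31)
  cl <- gen_checklist(spec)
  truth <- attr(cl, "truth")
  con <- truth[!is.na(truth$constraint_rank), ]
  for (i in seq_len(nrow(con))) {
    res <- resolve_name(cl, con$query[i],
                        clade_constraint(con$constraint_rank[i],
                                         con$constraint_name[i]))
    expect_false(res$mode == "unmatched")
    expect_equal(res$classification[[con$constraint_rank[i]]],
                 con$constraint_name[i])
  }
})

test_that("generated checklist queries resolve to their recorded truth", {
  spec <- fixture_spec(seed = 31)
  cl <- gen_checklist(spec)
  truth <- attr(cl, "truth")
  free <- truth[is.na(truth$constraint_rank), ]
  for (i in seq_len(nrow(free))) {
    res <- resolve_name(cl, free$query[i])
    expect_equal(res$mode, free$expected_mode[i], label = free$query[i])
    if (res$mode != "unmatched") {
      expect_equal(res$name, free$expected_name[i])
      expect_equal(res$rank, free$expected_rank[i])
    }
  }
})

test_that("curation replaces the query, logs the reason and re-resolves", {
  cl <- tiny_checklist()
  b <- mini_bundle(list(S1 = c("Diphaglosa gayi", "Bombus pascuorum")))
  db <- assemble_database(b)
  db <- resolve_taxonomy(db, cl)
  tid <- db$taxa$taxon_id[db$taxa$name_entered == "Diphaglosa gayi"]
  expect_equal(db$taxa$resolution_mode[db$taxa$taxon_id == tid],
               "unmatched")

  db <- apply_curation(db, tid, "Diphaglossa gayi",
                       "typographical error in source", cl)
  row <- db$taxa[db$taxa$taxon_id == tid, ]
  expect_equal(row$resolved_name, "Diphaglossa gayi")
  expect_equal(row$name_entered, "Diphaglosa gayi")   # never changed
  expect_equal(row$parsed_name, "Diphaglosa gayi")
  expect_equal(sum(db$curation_log$taxon_id == tid), 1)

  db <- apply_curation(db, tid, "Diphaglossa", "retreat to genus", cl)
  expect_equal(sum(db$curation_log$taxon_id == tid), 2)
  expect_error(apply_curation(db, tid, "X y", "", cl),
               class = "ecocollate_argument_error")
})

test_that("the review queue flags the four curation criteria", {
  cl <- tiny_checklist()
  b <- mini_bundle(list(
    S1 = c("Diphaglosa gayi",              # unmatched (typo)
           "Euophrys frontalis"),
    S2 = c("Eonycteris major Andersen",    # binomial missing from checklist
           "Bombus pascuorum"),
    S3 = c("Tepa",                         # hemipteran genus in a bird study
           "Accipiter badius")))
  db <- assemble_database(b)
  db <- resolve_taxonomy(db, cl)
  # the missing binomial is curated back to its genus, as a curator would
  tid <- db$taxa$taxon_id[db$taxa$name_entered == "Eonycteris major Andersen"]
  db <- apply_curation(db, tid, "Eonycteris",
                       "species absent from checklist; retreat to genus", cl)
  q <- build_review_queue(
    db, expected_clades = list(S3 = clade_constraint("class", "Aves")))
  expect_true("UNMATCHED" %in% q$criterion)
  expect_true(any(q$criterion == "COARSE_RESOLUTION" & q$taxon_id == tid))
  expect_true(any(q$criterion == "IMPLAUSIBLE_CLADE" & q$study_id == "S3"))

  # morphospecies resolving to their genus are expected, not queued
  b3 <- mini_bundle(list(S1 = c("Eonycteris sp. 1", "Bombus pascuorum")))
  db3 <- resolve_taxonomy(assemble_database(b3), cl)
  expect_equal(nrow(build_review_queue(db3)), 0)

  # clean database -> empty queue
  b2 <- mini_bundle(list(S1 = c("Euophrys frontalis", "Bombus pascuorum")))
  db2 <- resolve_taxonomy(assemble_database(b2), cl)
  expect_equal(nrow(build_review_queue(db2)), 0)
})

test_that("the same parsed name resolving differently across studies is flagged", {
  cl <- tiny_checklist()
  b <- mini_bundle(list(S1 = c("Notiophilus", "Bombus pascuorum"),
                        S2 = c("Notiophilus", "Euophrys frontalis")))
  db <- assemble_database(b)
  db <- resolve_taxonomy(
    db, cl, constraints = list(S1 = clade_constraint("family", "Carabidae"),
                               S2 = clade_constraint("family",
                                                     "Erirhinidae")))
  q <- build_review_queue(db)
  expect_true(any(q$criterion == "INCONSISTENT"))
})

test_that("bird codes expand by the genus/species prefix rule", {
  pool <- data.frame(
    name = c("Accipiter badius", "Ketupa zeylonensis",
             "Acanthiza bandita", "Pernis ptilorhynchus"),
    kingdom = "Animalia", phylum = "Chordata", class = "Aves",
    order = c("Accipitriformes", "Strigiformes", "Passeriformes",
              "Accipitriformes"),
    family = c("Accipitridae", "Strigidae", "Acanthizidae",
               "Accipitridae"),
    genus = c("Accipiter", "Ketupa", "Acanthiza", "Pernis"))
  res <- expand_bird_code("KEZE", pool)
  expect_equal(res$name, "Ketupa zeylonensis")
  expect_equal(res$rank, "species")

  # ACBA collides with Acanthiza bandita: lowest common rank is the class
  res <- expand_bird_code("ACBA", pool)
  expect_equal(res$mode, "lowest_common_rank")
  expect_equal(lowest_common_classification(list(
    c(kingdom = "Animalia", phylum = "Chordata", class = "Aves",
      order = "Accipitriformes"),
    c(kingdom = "Animalia", phylum = "Chordata", class = "Aves",
      order = "Passeriformes")))$name, res$name)

  expect_equal(expand_bird_code("XXXX", pool)$mode, "unmatched")
  expect_error(expand_bird_code("AB1", pool),
               class = "ecocollate_format_error")
})

test_that("single-candidate bird codes re-derive their own code", {
  pool <- data.frame(
    name = c("Falco sparverius", "Terpsiphone paradisi",
             "Ketupa zeylonensis", "Accipiter badius",
             "Pycnonotus cafer", "Halcyon smyrnensis"),
    kingdom = "Animalia", phylum = "Chordata", class = "Aves",
    genus = c("Falco", "Terpsiphone", "Ketupa", "Accipiter",
              "Pycnonotus", "Halcyon"))
  for (nm in pool$name) {
    w <- strsplit(nm, " ")[[1]]
    code <- toupper(paste0(substr(w[1], 1, 2), substr(w[2], 1, 2)))
    res <- expand_bird_code(code, pool)
    expect_equal(res$rank, "species")
    w2 <- strsplit(res$name, " ")[[1]]
    expect_equal(toupper(paste0(substr(w2[1], 1, 2),
                                substr(w2[2], 1, 2))), code)
  }
  # the fixture checklist's synthetic binomials share prefixes, so every
  # derived code collides and resolution retreats up the ladder
  cl <- gen_checklist(fixture_spec(seed = 8))
  fx <- as.data.frame(cl[cl$rank == "species" & cl$status == "accepted" &
                           !is.na(cl$class) & cl$class == "Aves", ])
  res <- expand_bird_code("GESP", fx)
  expect_equal(res$mode, "lowest_common_rank")
})

test_that("best-guess binomials follow the printed cascade", {
  expect_equal(best_guess_binomial("species", "Bombus pascuorum",
                                   "Bombus pascuorum"),
               "Bombus pascuorum")
  expect_equal(best_guess_binomial("infraspecies",
                                   "Genus species subsp",
                                   "Genus species"),
               "Genus species")
  expect_equal(best_guess_binomial("genus", "Bracon", "Bracon"), "")
  # above species but the parsed name is a binomial: first two words
  expect_equal(best_guess_binomial("genus", "Bracon", "Bracon celer"),
               "Bracon celer")
  expect_equal(best_guess_binomial(NA, NA, "Unknownus dubius"),
               "Unknownus dubius")
})

test_that("higher groups follow the three ordered rules", {
  bee <- c(kingdom = "Animalia", phylum = "Arthropoda", class = "Insecta",
           order = "Hymenoptera")
  wolf <- c(kingdom = "Animalia", phylum = "Chordata", class = "Mammalia",
            order = "Carnivora")
  snail <- c(kingdom = "Animalia", phylum = "Gastropoda")
  springtail <- c(kingdom = "Animalia", phylum = "Arthropoda",
                  class = "Entognatha", order = "Collembola")
  spider <- c(kingdom = "Animalia", phylum = "Arthropoda",
              class = "Arachnida")
  expect_equal(higher_group(bee), "Hymenoptera")
  expect_equal(higher_group(wolf), "Mammalia")
  expect_equal(higher_group(snail), "Gastropoda")
  expect_equal(higher_group(springtail), "Collembola")
  expect_equal(higher_group(spider), "Arachnida")
  expect_equal(higher_group(c(kingdom = "Animalia")), "unplaced")
  expect_equal(higher_group(c(kingdom = "Animalia", phylum = "Chordata")),
               "unplaced")
})

test_that("species counting dedups species globally but morphospecies per study", {
  cl <- tiny_checklist()
  b <- mini_bundle(list(
    A = c("Eonycteris sp. 1", "Eonycteris sp. 2", "Eonycteris sp. 3"),
    B = c("Eonycteris sp. 1", "Eonycteris sp. 2", "Eonycteris sp. 3")))
  db <- resolve_taxonomy(assemble_database(b), cl)
  expect_equal(count_species(db)$total, 6)

  b2 <- mini_bundle(list(A = c("Bombus pascuorum", "X x"),
                         B = c("Bombus pascuorum", "Y y")))
  db2 <- resolve_taxonomy(assemble_database(b2), cl)
  # 1 shared species + 2 unmatched names counted per study
  expect_equal(count_species(db2)$total, 3)
  counts <- count_species(db2)
  expect_true("unplaced" %in% counts$by_group$higher_group)
})

test_that("species counts are invariant to study order and additive when disjoint", {
  cl <- gen_checklist(fixture_spec(seed = 4))
  mk <- function(studies) {
    resolve_taxonomy(assemble_database(mini_bundle(studies)), cl)
  }
  sp <- cl$name[cl$rank == "species" & cl$status == "accepted"]
  s1 <- sp[1:4]; s2 <- sp[3:6]; s3 <- sp[7:10]
  t_ab <- count_species(mk(list(A = s1, B = s2)))$total
  t_ba <- count_species(mk(list(B = s2, A = s1)))$total
  expect_equal(t_ab, t_ba)
  expect_equal(t_ab, length(union(s1, s2)))
  # disjoint species sets: totals add exactly
  t_a <- count_species(mk(list(A = s1)))$total
  t_c <- count_species(mk(list(C = s3)))$total
  t_ac <- count_species(mk(list(A = s1, C = s3)))$total
  expect_equal(t_ac, t_a + t_c)
})

test_that("group roll-ups follow the four printed rules", {
  out <- aggregate_group_counts(c(Magnoliopsida = 3, Liliopsida = 2))
  expect_equal(out$n_species[out$group == "Magnoliophyta"], 5)
  out <- aggregate_group_counts(c(Pinopsida = 1, Gnetopsida = 0))
  expect_equal(out$n_species[out$group == "Gymnosperms"], 1)
  out <- aggregate_group_counts(c(Polypodiopsida = 2, Equisetopsida = 1,
                                  Malacostraca = 4, Aves = 7))
  expect_equal(out$n_species[out$group == "Ferns and allies"], 3)
  expect_equal(out$n_species[out$group == "Crustacea"], 4)
  expect_equal(out$n_species[out$group == "Aves"], 7)
})

test_that("attribute-database matching counts species first, genus second", {
  expect_equal(match_attribute_names(c("A b", "C d"), c("A b")),
               list(species_matches = 1L, genus_matches = 0L, total = 1L))
  expect_equal(match_attribute_names("A b", "A x", match_genus = TRUE),
               list(species_matches = 0L, genus_matches = 1L, total = 1L))
  expect_equal(match_attribute_names(c("A b"), c("Z z")),
               list(species_matches = 0L, genus_matches = 0L, total = 0L))
  # species matches are never double-counted at genus level
  expect_equal(match_attribute_names(c("A b", "A c"), c("A b"),
                                     match_genus = TRUE)$total, 2L)
})
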