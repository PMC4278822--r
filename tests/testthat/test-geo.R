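test_that("nearest matching returns zero inside and haversine distance outside", {
  layer <- region_layer("test", list(
    rect_feature(0, 0, 1, 1, list(ecoregion = "A")),
    rect_feature(2, 0, 3, 1, list(ecoregion = "B"))))
  m <- match_nearest(layer, c(0.5, 0.5))
  expect_equal(m$attributes$ecoregion, "A")
  expect_equal(m$distance, 0)

  # 0.01 degrees due east of A's edge at the equator: ~1112 m
  m <- match_nearest(layer, c(1.01, 0))
  expect_equal(m$attributes$ecoregion, "A")
  expect_equal(m$distance, 1111.95, tolerance = 0.005)

  # boundary point counts as inside
  m <- match_nearest(layer, c(1, 0.5))
  expect_equal(m$distance, 0)

  # equidistant between A and B: tie broken by feature order
  m <- match_nearest(layer, c(1.5, 0.5))
  expect_equal(m$attributes$ecoregion, "A")

  expect_error(match_nearest(region_layer("empty", list()), c(0, 0)),
               class = "ecocollate_config_error")
})

test_that("nearest distance agrees with brute force over densified vertices", {
  set.seed(6)
  layer <- region_layer("test", list(
    rect_feature(10, 40, 12, 42, list(ecoregion = "A"))))
  ring <- layer$features[[1]]$polygons[[1]][[1]]
  dense <- do.call(rbind, lapply(seq_len(nrow(ring) - 1), function(i) {
    t <- seq(0, 1, length.out = 4000)
    cbind(ring[i, 1] + t * (ring[i + 1, 1] - ring[i, 1]),
          ring[i, 2] + t * (ring[i + 1, 2] - ring[i, 2]))
  }))
  for (rep in 1:10) {
    p <- c(runif(1, 8, 14), runif(1, 38, 44))
    if (p[1] >= 10 && p[1] <= 12 && p[2] >= 40 && p[2] <= 42) next
    got <- match_nearest(layer, p)$distance
    brute <- min(geosphere::distHaversine(p, dense, r = 6371008.8))
    expect_equal(got, brute, tolerance = 0.005)
  }
})

test_that("hotspot matching is strict containment with no fallback", {
  layer <- region_layer("hotspot", list(
    rect_feature(0, 0, 1, 1, list(hotspot = "H1"))))
  expect_equal(match_within(layer, c(0.5, 0.5))$hotspot, "H1")
  expect_null(match_within(layer, c(1.0001, 0.5)))  # ~10 m outside
  expect_equal(match_within(layer, c(1, 0.5))$hotspot, "H1")  # boundary
})

test_that("containment and nearest agree for interior points", {
  layers <- square_layers()
  set.seed(8)
  for (i in 1:25) {
    p <- c(runif(1, 0.1, 9.9), runif(1, 0.1, 9.9))
    m <- match_nearest(layers$ecoregion, p)
    w <- match_within(layers$ecoregion, p)
    expect_equal(m$distance, 0)
    expect_identical(m$attributes, w)
  }
})

test_that("annotation fills all layers, is idempotent, and handles islands", {
  layers <- square_layers()
  b <- mini_bundle(list(S1 = c("A a", "B b", "C c")), n_sites = 3,
                   lat = c("2", "8", "5"), lon = c("2", "8", "10.02"))
  db <- assemble_database(b)
  db <- annotate_sites(db, layers)
  expect_equal(db$sites$ecoregion, c("Eco South", "Eco North", "Eco South"))
  expect_equal(db$sites$biome, c("Biome A", "Biome B", "Biome A"))
  expect_equal(db$sites$country, rep("Testland", 3))
  expect_equal(db$sites$hotspot, c("Hotspot SW", NA, NA))
  expect_equal(db$sites$country_distance_m[1:2], c(0, 0))
  expect_gt(db$sites$country_distance_m[3], 0)  # offshore island site

  again <- annotate_sites(db, layers)
  expect_identical(again$sites, db$sites)

  expect_error(annotate_sites(db, layers["ecoregion"]),
               class = "ecocollate_config_error")
})

test_that("study latitude is the median with the even-count convention", {
  b <- mini_bundle(list(S1 = c("A a", "B b")), n_sites = 3,
                   lat = c("0", "10", "20"), lon = c("1", "2", "3"))
  db <- assemble_database(b)
  expect_equal(study_latitude(db, "S1"), 10)
  b <- mini_bundle(list(S1 = c("A a", "B b")), n_sites = 2,
                   lat = c("0", "10"), lon = c("1", "2"))
  expect_equal(study_latitude(assemble_database(b), "S1"), 5)
})

test_that("latitudinal coverage assigns bands half-open and sums to 100", {
  b <- mini_bundle(list(S1 = c("A a", "B b"), S2 = c("C c", "D d")),
                   n_sites = 2, lat = c("2", "3"), lon = c("2", "3"))
  db <- assemble_database(b)
  cov <- latitudinal_coverage(db, area = FALSE)
  expect_equal(cov$band, "[0, 5)")
  expect_equal(cov$percent_studies, 100)
  expect_equal(cov$percent_sites, 100)
  expect_equal(cov$percent_samples, 100)

  # band edges: 5 falls in [5, 10); 90 in the closed top band
  expect_equal(ecocollate:::band_index(5, 5), 20)
  expect_equal(ecocollate:::band_index(4.999, 5), 19)
  expect_equal(ecocollate:::band_index(90, 5), 36)
  expect_equal(ecocollate:::band_index(-90, 5), 1)

  cov <- latitudinal_coverage(db)
  expect_equal(sum(cov$percent_area), 100, tolerance = 1e-6)
})

test_that("coverage tables partition sites and samples", {
  spec <- fixture_spec(seed = 13, n_sources = 3, sites_per_study = 8)
  sv <- gen_survey(spec)
  db <- assemble_database(sv$bundles)
  db <- resolve_taxonomy(db, gen_checklist(spec))
  db <- annotate_sites(db, sv$regions[c("ecoregion", "country", "hotspot")])
  for (cat in c("biome", "country", "hotspot")) {
    tab <- coverage_table(db, cat)
    expect_equal(sum(tab$percent_sites), 100, tolerance = 1e-8)
    expect_equal(sum(tab$percent_samples), 100, tolerance = 1e-8)
    expect_true(all(tab$percent_studies >= 0 & tab$percent_studies <= 100))
  }
  hot <- coverage_table(db, "hotspot")
  expect_true("None" %in% hot$category)
})

test_that("coverage percentages are invariant to site permutation", {
  spec <- fixture_spec(seed = 13)
  sv <- gen_survey(spec)
  db <- assemble_database(sv$bundles)
  db <- annotate_sites(db, sv$regions[c("ecoregion", "country")])
  t1 <- coverage_table(db, "biome")
  perm <- sample(nrow(db$sites))
  db2 <- db
  db2$sites <- db2$sites[perm, ]
  t2 <- coverage_table(db2, "biome")
  expect_equal(t1, t2)
})

test_that("cell areas follow the spherical band formula and conserve the sphere", {
  r_km <- 6371.0088
  a_eq <- cell_area(0, 5)
  a_60 <- cell_area(60, 5)
  expect_equal(a_eq / a_60,
               (sin(5 * pi / 180) - 0) /
                 (sin(65 * pi / 180) - sin(60 * pi / 180)))
  # whole sphere from summed cells
  lats <- seq(-90, 85, by = 5)
  total <- sum(vapply(lats, function(lo) cell_area(lo, 5, lon_width = 360),
                      numeric(1)))
  expect_equal(total, 4 * pi * r_km^2, tolerance = 1e-9)
  expect_equal(cell_area(10, 0), 0)
})

test_that("TNPP is the closed-form product on a uniform raster", {
  vals <- array(1, c(1, 1, 12))  # 1 g C m^-2 day^-1 all year
  r <- npp_raster(vals, xll = 0, yll = 0, cellsize = 5)
  tn <- total_npp(r, by = "band")
  area_m2 <- cell_area(0, 5) * 1e6
  expect_equal(tn$tnpp_g_c, 365 * area_m2)

  # all-missing raster -> zero
  r0 <- npp_raster(array(NA_real_, c(1, 1, 12)), 0, 0, 5)
  expect_equal(sum(total_npp(r0, by = "band")$tnpp_g_c), 0)

  # terrestrial fraction scales linearly
  rh <- npp_raster(vals, 0, 0, 5, mask = matrix(0.5, 1, 1))
  expect_equal(total_npp(rh, by = "band")$tnpp_g_c, 0.5 * 365 * area_m2)
})

test_that("TNPP is additive over disjoint regions and linear in the values", {
  spec <- fixture_spec(seed = 2)
  rg <- gen_regions(spec)
  tn_band <- total_npp(rg$raster, by = "band")
  tn_region <- total_npp(rg$raster, by = "region", regions = rg$ecoregion,
                         attribute = "ecoregion")
  # ecoregions tile the raster: totals must agree
  expect_equal(sum(tn_region$tnpp_g_c), sum(tn_band$tnpp_g_c),
               tolerance = 1e-12)
  # biome zones are unions of ecoregion zones
  tn_biome <- total_npp(rg$raster, by = "region", regions = rg$ecoregion,
                        attribute = "biome")
  expect_equal(sum(tn_biome$tnpp_g_c), sum(tn_region$tnpp_g_c),
               tolerance = 1e-12)
  # linearity
  r3 <- rg$raster
  r3$values <- r3$values * 3
  expect_equal(total_npp(r3, by = "band")$tnpp_g_c,
               3 * tn_band$tnpp_g_c, tolerance = 1e-12)
})
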