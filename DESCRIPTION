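Package: ecocollate
Title: Collation, Validation and Curation of Site-by-Species Biodiversity
    Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling heterogeneous site-by-species survey data
    into a referentially consistent database of sources, studies, sites, taxa
    and diversity measurements. Provides a rule-based validation engine
    (coordinate and calendar sanity, duplicate detection, GIS country
    consistency), taxonomic name parsing and resolution against a
    Catalogue-of-Life-style checklist with homonym disambiguation and a
    curation queue, a land-use/intensity/fragmentation site ontology with
    date-interval and time-since-conversion rules, biogeographic annotation
    (nearest ecoregion and country with distances, exact hotspot matching),
    coverage and representativeness statistics (latitudinal bands, total net
    primary production weighting, chi-squared goodness of fit), and Cohen's
    kappa with near-miss partial credit for repeatability studies.
    Deterministic fixture generators make every component testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    readr,
    sp,
    stats,
    stringi,
    tibble,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
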