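---
title: "Collation methods: data model, validation, taxonomy and coverage statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collation methods: data model, validation, taxonomy and coverage statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecocollate)
```

ecocollate turns heterogeneous site-by-species survey datasets — the raw
material of global syntheses of how local biodiversity responds to land
use — into a single, validated, taxonomically harmonized database, and
computes the statistics needed to judge how well that database covers the
world: geographically, bioclimatically and taxonomically.  This vignette
explains the models and procedures, the parameters that matter, and the
design decisions taken where the design was genuinely open.

## The data model

Data are organized in a three-level hierarchy.  A **source** is a
publication (or report, or thesis) that contributed data.  A **study** is
a set of observations within a source collected with a single sampling
method; comparing diversity measurements is meaningful within a study but
not between studies, because methods differ.  A study must contain at
least two **sites** — a single site supports no within-study comparison —
plus a taxon list and a site-by-taxon matrix of abundance, occurrence or
species-richness measurements.  The metric type is fixed per study,
because one matrix holds one kind of observation.

Empty matrix cells are ambiguous: they may mean "looked for, absent" or
"not looked for".  The rule, applied per study matrix: if every filled
cell is non-zero, the author plainly recorded presences only, and blanks
become zeros; if any filled cell is zero, the author did record absences,
so blanks must mean "not sampled" and stay missing.  The operation is
idempotent, and measurement counts downstream use only non-missing cells.

Patch area is a tri-state (`known` m², `unknown_large`, `unknown`); the
conventional sentinel −1 ("unknown but large") exists only in the CSV
files, never inside the logic, because sentinels that survive into
arithmetic are a reliable source of silent bugs.

Field-level values — coordinates, dates, times since conversion — are
carried verbatim (`*_entered` columns) alongside their parsed forms.
Assembly parses leniently (`NA` on failure) and enforces only structural
invariants (referential integrity, ≥ 2 sites per study, unique
identifiers); everything else is the validator's job.  This split keeps
the pipeline order honest: files are assembled, then *fully validated*
before any downstream stage runs.

## Validation

`validate_database()` emits issues, not errors; each issue carries a rule
code, a severity and a record reference.  The lower-level rules are:
mandatory-field presence, non-negative time since conversion, coordinate
range, angle-literal sanity (a latitude of `1° 61'` cannot exist —
minutes and seconds live in [0, 60)), real-calendar date validity (there
is no 32nd of January; leap years are honoured on the proleptic Gregorian
calendar), and duplicated site or taxon names within a study.

The higher-level check is geographic: the nearest country polygon to each
site's coordinates must be a country declared for the source (the
declaration `"Multiple countries"` waives the check).  Mismatches almost
always mean latitude/longitude swapped, a dropped hemisphere sign, or
degrees/minutes/seconds mis-assembled; `suggest_coordinate_fixes()`
evaluates those four transforms and reports the ones that land the point
in a declared country, without ever mutating the database.  Sites outside
every country polygon are flagged for review (coarse global layers clip
coasts and drop small islands); past a configurable threshold — default
10 km, a judgement call since coastal polygon error is typically far
below that — the flag escalates to a warning.  The severity of each rule
is a fixed table (`validation_rules()`), not an emergent property.

Mandatory fields are the set a downstream model cannot do without
(coordinates, dates, land use, intensity, metric type, effort unit); the
list is in one place (`mandatory_fields()`) and easy to extend.

## The site ontology

Predominant land use takes six classes — primary vegetation, secondary
vegetation, cropland, pasture, urban, plantation forest — plus "Cannot
decide"; secondary vegetation carries a successional stage (young,
intermediate, mature, indeterminate).  Use intensity is minimal, light or
intense, plus "Cannot decide".  Fragmentation layout is one of five
classes from "well within unfragmented habitat" to "part of the matrix
surrounding remnant patches".  Assigning these classes from free-text
habitat descriptions is deliberately left to trained human scorers, as in
the underlying data-capture workflow; the package validates entered
combinations and supplies the vocabularies, and makes no attempt at text
classification.

Two rules convert reported values into numbers.  Sampling dates arrive at
day, month or year precision; the stored interval is the earliest
possible start to the latest possible end at that precision ("June to
August 2007" becomes 2007-06-01 to 2007-08-31, resolution `month`), so
ordinary date columns retain the original precision losslessly.  Times
since conversion reported as ranges store the midpoint; "greater than N"
or "at least N" store N × 1.25, a fixed convention that keeps open-ended
reports usable without pretending to more information than they contain.

**Near misses.**  Repeatability scoring gives partial credit to
pre-specified pairs of confusable classes: primary vegetation vs *mature*
secondary; adjacent secondary stages (young–intermediate–mature, in that
order); indeterminate secondary vs any other secondary stage; "Cannot
decide" vs anything; and for intensity, adjacent levels or "Cannot
decide".  Both relations are symmetric and irreflexive, and the test
suite asserts this exhaustively over all class pairs.

**Maximum linear extent** — transect length, trap spread, or the diameter
of a point set — is the maximum pairwise great-circle distance.  All
great-circle computations in the package use a sphere of radius
6 371.0088 km (the IUGG mean radius); the contract tolerance is 0.1%,
generous against the ~0.3% latitude-dependent deviation of any single
sphere from the ellipsoid.

## Taxonomic names

Each taxon keeps three names.  *Name entered* is immutable — what the
data provider wrote.  *Parsed name* is the putative Latin binomial
extracted by a small deterministic grammar: the first token is the genus;
the second is kept iff it is all lowercase and not an open-nomenclature
qualifier (`sp`, `spp`, `cf`, `aff`, `gr`, `nr`, `indet`); parsing stops
at a qualifier, a capitalized token (an authority), a parenthesis or a
digit.  The grammar treats *every* input as a scientific name; common
names therefore parse nonsensically ("Black and White Casqued Hornbill" →
"Black and"), which is intentional — such names surface in the curation
queue rather than being silently guessed at.  *Query name* starts equal
to the parsed name and is the only name curation may change.

Resolution against a Catalogue-of-Life-style checklist (accepted names,
synonyms, ambiguous synonyms, misapplied names, common names, each with a
pointer to its accepted entry and a full classification) proceeds:

1. exact search by name, case-insensitive and diacritic-folded, optionally
   restricted to a clade (for cross-kingdom homonyms like *Bellardia*,
   *Dracaena* or *Ficus*, or a within-kingdom constraint such as family
   Carabidae for a carabid study);
2. if the results contain exactly one distinct accepted name — directly or
   through pointers — that accepted entry wins (the original identifier is
   assumed authoritative);
3. with zero or several distinct accepted names, the resolution is the
   **lowest common classification**: classifications are lineage paths,
   and the common level is the deepest rank *before the lineages diverge*.
   Names alone do not count — two homonym genera in different beetle
   families share a genus name but diverge at family, so their common
   level is the order.  A rank absent from every lineage is skipped (coarse
   checklists omit ranks); a rank where only some lineages have a value
   ends the walk;
4. no results at all is the value `unmatched`, never an error.

Fuzzy matching is deliberately absent: typographical repair is a human
judgement (is *Diphaglosa gayi* a typo for *Diphaglossa gayi* or a
different animal?), so misspellings land in the review queue, and
`apply_curation()` records each query change with its reason and re-runs
resolution — repeatedly if necessary.  The entered and parsed names are
never touched.  All non-accepted statuses behave identically as pointers
to their accepted entry; the distinction between "synonym" and "ambiguous
synonym" has no defined operational semantics here, and the behaviour is
isolated in one place should one be needed.

The **review queue** flags: unmatched names; parsed binomials that
resolved above species level (morphospecies like "Bracon sp. 1" parse to
a bare genus and are *expected* to resolve high, so they are not
flagged); identical parsed names resolving to different entries in
different studies; and studies whose lowest common taxon is implausible
against a declared expected clade — the signature of, for example, an
uncurated four-letter bird code colliding with a hemipteran genus.

**Bird codes.**  Codes contracted from binomials follow a fixed rule
(first two letters of genus + first two of epithet: ACBA → *Accipiter
badius*); `expand_bird_code()` inverts it against a regional species
pool, retreating to the lowest common classification when codes collide.
Codes contracted from North American common names follow external rules
that are out of scope; a dictionary lookup (curation) covers them.

**Counting species.**  Names resolved to species or infraspecies count
once per resolved name across the database; anything coarser counts once
per name per study.  The cost of this scheme is known and accepted: two
studies that each report *Eonycteris* sp. 1–3 contribute six "species"
even if they sampled the same three — the information to deduplicate them
simply does not exist in the names, and no cross-study reconciliation is
attempted.  Taxonomic coverage is summarized by a higher group: the order
for classes Insecta and Entognatha (Entognatha is excluded from the next
rule for the same reason Insecta is — its orders are the informative
level); the class for phyla Arthropoda, Chordata and Tracheophyta;
otherwise the phylum.  Four fixed roll-ups (Magnoliophyta, Gymnosperms,
Ferns and allies, Crustacea) align these groups with published
described-species totals.  Best-guess binomials — the resolved name at
species rank, its first two words at infraspecies rank, the parsed name's
first two words otherwise — maximize joins to trait databases even for
names the checklist does not know.

## Geographic annotation and coverage

Sites are matched to three kinds of layers: ecoregion/biome/realm and
country/UN region/subregion with **nearest-polygon fallback** (global
layers are coarse; a coastal site a few hundred meters "at sea" still
belongs to its country, and the distance in meters is recorded, zero when
inside), and biodiversity hotspots with **strict containment** — a site
just outside a hotspot is genuinely not in one.  Boundary points count as
inside; ties between equidistant features break deterministically by
layer order; antimeridian-crossing polygons are rejected rather than
mishandled.

The distance model is great-circle distance to the nearest point of the
polygon boundary, with edges treated as straight lines in lon/lat space —
the same geometry the point-in-polygon test uses, so containment and
distance can never disagree.  The minimum along each edge is located by a
coarse 33-point scan refined with a ternary search, accurate to well
under the 0.5% contract tolerance.

Coverage statistics follow.  A study's latitude is the median of its
sites' latitudes (mean of the central two for even counts); studies,
sites and samples (non-missing measurements) are tallied into five-degree
latitudinal bands, half-open `[lower, upper)` with the northernmost band
closed.  Category tables (biome, country, hotspot …) report the percent
of studies, sites and samples per category; a study counts in every
category its sites touch, so the studies column may exceed 100% across
categories while sites and samples always partition.  Sites outside all
hotspots form a `"None"` row.  Percent-of-area columns use polygon areas
over a total land area that defaults to the layer's own summed area.

Terrestrial area per grid cell uses the closed-form spherical band
formula R²·Δλ·(sin φ₂ − sin φ₁).  **Total net primary production** (TNPP)
weights coverage by productivity rather than area: monthly mean daily NPP
(g C m⁻² day⁻¹) × days in the month (non-leap calendar, matching the
single-year rasters the statistic is designed for) × terrestrial cell
area, summed over twelve months and over a region's cells; missing cells
contribute zero, and cells join regions by their center.  TNPP is exactly
additive over disjoint regions and linear in the raster values — both are
tested.

## Agreement statistics

A blind rescoring of land use and intensity for a random sample of sites
is summarized with Cohen's kappa, κ = (p₀ − pₑ)/(1 − pₑ).  The weighted
variant scores each ordered pair of categories with a credit in [0, 1]
(1 on the diagonal, symmetric); p₀ is the mean credit over items and pₑ
the expected credit under independent marginals.  With the exact-match
indicator the weighted statistic reduces to plain kappa *bit for bit*,
which the test suite checks on 500 random rating sets.  The conventional
near-miss credit is 0.5, injected from the ontology's near-miss relations
and overridable.  When the ratings put all mass on one cell pₑ = 1 and
kappa carries no information; the result is flagged `degenerate` with a
warning (κ = 1 when agreement is also perfect, `NA` otherwise).

Representativeness of the land-use × intensity distribution is a Pearson
goodness-of-fit test of observed site counts against expected terrestrial
area proportions.  Combinations with no defensible area estimate (urban
land under light use, in the canonical configuration) are excluded and
the remaining proportions renormalized; with six pooled land-use classes
× three intensities minus one exclusion, df = 17 − 1 = 16.  Secondary
stages are pooled by default — expected-area datasets do not distinguish
them.  P-values are upper-tail and printed as a bound (`P < 2.2e-16`)
when below double precision.

Published kappa values from the original repeatability studies are not
reproduction targets here: the underlying confusion matrices are
unpublished, so only the generator-based recovery properties (estimated
kappa within 0.02 of the analytic value at n = 10 000) are asserted.

## Fixtures: what the generators emulate, and what they do not

Every module is testable offline through deterministic generators driven
by a single spec (`fixture_spec()`).  One pseudo-random stream per
generator is derived from the master seed by a stable label, so adding a
generator never shifts existing outputs.  `gen_checklist()` builds the
structures resolution must survive — synonym chains, one-accepted-plus-
synonyms clusters, homonym genera within an order, cross-kingdom
homonyms, common names — with the expected resolution recorded alongside.
`gen_survey()` builds clean bundles, then injects a stated count of each
error kind with an exact ledger, so the validator can be held to
"exactly the ledger: no false negatives, no false positives".
`gen_regions()` tiles a lon/lat rectangle with ecoregions, biomes,
realms, countries and hotspots whose areas are available in closed form,
plus twelve monthly NPP grids with a cosine-of-latitude profile.
`gen_ratings()` samples from a known joint distribution and returns the
analytic kappa.

The fixtures emulate *structure*, not ecology: abundance matrices are
i.i.d. Poisson, with none of the aggregation, zero-inflation or
abundance-distribution shape of real assemblages, and polygons are
rectangles without the sliver-and-enclave pathology of real borders.
Passing tests therefore demonstrate that the machinery is correct on data
whose ground truth is known — not that real data are error-free, nor that
real GIS layers are benign.  Default sizes (2 sources × 1 study × 6
sites × 8 taxa; 4×3 ecoregions; 2×2 countries; 5° NPP grid) keep the full
suite under a minute; the statistical tests that need size use n = 10 000
ratings and 500–1 000 replicate property cases.

## Known limitations

- Name matching is exact (after case/diacritic folding); heavy typo loads
  will put weight on the curation queue rather than resolve silently.
- Nearest-polygon distances assume edges short enough that the lon/lat
  straight line and the geodesic are close; global layers with
  thousand-kilometer edges would need densification first.
- The representativeness test inherits chi-square's large-sample
  assumptions; with very small expected counts an exact multinomial test
  (out of scope) would be preferable.
- Species-richness studies may arrive as per-taxon rows or a single
  per-site total; both are accepted and flagged for review rather than
  guessed at.
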