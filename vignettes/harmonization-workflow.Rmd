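---
title: "Harmonizing native and alien species distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing native and alien species distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(aliendist)
library(dplyr)
```

`aliendist` integrates heterogeneous evidence about where alien species occur
— and where they are native — into one standardized dataset. This vignette
explains the procedure, its assumptions, the tunable parameters, and the
design choices made where the problem itself left the design open.

## The data model

The workflow produces two flat tables. The *distribution table* has one row
per (taxon, location, establishment) combination, with Darwin Core invasion
status fields:

* `establishmentMeans` — native, introduced, vagrant, uncertain, or the
  composite `"introduced; uncertain"`;
* `occurrenceStatus` — present or absent (absent means once recorded, now
  locally extinct or eradicated);
* `degreeOfEstablishment` — established, reproducing, invasive; only
  meaningful for introduced populations;
* `pathway` — CBD introduction pathway categories;
* `eventDate` — an integer year, the earliest documented record;
* `habitat` — a `"; "`-joined subset of {brackish, freshwater, marine,
  terrestrial}; a trait of the taxon, not of one record;
* `datasetName` / `bibliographicCitation` — provenance, the sorted union of
  contributing sources.

The *taxa table* has one row per original name as supplied by any source.
Following the published schema this original name is stored under the header
`verbatimTaxonRank`, although Darwin Core uses that term for rank
information; we keep the header for compatibility and note the discrepancy
here. `taxon` holds the accepted canonical name (or the verbatim name when
unmatched), alongside backbone status, match type, usage key, higher
taxonomy and a taxa group.

Absent values are written as empty strings in CSV output — not `"NA"` —
because real taxon names can collide with missing-value sentinels, and the
empty string round-trips unambiguously (`read_output_table()` inverts it).

## Source ingestion as configuration

Each source is declared, not coded: a `source_config()` names the columns
that play the roles of taxon, location(s), establishment, and the optional
fields; filter rules list allowed or disallowed values for any raw column;
binary establishment codes (`0`/`1`) are decoded by a per-source mapping;
and single-scope sources (alien-only or native-only) inherit their scope's
establishment value for records that carry none. This mirrors how the
field's compilations actually differ: one source flags establishment as
*established outdoors* vs *indoors only*, another codes nativeness as a
binary column plus a doubtful-location flag, a third scatters locations
across island and country columns, which are combined finest-first.

Every row a filter or restriction list removes is counted per (source,
reason) in the ingest log. Transparency over silence is a design rule
throughout: nothing is dropped without a ledger entry somewhere.

## The location reference system

Locations are non-overlapping named polygons with alternative spellings,
subdivisions, and membership in one or more regional aggregation schemes.
Name matching is deterministic and normalization-insensitive (Unicode
normalization, diacritic stripping, case folding, whitespace collapsing):
first against names and alternatives, then against subdivisions, which
up-scales state- or province-level records to their parent location. A name
claimed by two locations is treated as a configuration defect, not a data
defect, and raises an error rather than guessing.

Range maps are converted to checklists by overlay. The intersection
predicate requires *positive area*: a polygon that only shares a border or a
corner with a location does not create a presence there, which avoids
spurious records from shared boundaries. Because coarse expert range maps
overhang borders, `overlay_range_maps()` also accepts a minimal
intersection-to-location-area fraction (default 0, i.e. any positive-area
overlap counts); fractions are computed under a Lambert cylindrical
equal-area transform, which is exactly area-preserving on the sphere.

Geometries are read from WKT text columns. The geometry kernel computes
exact intersection areas by Sutherland–Hodgman clipping when the reference
polygon is convex, and falls back to documented grid sampling (default
120 × 120 over the joint bounding box) for concave references. Degenerate
features (unclosed, zero-area) are rejected at load and logged, never
repaired silently.

## Vocabulary and date standardization

All status and habitat fields are standardized by translation tables that
map verbatim variants to canonical terms; canonical terms map to themselves,
so standardization is idempotent. An unmatched term leaves the field absent
and adds a row to the per-field, per-source match report — for optional
fields the record survives; a record whose establishment cannot be resolved
at all is excluded (with a reason) at merge time. Pathway standardization is
deliberately strict table lookup: no inference from free text.

First-record dates follow an explicit grammar: a bare four-digit year; a
two-year range, reduced to the arithmetic mean and truncated toward the
earlier year when the mean is not an integer (consistent with the workflow's
later earliest-record preference); full dates truncated to their year;
`c.`/`ca.` prefixes stripped; decade forms (`1950s`) mapped to the decade's
first year. Anything else is reported as unparseable. Years outside a
plausibility window (default 1000 to the current year) are reported too,
not silently dropped. The grammar is a documented choice: the sources this
kind of workflow consumes do not share a dates dialect, and an explicit,
extensible grammar beats silent guessing.

## Taxonomic matching

The backbone is an interface with two implementations: a local table-backed
backbone used by all tests, and a cache-backed adapter for the GBIF
species-match web service whose responses persist in an append-only
JSON-lines cache, so a completed run reproduces offline. The shipped cache
is pre-seeded with the package's documented worked example.

The cascade is: exact lookup; if several entries share the name, homonym
resolution using source hints in the order author → kingdom → taxonomic
group, where each available hint discards non-conforming candidates and
anything other than a unique survivor abstains (flag `"Homonym in GBIF"`,
no backbone fields — choosing a wrong candidate would be worse than
abstaining); if no exact hit, a fuzzy lookup whose sole candidate is
accepted only at confidence 100. For the local backbone, confidence 100 is
defined deterministically: a unique entry within Damerau–Levenshtein
(optimal string alignment) distance 1 with no other canonical name within
distance 2. Synonyms are replaced by their accepted names and flagged;
a synonym resolving to several accepted keys, or several synonym entries
matching one query, get their own note values. Unmatched names stay in the
dataset verbatim.

Taxa groups (Birds, Mammals, Vascular plants, Insects, …, 20 labels) are
assigned by an ordered, user-editable rule table over the retrieved higher
taxonomy — first matching (rank, value) rule wins. Several groups are
ecological rather than monophyletic (algae, worms), which is why the table
is data, not code.

## Merge semantics

The merge key is (taxon, location, establishment class), where the class
pools `introduced` with `uncertain` — their co-occurrence for one taxon and
location yields the composite `"introduced; uncertain"` — and keeps
`native` and `vagrant` separate. Within a group: the earliest year wins;
`present` beats `absent`, and the disagreement is logged (a single extant
report should not be erased by an older extirpation claim, but the conflict
must remain visible); multiple pathway values join sorted and deduplicated;
for conflicting degrees of establishment we keep the most advanced stage
(established < reproducing < invasive), since the degrees are ordered stages
of the same invasion process. Degree and pathway are cleared on any merged
record whose establishment is not introduced-like. The composite label is
itself accepted on input, which makes the merge idempotent: feeding the
output back through `merge_records()` is the identity.

`locationID` comes from the translation table and is authoritative.
`taxonID` is assigned as consecutive integers over the taxa table sorted by
(taxon, original name) — stable under reruns, and appending a
lexicographically last name leaves existing IDs unchanged. When several
original names resolve to one accepted taxon, records carry the taxonID of
the first such entry, so every ID used in the records table occurs exactly
once in the taxa table and the (taxonID, taxon) pairing is consistent
across files.

All reported percentages are rounded half-up to one decimal; the mode is
stated in the summary itself because printed shares in compilations of this
kind are not always reproducible under a single rounding convention.

## The fixture generator and what passing tests mean

`generate_fixture_set()` builds a complete synthetic study: a backbone of
pronounceable invented binomials (never real names, so no accidental
collisions with a live service) with planted synonyms, across-kingdom
homonym pairs and one-edit misspellings; a grid of unit-square locations
with alternative spellings, subdivisions and two aggregation schemes; and
five sources in distinct dialects, each exercising a different ingestion
path, with every merge rule deliberately planted (an introduced+uncertain
pair, a native+introduced pair, duplicates with conflicting dates and
occurrence statuses, an unmatched location, unmatched status/pathway/date
terms). Accepted names are drawn pairwise at least four edits apart so that
each planted misspelling is uniquely attributable and the confidence-100
rule is exercised on both sides.

```{r}
fx  <- generate_fixture_set(fixture_spec(seed = 42), tempfile("fx"))
run <- run_pipeline(fx$sources$run_config_path)
glance(run)[, c("n_records", "n_taxa_total", "pct_introduced", "pct_native")]
```

The generator also emits a ground-truth ledger computed from its own
construction plan plus a deliberately naive reference merge
(`merge_records_naive()`, plain loops, no shared code with the vectorized
path). The central test asserts that the pipeline output equals that ledger
*exactly* — records, taxa table, unmatched reports:

```{r}
all.equal(as.data.frame(run$records),
          as.data.frame(fx$sources$ledger$records), check.attributes = FALSE)
```

Default fixture sizes (about 60 true taxa, 9 locations, 5 sources, roughly
80 raw records) keep the full suite fast while covering every code path;
property-style checks run the merge against its oracle on 100 random tables
of up to 200 records and the overlay against a fine-raster membership
oracle on 20 random convex features. Range features are snapped to a
0.25-degree lattice and rejection-sampled so any positive intersection has
area ≥ 0.02 square degrees, which guarantees the 0.05-degree raster oracle
can see every true overlap regardless of seed.

What passing does **not** show: fixtures are structurally realistic but
statistically arbitrary — they exercise code paths, not invasion ecology.
Real sources bring messier names (authorship embedded in name strings,
rank-mixed entries), far larger homonym neighborhoods in a live backbone,
and concave country polygons for which the overlay's exact path gives way
to grid sampling. Conclusions about any real dataset require running the
workflow on that dataset and reading its match and exclusion reports.

## Known limitations

* The geometry kernel targets the overlay decision (positive-area
  intersection, area fractions); it is not a general-purpose GIS. Concave
  reference polygons use sampled areas with resolution-bounded error.
* The live backbone adapter resolves queries only through its cache unless
  network access is explicitly enabled; drift in a living backbone between
  runs is therefore visible (and fixable) as cache differences.
* Homonym resolution abstains rather than ranks: a source providing no
  hints gets no backbone fields for homonymous names.
* The dataset records evidence at the resolution of administrative
  locations; ranges are overestimated near borders, and records derived
  from coarse range maps should be treated carefully toward range edges.
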