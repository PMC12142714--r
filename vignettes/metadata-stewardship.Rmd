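---
title: "Methods: auditing genome-assembly sample metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing genome-assembly sample metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblyaudit)
```

## The audit model

`assemblyaudit` operationalizes FAIR-style metadata stewardship for genome
assemblies as a per-record rubric followed by cohort aggregation. Each
assembly record carries its raw BioSample-style attributes verbatim; every
judgement the package makes is a deterministic function of those strings, so
an audit is reproducible and every classification can be traced back to the
text that produced it.

Three per-record quantities drive everything else:

1. **Spatial granularity**, ordered `none < country < region_city <
   coordinates`. A parseable `lat_lon` always wins; otherwise the INSDC
   `geo_loc_name` convention (`"Country: finer text"`) is used: any
   non-empty text after the first colon means region/city resolution, a
   recognizable bare country means country resolution.
2. **Temporal granularity**, ordered `none < year < month < day`, the finest
   precision the `collection_date` string actually states.
3. **Origin class** — field, laboratory, commercial, managed colony, or
   unknown — from keyword evidence in `isolation_source`, `strain`,
   `isolate` and `sample_name`.

A record is **complete** when origin is known, location reaches at least
country, and the date reaches at least year. This is deliberately a floor,
not an ideal: it is the minimum a record needs before it can participate in
any spatially or temporally explicit reuse.

## Parser decisions

**Null tokens.** The INSDC placeholder vocabulary (`missing`,
`not collected`, `not applicable`, `restricted access`, ...) is packaged as
an editable text file; every token behaves exactly like an absent attribute
in both parsers and in the presence flags. `restricted access` is treated as
missing because the datum, whatever it is, is unusable for reuse.

**Date dialects.** ISO `YYYY[-MM[-DD]]` plus the legacy `DD-Mmm-YYYY` and
`Mmm-YYYY` forms are accepted. A `start/end` range resolves to its earliest
bound at that bound's own precision: for invasion timelines the earliest
possible presence is the conservative choice. Anything else degrades to
`none` with a recorded parse warning — the audit never hard-fails on a
malformed record, it surfaces it.

**Coordinate dialects.** Two `lat_lon` forms are parsed: hemisphere style
(`"30.61 N 96.34 W"`) and signed decimal pairs. Coordinates are normalized
to signed decimal degrees with south and west negative and validated to
±90/±180; DMS strings are rejected to a warning rather than half-parsed,
and a malformed `lat_lon` falls back to whatever `geo_loc_name` supports.

**Country names.** Normalization uses a packaged alias table (e.g. `USA`,
`US`, `United States of America` → `United States`). Unmatched names pass
through flagged rather than being dropped: a wrong silent merge would be
worse than a visible unknown.

**Origin vocabulary and precedence.** The keyword lists are data (a packaged
TSV), not code, so the lexicon is auditable and extensible. When tokens from
several classes match, precedence `commercial > laboratory >
managed_colony > field` decides and a conflict flag is raised. The rationale:
a strain/colony/vendor token indicates captive propagation regardless of
founder provenance — "field-collected founders, lab colony F12" describes a
laboratory population. Conflicted records are therefore *classified and
flagged*, not counted unknown; `unknown` is reserved for records with no
origin evidence at all.

## Literature rescue

Curated overrides model the manual step of recovering origin or range from
publications. They are applied conservatively: an override must cite
evidence, only records currently `unknown` (or, for range, `undetermined`)
are touched, and everything else is skipped with a warning row. Attributes
outrank literature because the repository record is the primary artifact
being audited. The rescue report (reclassified to field, reclassified to
captive, remaining unknown) quantifies how much of the cohort's usability
depends on labour-intensive curation rather than on the submissions
themselves.

## Range analysis

Field-collected records are matched against a per-species home-range
gazetteer at country grain, with optional admin-region qualifiers. A country
present in exactly one of the native/expanded sets decides the status. When
the same country appears in both sets (legal only if at least one side
carries admin qualifiers — the species native to Texas and invasive in
California), an exact admin-region string match on exactly one side decides;
anything less resolves to `undetermined`, as do records without usable
location, species missing from the gazetteer, and species flagged feral.
Matching is exact-string after alias normalization — no polygon containment
or geocoding — which matches the desk-scale resolution of the underlying
records. A *dual-range species* has at least one native and one expanded
field-collected assembly.

## Aggregation and rounding

Every partition is reported as raw counts plus percentages rounded **half
away from zero** at caller-specified precision (default one decimal), so
that printed figures like 38 (76 of 199) and 35.5 (27 of 76) are exactly
reproducible; counts are always emitted alongside so rounding never hides
data. The per-year series splits field-collected from "other" (laboratory,
commercial, managed colony and unknown combined) and zero-fills years with
no submissions. Income groups use a strict GNI-per-capita threshold
(default USD 12,055; "exceeds" means strictly greater), classified from the
submitter country; countries absent from the income table are `unresolved`
rather than silently grouped.

## The synthetic generator

`synthetic_config()` defaults describe the cohort conditions the audit is
designed around: 199 assemblies submitted 2010–2022 with origin mixture
64 field / 42 laboratory / 14 commercial / 3 managed-colony / 76 unknown,
45 records with no usable location and 69 with no collection year, tissue
and developmental stage present for 134 records and sex for 100, 89
reference genomes, and a 64% SRA-linkage rate. Where only the aggregate was
known (the laboratory-vs-commercial split; how the located records divide
between country, region and coordinate resolution; how dated records divide
between year, month and day precision) one realistic split was fixed and is
not treated as a tunable: 42/14 for laboratory/commercial, 30/80/44 for
country/region/coordinates, 40/30/60 for year/month/day.

Two design choices matter for testing:

* **Exact allocation.** Category counts are realized by largest-remainder
  allocation, not sampling; seeds shuffle which record receives which
  category but never the marginal counts. Cohort-level arithmetic is
  therefore deterministic at any seed, which is appropriate because the
  audit is about classification, not sampling error.
* **Unambiguous templates.** Attribute strings are drawn from dialect
  templates with a single planted interpretation, so the pipeline must
  recover the planted truth on 100% of records — any miss is a defect, not
  noise. A separate adversarial template set (conflicting origin keywords,
  date ranges, malformed `lat_lon`) exercises the precedence and fallback
  paths and is only generated when explicitly enabled.

What the generator does *not* emulate: free-text chaos beyond its template
space (misspelled countries, DMS coordinates, prose dates), attribute keys
outside the recognized set, within-country location errors, or realistic
species abundance skew. Passing the recovery suites therefore demonstrates
the pipeline's correctness on well-formed dialect, and its *graceful
degradation* on the adversarial set — not that arbitrary real-world records
will parse at full resolution.

The packaged dual-range fixture (15 assemblies, 7 species) mirrors the
published record of species with both native- and expanded-range
field-collected assemblies: accessions, species, orders and collection
locations are verbatim; submission dates, assembly levels, flags and the
non-location attributes are synthetic stand-ins, which is irrelevant to what
the fixture tests (origin, granularity and range classification).

## Numerical and degenerate-input choices

* Ordered factors implement the granularity scales, so threshold logic is
  `spatial >= "country"` rather than hand-rolled comparisons.
* Mixture validation uses a 1e-9 tolerance on the sum; count allocation
  breaks remainder ties by category order, deterministically.
* Empty cohorts are schema errors at ingest and summary time; a single-row
  cohort is fully supported.
* Submission years are validated against a configurable window (default
  1990–present) to catch date typos at ingest rather than in downstream
  series.
* Percentages with zero denominators raise an error rather than returning
  NaN; the reporting layer never divides by a subset it has not checked.

## Problem sizes

The shipped test suite verifies exact generator→classifier recovery across
twenty seeded configurations (cohorts of 60–1,000 records) plus one
10,000-record cohort, and runs the property suites (partition conservation,
rounding bounds, enrichment monotonicity, dual-range detection against a
brute-force species scan) on cohorts of 100–300 records — sizes chosen to
exercise every category combination many times over while keeping the suite
fast on a single CPU.

## Known limitations

* Origin classification is lexical; it cannot see evidence living only in
  linked publications (that is what the override table is for) and inherits
  any bias in the packaged vocabulary.
* Range classification is country/admin-region exact matching; collection
  sites near borders, in unlisted regions, or specified only by coordinates
  (without a `geo_loc_name` country) resolve to `undetermined` rather than
  being geocoded.
* The alias table covers common submission spellings, not every toponym;
  unmatched countries are flagged and remain at `none` granularity unless a
  finer field rescues them.
* Income grouping reflects the submitter's country, a proxy for research
  provenance, not for where the sample was collected.
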