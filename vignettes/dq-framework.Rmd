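---
title: "Profiles, mechanisms and reports: the dwcdq quality model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiles, mechanisms and reports: the dwcdq quality model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwcdq)
```

## The model

`dwcdq` treats data quality as *fitness for a declared use*. Nothing in the
package judges a record absolutely; every measure, validation and
amendment is interpreted relative to a **profile**, the declarative
wish-list a data user writes down once and can then share, cite and reuse.
A profile holds:

* a **use case** — the data-use story that scopes everything else;
* **valuable information elements (IEs)** — named single fields or
  composed field sets. A composed IE such as `coordinates`
  (decimalLatitude, decimalLongitude, coordinateUncertaintyInMeters,
  geodeticDatum) is treated as one unit of meaning: it is complete only
  when *all* of its terms are filled;
* a **measurement policy** of contextualized dimensions. The same abstract
  dimension means different things in different contexts: completeness of
  `coordinates` for a *single record* is the qualitative presence of all
  four terms, while for a *dataset* it is the proportion of complete
  records, a number in [0, 1]. The resource type therefore fixes the
  result's value domain;
* a **validation policy** of criteria — comparator/threshold rules over
  one dimension's measure each. Dataset thresholds are stored as
  proportions; profile files may write `"100%"` or `1.0` and the reader
  normalizes. Record-level criteria state the required qualitative value
  and use equality;
* an **enhancement policy** — prevention, correction and recommendation
  activities. Prevention produces suggestions only and is never applied to
  data; corrections and recommendations yield *proposed* amendments whose
  acceptance is a curator's decision, encoded in an
  `amendment_policy()`.

Evaluation produces five-component **assertions**: the element in context,
the *specification* of the method, the *mechanism* that executed it, the
data resource (dataset or dataset + row), and the result. The report
contains exactly one measure per dimension (× N records for record-level
dimensions), one validation per criterion by the same rule, and one
amendment per enhancement per record — `NOT_PROPOSED` and
`PREREQUISITES_NOT_MET` are recorded explicitly rather than omitted, so a
report's shape is a function of the profile and the record count alone.
Because applicability of an amendment is otherwise undefined, recording
the explicit negative was the design choice here; it keeps report shapes
checkable and diffs stable.

Two further conventions are worth stating. First,
`PREREQUISITES_NOT_MET` is conservative everywhere: at dataset
aggregation an unassessable record counts as not-positive, and at
filtering it counts as a failure — a record that cannot be assessed is not
demonstrably fit. Second, record-level criteria are validated per record;
the per-criterion compliant proportions that a dataset-level reader may
want are emitted as a separate derived table
(`report$record_criterion_summaries`), not as extra assertions, so
assertion counts keep the one-per-criterion law exactly.

## Specifications, mechanisms and reuse

Specifications describe methods (at minimum informally, optionally with
formal parameters); mechanisms execute them. A *specific* mechanism
implements exactly one specification, a *broad* one several, and
mechanisms may delegate to others. The built-in registry
(`builtin_registry()`) follows that structure literally: coordinate
conformity is a broad mechanism composed of four independently callable
specific sub-checks —

1. each value parses as a number;
2. each value uses only valid characters (optional sign, digits, at most
   one dot: the strict decimal-degree dialect — no comma, no letters, no
   exponent; the alphabet had to be fixed somewhere, and the strict
   dialect rejects the ambiguous European comma-decimal rather than
   guessing);
3. latitude within [−90, 90], inclusive;
4. longitude within [−180, 180], inclusive (the latitude convention is
   inclusive by definition; longitude mirrors it).

The composition law (conformity = conjunction of the four) is asserted in
the test suite by running both routes. User-defined mechanisms register
alongside the built-ins with `register_mechanism()`, keyed by
specification id, so a profile never names code — only method ids.

## Geometry of the consistency check

A coordinate is *consistent* with its stated country when the circle
around the position, with radius `coordinateUncertaintyInMeters`,
intersects the country's area: the point is inside any polygon of the
(case-insensitively matched) country, or its distance to the nearest
boundary is at most the radius. Tangency counts as consistent
("intersects" includes touching). Choices that matter:

* **Planar approximation.** Distances use 1° latitude = 111,320 m and 1°
  longitude = 111,320·cos(latitude) m, evaluated at the record's
  latitude. No geodesic model, no datum transformation —
  `geodeticDatum` participates only in completeness of the composed IE.
  At fixture scales (uncertainties of metres to tens of kilometres) the
  approximation error is negligible relative to the radii involved.
* **Missing uncertainty** is treated as 0 m — the strictest reading of
  "radius equal to the coordinate uncertainty" — and the substitution is
  noted in the assertion detail.
* **Unknown or missing country is a prerequisite failure**, never
  `NOT_CONSISTENT`: the check cannot run, which is different from the
  check failing. Country names match exactly after case-folding; fuzzy
  geography invites silent errors. Same-named features in a boundaries
  file are merged into one polygon set (disjoint territories).
* Containment uses a winding-number test with boundary points counted
  inside; the test suite cross-checks it against an independent even-odd
  ray-casting oracle, and boundary distances against 1-d numerical
  minimization along each edge, on over a thousand random points.

Consistency is monotone in the uncertainty radius (consistent at *u*
implies consistent at any *u′* ≥ *u*), which the suite asserts as a
property.

## Amendments

All amendment mechanisms are pure: they read a record and return a
proposal; `apply_amendments()` builds a *new* dataset from accepted
proposals and a changelog, leaving the input untouched. Proposals are
always computed against the original data — no chaining of one
enhancement's output into another within a report, because the ordering
would be arbitrary; improving on improved data is an explicit re-report
cycle. Conflicting accepted proposals for the same (row, field) are both
dropped and logged.

The taxon backfill walks parent links from the most specific provided
name found in the reference taxonomy and proposes values only for rank
fields that are *declared in the record and blank*: absent fields are not
invented, non-blank fields are never overwritten, and a filled field that
contradicts the derived lineage is skipped with the conflict named in the
rationale. An ambiguous name (present at several taxonomy nodes) is a
prerequisite failure. Locality-based coordinate recommendation is an
exact lookup after case-folding and whitespace-collapsing — deliberately
not free-text georeferencing. Name suggestion returns accepted names
within a Levenshtein bound ordered by (distance, name); as a prevention
aid its proposals are reported but never auto-applied.

Missingness itself is defined once, package-wide: a value is missing when
its field is absent or its trimmed text is empty or equals `NULL`, `NA`
or `N/A` case-insensitively — the sentinels that dominate real occurrence
exports.

## The synthetic generator

`generate_dataset(n, rates, seed)` draws clean records over the interiors
of three square toy countries (plus a coarse synthetic Brazil outline used
by the worked example), then injects defects independently per record:
blanked coordinates, comma-decimal latitude, out-of-range latitude,
swapped country label, blanked genus/family, one-character name typos.
Coordinate defect classes follow a fixed precedence (missing ≻
non-numeric ≻ out-of-range ≻ wrong-country) so at most one applies per
record and ground-truth classes stay disjoint — overlapping defects would
make oracle counting ill-defined. All randomness comes from one seeded
stream consumed in fixed field order, so identical inputs give
byte-identical output and the caller's RNG state is restored afterwards.

Ground-truth flags are set *by construction* at generation time, never by
running the mechanisms under test; the suite then demands that every
dataset measure equal the realized ground-truth count over *n* exactly.
Default rates are zero (clean data); tests and the acceptance script set
explicit rates such as 30% missing coordinates. The generator emulates
structure, not the wild: real occurrence data have correlated defects,
heterogeneous vocabularies (datum spellings, country synonyms), dates and
identifiers with their own pathologies, and boundary-adjacent coordinates
where the planar approximation and gazetteer assumptions actually bite.
Passing tests on synthetic data therefore demonstrate the engine's
bookkeeping laws (shape, aggregation, partition, monotonicity,
determinism) and the mechanisms' definitional behaviour — not
performance on real aggregator exports.

## Problem sizes and numerical choices

The test suite exercises the shape law on 100 random profiles over
datasets of up to ~60 records, geometry oracles on >1,000 random points,
exact rate recovery at n = 10,000 over five seeds, and serialization
round-trips on 200 generated instances; the acceptance script uses
n = 10,000 for recovery and n = 200 for the management workflow. These
sizes give each property enough randomization to be convincing while
keeping a full run in the order of a couple of minutes. Proportions are
computed as integer-count ratios (k/n) so generator-vs-measure
comparisons are exact, not tolerance-based; thresholds read from profile
files are normalized to doubles on the proportion scale. Dataset measures
on empty datasets, unknown countries, unparseable coordinates and absent
reference tables all degrade to explicit `PREREQUISITES_NOT_MET` results
rather than errors or silent defaults.

## Known limitations

* Planar geometry only; no datum transformation; polygon holes are not
  modelled (rings are treated as parts of a union).
* Flat field→value records only; structured (multi-table or RDF)
  occurrence representations are out of scope.
* A criterion references exactly one dimension; multi-dimension criteria
  would need a composite-dimension extension.
* The mechanism registry is in-process; there is no networked registry or
  multi-user review workflow beyond the amendment policy modes.
* Country-name matching is exact (after case-folding) and locality lookup
  is exact-match only.
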