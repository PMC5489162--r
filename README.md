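# dwcdq — fitness-for-use data quality for Darwin Core occurrence data

Biodiversity occurrence records aggregated from museums, herbaria and
observation networks vary enormously in quality, and whether a record is
"good enough" depends entirely on what it will be used for: a coarse
species checklist tolerates coordinates a distribution model cannot.
`dwcdq` makes that relativity executable. Data users declare their quality
needs as a **profile** — a use case, the *information elements* that matter
for it (single fields or composed sets such as
`decimalLatitude` + `decimalLongitude` + `coordinateUncertaintyInMeters` +
`geodeticDatum`), and three policies:

- a **measurement policy** of contextualized dimensions (completeness,
  conformity, consistency, …), each bound to an information element and a
  resource type — single-record dimensions are measured qualitatively
  (`COMPLETE`/`NOT_COMPLETE`, …), dataset dimensions quantitatively as a
  proportion in [0, 1];
- a **validation policy** of criteria, pass/fail rules over those measures
  (e.g. *"coordinate completeness of the dataset must be equal to 100%"*);
- an **enhancement policy** of improvement activities (prevention,
  correction, recommendation).

The engine evaluates a profile against occurrence data with a registry of
**mechanisms** and emits a quality-status report of five-component
**assertions** (element in context, specification, mechanism, data
resource, result): one **measure** per dimension, one **validation** per
criterion, one proposed **amendment** per enhancement per applicable
record. Reports drive both management modes: *quality assurance* filters a
dataset down to its fit-for-use subset; *quality control* applies
curator-accepted amendment proposals to produce an improved copy — the
original data are never mutated.

Built-in mechanisms cover field completeness; coordinate conformity (four
reusable sub-checks: numeric parse, strict decimal-degree characters,
latitude in [−90, 90] and longitude in [−180, 180], both inclusive);
point-radius country consistency (the circle around the position with
radius `coordinateUncertaintyInMeters` must intersect the stated country's
boundary, under a local-planar approximation with 1° = 111,320 m);
taxon-hierarchy backfill from the most specific resolvable name;
country-from-coordinates and gazetteer-locality recommendations; and
Levenshtein accepted-name suggestion. A deterministic synthetic-data
generator produces occurrence datasets with seeded defect rates and
per-record ground-truth labels, plus toy reference geography and taxonomy.

## Worked example

The bundled profile declares coordinate completeness (record + dataset),
conformity, consistency and taxon completeness, with an equal-to-100%
dataset criterion and fill/recommend/suggest enhancements:

```r
library(dwcdq)

ref      <- generate_reference_fixtures()      # toy countries + coarse Brazil
registry <- builtin_registry(ref)
profile  <- read_profile(system.file("extdata", "profile-coordinates.yaml",
                                     package = "dwcdq"))
ds  <- read_occurrences(system.file("extdata", "occurrences-example.csv",
                                    package = "dwcdq"))
rep <- generate_report(profile, ds, registry)
summary(rep)
#> Report for profile 'sdm-tetragonisca' on 'occurrences-example.csv' (5 records)
#> Measures by status:
#>             COMPLETED PREREQUISITES_NOT_MET
#>                    14                     3
#> Validations by outcome:
#>             COMPLIANT         NOT_COMPLIANT PREREQUISITES_NOT_MET
#>                     9                     4                     3
#> Amendments by status:
#>          NOT_PROPOSED PREREQUISITES_NOT_MET              PROPOSED
#>                    15                     2                     3
#> Record-level criterion summaries (derived):
#>        criterion_id n n_compliant proportion_compliant
#> 1   record-complete 5           4                  0.8
#> 2 record-conformant 5           3                  0.6
#> 3 record-consistent 5           2                  0.4
```

Record `occ-2` carries the classic inconsistent point-radius case
(decimalLatitude −35.3848, decimalLongitude 13.8352, uncertainty 100 m,
country Brazil): the point lies in the South Atlantic, thousands of
kilometres from any Brazil boundary, so its consistency measure is
`NOT_CONSISTENT` and it is excluded by assurance filtering:

```r
flt <- filter_fit_for_use(ds, profile, rep)
flt$exclusions
#>   row_id                                     failed_criteria
#> 1      1                                   record-consistent
#> 2      2 record-complete;record-conformant;record-consistent
#> 3      4                 record-conformant;record-consistent
```

Quality control applies accepted proposals to a new copy — here the blank
genus/family of `occ-2` are backfilled from the taxonomy and the blank
coordinates of `occ-3` recommended from its gazetteer locality:

```r
ctl <- apply_amendments(ds, rep, amendment_policy("accept_all"), profile)
ctl$changelog
#>   row_id                         field old          new       enhancement_id
#> 1      1                        family           Apidae           fill-taxon
#> 2      1                         genus     Tetragonisca           fill-taxon
#> 3      2               decimalLatitude         -22.9056 coords-from-locality
#> 4      2              decimalLongitude         -47.0608 coords-from-locality
#> 5      2 coordinateUncertaintyInMeters             5000 coords-from-locality
```

A shell interface wraps the same functions
(`inst/cli/dwcdq profile validate | report | filter | amend | synth`).

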