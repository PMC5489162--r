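format_version: "1.0"
use_case:
  id: sdm-tetragonisca
  label: Distribution model for Tetragonisca angustula
  description: >
    Generate a species distribution model for the wild bee Tetragonisca
    angustula in Brazil; records need complete, conformant and
    country-consistent point-radius coordinates and a usable taxon
    hierarchy.
information_elements:
  - id: coordinates
    label: Decimal coordinates
    kind: COMPOSED
    terms:
      - decimalLatitude
      - decimalLongitude
      - coordinateUncertaintyInMeters
      - geodeticDatum
    description: Point-radius position in decimal degrees with its datum.
  - id: taxon
    label: Taxon identification
    kind: COMPOSED
    terms:
      - scientificName
      - genus
      - family
    description: The most specific name and its immediate hierarchy.
measurement_policy:
  - id: coord-completeness-record
    dimension: COMPLETENESS
    information_element: coordinates
    resource_type: SINGLE_RECORD
    specification: completeness
  - id: coord-completeness-dataset
    dimension: COMPLETENESS
    information_element: coordinates
    resource_type: DATASET
    specification: completeness
  - id: coord-conformity-record
    dimension: CONFORMITY
    information_element: coordinates
    resource_type: SINGLE_RECORD
    specification: coordinate-conformity
  - id: coord-consistency-record
    dimension: CONSISTENCY
    information_element: coordinates
    resource_type: SINGLE_RECORD
    specification: coordinate-consistency
  - id: taxon-completeness-dataset
    dimension: COMPLETENESS
    information_element: taxon
    resource_type: DATASET
    specification: completeness
validation_policy:
  - id: dataset-fully-complete
    statement: Coordinate completeness of the dataset must be equal to 100%.
    dimension: coord-completeness-dataset
    comparator: EQ
    threshold: "100%"
  - id: record-complete
    statement: Every coordinate term of the record must be filled.
    dimension: coord-completeness-record
    comparator: EQ
    threshold: COMPLETE
  - id: record-conformant
    statement: Latitude and longitude must be numeric decimal degrees in range.
    dimension: coord-conformity-record
    comparator: EQ
    threshold: CONFORMANT
  - id: record-consistent
    statement: The point-radius circle must intersect the stated country.
    dimension: coord-consistency-record
    comparator: EQ
    threshold: CONSISTENT
enhancement_policy:
  - id: fill-taxon
    statement: Fill in taxon hierarchy based on the most specific name.
    type: CORRECTION
    target_dimensions:
      - taxon-completeness-dataset
    specification: fill-taxon-hierarchy
  - id: country-from-coords
    statement: Recommend a country name on the basis of the coordinates.
    type: RECOMMENDATION
    target_dimensions:
      - coord-consistency-record
    specification: country-from-coordinates
  - id: coords-from-locality
    statement: Recommend coordinates based on the locality description.
    type: RECOMMENDATION
    target_dimensions:
      - coord-completeness-record
      - coord-completeness-dataset
    specification: coordinates-from-locality
  - id: suggest-names
    statement: Suggest similar and valid scientific names while typing.
    type: PREVENTION
    target_dimensions:
      - taxon-completeness-dataset
    specification: name-suggestion
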