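# Built-in mechanism catalogue: completeness, coordinate conformity (four
# reusable sub-checks), point-radius country consistency, criterion
# validation, taxon-hierarchy backfill, country-from-coordinates,
# gazetteer lookup, and scientific-name suggestion.

COORD_TERMS <- c("decimalLatitude", "decimalLongitude",
                 "coordinateUncertaintyInMeters", "geodeticDatum")

get_field <- function(record, term) {
  if (term %in% names(record)) record[[term]] else NULL
}

# occurrence exports write either countryName or the Darwin Core simple
# term country — accept both, preferring country.
get_country_field <- function(record) {
  for (term in c("country", "countryName")) {
    v <- get_field(record, term)
    if (!is_missing_value(v)) return(list(term = term, value = v))
  }
  for (term in c("country", "countryName"))
    if (term %in% names(record)) return(list(term = term, value = record[[term]]))
  list(term = "country", value = NULL)
}

as_single_record <- function(resource) {
  if (inherits(resource, "dq_data_resource")) {
    stopifnot(resource$resource_type == "SINGLE_RECORD")
    resource$record
  } else resource
}

# --- completeness -----------------------------------------------------------

#' Measure completeness of an information element in a single record
#'
#' The record is `COMPLETE` for the element iff none of its terms is missing
#' (see [is_missing_value()]); the detail lists the missing terms.
#'
#' @param record named character vector or single-record resource.
#' @param ie a [dq_information_element()].
#' @return a qualitative `dq_measure_result` (`COMPLETE`/`NOT_COMPLETE`).
#' @export
measure_completeness_record <- function(record, ie) {
  record <- as_single_record(record)
  res <- resolve_information_element(record, ie)
  if (any(res$missing))
    measure_result("COMPLETED", qualitative = "NOT_COMPLETE",
                   detail = paste("missing:",
                                  paste(res$term[res$missing], collapse = ", ")))
  else
    measure_result("COMPLETED", qualitative = "COMPLETE",
                   detail = "all terms present")
}

#' Measure completeness of an information element over a dataset
#'
#' The proportion of records that are `COMPLETE` for the element, as an exact
#' count ratio.
#'
#' @param dataset a dataset `dq_data_resource` or list of records.
#' @param ie a [dq_information_element()].
#' @return a quantitative `dq_measure_result`, or `PREREQUISITES_NOT_MET`
#'   for an empty dataset.
#' @export
measure_completeness_dataset <- function(dataset, ie) {
  records <- if (inherits(dataset, "dq_data_resource")) dataset$records
             else dataset
  n <- length(records)
  if (n == 0L)
    return(measure_result("PREREQUISITES_NOT_MET", detail = "empty dataset"))
  k <- 0L
  for (r in records)
    if (measure_completeness_record(r, ie)$qualitative == "COMPLETE")
      k <- k + 1L
  measure_result("COMPLETED", quantitative = k / n,
                 detail = sprintf("%d of %d records complete", k, n))
}

# --- coordinate conformity --------------------------------------------------

#' Sub-check: value parses as a number
#' @param x a field value as text.
#' @return logical.
#' @export
check_value_is_number <- function(x) {
  !is_missing_value(x) && !is.na(suppressWarnings(as.numeric(trimws(x))))
}

#' Sub-check: value contains only valid decimal-degree characters
#'
#' Optional leading sign, digits, at most one dot; no comma, no letters, no
#' exponent notation.
#'
#' @param x a field value as text.
#' @return logical.
#' @export
check_valid_characters <- function(x) {
  !is_missing_value(x) && grepl("^[+-]?[0-9]+(\\.[0-9]+)?$", trimws(x))
}

#' Sub-check: latitude within \[-90, 90\], inclusive
#' @param x a latitude value as text.
#' @return logical; `FALSE` when the value does not parse.
#' @export
check_latitude_range <- function(x) {
  v <- suppressWarnings(as.numeric(trimws(x %||% "")))
  !is.na(v) && v >= -90 && v <= 90
}

#' Sub-check: longitude within \[-180, 180\], inclusive
#' @param x a longitude value as text.
#' @return logical; `FALSE` when the value does not parse.
#' @export
check_longitude_range <- function(x) {
  v <- suppressWarnings(as.numeric(trimws(x %||% "")))
  !is.na(v) && v >= -180 && v <= 180
}

#' Measure coordinate conformity of a single record
#'
#' A broad mechanism composed of four reusable specific sub-checks applied to
#' decimalLatitude and decimalLongitude: both values are numbers, both use
#' only valid characters, latitude is in \[-90, 90\] and longitude in
#' \[-180, 180\]. The record is `CONFORMANT` iff all four pass; the detail
#' enumerates each sub-check outcome.
#'
#' @param record named character vector or single-record resource.
#' @return a qualitative `dq_measure_result`
#'   (`CONFORMANT`/`NOT_CONFORMANT`), or `PREREQUISITES_NOT_MET` when either
#'   coordinate is missing.
#' @export
measure_coordinate_conformity_record <- function(record) {
  record <- as_single_record(record)
  lat <- get_field(record, "decimalLatitude")
  lon <- get_field(record, "decimalLongitude")
  if (is_missing_value(lat) || is_missing_value(lon)) {
    miss <- c("decimalLatitude", "decimalLongitude")[
      c(is_missing_value(lat), is_missing_value(lon))]
    return(measure_result("PREREQUISITES_NOT_MET",
                          detail = paste("missing:",
                                         paste(miss, collapse = ", "))))
  }
  checks <- c(
    is_number = check_value_is_number(lat) && check_value_is_number(lon),
    valid_characters = check_valid_characters(lat) &&
      check_valid_characters(lon),
    latitude_range = check_latitude_range(lat),
    longitude_range = check_longitude_range(lon))
  detail <- paste(names(checks), ifelse(checks, "pass", "fail"),
                  sep = ":", collapse = "; ")
  measure_result("COMPLETED",
                 qualitative = if (all(checks)) "CONFORMANT"
                               else "NOT_CONFORMANT",
                 detail = detail)
}

# --- coordinate consistency -------------------------------------------------

#' Measure point-radius country consistency of a single record
#'
#' The coordinate is `CONSISTENT` only if the circle around
#' (decimalLatitude, decimalLongitude), with radius equal to
#' coordinateUncertaintyInMeters, intersects the area within the boundary of
#' the stated country: the point lies inside any of the country's polygons,
#' or its planar distance to the nearest boundary is at most the uncertainty
#' radius (tangency counts as consistent). A missing uncertainty is treated
#' as 0 m (point test only), noted in the detail.
#'
#' @param record named character vector or single-record resource.
#' @param reference a [reference_data()] with country boundaries.
#' @return a qualitative `dq_measure_result`
#'   (`CONSISTENT`/`NOT_CONSISTENT`); `PREREQUISITES_NOT_MET` (naming the
#'   unmet prerequisite) when the coordinates do not parse or are out of
#'   range, or when the country is absent or unknown to the boundaries.
#' @export
measure_coordinate_consistency_record <- function(record, reference) {
  record <- as_single_record(record)
  lat_s <- get_field(record, "decimalLatitude")
  lon_s <- get_field(record, "decimalLongitude")
  if (!check_latitude_range(lat_s) || !check_longitude_range(lon_s))
    return(measure_result("PREREQUISITES_NOT_MET",
                          detail = "coordinates absent, non-numeric or out of range"))
  country <- get_country_field(record)
  if (is_missing_value(country$value))
    return(measure_result("PREREQUISITES_NOT_MET",
                          detail = "country not provided"))
  rings <- match_country(reference, country$value)
  if (is.null(rings))
    return(measure_result("PREREQUISITES_NOT_MET",
                          detail = sprintf("unknown country '%s'",
                                           country$value)))
  lat <- as.numeric(trimws(lat_s)); lon <- as.numeric(trimws(lon_s))
  unc_s <- get_field(record, "coordinateUncertaintyInMeters")
  note <- ""
  unc <- suppressWarnings(as.numeric(trimws(unc_s %||% "")))
  if (is_missing_value(unc_s) || is.na(unc) || unc < 0) {
    unc <- 0
    note <- "; uncertainty missing, treated as 0 m"
  }
  inside <- point_in_polygons(lon, lat, rings)
  if (inside)
    return(measure_result("COMPLETED", qualitative = "CONSISTENT",
                          detail = paste0("point inside country boundary",
                                          note)))
  d <- distance_to_boundary_m(lon, lat, rings)
  if (d <= unc)
    measure_result("COMPLETED", qualitative = "CONSISTENT",
                   detail = sprintf(
                     "point %.1f m outside boundary, within %.1f m radius%s",
                     d, unc, note))
  else
    measure_result("COMPLETED", qualitative = "NOT_CONSISTENT",
                   detail = sprintf(
                     "point %.1f m outside boundary, beyond %.1f m radius%s",
                     d, unc, note))
}

# --- criterion validation ---------------------------------------------------

#' Validate a measure against a criterion
#'
#' A quantitative measure is compared to the criterion's numeric threshold
#' with its comparator; a qualitative measure is `COMPLIANT` iff it equals
#' the required value. A `PREREQUISITES_NOT_MET` measure propagates to a
#' `PREREQUISITES_NOT_MET` validation.
#'
#' @param measure a `dq_measure_result`.
#' @param criterion a [dq_criterion()].
#' @return a `dq_validation_result`.
#' @export
validate_against_criterion <- function(measure, criterion) {
  if (measure$status == "PREREQUISITES_NOT_MET")
    return(validation_result("PREREQUISITES_NOT_MET"))
  if (!is.null(measure$quantitative)) {
    if (!is.numeric(criterion$threshold))
      stop("configuration error: quantitative measure vs qualitative threshold for criterion '",
           criterion$id, "'", call. = FALSE)
    ok <- switch(criterion$comparator,
                 EQ = measure$quantitative == criterion$threshold,
                 GE = measure$quantitative >= criterion$threshold,
                 LE = measure$quantitative <= criterion$threshold,
                 GT = measure$quantitative > criterion$threshold,
                 LT = measure$quantitative < criterion$threshold)
  } else {
    if (!is.character(criterion$threshold))
      stop("configuration error: qualitative measure vs numeric threshold for criterion '",
           criterion$id, "'", call. = FALSE)
    if (criterion$comparator != "EQ")
      stop("configuration error: qualitative measures support only EQ",
           call. = FALSE)
    ok <- identical(measure$qualitative, criterion$threshold)
  }
  validation_result("COMPLETED",
                    outcome = if (ok) "COMPLIANT" else "NOT_COMPLIANT")
}

# --- amendments -------------------------------------------------------------

blank_in_record <- function(record, term) {
  term %in% names(record) && is_missing_value(record[[term]])
}

#' Propose filling the taxon hierarchy from the most specific name
#'
#' Finds the most specific (lowest-rank) provided name resolvable in the
#' reference taxonomy, walks its parent links, and proposes values only for
#' rank fields that are declared in the record and blank. Non-blank fields
#' are never overwritten; a non-blank field conflicting with the derived
#' lineage is skipped and the conflict reported in the rationale.
#'
#' @param record named character vector or single-record resource.
#' @param reference a [reference_data()] with a taxonomy table.
#' @return a `dq_amendment_result`; `PREREQUISITES_NOT_MET` when no provided
#'   name resolves or a name is ambiguous in the taxonomy.
#' @export
amend_fill_taxon_hierarchy <- function(record, reference) {
  record <- as_single_record(record)
  tax <- reference$taxonomy
  if (is.null(tax) || nrow(tax) == 0L)
    return(amendment_result("PREREQUISITES_NOT_MET",
                            rationale = "no taxonomy reference data"))
  # candidate names: rank-named fields plus scientificName, most specific last
  provided <- list()
  for (rk in TAXON_RANKS) {
    v <- get_field(record, rk)
    if (!is_missing_value(v)) provided[[rk]] <- trimws(v)
  }
  sn <- get_field(record, "scientificName")
  anchor <- NULL
  for (rk in rev(TAXON_RANKS)) {            # lowest rank first
    if (is.null(provided[[rk]])) next
    hits <- which(tax$name == provided[[rk]])
    if (length(hits) > 1L)
      return(amendment_result("PREREQUISITES_NOT_MET",
                              rationale = sprintf("ambiguous name '%s'",
                                                  provided[[rk]])))
    if (length(hits) == 1L) { anchor <- hits; break }
  }
  if (is.null(anchor) && !is_missing_value(sn)) {
    hits <- which(tax$name == trimws(sn))
    if (length(hits) > 1L)
      return(amendment_result("PREREQUISITES_NOT_MET",
                              rationale = sprintf("ambiguous name '%s'", sn)))
    if (length(hits) == 1L) anchor <- hits
  }
  if (is.null(anchor))
    return(amendment_result("PREREQUISITES_NOT_MET",
                            rationale = "no provided name found in taxonomy"))
  # walk parent links to the root, collecting rank -> name
  lineage <- character()
  i <- anchor
  repeat {
    lineage[[tax$rank[i]]] <- tax$name[i]
    p <- tax$parent[i]
    if (is.na(p) || !nzchar(p)) break
    i <- which(tax$name == p)[1L]
    if (is.na(i)) break
  }
  proposals <- character()
  conflicts <- character()
  anchor_rank <- match(tax$rank[anchor], TAXON_RANKS)
  for (rk in TAXON_RANKS[seq_len(anchor_rank - 1L)]) {
    if (!(rk %in% names(lineage))) next
    if (blank_in_record(record, rk)) {
      proposals[[rk]] <- lineage[[rk]]
    } else if (rk %in% names(record) &&
               trimws(record[[rk]]) != lineage[[rk]]) {
      conflicts <- c(conflicts,
                     sprintf("%s '%s' conflicts with lineage '%s'",
                             rk, record[[rk]], lineage[[rk]]))
    }
  }
  rationale <- sprintf("lineage derived from %s '%s'",
                       tax$rank[anchor], tax$name[anchor])
  if (length(conflicts))
    rationale <- paste(rationale, paste(conflicts, collapse = "; "),
                       sep = "; ")
  if (length(proposals) == 0L)
    amendment_result("NOT_PROPOSED", rationale = rationale)
  else
    amendment_result("PROPOSED", proposed_changes = proposals,
                     rationale = rationale)
}

#' Propose a country name from coordinates
#'
#' When the point falls inside exactly one country's polygons: proposes that
#' name for a blank country field, or a `RECOMMENDATION`-flagged replacement
#' when the field is filled with a different name. A matching filled field,
#' or a point inside no boundary, yields `NOT_PROPOSED`.
#'
#' @param record named character vector or single-record resource.
#' @param reference a [reference_data()] with country boundaries.
#' @return a `dq_amendment_result`; `PREREQUISITES_NOT_MET` when the
#'   coordinates do not parse or are out of range.
#' @export
amend_country_from_coordinates <- function(record, reference) {
  record <- as_single_record(record)
  lat_s <- get_field(record, "decimalLatitude")
  lon_s <- get_field(record, "decimalLongitude")
  if (!check_latitude_range(lat_s) || !check_longitude_range(lon_s))
    return(amendment_result("PREREQUISITES_NOT_MET",
                            rationale = "coordinates absent, non-numeric or out of range"))
  lat <- as.numeric(trimws(lat_s)); lon <- as.numeric(trimws(lon_s))
  containing <- names(reference$boundaries)[
    vapply(reference$boundaries,
           function(rings) point_in_polygons(lon, lat, rings), logical(1))]
  if (length(containing) == 0L)
    return(amendment_result("NOT_PROPOSED",
                            rationale = "no containing boundary"))
  if (length(containing) > 1L)
    return(amendment_result("NOT_PROPOSED",
                            rationale = paste("point inside multiple boundaries:",
                                              paste(containing, collapse = ", "))))
  hit <- containing[[1L]]
  country <- get_country_field(record)
  if (is_missing_value(country$value))
    return(amendment_result("PROPOSED",
                            proposed_changes = stats::setNames(hit, country$term),
                            rationale = "country derived from coordinates"))
  if (tolower(trimws(country$value)) == tolower(hit))
    return(amendment_result("NOT_PROPOSED",
                            rationale = "stated country matches coordinates"))
  amendment_result("PROPOSED",
                   proposed_changes = stats::setNames(hit, country$term),
                   rationale = sprintf(
                     "stated country '%s' differs from containing boundary '%s'",
                     country$value, hit),
                   flag = "RECOMMENDATION")
}

normalize_locality <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Propose coordinates from an exact gazetteer match of the locality
#'
#' The locality string is case-folded and whitespace-collapsed, then looked
#' up exactly in the gazetteer; a hit proposes latitude, longitude and
#' uncertainty for records whose coordinates are blank.
#'
#' @param record named character vector or single-record resource.
#' @param reference a [reference_data()] with a gazetteer table.
#' @return a `dq_amendment_result`; `NOT_PROPOSED` when the locality is
#'   absent, the coordinates are already filled, or there is no exact match.
#' @export
amend_coordinates_from_locality <- function(record, reference) {
  record <- as_single_record(record)
  gaz <- reference$gazetteer
  loc <- get_field(record, "locality")
  if (is_missing_value(loc))
    return(amendment_result("NOT_PROPOSED", rationale = "no locality provided"))
  lat_blank <- is_missing_value(get_field(record, "decimalLatitude"))
  lon_blank <- is_missing_value(get_field(record, "decimalLongitude"))
  if (!lat_blank && !lon_blank)
    return(amendment_result("NOT_PROPOSED",
                            rationale = "coordinates already present"))
  if (is.null(gaz) || nrow(gaz) == 0L)
    return(amendment_result("PREREQUISITES_NOT_MET",
                            rationale = "no gazetteer reference data"))
  hit <- which(normalize_locality(gaz$locality) == normalize_locality(loc))
  if (length(hit) == 0L)
    return(amendment_result("NOT_PROPOSED",
                            rationale = sprintf("locality '%s' not in gazetteer",
                                                loc)))
  g <- gaz[hit[[1L]], ]
  amendment_result(
    "PROPOSED",
    proposed_changes = c(
      decimalLatitude = as.character(g$decimalLatitude),
      decimalLongitude = as.character(g$decimalLongitude),
      coordinateUncertaintyInMeters =
        as.character(g$coordinateUncertaintyInMeters)),
    rationale = sprintf("exact gazetteer match for '%s'", loc))
}

#' Suggest similar accepted scientific names
#'
#' All accepted names within a Levenshtein distance bound of the input,
#' sorted by (distance, name) and truncated; an exact match appears at rank
#' 1 with distance 0. Intended as a prevention aid ("suggest while typing").
#'
#' @param value the (possibly misspelled) name.
#' @param reference a [reference_data()] with accepted names.
#' @param max_distance maximum edit distance (>= 0).
#' @param limit maximum number of suggestions (>= 1).
#' @return data.frame with columns `candidate`, `distance`, `rank_position`.
#' @export
suggest_scientific_names <- function(value, reference, max_distance = 2L,
                                     limit = 5L) {
  stopifnot(max_distance >= 0, limit >= 1)
  names <- reference$accepted_names
  if (length(names) == 0L || is_missing_value(value))
    return(data.frame(candidate = character(), distance = integer(),
                      rank_position = integer(), stringsAsFactors = FALSE))
  d <- as.integer(utils::adist(value, names))
  keep <- which(d <= max_distance)
  keep <- keep[order(d[keep], names[keep])]
  keep <- utils::head(keep, limit)
  data.frame(candidate = names[keep], distance = d[keep],
             rank_position = seq_along(keep), stringsAsFactors = FALSE)
}

# Prevention-type wrapper used by the engine: reports close accepted names
# for a misspelled scientificName as a suggestion-only amendment (never
# auto-applied).
amend_suggest_name <- function(record, reference, max_distance = 2L) {
  record <- as_single_record(record)
  sn <- get_field(record, "scientificName")
  if (is_missing_value(sn))
    return(amendment_result("PREREQUISITES_NOT_MET",
                            rationale = "no scientificName provided"))
  if (trimws(sn) %in% reference$accepted_names)
    return(amendment_result("NOT_PROPOSED",
                            rationale = "name already accepted"))
  sug <- suggest_scientific_names(trimws(sn), reference,
                                  max_distance = max_distance, limit = 3L)
  if (nrow(sug) == 0L)
    return(amendment_result("NOT_PROPOSED",
                            rationale = "no accepted name within edit-distance bound"))
  amendment_result("PROPOSED",
                   proposed_changes = c(scientificName = sug$candidate[[1L]]),
                   rationale = paste("suggestions:",
                                     paste(sprintf("%s (d=%d)", sug$candidate,
                                                   sug$distance),
                                           collapse = ", ")),
                   flag = "SUGGESTION")
}
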