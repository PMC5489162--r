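# The evaluation engine: a mechanism registry keyed by specification id,
# report generation following the profile-to-status mapping (one measure per
# dimension, one validation per criterion, one amendment per enhancement per
# applicable record), assurance filtering and control amendment.

DQ_ENGINE_VERSION <- "0.1.0"

#' Create a mechanism registry
#'
#' Maps specification ids to a mechanism descriptor plus a callable
#' implementation. Implementations receive
#' `(resource, ie, reference, params)` where `resource` is a single-record
#' or dataset `dq_data_resource` and return the matching result type.
#'
#' @param reference a [reference_data()] shared by all mechanisms.
#' @param specifications list of [dq_specification()] known to the registry.
#' @param mechanisms list of [dq_mechanism()] descriptors.
#' @return an empty `dq_registry`; add implementations with
#'   [register_mechanism()].
#' @export
mechanism_registry <- function(reference = reference_data(),
                               specifications = list(),
                               mechanisms = list()) {
  structure(list(entries = list(), reference = reference,
                 specifications = specifications, mechanisms = mechanisms),
            class = "dq_registry")
}

#' Register an implementation for a specification
#'
#' @param registry a `dq_registry`.
#' @param specification a [dq_specification()] (or its id, if already known).
#' @param mechanism the [dq_mechanism()] descriptor executing it.
#' @param fn implementation `function(resource, ie, reference, params)`.
#' @return the updated registry.
#' @export
register_mechanism <- function(registry, specification, mechanism, fn) {
  if (inherits(specification, "dq_specification")) {
    registry$specifications[[specification$id]] <- specification
    spec_id <- specification$id
  } else spec_id <- specification
  registry$mechanisms[[mechanism$id]] <- mechanism
  registry$entries[[spec_id]] <- list(mechanism = mechanism, fn = fn)
  registry
}

registry_resolves <- function(registry, spec_id) {
  !is.null(registry$entries[[spec_id]])
}

#' The built-in mechanism catalogue as a registry
#'
#' Registers specifications for field completeness, the four coordinate
#' conformity sub-checks and their broad composition, point-radius country
#' consistency, taxon-hierarchy backfill, country-from-coordinates,
#' gazetteer coordinate lookup, and scientific-name suggestion.
#'
#' @param reference a [reference_data()].
#' @return a populated `dq_registry`.
#' @export
builtin_registry <- function(reference = reference_data()) {
  reg <- mechanism_registry(reference)

  m_complete <- dq_mechanism("builtin/completeness-checker",
                             "Field-presence checker", "SPECIFIC",
                             implements = "completeness")
  reg <- register_mechanism(
    reg,
    dq_specification("completeness",
      "A record is COMPLETE for an information element iff every term has a non-blank value; over a dataset, the proportion of complete records."),
    m_complete,
    function(resource, ie, reference, params) {
      if (resource$resource_type == "DATASET")
        measure_completeness_dataset(resource, ie)
      else measure_completeness_record(resource, ie)
    })

  subchecks <- list(
    list("value-is-number", "Check whether each provided value is a number",
         function(x) check_value_is_number(x)),
    list("valid-characters",
         "Check whether each provided value contains only valid characters (optional sign, digits, at most one decimal point)",
         function(x) check_valid_characters(x)),
    list("latitude-range",
         "Check whether latitude is within -90 and 90, inclusive",
         function(x) check_latitude_range(x)),
    list("longitude-range",
         "Check whether longitude is within -180 and 180, inclusive",
         function(x) check_longitude_range(x)))
  sub_mech_ids <- character()
  for (sc in subchecks) {
    mech <- dq_mechanism(paste0("builtin/", sc[[1]], "-check"),
                         sc[[2]], "SPECIFIC", implements = sc[[1]])
    sub_mech_ids <- c(sub_mech_ids, mech$id)
    local({
      f <- sc[[3]]
      reg <<- register_mechanism(
        reg, dq_specification(sc[[1]], sc[[2]]), mech,
        function(resource, ie, reference, params) {
          rec <- as_single_record(resource)
          term <- if (!is.null(ie)) ie$terms[[1L]] else "decimalLatitude"
          ok <- f(get_field(rec, term))
          measure_result("COMPLETED",
                         qualitative = if (ok) "CONFORMANT" else "NOT_CONFORMANT",
                         detail = term)
        })
    })
  }

  m_coord <- dq_mechanism(
    "builtin/coordinate-suite", "Coordinate conformity and consistency suite",
    "BROAD", implements = c("coordinate-conformity", "coordinate-consistency"),
    uses = sub_mech_ids)
  reg <- register_mechanism(
    reg,
    dq_specification("coordinate-conformity",
      "Latitude and longitude must be numbers, contain no invalid characters, and lie in range (latitude -90..90, longitude -180..180, inclusive)."),
    m_coord,
    function(resource, ie, reference, params)
      measure_coordinate_conformity_record(resource))
  reg <- register_mechanism(
    reg,
    dq_specification("coordinate-consistency",
      "Consistent only if the circle around the position, with radius equal to the coordinate uncertainty in meters, intersects the area within the stated country's boundary.",
      formal_params = list(boundaries = "reference")),
    m_coord,
    function(resource, ie, reference, params)
      measure_coordinate_consistency_record(resource, reference))

  reg <- register_mechanism(
    reg,
    dq_specification("fill-taxon-hierarchy",
      "Fill in taxon hierarchy based on the most specific provided name, proposing values only for blank rank fields."),
    dq_mechanism("builtin/taxon-filler", "Taxon-hierarchy backfill",
                 "SPECIFIC", implements = "fill-taxon-hierarchy"),
    function(resource, ie, reference, params)
      amend_fill_taxon_hierarchy(resource, reference))

  m_geo <- dq_mechanism(
    "builtin/geo-amender", "Geographic amendment suite", "BROAD",
    implements = c("country-from-coordinates", "coordinates-from-locality"))
  reg <- register_mechanism(
    reg,
    dq_specification("country-from-coordinates",
      "Recommend a value for the country on the basis of the provided coordinates."),
    m_geo,
    function(resource, ie, reference, params)
      amend_country_from_coordinates(resource, reference))
  reg <- register_mechanism(
    reg,
    dq_specification("coordinates-from-locality",
      "Recommend coordinates from an exact gazetteer match of the locality description."),
    m_geo,
    function(resource, ie, reference, params)
      amend_coordinates_from_locality(resource, reference))

  reg <- register_mechanism(
    reg,
    dq_specification("name-suggestion",
      "Suggest similar and valid scientific names (prevention; suggestions are never auto-applied).",
      formal_params = list(max_distance = 2)),
    dq_mechanism("builtin/name-suggester", "Accepted-name suggester",
                 "SPECIFIC", implements = "name-suggestion"),
    function(resource, ie, reference, params)
      amend_suggest_name(resource, reference,
                         max_distance = params$max_distance %||% 2L))
  reg
}

record_ref <- function(resource, row_id) {
  rec <- resource$records[[row_id + 1L]]
  occ <- if ("occurrenceID" %in% names(rec)) rec[["occurrenceID"]]
         else NA_character_
  list(resource = resource$id, row_id = row_id, occurrence_id = occ)
}

single_record_resource <- function(resource, row_id) {
  dq_record(resource$records[[row_id + 1L]],
            id = resource$id, source_uri = resource$source_uri)
}

#' Generate the quality-status report for a resource under a profile
#'
#' Applies the profile's policies with the registry's mechanisms. For every
#' dimension in the measurement policy, `SINGLE_RECORD` dimensions yield one
#' measure assertion per record and `DATASET` dimensions exactly one; each
#' criterion yields validations from its dimension's measures (record-level
#' criteria validate every record); each enhancement yields one amendment
#' assertion per record, with `NOT_PROPOSED` and `PREREQUISITES_NOT_MET`
#' recorded rather than omitted. Assertions are ordered by policy order,
#' then row order.
#'
#' @param profile a valid `dq_profile`.
#' @param resource a `dq_data_resource`.
#' @param registry a `dq_registry` resolving every specification the profile
#'   references.
#' @return a `dq_report` with elements `measures`, `validations`,
#'   `amendments` (lists of `dq_assertion`), plus
#'   `record_criterion_summaries`, a derived convenience table (criterion
#'   id, n, n compliant, proportion) for record-level criteria.
#' @export
generate_report <- function(profile, resource, registry) {
  viol <- validate_profile(profile)
  if (nrow(viol) > 0L)
    stop("malformed profile: ",
         paste(sprintf("[%s/%s] %s", viol$section, viol$id, viol$rule),
               collapse = "; "), call. = FALSE)
  needed <- unique(c(
    vapply(profile$measurement_policy, `[[`, character(1),
           "specification_ref"),
    vapply(profile$enhancement_policy, `[[`, character(1),
           "specification_ref")))
  unresolved <- needed[!vapply(needed, registry_resolves,
                               logical(1), registry = registry)]
  if (length(unresolved))
    stop("unresolved specification(s): ",
         paste(unresolved, collapse = ", "), call. = FALSE)

  is_dataset <- resource$resource_type == "DATASET"
  n <- n_records(resource)
  row_ids <- if (is_dataset) seq_len(n) - 1L else integer()

  measures <- list()
  record_measures <- list()   # dim id -> list over rows
  dataset_measures <- list()  # dim id -> measure
  for (dm in profile$measurement_policy) {
    entry <- registry$entries[[dm$specification_ref]]
    ie <- profile_lookup(profile$information_elements, dm$ie_ref)
    params <- registry$specifications[[dm$specification_ref]]$formal_params
    if (dm$resource_type == "SINGLE_RECORD") {
      per_row <- vector("list", max(n, 1L))
      if (is_dataset) {
        for (rid in row_ids) {
          res <- entry$fn(single_record_resource(resource, rid), ie,
                          registry$reference, params)
          per_row[[rid + 1L]] <- res
          measures[[length(measures) + 1L]] <- build_assertion(
            dm$id, "dimension", dm$specification_ref, entry$mechanism$id,
            record_ref(resource, rid), res)
        }
      } else {
        res <- entry$fn(resource, ie, registry$reference, params)
        per_row[[1L]] <- res
        measures[[length(measures) + 1L]] <- build_assertion(
          dm$id, "dimension", dm$specification_ref, entry$mechanism$id,
          list(resource = resource$id, row_id = NA_integer_), res)
      }
      record_measures[[dm$id]] <- per_row
    } else {
      ds <- if (is_dataset) resource
            else dq_dataset(list(resource$record), id = resource$id)
      res <- entry$fn(ds, ie, registry$reference, params)
      dataset_measures[[dm$id]] <- res
      measures[[length(measures) + 1L]] <- build_assertion(
        dm$id, "dimension", dm$specification_ref, entry$mechanism$id,
        list(resource = resource$id, row_id = NA_integer_), res)
    }
  }

  validations <- list()
  summaries <- list()
  for (cr in profile$validation_policy) {
    dm <- profile_lookup(profile$measurement_policy, cr$dimension_ref)
    entry <- registry$entries[[dm$specification_ref]]
    if (dm$resource_type == "SINGLE_RECORD") {
      outcomes <- record_measures[[dm$id]]
      n_comp <- 0L
      if (is_dataset) {
        for (rid in row_ids) {
          vres <- validate_against_criterion(outcomes[[rid + 1L]], cr)
          if (identical(vres$outcome, "COMPLIANT")) n_comp <- n_comp + 1L
          validations[[length(validations) + 1L]] <- build_assertion(
            cr$id, "criterion", dm$specification_ref, entry$mechanism$id,
            record_ref(resource, rid), vres)
        }
        summaries[[length(summaries) + 1L]] <- data.frame(
          criterion_id = cr$id, n = n, n_compliant = n_comp,
          proportion_compliant = if (n > 0L) n_comp / n else NA_real_,
          stringsAsFactors = FALSE)
      } else {
        vres <- validate_against_criterion(outcomes[[1L]], cr)
        validations[[length(validations) + 1L]] <- build_assertion(
          cr$id, "criterion", dm$specification_ref, entry$mechanism$id,
          list(resource = resource$id, row_id = NA_integer_), vres)
      }
    } else {
      vres <- validate_against_criterion(dataset_measures[[dm$id]], cr)
      validations[[length(validations) + 1L]] <- build_assertion(
        cr$id, "criterion", dm$specification_ref, entry$mechanism$id,
        list(resource = resource$id, row_id = NA_integer_), vres)
    }
  }

  amendments <- list()
  for (en in profile$enhancement_policy) {
    entry <- registry$entries[[en$specification_ref]]
    params <- registry$specifications[[en$specification_ref]]$formal_params
    if (is_dataset) {
      for (rid in row_ids) {
        ares <- entry$fn(single_record_resource(resource, rid), NULL,
                         registry$reference, params)
        amendments[[length(amendments) + 1L]] <- build_assertion(
          en$id, "enhancement", en$specification_ref, entry$mechanism$id,
          record_ref(resource, rid), ares)
      }
    } else {
      ares <- entry$fn(resource, NULL, registry$reference, params)
      amendments[[length(amendments) + 1L]] <- build_assertion(
        en$id, "enhancement", en$specification_ref, entry$mechanism$id,
        list(resource = resource$id, row_id = NA_integer_), ares)
    }
  }

  structure(
    list(profile_ref = profile$id, resource_ref = resource$id,
         n_records = n,
         measures = measures, validations = validations,
         amendments = amendments,
         record_criterion_summaries =
           if (length(summaries)) do.call(rbind, summaries)
           else data.frame(criterion_id = character(), n = integer(),
                           n_compliant = integer(),
                           proportion_compliant = numeric(),
                           stringsAsFactors = FALSE),
         generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         engine_version = DQ_ENGINE_VERSION),
    class = "dq_report")
}

#' Aggregate qualitative record outcomes into a dataset proportion
#'
#' @param outcomes list of record-level `dq_measure_result`s.
#' @param positive_value the qualitative value counted as positive
#'   (e.g. `"COMPLETE"`). `PREREQUISITES_NOT_MET` outcomes count as not
#'   positive: unassessable records are not demonstrably fit.
#' @return a quantitative `dq_measure_result`; `PREREQUISITES_NOT_MET` for
#'   an empty list.
#' @export
aggregate_record_outcomes <- function(outcomes, positive_value) {
  n <- length(outcomes)
  if (n == 0L)
    return(measure_result("PREREQUISITES_NOT_MET", detail = "no outcomes"))
  k <- sum(vapply(outcomes, function(o)
    identical(o$qualitative, positive_value), logical(1)))
  measure_result("COMPLETED", quantitative = k / n,
                 detail = sprintf("%d of %d records %s", k, n, positive_value))
}

record_level_criteria <- function(profile) {
  Filter(function(cr) {
    dm <- profile_lookup(profile$measurement_policy, cr$dimension_ref)
    !is.null(dm) && dm$resource_type == "SINGLE_RECORD"
  }, profile$validation_policy)
}

#' Filter a dataset to its fit-for-use subset (quality assurance)
#'
#' Retains exactly the records whose record-level validations in the report
#' are all `COMPLIANT`; records with any `NOT_COMPLIANT` or
#' `PREREQUISITES_NOT_MET` validation are excluded and logged with the
#' failing criterion ids. Dataset-level criteria never remove individual
#' records.
#'
#' @param dataset the dataset the report was generated from.
#' @param profile the profile the report was generated under.
#' @param report the `dq_report`.
#' @return list with `retained` (a `dq_data_resource` preserving row order),
#'   `retained_row_ids` (original 0-based ids) and `exclusions` (data.frame
#'   `row_id`, `failed_criteria`).
#' @export
filter_fit_for_use <- function(dataset, profile, report) {
  stopifnot(dataset$resource_type == "DATASET")
  n <- n_records(dataset)
  rec_crit_ids <- ids_of(record_level_criteria(profile))
  failures <- rep(list(character()), n)
  for (a in report$validations) {
    if (!(a$element_ref %in% rec_crit_ids)) next
    rid <- a$resource_ref$row_id
    if (is.na(rid) || rid < 0L || rid >= n)
      stop("report/dataset mismatch: unknown row id ", rid, call. = FALSE)
    ok <- identical(a$result$outcome, "COMPLIANT")
    if (!ok)
      failures[[rid + 1L]] <- c(failures[[rid + 1L]], a$element_ref)
  }
  keep <- vapply(failures, function(f) length(f) == 0L, logical(1))
  excl <- data.frame(
    row_id = which(!keep) - 1L,
    failed_criteria = vapply(failures[!keep], paste,
                             character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  list(retained = dq_dataset(dataset$records[keep], id = dataset$id,
                             source_uri = dataset$source_uri),
       retained_row_ids = which(keep) - 1L,
       exclusions = excl)
}

#' Create an amendment-acceptance policy
#'
#' @param mode `"accept_all"`, `"accept_types"` (then `types` decides) or
#'   `"interactive_list"` (apply nothing; list proposals for review).
#'   Prevention-type enhancements are never applied regardless of mode.
#' @param types subset of `c("CORRECTION", "RECOMMENDATION")` accepted when
#'   `mode = "accept_types"`.
#' @param audit emit a changelog (always produced; flag retained for
#'   symmetry with external policy documents).
#' @return a `dq_amendment_policy`.
#' @export
amendment_policy <- function(mode = c("accept_all", "accept_types",
                                      "interactive_list"),
                             types = character(), audit = TRUE) {
  mode <- match.arg(mode)
  types <- intersect(toupper(types), c("CORRECTION", "RECOMMENDATION"))
  structure(list(mode = mode, types = types, audit = audit),
            class = "dq_amendment_policy")
}

#' Apply accepted amendment proposals to a dataset (quality control)
#'
#' Returns a new dataset in which accepted proposals replace field values;
#' the original is untouched. Proposals are applied against the original
#' data (no chaining between enhancements within one report); conflicting
#' proposals for the same (row, field) with different values are both
#' dropped and logged as conflicts.
#'
#' @param dataset the dataset the report was generated from.
#' @param report the `dq_report` containing amendment assertions.
#' @param policy a [amendment_policy()].
#' @param profile the profile (used to look up enhancement types); when
#'   omitted, all proposals are treated as corrections.
#' @return list with `amended` (new `dq_data_resource`), `changelog`
#'   (data.frame `row_id`, `field`, `old`, `new`, `enhancement_id`),
#'   `conflicts` (data.frame `row_id`, `field`, `values`) and `proposals`
#'   (all proposal rows considered, for interactive review).
#' @export
apply_amendments <- function(dataset, report, policy = amendment_policy(),
                             profile = NULL) {
  stopifnot(dataset$resource_type == "DATASET")
  enh_type <- function(eid) {
    if (is.null(profile)) return("CORRECTION")
    e <- profile_lookup(profile$enhancement_policy, eid)
    if (is.null(e)) "CORRECTION" else e$enhancement_type
  }
  rows <- list()
  for (a in report$amendments) {
    if (a$result$status != "PROPOSED") next
    etype <- enh_type(a$element_ref)
    if (etype == "PREVENTION") next       # suggestions only, never applied
    accepted <- switch(policy$mode,
                       accept_all = TRUE,
                       accept_types = etype %in% policy$types,
                       interactive_list = FALSE)
    for (f in names(a$result$proposed_changes))
      rows[[length(rows) + 1L]] <- data.frame(
        row_id = a$resource_ref$row_id, field = f,
        new = a$result$proposed_changes[[f]],
        enhancement_id = a$element_ref, accepted = accepted,
        stringsAsFactors = FALSE)
  }
  proposals <- if (length(rows)) do.call(rbind, rows)
               else data.frame(row_id = integer(), field = character(),
                               new = character(), enhancement_id = character(),
                               accepted = logical(), stringsAsFactors = FALSE)
  records <- dataset$records
  changelog <- list(); conflicts <- list()
  acc <- proposals[proposals$accepted, , drop = FALSE]
  if (nrow(acc) > 0L) {
    key <- paste(acc$row_id, acc$field, sep = "\r")
    for (k in unique(key)) {
      grp <- acc[key == k, , drop = FALSE]
      if (length(unique(grp$new)) > 1L) {
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          row_id = grp$row_id[[1L]], field = grp$field[[1L]],
          values = paste(unique(grp$new), collapse = "|"),
          stringsAsFactors = FALSE)
        next
      }
      rid <- grp$row_id[[1L]]; f <- grp$field[[1L]]
      old <- if (f %in% names(records[[rid + 1L]]))
        records[[rid + 1L]][[f]] else NA_character_
      records[[rid + 1L]][[f]] <- grp$new[[1L]]
      changelog[[length(changelog) + 1L]] <- data.frame(
        row_id = rid, field = f, old = old, new = grp$new[[1L]],
        enhancement_id = paste(unique(grp$enhancement_id), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  empty_log <- data.frame(row_id = integer(), field = character(),
                          old = character(), new = character(),
                          enhancement_id = character(),
                          stringsAsFactors = FALSE)
  list(amended = dq_dataset(records, id = dataset$id,
                            source_uri = dataset$source_uri),
       changelog = if (length(changelog)) do.call(rbind, changelog)
                   else empty_log,
       conflicts = if (length(conflicts)) do.call(rbind, conflicts)
                   else data.frame(row_id = integer(), field = character(),
                                   values = character(),
                                   stringsAsFactors = FALSE),
       proposals = proposals)
}

assertion_status_counts <- function(assertions, field = "status") {
  st <- vapply(assertions, function(a) a$result$status, character(1))
  table(st)
}

#' @export
print.dq_report <- function(x, ...) {
  cat("Data-quality status report\n")
  cat("  Profile: ", x$profile_ref, "   Resource: ", x$resource_ref,
      " (", x$n_records, " record(s))\n", sep = "")
  cat("  Measures: ", length(x$measures),
      "  Validations: ", length(x$validations),
      "  Amendments: ", length(x$amendments), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dq_report <- function(object, ...) {
  out <- list(
    profile = object$profile_ref,
    resource = object$resource_ref,
    n_records = object$n_records,
    measure_status = assertion_status_counts(object$measures),
    validation_outcomes = table(vapply(object$validations, function(a)
      a$result$outcome %||% a$result$status, character(1))),
    amendment_status = assertion_status_counts(object$amendments),
    record_criterion_summaries = object$record_criterion_summaries)
  class(out) <- "summary.dq_report"
  out
}

#' @export
print.summary.dq_report <- function(x, ...) {
  cat("Report for profile '", x$profile, "' on '", x$resource, "' (",
      x$n_records, " records)\n", sep = "")
  cat("Measures by status:\n"); print(x$measure_status)
  cat("Validations by outcome:\n"); print(x$validation_outcomes)
  cat("Amendments by status:\n"); print(x$amendment_status)
  if (nrow(x$record_criterion_summaries)) {
    cat("Record-level criterion summaries (derived):\n")
    print(x$record_criterion_summaries)
  }
  invisible(x)
}
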