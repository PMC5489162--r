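# Domain types for the data-quality framework: use case, information
# element, contextualized dimension / criterion / enhancement, specification,
# mechanism, data resource, results, assertion, profile.

DQ_DIMENSIONS_KNOWN <- c("COMPLETENESS", "CONFORMITY", "CONSISTENCY")
DQ_RESOURCE_TYPES <- c("SINGLE_RECORD", "DATASET")
DQ_COMPARATORS <- c("EQ", "GE", "LE", "GT", "LT")
DQ_ENHANCEMENT_TYPES <- c("PREVENTION", "CORRECTION", "RECOMMENDATION")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Test whether a field value counts as missing
#'
#' A value is missing when it is `NULL`/`NA`, or when its text, after
#' trimming whitespace, is empty or equals (case-insensitively) one of
#' `"NULL"`, `"NA"`, `"N/A"` — the sentinels that dominate real occurrence
#' exports.
#'
#' @param x a value (length-one character or `NULL`/`NA`).
#' @return `TRUE` if the value counts as missing.
#' @export
is_missing_value <- function(x) {
  if (is.null(x) || length(x) == 0L) return(TRUE)
  x <- x[[1L]]
  if (is.na(x)) return(TRUE)
  v <- trimws(as.character(x))
  v == "" || toupper(v) %in% c("NULL", "NA", "N/A")
}

chk_id <- function(id, what) {
  if (!is.character(id) || length(id) != 1L || is.na(id))
    stop(what, ": id must be a single string", call. = FALSE)
  id
}

#' Create a use case
#'
#' A use case is the data-use story that delimits the scope of every quality
#' need: quality is always fitness for *this* use, never absolute.
#'
#' @param id caller-supplied identifier (the package never invents ids).
#' @param label short display text.
#' @param description free-text data-use story.
#' @param stakeholder_notes optional notes from curators or other
#'   stakeholders.
#' @return a `dq_use_case` object.
#' @export
dq_use_case <- function(id, label = id, description = "",
                        stakeholder_notes = NULL) {
  structure(
    list(id = chk_id(id, "use case"), label = label,
         description = description, stakeholder_notes = stakeholder_notes),
    class = "dq_use_case")
}

#' Create an information element
#'
#' An information element (IE) names a single record field or a composed set
#' of fields that carries meaning for a use case — e.g. "coordinates" composed
#' of decimalLatitude, decimalLongitude, coordinateUncertaintyInMeters and
#' geodeticDatum.
#'
#' @param id identifier.
#' @param terms ordered character vector of record field names.
#' @param label display text.
#' @param kind `"SINGLE"` or `"COMPOSED"`; derived from `length(terms)` when
#'   omitted.
#' @param description free text.
#' @return a `dq_information_element` object.
#' @export
dq_information_element <- function(id, terms, label = id, kind = NULL,
                                   description = "") {
  chk_id(id, "information element")
  terms <- as.character(terms)
  if (is.null(kind)) kind <- if (length(terms) > 1L) "COMPOSED" else "SINGLE"
  if (!kind %in% c("SINGLE", "COMPOSED"))
    stop("information element kind must be SINGLE or COMPOSED", call. = FALSE)
  structure(
    list(id = id, label = label, kind = kind, terms = terms,
         description = description),
    class = "dq_information_element")
}

#' Create a contextualized dimension
#'
#' A quality dimension (completeness, conformity, consistency, or any named
#' measurable attribute) bound to an information element and a resource type.
#' `SINGLE_RECORD` dimensions are measured qualitatively per record;
#' `DATASET` dimensions quantitatively as a proportion in \[0, 1\].
#'
#' @param id identifier.
#' @param dimension dimension name (uppercased); `COMPLETENESS`,
#'   `CONFORMITY` and `CONSISTENCY` are built in, other names are allowed.
#' @param information_element id of the IE this dimension measures.
#' @param resource_type `"SINGLE_RECORD"` or `"DATASET"`.
#' @param specification id of the specification describing the measurement
#'   method (resolved through a mechanism registry at evaluation time).
#' @return a `dq_dimension` object.
#' @export
dq_dimension <- function(id, dimension, information_element, resource_type,
                         specification) {
  chk_id(id, "dimension")
  resource_type <- match.arg(resource_type, DQ_RESOURCE_TYPES)
  structure(
    list(id = id, dimension = toupper(dimension),
         ie_ref = information_element, resource_type = resource_type,
         specification_ref = specification),
    class = "dq_dimension")
}

#' Create a contextualized criterion
#'
#' A pass/fail rule over one dimension's measure: for `DATASET` dimensions a
#' comparator and numeric threshold on the proportion scale; for
#' `SINGLE_RECORD` dimensions the required qualitative value (comparator
#' `EQ`).
#'
#' @param id identifier.
#' @param statement human-readable rule, e.g. "coordinate completeness of a
#'   dataset must be equal to 100%".
#' @param dimension id of the dimension (must belong to the same profile's
#'   measurement policy).
#' @param comparator one of `EQ`, `GE`, `LE`, `GT`, `LT`.
#' @param threshold numeric proportion in \[0,1\] (dataset dimensions) or
#'   required qualitative value (record dimensions). Strings like `"100%"`
#'   are normalized to proportions.
#' @return a `dq_criterion` object.
#' @export
dq_criterion <- function(id, statement, dimension, comparator, threshold) {
  chk_id(id, "criterion")
  comparator <- match.arg(toupper(comparator), DQ_COMPARATORS)
  structure(
    list(id = id, statement = statement, dimension_ref = dimension,
         comparator = comparator, threshold = parse_threshold(threshold)),
    class = "dq_criterion")
}

# "100%" and "1.0" both mean proportion 1; numbers pass through, percent
# strings are divided by 100, qualitative strings are kept verbatim.
parse_threshold <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.character(x) && length(x) == 1L) {
    v <- trimws(x)
    if (grepl("^[+-]?[0-9.]+%$", v)) return(as.numeric(sub("%$", "", v)) / 100)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num) && grepl("^[+-]?[0-9.]+$", v)) return(num)
    return(v)
  }
  x
}

#' Create a contextualized enhancement
#'
#' A described improvement activity targeting one or more measured
#' dimensions. `PREVENTION` enhancements only produce suggestions and are
#' never applied to data; `CORRECTION` and `RECOMMENDATION` produce proposed
#' amendments a curator may accept.
#'
#' @param id identifier.
#' @param statement human-readable description.
#' @param type `"PREVENTION"`, `"CORRECTION"` or `"RECOMMENDATION"`.
#' @param target_dimensions ids of the measurement-policy dimensions whose
#'   measures this enhancement can improve.
#' @param specification id of the specification describing the method.
#' @return a `dq_enhancement` object.
#' @export
dq_enhancement <- function(id, statement, type, target_dimensions,
                           specification) {
  chk_id(id, "enhancement")
  type <- match.arg(toupper(type), DQ_ENHANCEMENT_TYPES)
  structure(
    list(id = id, statement = statement, enhancement_type = type,
         target_dimension_refs = as.character(target_dimensions),
         specification_ref = specification),
    class = "dq_enhancement")
}

#' Create a specification
#'
#' The (at minimum informal) description of a measurement, validation or
#' enhancement method, with optional formal parameters.
#'
#' @param id identifier.
#' @param human_text mandatory free-text method description.
#' @param formal_params named list of parameters (tolerances, reference-data
#'   ids, ranges); may be empty.
#' @return a `dq_specification` object.
#' @export
dq_specification <- function(id, human_text, formal_params = list()) {
  chk_id(id, "specification")
  if (!is.character(human_text) || length(human_text) != 1L ||
      !nzchar(trimws(human_text)))
    stop("specification requires a non-empty human_text description",
         call. = FALSE)
  structure(list(id = id, human_text = human_text,
                 formal_params = formal_params),
            class = "dq_specification")
}

#' Create a mechanism descriptor
#'
#' A mechanism is the artifact that executes specifications. A `SPECIFIC`
#' mechanism implements exactly one specification; a `BROAD` one implements
#' several, and may delegate to (`uses`) other mechanisms.
#'
#' @param id identifier.
#' @param label display text.
#' @param coverage `"BROAD"` or `"SPECIFIC"`.
#' @param implements character vector of specification ids.
#' @param uses character vector of mechanism ids this one delegates to.
#' @return a `dq_mechanism` object.
#' @export
dq_mechanism <- function(id, label = id, coverage, implements,
                         uses = character()) {
  chk_id(id, "mechanism")
  coverage <- match.arg(toupper(coverage), c("BROAD", "SPECIFIC"))
  implements <- as.character(implements)
  if (coverage == "SPECIFIC" && length(implements) != 1L)
    stop("SPECIFIC mechanism must implement exactly one specification",
         call. = FALSE)
  if (coverage == "BROAD" && length(implements) < 2L)
    stop("BROAD mechanism must implement at least two specifications",
         call. = FALSE)
  structure(list(id = id, label = label, coverage = coverage,
                 implements = implements, uses = as.character(uses)),
            class = "dq_mechanism")
}

#' Create a single-record data resource
#'
#' Field values are kept verbatim as text; type coercion happens only inside
#' mechanisms.
#'
#' @param fields named character vector or named list of field values.
#' @param id resource identifier used in assertion references.
#' @param source_uri optional provenance string.
#' @return a `dq_data_resource` with `resource_type = "SINGLE_RECORD"`.
#' @export
dq_record <- function(fields, id = "record", source_uri = NULL) {
  rec <- as_record(fields)
  structure(list(resource_type = "SINGLE_RECORD", id = id, record = rec,
                 records = NULL, source_uri = source_uri),
            class = "dq_data_resource")
}

#' Create a multi-record (dataset) data resource
#'
#' @param records list of named character vectors (one per record), or a
#'   data.frame whose rows become records. Rows get stable 0-based row ids.
#' @param id resource identifier used in assertion references.
#' @param source_uri optional provenance string.
#' @return a `dq_data_resource` with `resource_type = "DATASET"`.
#' @export
dq_dataset <- function(records, id = "dataset", source_uri = NULL) {
  if (is.data.frame(records)) {
    df <- records
    records <- lapply(seq_len(nrow(df)), function(i) {
      r <- vapply(df[i, , drop = FALSE], as.character, character(1))
      names(r) <- names(df)
      r
    })
  }
  records <- lapply(records, as_record)
  structure(list(resource_type = "DATASET", id = id, record = NULL,
                 records = records, source_uri = source_uri),
            class = "dq_data_resource")
}

as_record <- function(fields) {
  if (is.list(fields))
    fields <- vapply(fields, function(v) {
      if (is.null(v) || length(v) == 0L) NA_character_ else as.character(v[[1L]])
    }, character(1))
  fields <- as.character(fields) |> stats::setNames(names(fields))
  if (length(fields) > 0L && is.null(names(fields)))
    stop("record fields must be named", call. = FALSE)
  fields
}

#' Number of records in a data resource
#' @param resource a `dq_data_resource`.
#' @return integer count (1 for a single record).
#' @export
n_records <- function(resource) {
  if (resource$resource_type == "DATASET") length(resource$records) else 1L
}

# --- assertion results ------------------------------------------------------

#' Create a measure result
#'
#' Record-level dimensions yield a qualitative value (e.g. `COMPLETE`,
#' `NOT_CONSISTENT`); dataset-level dimensions yield a quantitative
#' proportion in \[0, 1\]. `PREREQUISITES_NOT_MET` carries neither.
#'
#' @param status `"COMPLETED"` or `"PREREQUISITES_NOT_MET"`.
#' @param qualitative optional qualitative value.
#' @param quantitative optional proportion in \[0, 1\].
#' @param detail free-text detail (e.g. missing terms, sub-check outcomes).
#' @return a `dq_measure_result`.
#' @export
measure_result <- function(status, qualitative = NULL, quantitative = NULL,
                           detail = "") {
  status <- match.arg(status, c("COMPLETED", "PREREQUISITES_NOT_MET"))
  if (status == "COMPLETED") {
    if (is.null(qualitative) == is.null(quantitative))
      stop("COMPLETED measure must carry exactly one of qualitative/quantitative",
           call. = FALSE)
    if (!is.null(quantitative) &&
        (!is.numeric(quantitative) || quantitative < 0 || quantitative > 1))
      stop("quantitative measure must be a proportion in [0, 1]", call. = FALSE)
  } else if (!is.null(qualitative) || !is.null(quantitative)) {
    stop("PREREQUISITES_NOT_MET measure carries no value", call. = FALSE)
  }
  structure(list(status = status, qualitative = qualitative,
                 quantitative = quantitative, detail = detail),
            class = "dq_measure_result")
}

#' Create a validation result
#'
#' @param status `"COMPLETED"` or `"PREREQUISITES_NOT_MET"`.
#' @param outcome `"COMPLIANT"` or `"NOT_COMPLIANT"`; required iff COMPLETED.
#' @return a `dq_validation_result`.
#' @export
validation_result <- function(status, outcome = NULL) {
  status <- match.arg(status, c("COMPLETED", "PREREQUISITES_NOT_MET"))
  if ((status == "COMPLETED") != !is.null(outcome))
    stop("validation outcome present iff status is COMPLETED", call. = FALSE)
  if (!is.null(outcome))
    outcome <- match.arg(outcome, c("COMPLIANT", "NOT_COMPLIANT"))
  structure(list(status = status, outcome = outcome),
            class = "dq_validation_result")
}

#' Create an amendment result
#'
#' Proposals never mutate the source data; they are carried in the report
#' only, for a curator to accept or reject.
#'
#' @param status `"PROPOSED"`, `"NOT_PROPOSED"` or `"PREREQUISITES_NOT_MET"`.
#' @param proposed_changes named character vector of field → new value;
#'   non-empty iff PROPOSED.
#' @param rationale free text (conflicts, substitutions, suggestions).
#' @param flag optional marker, e.g. `"RECOMMENDATION"` for a proposed
#'   replacement of an already-filled field.
#' @return a `dq_amendment_result`.
#' @export
amendment_result <- function(status, proposed_changes = character(),
                             rationale = "", flag = NULL) {
  status <- match.arg(status,
                      c("PROPOSED", "NOT_PROPOSED", "PREREQUISITES_NOT_MET"))
  proposed_changes <- unlist(proposed_changes) %||% character()
  if ((status == "PROPOSED") != (length(proposed_changes) > 0L))
    stop("proposed_changes non-empty iff status is PROPOSED", call. = FALSE)
  structure(list(status = status, proposed_changes = proposed_changes,
                 rationale = rationale, flag = flag),
            class = "dq_amendment_result")
}

# --- assertion --------------------------------------------------------------

result_class_for <- c(dimension = "dq_measure_result",
                      criterion = "dq_validation_result",
                      enhancement = "dq_amendment_result")

#' Build a five-component assertion
#'
#' Every assertion carries: (1) the dimension, criterion or enhancement it
#' answers; (2) the specification of the method; (3) the mechanism that ran
#' it; (4) the data resource (dataset, or dataset + row) it targets; and
#' (5) the result. All five must be present, and the result subtype must
#' match the element subtype (dimension → measure, criterion → validation,
#' enhancement → amendment).
#'
#' @param element_ref id of the dimension/criterion/enhancement.
#' @param element_type `"dimension"`, `"criterion"` or `"enhancement"`.
#' @param specification_ref specification id.
#' @param mechanism_ref mechanism id.
#' @param resource_ref a list with `resource` (resource id), `row_id`
#'   (0-based integer or `NA` for dataset-level) and optional
#'   `occurrence_id`; a bare string is taken as a dataset-level reference.
#' @param result a `dq_measure_result`, `dq_validation_result` or
#'   `dq_amendment_result`.
#' @return an immutable `dq_assertion`.
#' @export
build_assertion <- function(element_ref, element_type, specification_ref,
                            mechanism_ref, resource_ref, result) {
  args <- list(element_ref = element_ref, element_type = element_type,
               specification_ref = specification_ref,
               mechanism_ref = mechanism_ref, resource_ref = resource_ref,
               result = result)
  nul <- vapply(args, is.null, logical(1))
  if (any(nul))
    stop("incomplete assertion: missing component(s) ",
         paste(names(args)[nul], collapse = ", "), call. = FALSE)
  element_type <- match.arg(element_type,
                            c("dimension", "criterion", "enhancement"))
  want <- result_class_for[[element_type]]
  if (!inherits(result, want))
    stop("assertion subtype mismatch: a ", element_type,
         " must carry a ", want, call. = FALSE)
  if (is.character(resource_ref))
    resource_ref <- list(resource = resource_ref, row_id = NA_integer_)
  structure(list(element_ref = element_ref, element_type = element_type,
                 specification_ref = specification_ref,
                 mechanism_ref = mechanism_ref,
                 resource_ref = resource_ref, result = result),
            class = "dq_assertion")
}

# --- profile ----------------------------------------------------------------

#' Assemble a data-quality profile
#'
#' A profile is the declarative "wish-list" for a use case: the valuable
#' information elements, the measurement policy (contextualized dimensions),
#' the validation policy (criteria over those dimensions) and the enhancement
#' policy. Use [validate_profile()] to check cross-references.
#'
#' @param use_case a [dq_use_case()].
#' @param information_elements list of [dq_information_element()].
#' @param measurement_policy list of [dq_dimension()].
#' @param validation_policy list of [dq_criterion()].
#' @param enhancement_policy list of [dq_enhancement()].
#' @param id profile identifier; defaults to the use-case id.
#' @param format_version profile schema version.
#' @return a `dq_profile`.
#' @export
dq_profile <- function(use_case, information_elements,
                       measurement_policy = list(),
                       validation_policy = list(),
                       enhancement_policy = list(),
                       id = use_case$id, format_version = "1.0") {
  structure(
    list(id = id, format_version = format_version, use_case = use_case,
         information_elements = information_elements,
         measurement_policy = measurement_policy,
         validation_policy = validation_policy,
         enhancement_policy = enhancement_policy),
    class = "dq_profile")
}

ids_of <- function(xs) vapply(xs, `[[`, character(1), "id")

profile_lookup <- function(items, id) {
  hit <- which(ids_of(items) == id)
  if (length(hit) == 0L) NULL else items[[hit[[1L]]]]
}

#' Validate a profile's structural invariants
#'
#' Checks all structural rules: non-empty unique ids per section, IE term
#' rules (a composed IE has at least two distinct terms), criteria referencing
#' declared dimensions with type-consistent thresholds, and enhancements
#' targeting declared dimensions. Violations are data, not exceptions.
#'
#' @param profile a `dq_profile`.
#' @param registry optional mechanism registry; when supplied, specification
#'   references are also resolved against it.
#' @return a data.frame with columns `section`, `id`, `rule`; zero rows iff
#'   the profile is structurally valid. Deterministic and insensitive to
#'   list order within sections.
#' @export
validate_profile <- function(profile, registry = NULL) {
  v <- list()
  bad <- function(section, id, rule)
    v[[length(v) + 1L]] <<- data.frame(section = section,
                                       id = id %||% NA_character_,
                                       rule = rule,
                                       stringsAsFactors = FALSE)
  uc <- profile$use_case
  if (is.null(uc) || is.null(uc$id) || !nzchar(trimws(uc$id %||% "")))
    bad("use_case", uc$id %||% "", "use case id must be non-empty")

  check_unique <- function(items, section) {
    ids <- ids_of(items)
    for (d in unique(ids[duplicated(ids)]))
      bad(section, d, sprintf("duplicate id '%s' within section", d))
  }
  ies <- profile$information_elements
  if (length(ies) == 0L)
    bad("information_elements", NA_character_,
        "profile must declare at least one valuable information element")
  check_unique(ies, "information_elements")
  for (ie in ies) {
    if (length(ie$terms) == 0L)
      bad("information_elements", ie$id, "terms must be non-empty")
    if (ie$kind == "COMPOSED" && length(ie$terms) < 2L)
      bad("information_elements", ie$id,
          "a COMPOSED information element requires at least two terms")
    if (ie$kind == "SINGLE" && length(ie$terms) != 1L)
      bad("information_elements", ie$id,
          "a SINGLE information element requires exactly one term")
    if (anyDuplicated(ie$terms))
      bad("information_elements", ie$id, "terms must be unique within element")
  }

  dims <- profile$measurement_policy
  check_unique(dims, "measurement_policy")
  ie_ids <- ids_of(ies)
  for (d in dims) {
    if (!(d$ie_ref %in% ie_ids))
      bad("measurement_policy", d$id,
          sprintf("dimension references undeclared information element '%s'",
                  d$ie_ref))
    if (!is.null(registry) && !registry_resolves(registry, d$specification_ref))
      bad("measurement_policy", d$id,
          sprintf("specification '%s' not resolved by the registry",
                  d$specification_ref))
  }

  crits <- profile$validation_policy
  check_unique(crits, "validation_policy")
  dim_ids <- ids_of(dims)
  for (cr in crits) {
    dm <- profile_lookup(dims, cr$dimension_ref)
    if (is.null(dm)) {
      bad("validation_policy", cr$id,
          "criterion references undeclared dimension")
      next
    }
    if (dm$resource_type == "DATASET") {
      if (!is.numeric(cr$threshold) || cr$threshold < 0 || cr$threshold > 1)
        bad("validation_policy", cr$id,
            "dataset criterion threshold must be a proportion in [0, 1]")
    } else {
      if (!is.character(cr$threshold))
        bad("validation_policy", cr$id,
            "record criterion threshold must be a qualitative value")
      else if (cr$comparator != "EQ")
        bad("validation_policy", cr$id,
            "record criterion comparator must be EQ")
    }
  }

  enhs <- profile$enhancement_policy
  check_unique(enhs, "enhancement_policy")
  for (e in enhs) {
    if (length(e$target_dimension_refs) == 0L)
      bad("enhancement_policy", e$id,
          "enhancement must target at least one dimension")
    for (tr in e$target_dimension_refs)
      if (!(tr %in% dim_ids))
        bad("enhancement_policy", e$id,
            sprintf("enhancement targets undeclared dimension '%s'", tr))
    if (!is.null(registry) && !registry_resolves(registry, e$specification_ref))
      bad("enhancement_policy", e$id,
          sprintf("specification '%s' not resolved by the registry",
                  e$specification_ref))
  }

  if (length(v) == 0L)
    return(data.frame(section = character(), id = character(),
                      rule = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, v)
  out[order(out$section, out$id, out$rule), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Resolve an information element against a record
#'
#' Looks up each term of the element in the record, in declared order. A term
#' is missing when absent from the record or when its value normalizes to
#' empty (see [is_missing_value()]).
#'
#' @param record named character vector of field values, or a single-record
#'   `dq_data_resource`.
#' @param ie a [dq_information_element()].
#' @return a data.frame with columns `term`, `value` (`NA` when missing) and
#'   `missing` (logical), one row per term in declared order.
#' @export
resolve_information_element <- function(record, ie) {
  if (inherits(record, "dq_data_resource")) {
    stopifnot(record$resource_type == "SINGLE_RECORD")
    record <- record$record
  }
  vals <- lapply(ie$terms, function(t)
    if (t %in% names(record)) record[[t]] else NULL)
  miss <- vapply(vals, is_missing_value, logical(1))
  data.frame(
    term = ie$terms,
    value = vapply(vals, function(v) if (is.null(v)) NA_character_ else v,
                   character(1)),
    missing = miss,
    stringsAsFactors = FALSE)
}

#' @export
print.dq_profile <- function(x, ...) {
  cat("Data-quality profile '", x$id, "' (format ", x$format_version, ")\n",
      sep = "")
  cat("  Use case: ", x$use_case$label, "\n", sep = "")
  cat("  Valuable information elements: ",
      paste(ids_of(x$information_elements), collapse = ", "), "\n", sep = "")
  cat("  Measurement policy: ", length(x$measurement_policy),
      " dimension(s)\n", sep = "")
  cat("  Validation policy: ", length(x$validation_policy),
      " criterion/criteria\n", sep = "")
  cat("  Enhancement policy: ", length(x$enhancement_policy),
      " enhancement(s)\n", sep = "")
  invisible(x)
}

#' @export
print.dq_assertion <- function(x, ...) {
  res <- x$result
  val <- if (inherits(res, "dq_measure_result")) {
    res$qualitative %||% res$quantitative %||% ""
  } else if (inherits(res, "dq_validation_result")) {
    res$outcome %||% ""
  } else {
    if (length(res$proposed_changes))
      paste(names(res$proposed_changes), res$proposed_changes,
            sep = "=", collapse = ", ")
    else ""
  }
  cat(sprintf("<dq_assertion %s '%s' via %s/%s on %s%s: %s%s>\n",
              x$element_type, x$element_ref, x$specification_ref,
              x$mechanism_ref, x$resource_ref$resource,
              if (!is.na(x$resource_ref$row_id %||% NA))
                paste0("[", x$resource_ref$row_id, "]") else "",
              res$status,
              if (nzchar(as.character(val)[1] %||% "")) paste0(" ", val) else ""))
  invisible(x)
}
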