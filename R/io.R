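# Readers and writers: occurrence CSV/TSV, profile YAML/JSON, report
# JSON/CSV, and reference data (GeoJSON boundaries, taxonomy and gazetteer
# CSV, accepted-name list). Readers reject malformed input with located
# messages rather than silently coercing.

PROFILE_FORMAT_MAJOR <- 1L

#' Read Darwin Core occurrence records from CSV or TSV
#'
#' The first row must be a header of term names. Values are kept verbatim as
#' text (no NA conversion, no trimming); rows get stable 0-based row ids.
#'
#' @param path file path (UTF-8 text).
#' @param delimiter `","` or `"\t"`; auto-detected from the header when
#'   `NULL`.
#' @param id resource id for the resulting dataset; defaults to the file
#'   name.
#' @return a dataset `dq_data_resource` (possibly with zero records for a
#'   header-only file).
#' @export
read_occurrences <- function(path, delimiter = NULL, id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header_line <- readLines(path, n = 1L, warn = FALSE)
  if (length(header_line) == 0L)
    stop(path, ": empty file (no header row)", call. = FALSE)
  if (is.null(delimiter)) {
    n_tab <- lengths(regmatches(header_line, gregexpr("\t", header_line)))
    n_com <- lengths(regmatches(header_line, gregexpr(",", header_line)))
    delimiter <- if (n_tab > n_com) "\t" else ","
  }
  fields_per_row <- utils::count.fields(path, sep = delimiter, quote = "\"",
                                        blank.lines.skip = FALSE,
                                        comment.char = "")
  n_col <- fields_per_row[[1L]]
  ragged <- which(fields_per_row != n_col)
  if (length(ragged))
    stop(path, ": ragged row(s) at line(s) ",
         paste(utils::head(ragged, 5L), collapse = ", "),
         " (expected ", n_col, " fields)", call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          quote = "\"", colClasses = "character",
                          check.names = FALSE, comment.char = "",
                          na.strings = character(), stringsAsFactors = FALSE)
  dup <- unique(names(df)[duplicated(names(df))])
  if (length(dup))
    stop(path, ": duplicate header name(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  dq_dataset(df, id = id, source_uri = path)
}

#' Write a dataset back to CSV
#' @param dataset a dataset `dq_data_resource`.
#' @param path output path.
#' @param delimiter field separator.
#' @return invisibly, the path.
#' @export
write_occurrences <- function(dataset, path, delimiter = ",") {
  stopifnot(dataset$resource_type == "DATASET")
  fields <- unique(unlist(lapply(dataset$records, names)))
  df <- as.data.frame(
    lapply(fields, function(f)
      vapply(dataset$records, function(r)
        if (f %in% names(r)) r[[f]] else "", character(1))),
    col.names = fields, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = TRUE, na = "")
  invisible(path)
}

# --- profiles ---------------------------------------------------------------

profile_schema <- list(
  top = c("format_version", "use_case", "information_elements",
          "measurement_policy", "validation_policy", "enhancement_policy"),
  use_case = c("id", "label", "description", "stakeholder_notes"),
  information_elements = c("id", "label", "kind", "terms", "description"),
  measurement_policy = c("id", "dimension", "information_element",
                         "resource_type", "specification"),
  validation_policy = c("id", "statement", "dimension", "comparator",
                        "threshold"),
  enhancement_policy = c("id", "statement", "type", "target_dimensions",
                         "specification"))

reject_unknown <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown key(s) at ", where, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
}

need_key <- function(x, key, where) {
  if (is.null(x[[key]]))
    stop("missing required key '", key, "' at ", where, call. = FALSE)
  x[[key]]
}

#' Read a data-quality profile from YAML or JSON
#'
#' The format is chosen by extension (`.yml`/`.yaml` vs `.json`). Unknown
#' keys are rejected with their document paths; percent strings on
#' thresholds (`"100%"`) are normalized to proportions; readers refuse
#' documents whose `format_version` has a newer major than the package
#' supports. Dangling references are not an error here — check them with
#' [validate_profile()].
#'
#' @param path profile file path.
#' @return a `dq_profile`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", path))
  doc <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else if (ext == "json")
           jsonlite::fromJSON(path, simplifyVector = FALSE)
         else stop("unsupported profile extension '.", ext,
                   "' (use .yaml/.yml or .json)", call. = FALSE)
  profile_from_document(doc, where = path)
}

profile_from_document <- function(doc, where = "profile") {
  reject_unknown(doc, profile_schema$top, where)
  fv <- as.character(need_key(doc, "format_version", where))
  major <- suppressWarnings(as.integer(sub("\\..*$", "", fv)))
  if (is.na(major))
    stop(where, ": format_version '", fv, "' is not a version string",
         call. = FALSE)
  if (major > PROFILE_FORMAT_MAJOR)
    stop(where, ": format_version ", fv,
         " is newer than the supported major ", PROFILE_FORMAT_MAJOR,
         call. = FALSE)
  ucd <- need_key(doc, "use_case", paste0(where, "/use_case"))
  reject_unknown(ucd, profile_schema$use_case, paste0(where, "/use_case"))
  uc <- dq_use_case(need_key(ucd, "id", paste0(where, "/use_case")),
                    label = ucd$label %||% ucd$id,
                    description = ucd$description %||% "",
                    stakeholder_notes = ucd$stakeholder_notes)
  section <- function(name, build) {
    items <- doc[[name]] %||% list()
    lapply(seq_along(items), function(i) {
      it <- items[[i]]
      p <- sprintf("%s/%s[%d]", where, name, i)
      reject_unknown(it, profile_schema[[name]], p)
      build(it, p)
    })
  }
  ies <- section("information_elements", function(it, p)
    dq_information_element(need_key(it, "id", p),
                           terms = as.character(unlist(need_key(it, "terms", p))),
                           label = it$label %||% it$id,
                           kind = it$kind,
                           description = it$description %||% ""))
  dims <- section("measurement_policy", function(it, p)
    dq_dimension(need_key(it, "id", p),
                 dimension = need_key(it, "dimension", p),
                 information_element = need_key(it, "information_element", p),
                 resource_type = need_key(it, "resource_type", p),
                 specification = need_key(it, "specification", p)))
  crits <- section("validation_policy", function(it, p)
    dq_criterion(need_key(it, "id", p),
                 statement = it$statement %||% "",
                 dimension = need_key(it, "dimension", p),
                 comparator = need_key(it, "comparator", p),
                 threshold = need_key(it, "threshold", p)))
  enhs <- section("enhancement_policy", function(it, p)
    dq_enhancement(need_key(it, "id", p),
                   statement = it$statement %||% "",
                   type = need_key(it, "type", p),
                   target_dimensions =
                     as.character(unlist(need_key(it, "target_dimensions", p))),
                   specification = need_key(it, "specification", p)))
  dq_profile(uc, ies, dims, crits, enhs,
             id = uc$id, format_version = fv)
}

profile_to_document <- function(profile) {
  uc <- profile$use_case
  ucd <- list(id = uc$id, label = uc$label, description = uc$description)
  if (!is.null(uc$stakeholder_notes))
    ucd$stakeholder_notes <- uc$stakeholder_notes
  list(
    format_version = profile$format_version,
    use_case = ucd,
    information_elements = lapply(profile$information_elements, function(ie)
      list(id = ie$id, label = ie$label, kind = ie$kind,
           terms = as.list(ie$terms), description = ie$description)),
    measurement_policy = lapply(profile$measurement_policy, function(d)
      list(id = d$id, dimension = d$dimension,
           information_element = d$ie_ref, resource_type = d$resource_type,
           specification = d$specification_ref)),
    validation_policy = lapply(profile$validation_policy, function(cr)
      list(id = cr$id, statement = cr$statement,
           dimension = cr$dimension_ref, comparator = cr$comparator,
           threshold = cr$threshold)),
    enhancement_policy = lapply(profile$enhancement_policy, function(e)
      list(id = e$id, statement = e$statement, type = e$enhancement_type,
           target_dimensions = as.list(e$target_dimension_refs),
           specification = e$specification_ref)))
}

#' Write a profile to YAML or JSON
#' @param profile a `dq_profile`.
#' @param path output path; format chosen by extension.
#' @return invisibly, the path.
#' @export
write_profile <- function(profile, path) {
  doc <- profile_to_document(profile)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(doc, path)
  } else if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("unsupported profile extension '.", ext, "'", call. = FALSE)
  invisible(path)
}

# --- reports ----------------------------------------------------------------

result_payload <- function(res) {
  if (inherits(res, "dq_measure_result")) {
    out <- list(type = "measure", status = res$status)
    if (!is.null(res$qualitative)) out$qualitative <- res$qualitative
    if (!is.null(res$quantitative)) out$quantitative <- res$quantitative
    out$detail <- res$detail
  } else if (inherits(res, "dq_validation_result")) {
    out <- list(type = "validation", status = res$status)
    if (!is.null(res$outcome)) out$outcome <- res$outcome
  } else {
    out <- list(type = "amendment", status = res$status)
    if (length(res$proposed_changes))
      out$proposed_changes <- as.list(res$proposed_changes)
    out$rationale <- res$rationale
    if (!is.null(res$flag)) out$flag <- res$flag
  }
  out
}

result_from_payload <- function(p) {
  switch(p$type,
    measure = measure_result(p$status, qualitative = p$qualitative,
                             quantitative =
                               if (is.null(p$quantitative)) NULL
                               else as.numeric(p$quantitative),
                             detail = p$detail %||% ""),
    validation = validation_result(p$status, outcome = p$outcome),
    amendment = amendment_result(
      p$status,
      proposed_changes = unlist(p$proposed_changes) %||% character(),
      rationale = p$rationale %||% "", flag = p$flag),
    stop("unknown result type '", p$type, "'", call. = FALSE))
}

assertion_payload <- function(a) {
  rr <- a$resource_ref
  rp <- list(resource = rr$resource)
  if (!is.na(rr$row_id %||% NA)) rp$row_id <- rr$row_id
  if (!is.na(rr$occurrence_id %||% NA)) rp$occurrence_id <- rr$occurrence_id
  list(element_ref = a$element_ref, element_type = a$element_type,
       specification_ref = a$specification_ref,
       mechanism_ref = a$mechanism_ref,
       resource_ref = rp,
       result = result_payload(a$result))
}

assertion_from_payload <- function(p) {
  rr <- p$resource_ref
  ref <- list(resource = rr$resource,
              row_id = if (is.null(rr$row_id)) NA_integer_
                       else as.integer(rr$row_id))
  if (!is.null(rr$occurrence_id)) ref$occurrence_id <- rr$occurrence_id
  else if ("occurrence_id" %in% names(rr) || !is.null(p$resource_ref$row_id))
    ref$occurrence_id <- NA_character_
  build_assertion(p$element_ref, p$element_type, p$specification_ref,
                  p$mechanism_ref, ref, result_from_payload(p$result))
}

report_payload <- function(report) {
  list(profile_ref = report$profile_ref,
       resource_ref = report$resource_ref,
       n_records = report$n_records,
       measures = lapply(report$measures, assertion_payload),
       validations = lapply(report$validations, assertion_payload),
       amendments = lapply(report$amendments, assertion_payload),
       record_criterion_summaries = lapply(
         seq_len(nrow(report$record_criterion_summaries)), function(i)
           as.list(report$record_criterion_summaries[i, ])),
       generated_at = report$generated_at,
       engine_version = report$engine_version)
}

#' Write a quality report to JSON or CSV
#'
#' JSON spells out all five assertion components by id and is loss-free
#' (see [read_report()]). CSV is one assertion per row with columns
#' assertion_type, element_id, specification_id, mechanism_id, resource_ref,
#' status, result, detail.
#'
#' @param report a `dq_report`.
#' @param path output path.
#' @param format `"json"` or `"csv"`; defaults by extension.
#' @return invisibly, the path.
#' @export
write_report <- function(report, path, format = NULL) {
  if (is.null(format))
    format <- if (tolower(sub(".*\\.", "", path)) == "csv") "csv" else "json"
  format <- match.arg(tolower(format), c("json", "csv"))
  if (format == "json") {
    jsonlite::write_json(report_payload(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(report_table(report), path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Flatten a report to one-assertion-per-row form
#' @param report a `dq_report`.
#' @return a data.frame with one row per assertion.
#' @export
report_table <- function(report) {
  row_of <- function(a, type) {
    res <- a$result
    value <- if (inherits(res, "dq_measure_result"))
      as.character(res$qualitative %||% res$quantitative %||% "")
    else if (inherits(res, "dq_validation_result")) res$outcome %||% ""
    else if (length(res$proposed_changes))
      paste(names(res$proposed_changes), res$proposed_changes, sep = "=",
            collapse = "|")
    else ""
    detail <- if (inherits(res, "dq_measure_result")) res$detail
              else if (inherits(res, "dq_amendment_result")) res$rationale
              else ""
    rid <- a$resource_ref$row_id
    data.frame(
      assertion_type = type, element_id = a$element_ref,
      specification_id = a$specification_ref,
      mechanism_id = a$mechanism_ref,
      resource_ref = if (is.na(rid %||% NA)) a$resource_ref$resource
                     else paste0(a$resource_ref$resource, "#", rid),
      status = res$status, result = value, detail = detail,
      stringsAsFactors = FALSE)
  }
  rows <- c(lapply(report$measures, row_of, type = "measure"),
            lapply(report$validations, row_of, type = "validation"),
            lapply(report$amendments, row_of, type = "amendment"))
  if (length(rows)) do.call(rbind, rows)
  else data.frame(assertion_type = character(), element_id = character(),
                  specification_id = character(), mechanism_id = character(),
                  resource_ref = character(), status = character(),
                  result = character(), detail = character(),
                  stringsAsFactors = FALSE)
}

#' Read a JSON report back into a `dq_report`
#' @param path a JSON report written by [write_report()].
#' @return a `dq_report` structurally equal to the one written.
#' @export
read_report <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  summaries <- if (length(p$record_criterion_summaries))
    do.call(rbind, lapply(p$record_criterion_summaries, function(s)
      data.frame(criterion_id = s$criterion_id, n = as.integer(s$n),
                 n_compliant = as.integer(s$n_compliant),
                 proportion_compliant = as.numeric(s$proportion_compliant),
                 stringsAsFactors = FALSE)))
  else data.frame(criterion_id = character(), n = integer(),
                  n_compliant = integer(), proportion_compliant = numeric(),
                  stringsAsFactors = FALSE)
  structure(
    list(profile_ref = p$profile_ref, resource_ref = p$resource_ref,
         n_records = as.integer(p$n_records),
         measures = lapply(p$measures, assertion_from_payload),
         validations = lapply(p$validations, assertion_from_payload),
         amendments = lapply(p$amendments, assertion_from_payload),
         record_criterion_summaries = summaries,
         generated_at = p$generated_at,
         engine_version = p$engine_version),
    class = "dq_report")
}

# --- reference data ---------------------------------------------------------

#' Load reference data from files
#'
#' @param boundaries_path GeoJSON FeatureCollection of country boundaries;
#'   each feature needs a `name` property and Polygon/MultiPolygon geometry.
#' @param taxonomy_path CSV with columns name,rank,parent.
#' @param gazetteer_path CSV with columns
#'   locality,decimalLatitude,decimalLongitude,coordinateUncertaintyInMeters.
#' @param names_path accepted scientific names, one per line (UTF-8).
#' @return a validated [reference_data()]; omitted paths yield empty
#'   components.
#' @export
load_reference_data <- function(boundaries_path = NULL, taxonomy_path = NULL,
                                gazetteer_path = NULL, names_path = NULL) {
  boundaries <- list()
  if (!is.null(boundaries_path))
    boundaries <- read_boundaries_geojson(boundaries_path)
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    taxonomy <- utils::read.csv(taxonomy_path, colClasses = "character",
                                na.strings = character(),
                                stringsAsFactors = FALSE)
    miss <- setdiff(c("name", "rank", "parent"), names(taxonomy))
    if (length(miss))
      stop(taxonomy_path, ": missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  gazetteer <- NULL
  if (!is.null(gazetteer_path)) {
    gazetteer <- utils::read.csv(gazetteer_path, colClasses = "character",
                                 na.strings = character(),
                                 stringsAsFactors = FALSE)
    need <- c("locality", "decimalLatitude", "decimalLongitude",
              "coordinateUncertaintyInMeters")
    miss <- setdiff(need, names(gazetteer))
    if (length(miss))
      stop(gazetteer_path, ": missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  accepted <- character()
  if (!is.null(names_path)) {
    accepted <- readLines(names_path, warn = FALSE, encoding = "UTF-8")
    accepted <- trimws(accepted)
    accepted <- accepted[nzchar(accepted)]
  }
  reference_data(boundaries = boundaries, taxonomy = taxonomy,
                 gazetteer = gazetteer, accepted_names = accepted)
}

read_boundaries_geojson <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(g$type, "FeatureCollection"))
    stop(path, ": expected a GeoJSON FeatureCollection", call. = FALSE)
  boundaries <- list()
  for (i in seq_along(g$features)) {
    f <- g$features[[i]]
    name <- f$properties$name
    if (is.null(name))
      stop(path, ": feature ", i, " lacks a 'name' property", call. = FALSE)
    geom <- f$geometry
    ring_to_matrix <- function(ring, what) {
      m <- do.call(rbind, lapply(ring, function(pt)
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
      if (nrow(m) < 4L || any(m[1L, ] != m[nrow(m), ]))
        stop(path, ": malformed (unclosed or degenerate) ring in feature '",
             what, "'", call. = FALSE)
      m
    }
    rings <- switch(
      geom$type %||% "",
      Polygon = lapply(geom$coordinates, ring_to_matrix, what = name),
      MultiPolygon = unlist(lapply(geom$coordinates, function(poly)
        lapply(poly, ring_to_matrix, what = name)), recursive = FALSE),
      stop(path, ": feature '", name,
           "' must be Polygon or MultiPolygon", call. = FALSE))
    # same-named features (disjoint territories) merge into one polygon set
    key <- names(boundaries)[tolower(names(boundaries)) == tolower(name)]
    if (length(key)) boundaries[[key[[1L]]]] <-
        c(boundaries[[key[[1L]]]], rings)
    else boundaries[[name]] <- rings
  }
  boundaries
}
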