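# Reference data (country boundaries, taxonomy, gazetteer, accepted names)
# and the planar geometry used by the point-radius consistency mechanism.

METERS_PER_DEG <- 111320

TAXON_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
                 "species")

#' Assemble validated reference data
#'
#' @param boundaries named list: country name → list of rings, each ring a
#'   two-column (lon, lat) numeric matrix with the first vertex repeated as
#'   the last (closed ring, at least 3 distinct vertices). Multi-part
#'   territories are additional rings under the same name.
#' @param taxonomy data.frame with columns `name`, `rank`, `parent`
#'   (empty parent for roots). Ranks are drawn from
#'   kingdom > phylum > class > order > family > genus > species and parent
#'   links must form a forest.
#' @param gazetteer data.frame with columns `locality`, `decimalLatitude`,
#'   `decimalLongitude`, `coordinateUncertaintyInMeters`. Lookup keys are
#'   case-folded and whitespace-collapsed.
#' @param accepted_names character vector of accepted scientific names.
#' @return a `dq_reference_data` object.
#' @export
reference_data <- function(boundaries = list(),
                           taxonomy = NULL,
                           gazetteer = NULL,
                           accepted_names = character()) {
  nm <- names(boundaries) %||% character()
  if (anyDuplicated(tolower(nm)))
    stop("country names must be unique after case-folding", call. = FALSE)
  for (country in nm) {
    rings <- boundaries[[country]]
    for (ring in rings) {
      if (!is.matrix(ring) || ncol(ring) != 2L)
        stop("ring for '", country, "' must be a two-column (lon, lat) matrix",
             call. = FALSE)
      if (nrow(ring) < 4L ||
          any(ring[1L, ] != ring[nrow(ring), ]))
        stop("ring for '", country, "' must be closed (first vertex repeated)",
             call. = FALSE)
      if (nrow(unique(ring[-nrow(ring), , drop = FALSE])) < 3L)
        stop("ring for '", country, "' needs at least 3 distinct vertices",
             call. = FALSE)
    }
  }
  if (!is.null(taxonomy)) {
    stopifnot(all(c("name", "rank", "parent") %in% names(taxonomy)))
    taxonomy$name <- as.character(taxonomy$name)
    taxonomy$rank <- as.character(taxonomy$rank)
    taxonomy$parent <- as.character(taxonomy$parent)
    unknown <- setdiff(unique(taxonomy$rank), TAXON_RANKS)
    if (length(unknown))
      stop("unknown taxonomic rank(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    check_taxonomy_forest(taxonomy)
  }
  if (!is.null(gazetteer)) {
    need <- c("locality", "decimalLatitude", "decimalLongitude",
              "coordinateUncertaintyInMeters")
    stopifnot(all(need %in% names(gazetteer)))
  }
  structure(list(boundaries = boundaries, taxonomy = taxonomy,
                 gazetteer = gazetteer,
                 accepted_names = as.character(accepted_names)),
            class = "dq_reference_data")
}

# parent links must not cycle; walk each node to a root, erroring on revisit.
check_taxonomy_forest <- function(tax) {
  parent <- stats::setNames(tax$parent, tax$name)
  for (start in tax$name) {
    seen <- character()
    cur <- start
    while (!is.na(cur) && nzchar(cur)) {
      if (cur %in% seen)
        stop("taxonomy parent links contain a cycle involving '", cur, "'",
             call. = FALSE)
      seen <- c(seen, cur)
      cur <- if (cur %in% names(parent)) parent[[cur]] else ""
    }
  }
  invisible(TRUE)
}

#' Find a country's polygon rings by case-insensitive name
#' @param reference a `dq_reference_data`.
#' @param name country name.
#' @return list of rings, or `NULL` when the name is unknown.
#' @export
match_country <- function(reference, name) {
  if (is.null(name) || is.na(name)) return(NULL)
  hit <- which(tolower(names(reference$boundaries)) == tolower(trimws(name)))
  if (length(hit) == 0L) NULL else reference$boundaries[[hit[[1L]]]]
}

# --- planar geometry --------------------------------------------------------
# Local-planar approximation: 1 degree latitude = 111,320 m; 1 degree
# longitude = 111,320 * cos(latitude) m, evaluated at the query point's
# latitude. Adequate at fixture scales; no geodesic model.

#' Point-in-ring test (winding number)
#'
#' @param lon,lat query point in decimal degrees.
#' @param ring closed two-column (lon, lat) matrix.
#' @return `TRUE` when the point is strictly inside or on the boundary.
#' @export
point_in_ring <- function(lon, lat, ring) {
  n <- nrow(ring) - 1L
  x <- ring[, 1L]; y <- ring[, 2L]
  wn <- 0L
  for (i in seq_len(n)) {
    x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1L]; y2 <- y[i + 1L]
    # boundary points count as inside
    cross <- (x2 - x1) * (lat - y1) - (lon - x1) * (y2 - y1)
    if (min(y1, y2) <= lat && lat <= max(y1, y2) &&
        min(x1, x2) <= lon && lon <= max(x1, x2) && cross == 0)
      return(TRUE)
    if (y1 <= lat) {
      if (y2 > lat && cross > 0) wn <- wn + 1L
    } else {
      if (y2 <= lat && cross < 0) wn <- wn - 1L
    }
  }
  wn != 0L
}

#' Point containment in a set of polygon rings
#' @inheritParams point_in_ring
#' @param rings list of closed rings (a country's parts).
#' @return `TRUE` if inside any ring.
#' @export
point_in_polygons <- function(lon, lat, rings) {
  for (ring in rings) if (point_in_ring(lon, lat, ring)) return(TRUE)
  FALSE
}

#' Planar distance from a point to a polygon boundary, in meters
#'
#' Projects lon/lat to a local planar frame at the query latitude and takes
#' the minimum point-to-segment distance over all edges of all rings.
#'
#' @inheritParams point_in_polygons
#' @return non-negative distance in meters.
#' @export
distance_to_boundary_m <- function(lon, lat, rings) {
  kx <- METERS_PER_DEG * cos(lat * pi / 180)
  ky <- METERS_PER_DEG
  px <- lon * kx; py <- lat * ky
  best <- Inf
  for (ring in rings) {
    x <- ring[, 1L] * kx; y <- ring[, 2L] * ky
    n <- length(x) - 1L
    for (i in seq_len(n)) {
      dx <- x[i + 1L] - x[i]; dy <- y[i + 1L] - y[i]
      len2 <- dx * dx + dy * dy
      t <- if (len2 == 0) 0 else
        max(0, min(1, ((px - x[i]) * dx + (py - y[i]) * dy) / len2))
      qx <- x[i] + t * dx; qy <- y[i] + t * dy
      d <- sqrt((px - qx)^2 + (py - qy)^2)
      if (d < best) best <- d
    }
  }
  best
}
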