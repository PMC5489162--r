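# Shared fixtures and independent oracles. Oracles deliberately re-derive
# results by a different route than the implementation (even-odd ray
# casting vs winding number, dense edge sampling vs segment projection,
# dynamic-programming Levenshtein vs utils::adist).

toy_reference <- function() generate_reference_fixtures()

coordinates_ie <- function() {
  dq_information_element(
    "coordinates", c("decimalLatitude", "decimalLongitude",
                     "coordinateUncertaintyInMeters", "geodeticDatum"))
}

taxon_ie <- function() {
  dq_information_element("taxon", c("scientificName", "genus", "family"))
}

# a unit-square country used for hand-checkable geometry
square_reference <- function() {
  ring <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  reference_data(boundaries = list(Atlantis = list(ring)))
}

worked_example_record <- function() {
  c(decimalLatitude = "-35.3848", decimalLongitude = "13.8352",
    coordinateUncertaintyInMeters = "100", geodeticDatum = "SIRGAS2000",
    countryName = "Brazil")
}

# --- oracles ----------------------------------------------------------------

# even-odd ray casting (horizontal ray to +infinity)
oracle_point_in_ring <- function(lon, lat, ring) {
  n <- nrow(ring) - 1L
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    if ((y1 > lat) != (y2 > lat)) {
      xint <- x1 + (lat - y1) / (y2 - y1) * (x2 - x1)
      if (lon < xint) inside <- !inside
    }
  }
  inside
}

oracle_point_in_polygons <- function(lon, lat, rings) {
  any(vapply(rings, function(r) oracle_point_in_ring(lon, lat, r),
             logical(1)))
}

# minimum planar distance by 1-d numerical minimization along every edge
# (same metric as the implementation, independent computation: no
# closed-form projection)
oracle_distance_m <- function(lon, lat, rings) {
  kx <- 111320 * cos(lat * pi / 180); ky <- 111320
  best <- Inf
  for (ring in rings) {
    for (i in seq_len(nrow(ring) - 1L)) {
      f <- function(t) {
        ex <- ring[i, 1] + t * (ring[i + 1, 1] - ring[i, 1])
        ey <- ring[i, 2] + t * (ring[i + 1, 2] - ring[i, 2])
        sqrt(((lon - ex) * kx)^2 + ((lat - ey) * ky)^2)
      }
      best <- min(best, f(0), f(1),
                  stats::optimize(f, c(0, 1), tol = 1e-10)$objective)
    }
  }
  best
}

# quadratic dynamic-programming Levenshtein distance
oracle_levenshtein <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  d <- matrix(0L, m + 1L, n + 1L)
  d[, 1L] <- 0:m; d[1L, ] <- 0:n
  for (i in seq_len(m)) for (j in seq_len(n))
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                             d[i, j] + (a[i] != b[j]))
  d[m + 1L, n + 1L]
}

# --- random profile generation for property tests ---------------------------

dim_kinds <- list(
  list(spec = "completeness", positive = "COMPLETE",
       ies = c("coordinates", "taxon"), record_only = FALSE),
  list(spec = "coordinate-conformity", positive = "CONFORMANT",
       ies = "coordinates", record_only = TRUE),
  list(spec = "coordinate-consistency", positive = "CONSISTENT",
       ies = "coordinates", record_only = TRUE))

enh_specs <- c("fill-taxon-hierarchy", "country-from-coordinates",
               "coordinates-from-locality", "name-suggestion")
enh_types <- c("CORRECTION", "RECOMMENDATION", "RECOMMENDATION",
               "PREVENTION")

# a random well-formed profile over the built-in specifications
random_profile <- function(max_dims = 5L, max_crit = 5L, max_enh = 5L) {
  n_dims <- sample.int(max_dims, 1L)
  dims <- lapply(seq_len(n_dims), function(i) {
    kind <- dim_kinds[[sample.int(length(dim_kinds), 1L)]]
    rt <- if (kind$record_only) "SINGLE_RECORD"
          else sample(c("SINGLE_RECORD", "DATASET"), 1L)
    dq_dimension(sprintf("dim-%d", i), "QUALITY",
                 information_element = sample(kind$ies, 1L),
                 resource_type = rt, specification = kind$spec)
  })
  positives <- vapply(dims, function(d) {
    k <- Filter(function(kk) kk$spec == d$specification_ref, dim_kinds)[[1]]
    k$positive
  }, character(1))
  n_crit <- sample.int(max_crit + 1L, 1L) - 1L
  crits <- lapply(seq_len(n_crit), function(i) {
    j <- sample.int(n_dims, 1L)
    if (dims[[j]]$resource_type == "DATASET")
      dq_criterion(sprintf("crit-%d", i), "random dataset rule",
                   dims[[j]]$id, sample(c("EQ", "GE", "LE"), 1L),
                   round(stats::runif(1), 2))
    else
      dq_criterion(sprintf("crit-%d", i), "random record rule",
                   dims[[j]]$id, "EQ", positives[[j]])
  })
  n_enh <- sample.int(max_enh + 1L, 1L) - 1L
  enhs <- lapply(seq_len(n_enh), function(i) {
    k <- sample.int(length(enh_specs), 1L)
    dq_enhancement(sprintf("enh-%d", i), "random enhancement",
                   enh_types[[k]],
                   target_dimensions = dims[[sample.int(n_dims, 1L)]]$id,
                   specification = enh_specs[[k]])
  })
  dq_profile(dq_use_case("random-uc", "random use case"),
             list(coordinates_ie(), taxon_ie()),
             dims, crits, enhs)
}

random_rates <- function() {
  defect_rates(p_missing_coord = stats::runif(1, 0, 0.4),
               p_nonnumeric_coord = stats::runif(1, 0, 0.3),
               p_out_of_range = stats::runif(1, 0, 0.3),
               p_wrong_country = stats::runif(1, 0, 0.3),
               p_missing_taxon_ranks = stats::runif(1, 0, 0.4),
               p_misspelled_name = stats::runif(1, 0, 0.3))
}

# brute-force recount of a dataset proportion from record-level outcomes
oracle_proportion <- function(outcomes, positive) {
  if (length(outcomes) == 0L) return(NA_real_)
  mean(vapply(outcomes, function(o) identical(o$qualitative, positive),
              logical(1)))
}

expect_valid_assertion <- function(a) {
  expect_s3_class(a, "dq_assertion")
  for (f in c("element_ref", "element_type", "specification_ref",
              "mechanism_ref", "resource_ref", "result"))
    expect_false(is.null(a[[f]]))
  want <- c(dimension = "dq_measure_result",
            criterion = "dq_validation_result",
            enhancement = "dq_amendment_result")[[a$element_type]]
  expect_s3_class(a$result, want)
}

# internal helpers reached through the namespace
toy_gazetteer_table <- function() dwcdq:::toy_gazetteer()
report_payload <- function(r) dwcdq:::report_payload(r)
profile_lookup <- function(items, id) dwcdq:::profile_lookup(items, id)
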