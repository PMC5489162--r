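# Mechanism catalogue: completeness, coordinate conformity and its
# sub-checks, point-radius country consistency, criterion validation,
# amendments, and name suggestion — each checked against hand-derived
# values or an independent oracle.

test_that("record completeness is COMPLETE iff no term is missing", {
  ie <- coordinates_ie()
  full <- worked_example_record()
  expect_identical(measure_completeness_record(full, ie)$qualitative,
                   "COMPLETE")

  empty <- measure_completeness_record(character(), ie)
  expect_identical(empty$qualitative, "NOT_COMPLETE")
  for (t in ie$terms) expect_match(empty$detail, t, fixed = TRUE)

  nodatum <- full[setdiff(names(full), "geodeticDatum")]
  res <- measure_completeness_record(nodatum, ie)
  expect_identical(res$qualitative, "NOT_COMPLETE")
  expect_match(res$detail, "geodeticDatum")
  expect_false(grepl("decimalLatitude", res$detail))
})

test_that("dataset completeness is the exact proportion of complete records", {
  ie <- coordinates_ie()
  full <- worked_example_record()
  partial <- full[-1]
  ds <- dq_dataset(list(full, full, full, partial))
  expect_identical(measure_completeness_dataset(ds, ie)$quantitative, 0.75)
  expect_identical(
    measure_completeness_dataset(dq_dataset(list(full, full)), ie)$quantitative,
    1)
  expect_identical(
    measure_completeness_dataset(dq_dataset(list()), ie)$status,
    "PREREQUISITES_NOT_MET")
})

test_that("coordinate conformity composes its four sub-checks", {
  conf <- function(lat, lon)
    measure_coordinate_conformity_record(
      c(decimalLatitude = lat, decimalLongitude = lon))

  # inclusive range ends conform
  expect_identical(conf("-90", "180")$qualitative, "CONFORMANT")
  expect_identical(conf("90", "-180")$qualitative, "CONFORMANT")
  expect_identical(conf("0", "0")$qualitative, "CONFORMANT")

  # only the latitude-range sub-check fails for 91.5
  r <- conf("91.5", "10")
  expect_identical(r$qualitative, "NOT_CONFORMANT")
  expect_match(r$detail, "latitude_range:fail")
  expect_match(r$detail, "is_number:pass")
  expect_match(r$detail, "valid_characters:pass")
  expect_match(r$detail, "longitude_range:pass")

  # comma decimal fails the character sub-check
  r <- conf("12,34", "10")
  expect_identical(r$qualitative, "NOT_CONFORMANT")
  expect_match(r$detail, "valid_characters:fail")

  # lettered value fails characters even though it parses as a number
  r <- conf("1e2", "10")
  expect_match(r$detail, "valid_characters:fail")

  # missing coordinate is a prerequisite failure, not NOT_CONFORMANT
  expect_identical(
    measure_coordinate_conformity_record(
      c(decimalLongitude = "10"))$status,
    "PREREQUISITES_NOT_MET")
})

test_that("conformity equals the conjunction of independently-run sub-checks", {
  set.seed(11)
  vals <- c("0", "45.5", "-90", "90", "91.5", "-90.0000001", "12,34",
            "abc", "1e2", "++5", "7.", ".5", "100", "-181", "180")
  for (i in 1:60) {
    lat <- sample(vals, 1); lon <- sample(vals, 1)
    both <- measure_coordinate_conformity_record(
      c(decimalLatitude = lat, decimalLongitude = lon))
    conj <- check_value_is_number(lat) && check_value_is_number(lon) &&
      check_valid_characters(lat) && check_valid_characters(lon) &&
      check_latitude_range(lat) && check_longitude_range(lon)
    expect_identical(both$qualitative,
                     if (conj) "CONFORMANT" else "NOT_CONFORMANT")
  }
})

test_that("consistency follows the point-radius rule on a toy square country", {
  ref <- square_reference()
  mk <- function(lat, lon, unc, country = "Atlantis")
    c(decimalLatitude = lat, decimalLongitude = lon,
      coordinateUncertaintyInMeters = unc, country = country)

  # interior point, zero uncertainty
  expect_identical(
    measure_coordinate_consistency_record(mk("5", "5", "0"), ref)$qualitative,
    "CONSISTENT")
  # ~1000 m outside the eastern edge (10 degrees lon at lat 5):
  # 0.01 degrees lon ~ 1108.9 m at lat 5
  expect_identical(
    measure_coordinate_consistency_record(
      mk("5", "10.01", "100"), ref)$qualitative,
    "NOT_CONSISTENT")
  expect_identical(
    measure_coordinate_consistency_record(
      mk("5", "10.01", "2000"), ref)$qualitative,
    "CONSISTENT")
  # unknown country is a prerequisite failure, never NOT_CONSISTENT
  r <- measure_coordinate_consistency_record(mk("5", "5", "0", "Nowhere"), ref)
  expect_identical(r$status, "PREREQUISITES_NOT_MET")
  expect_match(r$detail, "Nowhere")
  # country matching is case-insensitive
  expect_identical(
    measure_coordinate_consistency_record(
      mk("5", "5", "0", "atlantis"), ref)$qualitative,
    "CONSISTENT")
  # missing uncertainty is treated as a 0 m point test, noted in detail
  r <- measure_coordinate_consistency_record(
    c(decimalLatitude = "5", decimalLongitude = "10.01",
      country = "Atlantis"), ref)
  expect_identical(r$qualitative, "NOT_CONSISTENT")
  expect_match(r$detail, "treated as 0 m")
})

test_that("consistency is monotone in uncertainty and true inside", {
  ref <- square_reference()
  set.seed(23)
  for (i in 1:25) {
    inside_lat <- runif(1, 0.5, 9.5); inside_lon <- runif(1, 0.5, 9.5)
    for (u in c("0", "10", "100000"))
      expect_identical(measure_coordinate_consistency_record(
        c(decimalLatitude = sprintf("%.4f", inside_lat),
          decimalLongitude = sprintf("%.4f", inside_lon),
          coordinateUncertaintyInMeters = u, country = "Atlantis"),
        ref)$qualitative, "CONSISTENT")
    # outside point: once CONSISTENT at u, stays CONSISTENT at larger u
    lon <- runif(1, 10.001, 10.2)
    us <- c(10, 1000, 5000, 30000)
    res <- vapply(us, function(u) measure_coordinate_consistency_record(
      c(decimalLatitude = "5.0", decimalLongitude = sprintf("%.4f", lon),
        coordinateUncertaintyInMeters = as.character(u),
        country = "Atlantis"), ref)$qualitative, character(1))
    ok <- res == "CONSISTENT"
    expect_true(all(diff(ok) >= 0))
  }
})

test_that("containment and boundary distance agree with ray-casting and edge-sampling oracles", {
  ref <- toy_reference()
  set.seed(41)
  n_pts <- 1200L
  lon <- runif(n_pts, -80, 40); lat <- runif(n_pts, -40, 35)
  countries <- names(ref$boundaries)
  for (i in seq_len(n_pts)) {
    cn <- countries[[(i %% length(countries)) + 1L]]
    rings <- ref$boundaries[[cn]]
    expect_identical(point_in_polygons(lon[i], lat[i], rings),
                     oracle_point_in_polygons(lon[i], lat[i], rings))
  }
  # distances on a subsample (the oracle is expensive)
  for (i in seq_len(40)) {
    cn <- countries[[(i %% length(countries)) + 1L]]
    rings <- ref$boundaries[[cn]]
    d_impl <- distance_to_boundary_m(lon[i], lat[i], rings)
    d_orac <- oracle_distance_m(lon[i], lat[i], rings)
    expect_equal(d_impl, d_orac, tolerance = 1e-3)
  }
})

test_that("criterion validation applies comparators and propagates prerequisites", {
  crit_eq1 <- dq_criterion("c", "must equal 100%", "d", "EQ", "100%")
  m <- function(q) measure_result("COMPLETED", quantitative = q)
  expect_identical(validate_against_criterion(m(1), crit_eq1)$outcome,
                   "COMPLIANT")
  expect_identical(validate_against_criterion(m(0.75), crit_eq1)$outcome,
                   "NOT_COMPLIANT")

  set.seed(5)
  for (i in 1:50) {
    q <- round(runif(1), 2); thr <- round(runif(1), 2)
    cmp <- sample(c("EQ", "GE", "LE", "GT", "LT"), 1)
    expected <- switch(cmp, EQ = q == thr, GE = q >= thr, LE = q <= thr,
                       GT = q > thr, LT = q < thr)
    got <- validate_against_criterion(
      m(q), dq_criterion("c", "s", "d", cmp, thr))$outcome
    expect_identical(got, if (expected) "COMPLIANT" else "NOT_COMPLIANT")
  }

  qual <- measure_result("COMPLETED", qualitative = "COMPLETE")
  crit_q <- dq_criterion("c", "s", "d", "EQ", "COMPLETE")
  expect_identical(validate_against_criterion(qual, crit_q)$outcome,
                   "COMPLIANT")
  expect_identical(
    validate_against_criterion(
      measure_result("PREREQUISITES_NOT_MET"), crit_q)$status,
    "PREREQUISITES_NOT_MET")
  expect_error(validate_against_criterion(qual, crit_eq1),
               "configuration error")
  expect_error(validate_against_criterion(m(0.5), crit_q),
               "configuration error")
})

test_that("taxon-hierarchy backfill proposes only blank higher ranks", {
  ref <- toy_reference()
  rec <- c(species = "Tetragonisca angustula", genus = "", family = "")
  res <- amend_fill_taxon_hierarchy(rec, ref)
  expect_identical(res$status, "PROPOSED")
  expect_identical(res$proposed_changes[["genus"]], "Tetragonisca")
  expect_identical(res$proposed_changes[["family"]], "Apidae")
  expect_identical(sort(names(res$proposed_changes)), c("family", "genus"))

  # fully populated hierarchy: nothing to do
  full <- c(species = "Tetragonisca angustula", genus = "Tetragonisca",
            family = "Apidae")
  expect_identical(amend_fill_taxon_hierarchy(full, ref)$status,
                   "NOT_PROPOSED")

  # conflicting filled family: proposal omits it, rationale names it
  confl <- c(species = "Tetragonisca angustula", genus = "",
             family = "Fabaceae")
  res <- amend_fill_taxon_hierarchy(confl, ref)
  expect_identical(res$status, "PROPOSED")
  expect_false("family" %in% names(res$proposed_changes))
  expect_match(res$rationale, "Fabaceae")
  expect_match(res$rationale, "conflict")

  # scientificName anchors the walk too
  sn <- c(scientificName = "Mimosa pudica", genus = "", family = "")
  res <- amend_fill_taxon_hierarchy(sn, ref)
  expect_identical(res$proposed_changes[["genus"]], "Mimosa")
  expect_identical(res$proposed_changes[["family"]], "Fabaceae")

  # unknown name: prerequisites not met
  expect_identical(
    amend_fill_taxon_hierarchy(c(species = "Unknownia species"), ref)$status,
    "PREREQUISITES_NOT_MET")
})

test_that("taxon-hierarchy backfill flags ambiguous names", {
  tax <- rbind(toy_taxonomy_copy <- toy_reference()$taxonomy,
               data.frame(name = "Tetragonisca angustula", rank = "species",
                          parent = "Mimosa", stringsAsFactors = FALSE))
  ref <- reference_data(taxonomy = tax)
  res <- amend_fill_taxon_hierarchy(
    c(species = "Tetragonisca angustula", genus = ""), ref)
  expect_identical(res$status, "PREREQUISITES_NOT_MET")
  expect_match(res$rationale, "ambiguous")
})

test_that("country-from-coordinates proposes, recommends or abstains", {
  ref <- toy_reference()
  inside_atlantis <- c(decimalLatitude = "5", decimalLongitude = "5")

  res <- amend_country_from_coordinates(c(inside_atlantis, country = ""), ref)
  expect_identical(res$status, "PROPOSED")
  expect_identical(res$proposed_changes[["country"]], "Atlantis")
  expect_null(res$flag)

  expect_identical(
    amend_country_from_coordinates(
      c(inside_atlantis, country = "Atlantis"), ref)$status,
    "NOT_PROPOSED")

  res <- amend_country_from_coordinates(
    c(inside_atlantis, country = "Borduria"), ref)
  expect_identical(res$status, "PROPOSED")
  expect_identical(res$flag, "RECOMMENDATION")
  expect_identical(res$proposed_changes[["country"]], "Atlantis")

  res <- amend_country_from_coordinates(
    c(decimalLatitude = "-5", decimalLongitude = "15", country = ""), ref)
  expect_identical(res$status, "NOT_PROPOSED")
  expect_match(res$rationale, "no containing boundary")

  expect_identical(
    amend_country_from_coordinates(
      c(decimalLatitude = "95", decimalLongitude = "5"), ref)$status,
    "PREREQUISITES_NOT_MET")
})

test_that("locality lookup proposes coordinates only on exact normalized match", {
  ref <- toy_reference()
  blank <- c(decimalLatitude = "", decimalLongitude = "")

  res <- amend_coordinates_from_locality(
    c(blank, locality = "Campinas, SP"), ref)
  expect_identical(res$status, "PROPOSED")
  expect_identical(res$proposed_changes[["decimalLatitude"]], "-22.9056")
  expect_identical(res$proposed_changes[["decimalLongitude"]], "-47.0608")

  # case and whitespace differences still match
  res <- amend_coordinates_from_locality(
    c(blank, locality = "  campinas,   sp "), ref)
  expect_identical(res$status, "PROPOSED")

  expect_identical(
    amend_coordinates_from_locality(
      c(blank, locality = "Ruritania - site 9"), ref)$status,
    "NOT_PROPOSED")
  # coordinates already present: nothing proposed
  expect_identical(
    amend_coordinates_from_locality(
      c(decimalLatitude = "5", decimalLongitude = "5",
        locality = "Campinas, SP"), ref)$status,
    "NOT_PROPOSED")
})

test_that("amendments are pure: inputs unchanged, repeat calls identical", {
  ref <- toy_reference()
  rec <- c(species = "Tetragonisca angustula", genus = "", family = "",
           decimalLatitude = "5", decimalLongitude = "5", country = "")
  snapshot <- rec
  r1 <- amend_fill_taxon_hierarchy(rec, ref)
  r2 <- amend_fill_taxon_hierarchy(rec, ref)
  r3 <- amend_country_from_coordinates(rec, ref)
  r4 <- amend_country_from_coordinates(rec, ref)
  expect_identical(rec, snapshot)
  expect_identical(r1, r2)
  expect_identical(r3, r4)
})

test_that("name suggestions match a dynamic-programming Levenshtein oracle", {
  ref <- toy_reference()
  exact <- suggest_scientific_names("Tetragonisca angustula", ref, 2, 5)
  expect_identical(exact$candidate[[1]], "Tetragonisca angustula")
  expect_identical(exact$distance[[1]], 0L)
  expect_identical(exact$rank_position[[1]], 1L)

  typo <- suggest_scientific_names("Tetragonisca angustvla", ref, 2, 5)
  expect_identical(typo$candidate[[1]], "Tetragonisca angustula")
  expect_identical(typo$distance[[1]], 1L)

  expect_identical(
    nrow(suggest_scientific_names("No Such Name At All", ref, 0, 5)), 0L)

  # distances agree with the DP oracle; ordering is (distance, name)
  queries <- c("Apis melifera", "Mimosa pudica", "Bombus varia",
               "Trigona spinipes", "Xtrigona spinipes")
  for (q in queries) {
    sug <- suggest_scientific_names(q, ref, 3, 10)
    for (i in seq_len(nrow(sug)))
      expect_identical(sug$distance[[i]],
                       oracle_levenshtein(q, sug$candidate[[i]]))
    if (nrow(sug) > 1) {
      ord <- order(sug$distance, sug$candidate)
      expect_identical(ord, seq_len(nrow(sug)))
    }
  }
})
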