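# Engine: report shape, aggregation, assurance filtering, amendment
# application, determinism.

engine_fixture <- function(n = 10, rates = defect_rates(), seed = 1) {
  ref <- toy_reference()
  gen <- generate_dataset(n, rates, seed)
  list(ref = ref, registry = builtin_registry(ref),
       dataset = gen$resource, truth = gen$truth,
       profile = read_profile(
         system.file("extdata", "profile-coordinates.yaml",
                     package = "dwcdq")))
}

test_that("report shape follows the profile-to-status mapping", {
  # 1 dataset dimension, 1 criterion on it, 1 enhancement, 10 records
  fx <- engine_fixture(n = 10)
  profile <- dq_profile(
    dq_use_case("uc", "shape"),
    list(coordinates_ie()),
    list(dq_dimension("d", "COMPLETENESS", "coordinates", "DATASET",
                      "completeness")),
    list(dq_criterion("c", "complete", "d", "EQ", 1)),
    list(dq_enhancement("e", "locality", "RECOMMENDATION", "d",
                        "coordinates-from-locality")))
  rep <- generate_report(profile, fx$dataset, fx$registry)
  expect_length(rep$measures, 1L)
  expect_length(rep$validations, 1L)
  expect_length(rep$amendments, 10L)

  # empty enhancement policy: no amendment assertions
  profile$enhancement_policy <- list()
  rep <- generate_report(profile, fx$dataset, fx$registry)
  expect_length(rep$amendments, 0L)
})

test_that("the worked single-record consistency report carries five components", {
  ref <- toy_reference()
  profile <- dq_profile(
    dq_use_case("uc-consistency", "coordinate-country agreement"),
    list(coordinates_ie()),
    list(dq_dimension("coord-consistency", "CONSISTENCY", "coordinates",
                      "SINGLE_RECORD", "coordinate-consistency")))
  resource <- dq_record(worked_example_record(), id = "worked-example")
  rep <- generate_report(profile, resource, builtin_registry(ref))
  expect_length(rep$measures, 1L)
  a <- rep$measures[[1]]
  expect_valid_assertion(a)
  expect_identical(a$result$qualitative, "NOT_CONSISTENT")
  expect_identical(a$element_ref, "coord-consistency")
  expect_identical(a$specification_ref, "coordinate-consistency")
  expect_identical(a$resource_ref$resource, "worked-example")
})

test_that("unresolved specifications and malformed profiles fail before evaluation", {
  fx <- engine_fixture(n = 3)
  p <- dq_profile(
    dq_use_case("uc", "x"), list(coordinates_ie()),
    list(dq_dimension("d", "COMPLETENESS", "coordinates", "DATASET",
                      "no-such-spec")))
  expect_error(generate_report(p, fx$dataset, fx$registry),
               "unresolved specification.*no-such-spec")

  p2 <- dq_profile(
    dq_use_case("uc", "x"), list(coordinates_ie()),
    list(dq_dimension("d", "COMPLETENESS", "ghost-ie", "DATASET",
                      "completeness")))
  expect_error(generate_report(p2, fx$dataset, fx$registry),
               "malformed profile")
})

test_that("record outcomes aggregate to exact proportions", {
  q <- function(v) measure_result("COMPLETED", qualitative = v)
  expect_identical(
    aggregate_record_outcomes(list(q("COMPLETE"), q("COMPLETE"),
                                   q("NOT_COMPLETE")),
                              "COMPLETE")$quantitative,
    2 / 3)
  expect_identical(
    aggregate_record_outcomes(list(q("X"), q("X")), "X")$quantitative, 1)
  expect_identical(aggregate_record_outcomes(list(), "X")$status,
                   "PREREQUISITES_NOT_MET")
  # prerequisite failures count as not positive
  expect_identical(
    aggregate_record_outcomes(
      list(q("COMPLETE"), measure_result("PREREQUISITES_NOT_MET")),
      "COMPLETE")$quantitative,
    0.5)
  set.seed(13)
  for (i in 1:20) {
    vals <- sample(c("COMPLETE", "NOT_COMPLETE"), sample(1:30, 1),
                   replace = TRUE)
    out <- aggregate_record_outcomes(lapply(vals, q), "COMPLETE")
    expect_identical(out$quantitative, mean(vals == "COMPLETE"))
  }
})

test_that("dataset-level proportions in reports equal brute-force recounts", {
  fx <- engine_fixture(n = 40,
                       rates = defect_rates(p_missing_coord = 0.3,
                                            p_missing_taxon_ranks = 0.3),
                       seed = 9)
  rep <- generate_report(fx$profile, fx$dataset, fx$registry)
  by_elem <- split(rep$measures,
                   vapply(rep$measures, `[[`, character(1), "element_ref"))
  # coordinate completeness: dataset measure vs recount of record measures
  ds <- by_elem[["coord-completeness-dataset"]][[1]]$result$quantitative
  recount <- oracle_proportion(
    lapply(by_elem[["coord-completeness-record"]], function(a) a$result),
    "COMPLETE")
  expect_identical(ds, recount)
})

test_that("assurance filtering retains exactly the fully-compliant records", {
  fx <- engine_fixture(n = 30,
                       rates = defect_rates(p_missing_coord = 0.25,
                                            p_out_of_range = 0.2,
                                            p_wrong_country = 0.2),
                       seed = 4)
  rep <- generate_report(fx$profile, fx$dataset, fx$registry)
  res <- filter_fit_for_use(fx$dataset, fx$profile, rep)

  # partition: retained and excluded are disjoint and cover the dataset
  expect_identical(
    sort(c(res$retained_row_ids, res$exclusions$row_id)),
    0:(n_records(fx$dataset) - 1L))
  expect_length(intersect(res$retained_row_ids, res$exclusions$row_id), 0L)
  # every exclusion names at least one failing criterion
  expect_true(all(nzchar(res$exclusions$failed_criteria)))
  # ground truth: a record survives iff all its coordinate flags hold
  fl <- fx$truth$flags
  expect_identical(res$retained_row_ids,
                   which(fl$coord_complete & fl$coord_conformant &
                           fl$coord_consistent) - 1L)
  # retained records re-validate compliant on all record-level criteria
  rep2 <- generate_report(fx$profile, res$retained, fx$registry)
  res2 <- filter_fit_for_use(res$retained, fx$profile, rep2)
  expect_identical(nrow(res2$exclusions), 0L)
  expect_identical(res2$retained$records, res$retained$records)
})

test_that("filtering an all-compliant dataset is the identity", {
  fx <- engine_fixture(n = 12, rates = defect_rates(), seed = 2)
  rep <- generate_report(fx$profile, fx$dataset, fx$registry)
  res <- filter_fit_for_use(fx$dataset, fx$profile, rep)
  expect_identical(res$retained$records, fx$dataset$records)
  expect_identical(nrow(res$exclusions), 0L)
})

test_that("accepted amendments produce a new dataset and changelog; originals untouched", {
  fx <- engine_fixture(n = 20,
                       rates = defect_rates(p_missing_taxon_ranks = 0.4),
                       seed = 6)
  before <- fx$dataset$records
  rep <- generate_report(fx$profile, fx$dataset, fx$registry)
  res <- apply_amendments(fx$dataset, rep, amendment_policy("accept_all"),
                          fx$profile)
  expect_identical(fx$dataset$records, before)
  n_blanked <- sum(!fx$truth$flags$taxon_complete)
  expect_identical(sort(unique(res$changelog$row_id)),
                   (which(!fx$truth$flags$taxon_complete) - 1L))
  expect_true(all(res$changelog$field %in% c("genus", "family")))
  expect_identical(nrow(res$changelog), 2L * n_blanked)

  # monotonicity: taxon completeness never decreases after control
  ie <- taxon_ie()
  m_before <- measure_completeness_dataset(fx$dataset, ie)$quantitative
  m_after <- measure_completeness_dataset(res$amended, ie)$quantitative
  expect_gte(m_after, m_before)
  expect_identical(m_after, 1)
})

test_that("amendment policies gate acceptance; prevention is never applied", {
  fx <- engine_fixture(n = 15,
                       rates = defect_rates(p_missing_taxon_ranks = 0.5,
                                            p_misspelled_name = 0.5),
                       seed = 8)
  rep <- generate_report(fx$profile, fx$dataset, fx$registry)

  none <- apply_amendments(fx$dataset, rep,
                           amendment_policy("accept_types",
                                            types = character()),
                           fx$profile)
  expect_identical(none$amended$records, fx$dataset$records)
  expect_identical(nrow(none$changelog), 0L)

  corr <- apply_amendments(fx$dataset, rep,
                           amendment_policy("accept_types",
                                            types = "CORRECTION"),
                           fx$profile)
  expect_true(all(corr$changelog$enhancement_id == "fill-taxon"))

  # accept_all never applies the PREVENTION name suggestions
  all_res <- apply_amendments(fx$dataset, rep,
                              amendment_policy("accept_all"), fx$profile)
  expect_false("scientificName" %in% all_res$changelog$field)
  # but the suggestions were still reported as assertions
  sug <- Filter(function(a) a$element_ref == "suggest-names",
                rep$amendments)
  expect_length(sug, 15L)
  expect_true(any(vapply(sug, function(a) a$result$status, character(1))
                  == "PROPOSED"))

  # interactive_list applies nothing but lists proposals
  inter <- apply_amendments(fx$dataset, rep,
                            amendment_policy("interactive_list"),
                            fx$profile)
  expect_identical(nrow(inter$changelog), 0L)
  expect_gt(nrow(inter$proposals), 0L)
})

test_that("conflicting proposals for the same field are dropped and logged", {
  ref <- toy_reference()
  registry <- builtin_registry(ref)
  # two correction enhancements proposing different countries for one record
  fake_spec_a <- dq_specification("force-country-a", "always proposes Atlantis")
  fake_spec_b <- dq_specification("force-country-b", "always proposes Borduria")
  registry <- register_mechanism(
    registry, fake_spec_a,
    dq_mechanism("test/a", coverage = "SPECIFIC",
                 implements = "force-country-a"),
    function(resource, ie, reference, params)
      amendment_result("PROPOSED", c(country = "Atlantis"), "forced"))
  registry <- register_mechanism(
    registry, fake_spec_b,
    dq_mechanism("test/b", coverage = "SPECIFIC",
                 implements = "force-country-b"),
    function(resource, ie, reference, params)
      amendment_result("PROPOSED", c(country = "Borduria"), "forced"))
  profile <- dq_profile(
    dq_use_case("uc", "conflict"), list(coordinates_ie()),
    list(dq_dimension("d", "CONSISTENCY", "coordinates", "SINGLE_RECORD",
                      "coordinate-consistency")),
    list(),
    list(dq_enhancement("ea", "set country A", "CORRECTION", "d",
                        "force-country-a"),
         dq_enhancement("eb", "set country B", "CORRECTION", "d",
                        "force-country-b")))
  dataset <- dq_dataset(list(c(decimalLatitude = "5",
                               decimalLongitude = "5", country = "")))
  rep <- generate_report(profile, dataset, registry)
  res <- apply_amendments(dataset, rep, amendment_policy("accept_all"),
                          profile)
  expect_identical(nrow(res$changelog), 0L)
  expect_identical(nrow(res$conflicts), 1L)
  expect_identical(res$conflicts$field, "country")
  expect_identical(res$amended$records[[1]][["country"]], "")
})

test_that("reports are deterministic for fixed inputs (excluding timestamp)", {
  fx <- engine_fixture(n = 8,
                       rates = defect_rates(p_missing_coord = 0.3),
                       seed = 5)
  r1 <- generate_report(fx$profile, fx$dataset, fx$registry)
  r2 <- generate_report(fx$profile, fx$dataset, fx$registry)
  r1$generated_at <- r2$generated_at <- "fixed"
  expect_identical(report_payload(r1), report_payload(r2))
})

test_that("every assertion in a full engine run passes the five-component invariant", {
  fx <- engine_fixture(n = 10, rates = random_seeded <- defect_rates(
    p_missing_coord = 0.3, p_missing_taxon_ranks = 0.3,
    p_misspelled_name = 0.3), seed = 10)
  rep <- generate_report(fx$profile, fx$dataset, fx$registry)
  for (a in c(rep$measures, rep$validations, rep$amendments))
    expect_valid_assertion(a)
})
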