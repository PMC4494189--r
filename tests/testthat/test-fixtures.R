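test_that("fixture specs validate their fields", {
  expect_error(fixture_spec(codelist_probability = 1.2), "probability")
  expect_error(fixture_spec(n_items_per_group = c(5L, 2L)), "range")
  expect_error(fixture_spec(datatype_weights = c(text = 1)), "sum")
  expect_s3_class(fixture_spec(), "fixture_spec")
})

test_that("generators are fully deterministic under the seed", {
  expect_equal(generate_odm_fixture(fixture_spec(seed = 1, n_forms = 10L)),
               generate_odm_fixture(fixture_spec(seed = 1, n_forms = 10L)))
  a <- suppressMessages(generate_cda_fixture(fixture_spec(seed = 5)))
  b <- suppressMessages(generate_cda_fixture(fixture_spec(seed = 5)))
  expect_identical(fixture_xml(a), fixture_xml(b))
  # and do not disturb the caller's RNG stream
  set.seed(99); x <- runif(1)
  set.seed(99); invisible(generate_odm_fixture(fixture_spec(seed = 2)))
  expect_identical(runif(1), x)
})

test_that("generated studies span shapes and exercise every data type", {
  expect_length(generate_odm_fixture(fixture_spec(n_forms = 0L))$forms, 0L)
  s <- generate_odm_fixture(fixture_spec(seed = 3, n_forms = 4L))
  expect_setequal(unique(vapply(s$items, `[[`, character(1), "data_type")),
                  odm_datatypes)
  expect_equal(nrow(validate_odm_structure(s)), 0L)
  # a one-form CRF of about 14 items, the scale of a small vital-signs form
  crf <- generate_odm_fixture(fixture_spec(
    seed = 4, n_forms = 1L, n_itemgroups_per_form = 2L,
    n_items_per_group = 7L))
  expect_length(crf$items, 14L)
})

test_that("generated documents validate and exercise the naming cases", {
  for (seed in c(1L, 6L)) {
    doc <- suppressMessages(generate_cda_fixture(fixture_spec(seed = seed)))
    expect_equal(nrow(validate_cda_structure(doc)), 0L)
    nms <- flat_names(flatten_cda(doc))
    expect_true("recordTarget.patientRole.patient.name.given" %in% nms)
    expect_true("recordTarget.patientRole.patient.name.family" %in% nms)
    expect_true("recordTarget.patientRole.telecom.attributes.value" %in% nms)
  }
  # attribute_probability only governs the random subtrees: with the same
  # seed, raising it from 0 to 1 adds attribute items and nothing else is
  # structurally different about where they can appear
  n_attr <- function(p) {
    doc <- suppressMessages(generate_cda_fixture(fixture_spec(
      seed = 2, attribute_probability = p)))
    sum(vapply(flatten_cda(doc), `[[`, character(1),
               "source_kind") == "attribute")
  }
  expect_true(n_attr(1) > n_attr(0))
})

test_that("every injected defect kind is detected by the validator", {
  kinds_study <- c("dangling-reference", "duplicate-oid")
  kinds_doc <- c("missing-header-field", "unknown-value-type")
  for (seed in 1:10) {
    s <- generate_odm_fixture(fixture_spec(seed = seed))
    for (k in kinds_study) {
      m <- inject_defect(s, k)
      f <- validate_odm_structure(m)
      expect_true(nrow(f) >= 1L, info = paste(k, "seed", seed))
      expect_true(k %in% f$kind, info = paste(k, "seed", seed))
    }
    d <- suppressMessages(generate_cda_fixture(fixture_spec(seed = seed)))
    for (k in kinds_doc) {
      f <- validate_cda_structure(inject_defect(d, k))
      expect_true(nrow(f) >= 1L, info = paste(k, "seed", seed))
      expect_true(k %in% f$kind, info = paste(k, "seed", seed))
    }
  }
})

test_that("defect injection rejects impossible combinations", {
  s <- generate_odm_fixture(fixture_spec(seed = 1))
  d <- suppressMessages(generate_cda_fixture(fixture_spec(seed = 1)))
  expect_error(inject_defect(s, "missing-header-field"), "CDA")
  expect_error(inject_defect(d, "duplicate-oid"), "ODM")
  expect_error(inject_defect(s, "no-such-kind"))
})
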