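test_that("nested patient names flatten to dotted path names", {
  frag <- paste0("<doc><patient><name><given>Herbert</given>",
                 "<family>Mustermann</family></name></patient></doc>")
  items <- flatten_cda(frag)
  expect_equal(flat_names(items),
               c("patient.name.given", "patient.name.family"))
  expect_equal(vapply(items, `[[`, character(1), "source_kind"),
               c("node_text", "node_text"))
  expect_equal(items[[2L]]$example_value, "Mustermann")
})

test_that("attributes flatten to .attributes. names", {
  items <- flatten_cda(
    '<doc><telecom value="mailto:mustermann@mail.de"/></doc>')
  expect_length(items, 1L)
  expect_equal(items[[1L]]$name, "telecom.attributes.value")
  expect_equal(items[[1L]]$source_kind, "attribute")
  expect_equal(items[[1L]]$attribute_name, "value")
})

test_that("make_item_name joins, suffixes, and rejects empty paths", {
  expect_equal(make_item_name(c("patient", "name", "family")),
               "patient.name.family")
  expect_equal(make_item_name("telecom", "value"),
               "telecom.attributes.value")
  expect_equal(make_item_name("telecom", "value", occurrence = 2L),
               "telecom.attributes.value.2")
  expect_equal(make_item_name(c("a", "b"), occurrence = 3L), "a.b.3")
  expect_error(make_item_name(character()), "path")
})

test_that("repeated siblings get ordinal suffixes from the second on", {
  frag <- paste0("<doc><entry><code>a</code></entry>",
                 "<entry><code>b</code></entry>",
                 "<entry><code>c</code></entry></doc>")
  expect_equal(flat_names(flatten_cda(frag)),
               c("entry.code", "entry.code.2", "entry.code.3"))
})

test_that("type inference follows the documented precedence", {
  expect_equal(infer_datatype("20130324082015+0100"), "datetime")
  expect_equal(infer_datatype("42"), "integer")
  expect_equal(infer_datatype(c("42", "x")), "string")
  expect_equal(infer_datatype(c("1.5", "2.25")), "float")
  expect_equal(infer_datatype(c("true", "false")), "boolean")
  expect_equal(infer_datatype("mailto:a@b.c"), "string")
  # order independence
  expect_equal(infer_datatype(c("x", "42")), infer_datatype(c("42", "x")))
})

test_that("flattening matches the brute-force oracle on random trees", {
  for (seed in 1:40) {
    doc <- suppressMessages(generate_cda_fixture(fixture_spec(
      seed = seed, cda_depth = c(2L, 6L), cda_fanout = c(1L, 3L))))
    got <- flat_names(flatten_cda(doc))
    want <- oracle_flatten_names(fixture_xml(doc))
    expect_equal(length(got), length(want), info = paste("seed", seed))
    expect_equal(sort(got), sort(want), info = paste("seed", seed))
    expect_false(anyDuplicated(got) > 0L)
  }
})

test_that("flattening is deterministic for identical input and config", {
  doc <- suppressMessages(generate_cda_fixture(fixture_spec(seed = 77)))
  expect_identical(flatten_cda(doc), flatten_cda(doc))
})

test_that("names stripped of suffixes equal the joined source path", {
  doc <- suppressMessages(generate_cda_fixture(fixture_spec(seed = 8)))
  for (it in flatten_cda(doc)) {
    base <- sub("\\.attributes\\..*$", "", it$name)
    base <- sub("\\.[0-9]+$", "", base)
    expect_equal(base, paste(it$source_path, collapse = "."))
  }
})

test_that("config controls skipped attributes, elements and depth", {
  frag <- paste0('<doc><obs classCode="OBS"><value>1</value></obs>',
                 "<skipme><x>2</x></skipme></doc>")
  default_names <- flat_names(flatten_cda(frag))
  expect_true("obs.attributes.classCode" %in% default_names)
  no_struct <- flat_names(flatten_cda(
    frag, reverse_config(keep_structural_attributes = FALSE)))
  expect_false("obs.attributes.classCode" %in% no_struct)
  skipped <- flat_names(flatten_cda(
    frag, reverse_config(skip_elements = "skipme")))
  expect_false(any(grepl("^skipme", skipped)))
  shallow <- flat_names(flatten_cda(frag,
                                    reverse_config(max_path_depth = 1L)))
  expect_equal(shallow, "obs.attributes.classCode")
})

test_that("cda_to_odm builds one valid form with the documented defaults", {
  doc <- read_cda(MINIMAL_CDA)
  study <- suppressMessages(cda_to_odm(doc))
  expect_length(study$forms, 1L)
  expect_equal(study$forms[[1L]]$name, "Brieftext")
  expect_equal(nrow(validate_odm_structure(study)), 0L)
  expect_true(all(vapply(study$items, `[[`, logical(1), "mandatory")))
  expect_false(any(vapply(study$items, `[[`, logical(1), "repeating")))
  nms <- flat_names(study$items)
  expect_true("recordTarget.patientRole.patient.name.given" %in% nms)
  expect_true("recordTarget.patientRole.telecom.attributes.value" %in% nms)
  # example values are preserved as question text
  tele <- Find(function(i)
    i$name == "recordTarget.patientRole.telecom.attributes.value",
    study$items)
  expect_equal(unname(tele$question_text["en"]), "mailto:mustermann@mail.de")
})

test_that("items are grouped by leading path components", {
  study <- suppressMessages(cda_to_odm(read_cda(MINIMAL_CDA)))
  by_oid <- setNames(study$item_groups,
                     vapply(study$item_groups, `[[`, character(1), "oid"))
  g_names <- vapply(study$item_groups, `[[`, character(1), "name")
  expect_true("recordTarget" %in% g_names)
  rt_group <- study$item_groups[[match("recordTarget", g_names)]]
  member_names <- flat_names(lapply(rt_group$item_refs$oid, function(o)
    Find(function(i) i$oid == o, study$items)))
  expect_true(all(grepl("^recordTarget\\.", member_names)))

  deeper <- suppressMessages(cda_to_odm(read_cda(MINIMAL_CDA),
                                        reverse_config(group_by_depth = 2L)))
  expect_true("recordTarget.patientRole" %in%
                vapply(deeper$item_groups, `[[`, character(1), "name"))
})

test_that("a built document without a source tree is a state error", {
  doc <- odm_form_to_cda(build_dob_study(), "F.1")
  expect_error(cda_to_odm(doc), "state error")
  expect_error(flatten_cda(doc), "state error")
})

test_that("reverse conversion output always validates", {
  for (seed in 1:25) {
    doc <- suppressMessages(generate_cda_fixture(fixture_spec(seed = seed)))
    study <- suppressMessages(cda_to_odm(doc))
    expect_equal(nrow(validate_odm_structure(study)), 0L,
                 info = paste("seed", seed))
    expect_false(anyDuplicated(flat_names(study$items)) > 0L)
  }
})
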