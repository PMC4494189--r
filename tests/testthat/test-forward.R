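test_that("the Date-of-Birth item maps to a coded TS entry", {
  doc <- odm_form_to_cda(build_dob_study(), "F.1")
  entry <- doc$sections[[1L]]$entries[[1L]]
  expect_equal(entry$code$code, "C0421451")
  expect_equal(entry$code$display_name, "Date of Birth")
  expect_equal(entry$value_type, "TS")
  expect_equal(nrow(validate_cda_structure(doc)), 0L)
  xml <- xml2::read_xml(write_cda(doc))
  xml2::xml_ns_strip(xml)
  code <- xml2::xml_find_first(xml, "//entry/observation/code")
  expect_equal(xml2::xml_attr(code, "code"), "C0421451")
  expect_equal(xml2::xml_attr(code, "displayName"), "Date of Birth")
  expect_equal(xml2::xml_attr(code, "codeSystem"), "2.16.840.1.113883.6.86")
})

test_that("the type crosswalk is total and code lists force CD", {
  expect_equal(map_item_datatype("float"), "REAL")
  expect_equal(map_item_datatype("date"), "TS")
  expect_equal(map_item_datatype("integer"), "INT")
  expect_equal(map_item_datatype("boolean"), "BL")
  for (dt in odm_datatypes) {
    expect_true(map_item_datatype(dt) %in% cda_value_types)
    expect_equal(map_item_datatype(dt, has_code_list = TRUE), "CD")
  }
})

test_that("a coded item carries its permissible values into the CDA entry", {
  cl <- code_list("CL.1", "Severity", "integer",
                  entries = list(
                    list(coded_value = "1", decode = c(en = "Mild")),
                    list(coded_value = "2", decode = c(en = "Severe"))))
  study <- study_metadata(
    "S.CD", "Coded study",
    forms = list(form_definition("F.1", "Coded form", ref_frame("IG.1", TRUE))),
    item_groups = list(item_group_definition("IG.1", "G", ref_frame("I.1", TRUE))),
    items = list(item_definition("I.1", "Severity", "integer",
                                 code_list_oid = "CL.1")),
    code_lists = list(cl))
  doc <- odm_form_to_cda(study, "F.1")
  entry <- doc$sections[[1L]]$entries[[1L]]
  expect_equal(entry$value_type, "CD")
  expect_equal(entry$code_list_values$code, c("1", "2"))
  # verified again through serialization: the pairs survive write/read
  back <- read_cda(write_cda(doc))
  e2 <- back$sections[[1L]]$entries[[1L]]
  expect_equal(e2$value_type, "CD")
  expect_equal(e2$code_list_values$code, c("1", "2"))
  expect_equal(e2$code_list_values$label, c("Mild", "Severe"))
})

test_that("a form with several item groups flattens to entries in order", {
  sizes <- c(3L, 5L, 2L, 7L)
  items <- list(); groups <- list()
  n <- 0L
  for (g in seq_along(sizes)) {
    oids <- character()
    for (i in seq_len(sizes[g])) {
      n <- n + 1L
      items[[n]] <- item_definition(paste0("I.", n), paste0("Item ", n),
                                    "string")
      oids <- c(oids, paste0("I.", n))
    }
    groups[[g]] <- item_group_definition(paste0("IG.", g), paste0("G", g),
                                         item_refs = ref_frame(oids, TRUE))
  }
  study <- study_metadata(
    "S.SZ", "Sized study",
    forms = list(form_definition("F.1", "Sized form",
                                 ref_frame(paste0("IG.", seq_along(sizes)),
                                           TRUE))),
    item_groups = groups, items = items)
  expect_message(doc <- odm_form_to_cda(study, "F.1"), "itemgroup")
  expect_length(doc$sections, 1L)
  expect_length(doc$sections[[1L]]$entries, sum(sizes))
  expect_equal(doc$sections[[1L]]$title, "Sized form")
  expect_equal(vapply(doc$sections[[1L]]$entries, function(e)
    e$code$display_name, character(1)), paste("Item", seq_len(sum(sizes))))
})

test_that("an empty form yields one empty assessment section", {
  study <- study_metadata(
    "S.E", "Empty form study",
    forms = list(form_definition("F.1", "Empty form")))
  doc <- odm_form_to_cda(study, "F.1")
  expect_length(doc$sections, 1L)
  expect_length(doc$sections[[1L]]$entries, 0L)
  xml <- xml2::read_xml(write_cda(doc))
  xml2::xml_ns_strip(xml)
  expect_true(nzchar(xml2::xml_text(
    xml2::xml_find_first(xml, "//section/text"))))
})

test_that("an unresolvable form OID is a reference error", {
  expect_error(odm_form_to_cda(build_demo_study(), "F.404"),
               "reference error")
})

test_that("whole-study conversion conserves documents and entries", {
  for (seed in c(4L, 21L)) {
    s <- generate_odm_fixture(fixture_spec(seed = seed, n_forms = 10L))
    docs <- suppressMessages(odm_to_cda(s))
    expect_length(docs, 10L)
    total_entries <- sum(vapply(docs, function(d)
      length(d$sections[[1L]]$entries), integer(1)))
    total_refs <- sum(vapply(s$item_groups, function(g)
      nrow(g$item_refs), integer(1)))
    expect_equal(total_entries, total_refs)
    for (d in docs) expect_equal(nrow(validate_cda_structure(d)), 0L)
  }
  empty <- study_metadata("S.N", "No forms")
  expect_length(odm_to_cda(empty), 0L)
})

test_that("every semantic code survives into its entry verbatim", {
  s <- generate_odm_fixture(fixture_spec(seed = 31, umls_probability = 1))
  docs <- suppressMessages(odm_to_cda(s))
  entry_codes <- list()
  for (d in docs)
    for (e in d$sections[[1L]]$entries)
      entry_codes <- c(entry_codes, list(e$code), e$translations)
  entry_keys <- vapply(entry_codes, function(c)
    paste(c$system, c$code), character(1))
  for (it in s$items)
    for (sc in it$semantic_codes)
      expect_true(paste(sc$system, sc$code) %in% entry_keys)
})

test_that("locally minted codes are deterministic across conversions", {
  s <- build_demo_study(n_groups = 2L)
  c1 <- odm_form_to_cda(s, "F.1")$sections[[1L]]$entries[[2L]]$code
  c2 <- odm_form_to_cda(s, "F.1")$sections[[1L]]$entries[[2L]]$code
  expect_identical(c1, c2)
  expect_equal(c1$system, "LOCAL")
})
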