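test_that("a CRF-style ODM document reads into the expected structure", {
  study <- build_demo_study(n_groups = 4L)
  xml <- write_odm(study)
  got <- read_odm(xml)
  expect_length(got$forms, 1L)
  expect_equal(nrow(got$forms[[1L]]$itemgroup_refs), 4L)
  i1001 <- Find(function(i) i$oid == "I.1001", got$items)
  expect_equal(i1001$data_type, "integer")
  expect_equal(i1001$question_text[["en"]], "Value of item 1001?")
})

test_that("a study with zero forms survives the write/read cycle", {
  study <- study_metadata("S.0", "Empty study")
  xml <- write_odm(study)
  expect_false(grepl("FormDef", xml, fixed = TRUE))
  got <- read_odm(xml)
  expect_length(got$forms, 0L)
  expect_length(got$items, 0L)
})

test_that("semantic codes serialize as Alias with Context and Name", {
  xml <- write_odm(build_dob_study())
  doc <- xml2::read_xml(xml)
  xml2::xml_ns_strip(doc)
  alias <- xml2::xml_find_first(doc, "//ItemDef[@OID='I.1']/Alias")
  expect_equal(xml2::xml_attr(alias, "Context"), "UMLS")
  expect_equal(xml2::xml_attr(alias, "Name"), "C0421451")
})

test_that("write/read is the identity on generated studies", {
  for (seed in 1:20) {
    s <- generate_odm_fixture(fixture_spec(seed = seed))
    expect_equal(read_odm(write_odm(s)), s, info = paste("seed", seed))
  }
})

test_that("write_odm is byte-deterministic", {
  s <- generate_odm_fixture(fixture_spec(seed = 9))
  expect_identical(write_odm(s), write_odm(s))
})

test_that("ClinicalData subtrees are ignored with a notice", {
  xml <- write_odm(build_demo_study())
  doc <- xml2::read_xml(xml)
  odm <- xml2::xml_root(doc)
  cd <- xml2::xml_add_child(odm, "ClinicalData", StudyOID = "S.DEMO",
                            MetaDataVersionOID = "MDV.1")
  sd <- xml2::xml_add_child(cd, "SubjectData", SubjectKey = "P-001")
  xml2::xml_add_child(sd, "FormData", FormOID = "F.1")
  expect_message(got <- read_odm(as.character(doc)), "ClinicalData")
  expect_equal(suppressMessages(read_odm(as.character(doc))),
               read_odm(xml))
  expect_length(got$forms, 1L)
})

test_that("malformed and structurally broken input raise typed errors", {
  expect_error(read_odm("<ODM xmlns='http://www.cdisc.org/ns/odm/v1.3'>"),
               "parse error")
  expect_error(
    read_odm(paste0("<ODM xmlns='http://www.cdisc.org/ns/odm/v1.3'>",
                    "<Study OID='S.1'/></ODM>")),
    "MetaDataVersion")
  expect_error(read_odm("<NotODM/>"), "structure error")
})

test_that("reading a document with a dangling ref names the OID", {
  xml <- write_odm(build_demo_study())
  doc <- xml2::read_xml(xml)
  xml2::xml_ns_strip(doc)
  ref <- xml2::xml_find_first(doc, "//ItemGroupRef")
  xml2::xml_set_attr(ref, "ItemGroupOID", "IG.GONE")
  expect_error(read_odm(as.character(doc)), "IG.GONE")
})

test_that("validate_odm_structure flags constructed violations and only those", {
  study <- build_demo_study()
  expect_equal(nrow(validate_odm_structure(study)), 0L)

  broken <- study
  broken$forms[[1L]]$itemgroup_refs$oid[1L] <- "IG.NOPE"
  f <- validate_odm_structure(broken)
  expect_equal(f$kind, "dangling-reference")
  expect_equal(f$subject, "IG.NOPE")
})

test_that("write_odm refuses a study with structural findings", {
  broken <- build_demo_study()
  broken$forms[[1L]]$itemgroup_refs$oid[1L] <- "IG.NOPE"
  expect_error(write_odm(broken), "validation error")
})

test_that("item flags round-trip through ItemRef attributes", {
  s <- build_demo_study()
  s$items[[1L]]$mandatory <- FALSE
  s$item_groups[[1L]]$item_refs$mandatory[1L] <- FALSE
  s$items[[2L]]$repeating <- TRUE
  got <- read_odm(write_odm(s))
  expect_false(got$items[[1L]]$mandatory)
  expect_true(got$items[[2L]]$repeating)
  expect_false(got$items[[3L]]$repeating)
})
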