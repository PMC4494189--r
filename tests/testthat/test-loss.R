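test_that("a header-bearing document round trip is never lossless", {
  doc <- suppressMessages(generate_cda_fixture(fixture_spec(seed = 14)))
  study <- suppressMessages(cda_to_odm(doc))
  regen <- suppressMessages(odm_form_to_cda(study, "F.1"))
  report <- loss_report(doc, regen)
  expect_false(report$identical)
  expect_true(nrow(report$lost) > 0L)
  expect_true("header-dropped" %in% report$lost$class)
})

test_that("identity round trip yields an empty loss record", {
  doc <- suppressMessages(generate_cda_fixture(fixture_spec(seed = 15)))
  report <- loss_report(doc, doc)
  expect_true(report$identical)
  expect_equal(nrow(report$lost), 0L)
  expect_equal(nrow(report$added), 0L)
})

test_that("lost paths equal the brute-force diff of path multisets", {
  naive_paths <- function(doc) {
    x <- xml2::read_xml(as.character(
      if (is.null(doc$raw_tree)) write_cda(doc) else doc$raw_tree))
    xml2::xml_ns_strip(x)
    els <- xml2::xml_find_all(x, "/*//*")
    unlist(lapply(els, function(el) {
      p <- gsub("\\[[0-9]+\\]", "", xml2::xml_path(el))
      p <- paste(strsplit(p, "/", fixed = TRUE)[[1L]][-(1:2)], collapse = "/")
      ats <- names(xml2::xml_attrs(el))
      ats <- ats[!grepl("^xmlns", ats)]
      c(p, if (length(ats)) paste0(p, "/@", sub("^.*:", "", ats)))
    }))
  }
  for (seed in c(3L, 19L, 27L)) {
    doc <- suppressMessages(generate_cda_fixture(fixture_spec(seed = seed)))
    study <- suppressMessages(cda_to_odm(doc))
    regen <- suppressMessages(odm_form_to_cda(study, "F.1"))
    report <- loss_report(doc, regen)
    a <- naive_paths(doc); b <- naive_paths(regen)
    tb <- table(b)
    want_lost <- sort(unlist(lapply(unique(a), function(p) {
      extra <- sum(a == p) - if (p %in% names(tb)) tb[[p]] else 0L
      rep(p, max(extra, 0L))
    })))
    expect_equal(sort(report$lost$path), want_lost, info = paste("seed", seed))
  }
})

test_that("loss classes separate header, narrative and body structure", {
  xml <- paste0(
    '<ClinicalDocument xmlns="urn:hl7-org:v3">',
    '<id root="2.25.77"/><code code="11490-0" codeSystemName="LOINC"/>',
    '<title>T</title><effectiveTime value="20130324082015+0100"/>',
    '<recordTarget><patientRole><id root="1.2.3"/></patientRole>',
    '</recordTarget>',
    '<component><structuredBody><component><section>',
    '<title>S</title><text><table><tr><td>styled</td></tr></table></text>',
    '<organizer><component><observation><value>7</value></observation>',
    '</component></organizer>',
    '</section></component></structuredBody></component>',
    '</ClinicalDocument>')
  doc <- read_cda(xml)
  study <- suppressMessages(cda_to_odm(doc))
  regen <- suppressMessages(odm_form_to_cda(study, "F.1"))
  report <- loss_report(doc, regen)
  classes <- split(report$lost$path, report$lost$class)
  expect_true(any(grepl("^recordTarget", classes[["header-dropped"]])))
  expect_true(any(grepl("section/text/table", classes[["narrative-ignored"]])))
  expect_true(any(grepl("organizer", classes[["hierarchy-flattened"]])))
})

test_that("forward round trip loses the itemgroup partition and says so", {
  s <- generate_odm_fixture(fixture_spec(seed = 23, n_forms = 1L,
                                         n_itemgroups_per_form = c(2L, 4L)))
  doc <- suppressMessages(odm_form_to_cda(s, s$forms[[1L]]$oid))
  rt <- suppressMessages(cda_to_odm(read_cda(write_cda(doc))))
  report <- loss_report(s, rt)
  expect_true("itemgroup-lost" %in% report$lost$class)
  # but no item was dropped
  expect_false("item-dropped" %in% report$lost$class)
})

test_that("an unchanged study reports no itemgroup loss", {
  s <- generate_odm_fixture(fixture_spec(seed = 24))
  report <- loss_report(s, s)
  expect_true(report$identical)
})
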