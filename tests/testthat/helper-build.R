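# Small hand-built fixtures shared across test files.

# One-form study in the shape of a CRF with several item groups; item I.1001
# carries a data type, question text and a UMLS annotation.
build_demo_study <- function(n_groups = 4L, items_per_group = 1L) {
  items <- list(); groups <- list()
  k <- 1000L
  for (g in seq_len(n_groups)) {
    oids <- character()
    for (i in seq_len(items_per_group)) {
      k <- k + 1L
      oid <- paste0("I.", k)
      items[[length(items) + 1L]] <- item_definition(
        oid = oid, name = paste0("Item ", k), data_type = "integer",
        question_text = c(en = paste0("Value of item ", k, "?")),
        semantic_codes = if (k == 1001L)
          list(semantic_code("UMLS", "C0421451")) else list())
      oids <- c(oids, oid)
    }
    groups[[g]] <- item_group_definition(
      oid = paste0("IG.", g), name = paste0("Group ", g),
      item_refs = ref_frame(oids, TRUE))
  }
  study_metadata(
    study_oid = "S.DEMO", study_name = "Demo study",
    forms = list(form_definition(
      "F.1", "Demo CRF",
      ref_frame(vapply(groups, `[[`, character(1), "oid"), TRUE))),
    item_groups = groups, items = items)
}

# the Date-of-Birth item: UMLS C0421451, date-typed
build_dob_study <- function() {
  study_metadata(
    study_oid = "S.DOB", study_name = "Birth data",
    forms = list(form_definition("F.1", "Demographics",
                                 ref_frame("IG.1", TRUE))),
    item_groups = list(item_group_definition("IG.1", "Demographics",
                                             ref_frame("I.1", TRUE))),
    items = list(item_definition(
      "I.1", "Date of Birth", "date",
      semantic_codes = list(semantic_code("UMLS", "C0421451")))))
}

# minimal hand-written CDA with a patient name and a telecom attribute
MINIMAL_CDA <- paste0(
  '<ClinicalDocument xmlns="urn:hl7-org:v3">',
  '<typeId root="2.16.840.1.113883.1.3" extension="POCD_HD000040"/>',
  '<id root="2.25.1"/>',
  '<code code="11490-0" codeSystem="2.16.840.1.113883.6.1"',
  ' codeSystemName="LOINC" displayName="Physician Discharge summary"/>',
  '<title>Brieftext</title>',
  '<effectiveTime value="20130324082015+0100"/>',
  '<confidentialityCode code="N"/>',
  '<recordTarget><patientRole>',
  '<telecom value="mailto:mustermann@mail.de"/>',
  '<patient><name><given>Herbert</given><family>Mustermann</family>',
  '</name></patient>',
  '</patientRole></recordTarget>',
  '<component><structuredBody><component><section>',
  '<title>Brieftext</title><text>Sehr geehrte Kollegin!</text>',
  '</section></component></structuredBody></component>',
  '</ClinicalDocument>')

flat_names <- function(items) vapply(items, `[[`, character(1), "name")
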