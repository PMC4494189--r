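# Reading, writing and structural validation of HL7 CDA R2 documents
# (namespace urn:hl7-org:v3, ISO/HL7 27932:2009).  The writer emits valid
# CDA *structures*, not HL7-registered templates: no templateId unless the
# caller injects one.

CDA_NS <- "urn:hl7-org:v3"
XSI_NS <- "http://www.w3.org/2001/XMLSchema-instance"

# well-known code system OIDs; vocabularies outside this table fall back to
# a locally minted arc under 2.25 (UUID-derived OIDs)
KNOWN_CODE_SYSTEMS <- c(
  LOINC    = "2.16.840.1.113883.6.1",
  UMLS     = "2.16.840.1.113883.6.86",
  SNOMEDCT = "2.16.840.1.113883.6.96",
  ICD10    = "2.16.840.1.113883.6.3"
)

code_system_oid <- function(system, map = character()) {
  map <- c(map, KNOWN_CODE_SYSTEMS)
  if (system %in% names(map)) return(unname(map[[system]]))
  paste0("2.25.", fnv1a32(system))
}

ACT_CLASS_CODES <- c(observation = "OBS", act = "ACT", procedure = "PROC",
                     encounter = "ENC", supply = "SPLY", organizer = "CLUSTER",
                     substanceAdministration = "SBADM")

# header element names in schema order; also used by the loss classifier
CDA_HEADER_ELEMENTS <- c(
  "realmCode", "typeId", "templateId", "id", "code", "title",
  "effectiveTime", "confidentialityCode", "languageCode", "setId",
  "versionNumber", "copyTime", "recordTarget", "author", "dataEnterer",
  "informant", "custodian", "informationRecipient", "legalAuthenticator",
  "authenticator", "participant", "inFulfillmentOf", "documentationOf",
  "relatedDocument", "authorization", "componentOf"
)

#' Read an HL7 CDA document
#'
#' Parses a ClinicalDocument into a [cda_document].  Header fields are
#' populated where present (missing optional fields become empty strings);
#' every `structuredBody` component becomes one [cda_section] whose entries
#' are recovered from recognizable act-class elements.  A
#' `nonXMLBody`/missing body is tolerated and yields zero sections with a
#' notice.  The parsed source tree is retained in `raw_tree` for the
#' reverse mapping, which flattens the full hierarchy.
#'
#' @param source path to a CDA XML file, a literal XML string, or an
#'   `xml2::xml_document`.
#' @return a [cda_document] with `raw_tree` set.
#' @export
read_cda <- function(source) {
  raw <- parse_xml_input(source)
  if (xml2::xml_name(xml2::xml_root(raw)) != "ClinicalDocument")
    stop("structure error: root element is <",
         xml2::xml_name(xml2::xml_root(raw)),
         ">, expected <ClinicalDocument>", call. = FALSE)

  doc <- xml2::read_xml(as.character(raw))
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)

  txt1 <- function(xpath, node = root) {
    v <- xml2::xml_text(xml2::xml_find_first(node, xpath))
    if (is.na(v)) "" else v
  }
  attr1 <- function(xpath, attr, node = root, default = "") {
    n <- xml2::xml_find_first(node, xpath)
    if (inherits(n, "xml_missing")) return(default)
    v <- xml2::xml_attr(n, attr)
    if (is.na(v)) default else v
  }

  code_from <- function(node) {
    if (inherits(node, "xml_missing") || is.null(node)) return(NULL)
    code <- xml2::xml_attr(node, "code")
    if (is.na(code)) return(NULL)
    sysname <- xml2::xml_attr(node, "codeSystemName")
    sysoid <- xml2::xml_attr(node, "codeSystem")
    dn <- xml2::xml_attr(node, "displayName")
    semantic_code(
      system = if (!is.na(sysname) && nzchar(sysname)) sysname
               else if (!is.na(sysoid)) sysoid else "unknown",
      code = code,
      display_name = if (!is.na(dn)) dn
    )
  }

  doc_code <- code_from(xml2::xml_find_first(root, "./code"))
  if (is.null(doc_code)) doc_code <- semantic_code("unknown", "unknown")

  given <- xml2::xml_text(xml2::xml_find_all(
    root, "./recordTarget/patientRole/patient/name/given"))
  family <- txt1("./recordTarget/patientRole/patient/name/family")
  patient_name <- if (length(given) || nzchar(family))
    list(given = given, family = family)

  header <- cda_header(
    document_id = attr1("./id", "root"),
    document_code = doc_code,
    title = txt1("./title"),
    effective_time = attr1("./effectiveTime", "value"),
    confidentiality_code = attr1("./confidentialityCode", "code"),
    language_code = attr1("./languageCode", "code"),
    patient_name = patient_name,
    custodian_name = txt1(paste0("./custodian/assignedCustodian/",
                                 "representedCustodianOrganization/name")),
    author_name = txt1("./author/assignedAuthor/assignedPerson/name")
  )

  section_nodes <- xml2::xml_find_all(
    root, "./component/structuredBody/component/section")
  if (length(section_nodes) == 0L &&
      length(xml2::xml_find_all(root, "./component/structuredBody")) == 0L)
    odmcda_notice("document has no structuredBody; 0 sections read")

  sections <- lapply(section_nodes, function(sn) {
    entries <- lapply(xml2::xml_find_all(sn, "./entry/*"), function(act) {
      code <- code_from(xml2::xml_find_first(act, "./code"))
      if (is.null(code)) return(NULL)
      values <- xml2::xml_find_all(act, "./value")
      vt <- NULL; val <- NULL; clv <- NULL
      if (length(values)) {
        types <- xml2::xml_attr(values, "type")
        vt <- types[!is.na(types)][1]
        if (identical(vt, "CD")) {
          clv <- data.frame(
            code = xml2::xml_attr(values, "code"),
            label = xml2::xml_attr(values, "displayName"),
            stringsAsFactors = FALSE)
          clv <- clv[!is.na(clv$code), , drop = FALSE]
          clv$label[is.na(clv$label)] <- ""
          if (nrow(clv) == 0L) clv <- NULL
        } else if (identical(vt, "ST")) {
          v <- xml2::xml_text(values[[1]])
          if (nzchar(v)) val <- v
        } else {
          v <- xml2::xml_attr(values[[1]], "value")
          if (!is.na(v)) val <- v
        }
      }
      if (is.null(vt) || is.na(vt)) vt <- "ST"
      trans <- lapply(xml2::xml_find_all(act, "./code/translation"), code_from)
      cda_entry(code = code, value_type = vt,
                act_class = xml2::xml_name(act),
                mood = { m <- xml2::xml_attr(act, "moodCode")
                         if (is.na(m)) "EVN" else m },
                value = val, code_list_values = clv,
                translations = Filter(Negate(is.null), trans))
    })
    cda_section(
      title = txt1("./title", sn),
      section_code = code_from(xml2::xml_find_first(sn, "./code")),
      narrative_text = txt1("./text", sn),
      entries = Filter(Negate(is.null), entries)
    )
  })

  cda_document(header = header, sections = sections, raw_tree = raw)
}

#' Write an HL7 CDA document
#'
#' Serializes a [cda_document] with the mandatory header skeleton (typeId,
#' id, code, title, effectiveTime, confidentialityCode, languageCode,
#' recordTarget, author, custodian) and one `structuredBody` component per
#' section.  Entries serialize as act-class elements with a `code` and a
#' typed `value`; CD entries emit one `<value xsi:type="CD">` per
#' permissible (code, label) pair.  Sections with entries but no narrative
#' get a synthesized text block listing entry display names, since CDA
#' requires human-readable text.  Output is deterministic for equal input.
#'
#' @param doc a [cda_document]; header invariants are validated first.
#' @param path optional output file path.
#' @param code_system_map named character vector mapping vocabulary names to
#'   code-system OIDs, merged over the built-in table (LOINC, UMLS, ...).
#' @return the XML as a character scalar (invisibly `path` when given).
#' @export
write_cda <- function(doc, path = NULL, code_system_map = character()) {
  stopifnot(inherits(doc, "cda_document"))
  findings <- validate_cda_structure(doc)
  if (nrow(findings) > 0L)
    stop("validation error: ", nrow(findings), " structural finding(s); ",
         "first: ", findings$message[1L], call. = FALSE)
  h <- doc$header

  x <- xml2::xml_new_root("ClinicalDocument", xmlns = CDA_NS,
                          `xmlns:xsi` = XSI_NS)
  xml2::xml_add_child(x, "typeId", root = "2.16.840.1.113883.1.3",
                      extension = "POCD_HD000040")
  xml2::xml_add_child(x, "id", root = h$document_id)

  add_code <- function(parent, name, sc, with_translations = list()) {
    cn <- xml2::xml_add_child(parent, name, code = sc$code,
                              codeSystem = code_system_oid(sc$system,
                                                           code_system_map),
                              codeSystemName = sc$system)
    if (!is.null(sc$display_name))
      xml2::xml_set_attr(cn, "displayName", sc$display_name)
    for (tr in with_translations)
      add_code(cn, "translation", tr)
    cn
  }

  add_code(x, "code", h$document_code)
  xml2::xml_add_child(x, "title", h$title)
  xml2::xml_add_child(x, "effectiveTime", value = h$effective_time)
  xml2::xml_add_child(x, "confidentialityCode", code = h$confidentiality_code,
                      codeSystem = "2.16.840.1.113883.5.25")
  if (nzchar(h$language_code))
    xml2::xml_add_child(x, "languageCode", code = h$language_code)

  rt <- xml2::xml_add_child(x, "recordTarget")
  pr <- xml2::xml_add_child(rt, "patientRole")
  xml2::xml_add_child(pr, "id", nullFlavor = "NI")
  if (!is.null(h$patient_name)) {
    pat <- xml2::xml_add_child(pr, "patient")
    nm <- xml2::xml_add_child(pat, "name")
    for (g in h$patient_name$given) xml2::xml_add_child(nm, "given", g)
    if (nzchar(h$patient_name$family %||% ""))
      xml2::xml_add_child(nm, "family", h$patient_name$family)
  }
  au <- xml2::xml_add_child(x, "author")
  xml2::xml_add_child(au, "time", value = h$effective_time)
  aa <- xml2::xml_add_child(au, "assignedAuthor")
  xml2::xml_add_child(aa, "id", nullFlavor = "NI")
  ap <- xml2::xml_add_child(aa, "assignedPerson")
  xml2::xml_add_child(ap, "name", h$author_name)
  cu <- xml2::xml_add_child(x, "custodian")
  ac <- xml2::xml_add_child(cu, "assignedCustodian")
  co <- xml2::xml_add_child(ac, "representedCustodianOrganization")
  xml2::xml_add_child(co, "id", nullFlavor = "NI")
  xml2::xml_add_child(co, "name", h$custodian_name)

  comp <- xml2::xml_add_child(x, "component")
  body <- xml2::xml_add_child(comp, "structuredBody")
  for (s in doc$sections) {
    sc <- xml2::xml_add_child(xml2::xml_add_child(body, "component"), "section")
    if (!is.null(s$section_code)) add_code(sc, "code", s$section_code)
    xml2::xml_add_child(sc, "title", s$title)
    narrative <- s$narrative_text
    if (!nzchar(narrative))
      narrative <- synthesize_narrative(s)
    xml2::xml_add_child(sc, "text", narrative)
    for (e in s$entries) {
      en <- xml2::xml_add_child(sc, "entry")
      act <- xml2::xml_add_child(
        en, e$act_class,
        classCode = ACT_CLASS_CODES[[e$act_class]] %||% "ACT",
        moodCode = e$mood)
      add_code(act, "code", e$code, with_translations = e$translations)
      if (identical(e$value_type, "CD") && !is.null(e$code_list_values)) {
        for (i in seq_len(nrow(e$code_list_values))) {
          vn <- xml2::xml_add_child(act, "value",
                                    code = e$code_list_values$code[i],
                                    displayName = e$code_list_values$label[i])
          xml2::xml_set_attr(vn, "xsi:type", "CD")
        }
      } else if (identical(e$value_type, "ST")) {
        vn <- xml2::xml_add_child(act, "value", e$value %||% "")
        xml2::xml_set_attr(vn, "xsi:type", "ST")
      } else {
        vn <- xml2::xml_add_child(act, "value")
        xml2::xml_set_attr(vn, "xsi:type", e$value_type)
        if (!is.null(e$value)) xml2::xml_set_attr(vn, "value", e$value)
      }
    }
  }
  emit_xml(x, path)
}

synthesize_narrative <- function(section) {
  if (length(section$entries) == 0L)
    return(paste0("Section '", section$title, "' contains no entries."))
  labels <- vapply(section$entries, function(e)
    e$code$display_name %||% e$code$code, character(1))
  paste0("Data elements: ", paste(labels, collapse = "; "), ".")
}

#' Structural validation of a CDA document
#'
#' Self-contained checks mirroring schema conformance at the model's
#' fidelity: mandatory header fields present (`id`, `code`,
#' `effectiveTime`), entry value types from the closed CDA set, CD entries
#' carrying at least one permissible value, and narrative present in any
#' section that has entries (a synthesized narrative counts, so documents
#' headed for [write_cda()] validate before writing).  When `xsd` points to
#' a CDA schema file (user-supplied, not bundled), full schema validation
#' of the serialized document is appended.
#'
#' @param doc a [cda_document].
#' @param xsd optional path to a CDA XSD file.
#' @return a findings data.frame (`kind`, `subject`, `message`); zero rows
#'   means conformant.
#' @export
validate_cda_structure <- function(doc, xsd = NULL) {
  stopifnot(inherits(doc, "cda_document"))
  f <- list()
  h <- doc$header
  hdr_field <- c(id = "document_id", effectiveTime = "effective_time")
  for (el in names(hdr_field)) {
    v <- h[[hdr_field[[el]]]]
    if (is.null(v) || !nzchar(v))
      f[[length(f) + 1L]] <- finding("missing-header-field", el,
        sprintf("missing-header-field: %s", el))
  }
  if (is.null(h$document_code) || !nzchar(h$document_code$code %||% ""))
    f[[length(f) + 1L]] <- finding("missing-header-field", "code",
                                   "missing-header-field: code")
  for (si in seq_along(doc$sections)) {
    s <- doc$sections[[si]]
    for (ei in seq_along(s$entries)) {
      e <- s$entries[[ei]]
      subj <- sprintf("section %d entry %d", si, ei)
      if (!(e$value_type %in% cda_value_types))
        f[[length(f) + 1L]] <- finding("unknown-value-type", subj,
          sprintf("unknown-value-type: '%s' (%s)", e$value_type, subj))
      if (identical(e$value_type, "CD") &&
          !is.null(e$code_list_values) && nrow(e$code_list_values) == 0L)
        f[[length(f) + 1L]] <- finding("empty-code-list", subj,
          sprintf("CD entry with empty permissible-value list (%s)", subj))
      if (!nzchar(e$code$code))
        f[[length(f) + 1L]] <- finding("missing-entry-code", subj,
          sprintf("entry without concept code (%s)", subj))
    }
  }
  out <- do.call(bind_findings, f)
  if (!is.null(xsd) && nrow(out) == 0L)
    out <- bind_findings(out, xsd_findings(write_cda(doc), xsd))
  out
}
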