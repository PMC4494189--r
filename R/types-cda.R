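# In-memory model of an HL7 CDA R2 document at the fidelity the conversion
# needs: a header, a list of sections, and for documents that were read from
# XML the retained parsed tree (needed by the reverse mapping, which flattens
# the full hierarchy rather than this reduced model).

#' CDA entry value types
#'
#' The closed set of CDA data types entries may carry: INT (integer),
#' REAL, ST (string), TS (timestamp), BL (boolean), CD (coded value),
#' ED (encapsulated data).
#' @export
cda_value_types <- c("INT", "REAL", "ST", "TS", "BL", "CD", "ED")

#' Construct a CDA header
#'
#' The descriptive metadata of a ClinicalDocument.  `document_id`,
#' `document_code` and `effective_time` are mandatory on any document this
#' package writes; CDA timestamps use the TS format `YYYYMMDDhhmmss+zzzz`
#' (e.g. `20130324082015+0100`).
#'
#' @param document_id document identifier (serialized as `<id root=...>`) .
#' @param document_code [semantic_code] classifying the document type, e.g.
#'   LOINC `11490-0` for a physician discharge summary.
#' @param title document title.
#' @param effective_time creation timestamp, CDA TS format.
#' @param confidentiality_code confidentiality code (default `"N"`).
#' @param language_code language code (default `"en"`).
#' @param patient_name optional `list(given = , family = )` structured name.
#' @param custodian_name custodian organization name.
#' @param author_name author name.
#' @return an object of class `cda_header`.
#' @export
cda_header <- function(document_id, document_code, title = "",
                       effective_time = "", confidentiality_code = "N",
                       language_code = "en", patient_name = NULL,
                       custodian_name = "", author_name = "") {
  if (!is.null(patient_name))
    stopifnot(is.list(patient_name),
              all(names(patient_name) %in% c("given", "family")))
  stopifnot(inherits(document_code, "semantic_code"))
  structure(list(document_id = document_id, document_code = document_code,
                 title = title, effective_time = effective_time,
                 confidentiality_code = confidentiality_code,
                 language_code = language_code, patient_name = patient_name,
                 custodian_name = custodian_name, author_name = author_name),
            class = "cda_header")
}

#' Construct a CDA entry
#'
#' One structured data point inside a section: an act-class element
#' (observation by default) with a concept code and a typed value slot.
#' For metadata-level conversion the value is usually absent — the entry
#' describes the data element, it does not carry patient data.  CD-typed
#' entries enumerate their permissible values as (code, label) pairs.
#'
#' @param code [semantic_code] identifying the data element.
#' @param value_type one of [cda_value_types].
#' @param act_class act class name, e.g. `"observation"`, `"act"`.
#' @param mood mood code (default `"EVN"`, event).
#' @param value optional value string.
#' @param code_list_values optional data.frame with columns `code`, `label`
#'   for CD entries.
#' @param translations list of additional [semantic_code]s for the same
#'   concept in other vocabularies.
#' @return an object of class `cda_entry`.
#' @export
cda_entry <- function(code, value_type, act_class = "observation",
                      mood = "EVN", value = NULL, code_list_values = NULL,
                      translations = list()) {
  stopifnot(inherits(code, "semantic_code"))
  if (!is.null(code_list_values)) {
    stopifnot(is.data.frame(code_list_values),
              all(c("code", "label") %in% names(code_list_values)))
    rownames(code_list_values) <- NULL
  }
  structure(list(act_class = act_class, mood = mood, code = code,
                 value_type = value_type, value = value,
                 code_list_values = code_list_values,
                 translations = translations),
            class = "cda_entry")
}

#' Construct a CDA section
#'
#' @param title section title.
#' @param entries list of [cda_entry].
#' @param narrative_text human-readable block; when empty at write time a
#'   narrative is synthesized from the entry display names (CDA requires
#'   human-readable text in every section).
#' @param section_code optional [semantic_code] for the section.
#' @return an object of class `cda_section`.
#' @export
cda_section <- function(title, entries = list(), narrative_text = "",
                        section_code = NULL) {
  stopifnot(all(vapply(entries, inherits, logical(1), "cda_entry")))
  structure(list(section_code = section_code, title = title,
                 narrative_text = narrative_text, entries = entries),
            class = "cda_section")
}

#' Construct a CDA document
#'
#' @param header a [cda_header].
#' @param sections list of [cda_section]; may be empty.
#' @param raw_tree retained `xml2::xml_document` of the source; present only
#'   on documents that were read from XML ([read_cda()]), never on built
#'   ones.  The reverse mapping flattens this tree, not the reduced model.
#' @return an object of class `cda_document`.
#' @export
cda_document <- function(header, sections = list(), raw_tree = NULL) {
  stopifnot(inherits(header, "cda_header"),
            all(vapply(sections, inherits, logical(1), "cda_section")))
  structure(list(header = header, sections = sections, raw_tree = raw_tree),
            class = "cda_document")
}

#' @export
print.cda_document <- function(x, ...) {
  cat(sprintf("CDA document '%s' (code %s, %d section(s))%s\n",
              x$header$title, x$header$document_code$code, length(x$sections),
              if (is.null(x$raw_tree)) "" else " [source tree retained]"))
  for (s in x$sections)
    cat(sprintf("  section '%s': %d entr%s\n", s$title, length(s$entries),
                if (length(s$entries) == 1L) "y" else "ies"))
  invisible(x)
}
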