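# Forward mapping: ODM study metadata -> CDA documents.  Each CRF (form)
# becomes one CDA document whose single assessment section holds one coded
# entry per item.  Item-group boundaries cannot be expressed in this layout
# and are dropped with a notice — the conversion is lossy by design.

#' Forward-mapping configuration
#'
#' @param code_system_map named character vector mapping vocabulary names to
#'   code-system OIDs.  UMLS defaults to `2.16.840.1.113883.6.86`;
#'   vocabularies absent from the map fall back to a locally minted OID arc
#'   with a notice.
#' @param default_act_class act class generated for every entry; ODM has no
#'   act-class notion, so one must be chosen.  Default `"observation"` in
#'   event mood, the natural class for a measured data element.
#' @param language language code stamped on the documents.
#' @param document_code [semantic_code] classifying generated documents;
#'   defaults to LOINC `51848-0` (assessment note), matching the choice of
#'   the assessment section as the host for CRF items.
#' @param effective_time fixed CDA TS timestamp used for generated
#'   documents, so conversion output is deterministic.
#' @param header_overrides named list of [cda_header] fields overriding the
#'   placeholder header (a converted form has no real patient, author or
#'   custodian; CDA requires all three, so placeholders are used).
#' @return an object of class `forward_config`.
#' @export
forward_config <- function(code_system_map = c(UMLS = "2.16.840.1.113883.6.86"),
                           default_act_class = "observation",
                           language = "en",
                           document_code = semantic_code(
                             "LOINC", "51848-0", "Assessment note"),
                           effective_time = "20150526000000+0000",
                           header_overrides = list()) {
  assert_string(default_act_class, "default_act_class")
  stopifnot(inherits(document_code, "semantic_code"))
  structure(list(code_system_map = code_system_map,
                 default_act_class = default_act_class,
                 language = language,
                 document_code = document_code,
                 effective_time = effective_time,
                 header_overrides = header_overrides),
            class = "forward_config")
}

#' Map an ODM data type to a CDA value type
#'
#' The total type crosswalk used by the forward mapping:
#' integer -> INT, float -> REAL, text/string -> ST,
#' date/datetime/time -> TS, boolean -> BL.  An item with a code list maps
#' to CD regardless of its base type, since its value space is the
#' enumerated code set.
#'
#' @param data_type one of [odm_datatypes].
#' @param has_code_list whether the item references a code list.
#' @return one of [cda_value_types].
#' @examples
#' map_item_datatype("float")            # "REAL"
#' map_item_datatype("date")             # "TS"
#' map_item_datatype("integer", TRUE)    # "CD"
#' @export
map_item_datatype <- function(data_type, has_code_list = FALSE) {
  data_type <- match.arg(data_type, odm_datatypes)
  if (isTRUE(has_code_list)) return("CD")
  c(text = "ST", string = "ST", integer = "INT", float = "REAL",
    date = "TS", datetime = "TS", time = "TS", boolean = "BL")[[data_type]]
}

#' Convert one ODM form to a CDA document
#'
#' Builds a CDA document with exactly one section — the generic assessment
#' section, titled after the form — containing one entry per item reachable
#' through the form's item groups, in document order.  Entry codes come
#' from the item's first semantic code; items without semantic annotation
#' get a deterministic locally minted code derived from study and item OID.
#' Additional semantic codes become `translation` codes on the entry.
#' Item-group boundaries are not representable and are dropped with a
#' notice; [loss_report()] on the round-tripped study accounts for them.
#'
#' @param study a [study_metadata] object.
#' @param form_oid OID of the form to convert; must resolve in `study`.
#' @param config a [forward_config].
#' @return a [cda_document] (no `raw_tree`; it was built, not read).
#' @export
odm_form_to_cda <- function(study, form_oid, config = forward_config()) {
  stopifnot(inherits(study, "study_metadata"),
            inherits(config, "forward_config"))
  form <- find_by_oid(study$forms, form_oid)
  if (is.null(form))
    stop("reference error: no form with OID '", form_oid, "' in study '",
         study$study_oid, "'", call. = FALSE)

  seen_systems <- character()
  entries <- list()
  n_groups <- 0L
  for (gi in seq_len(nrow(form$itemgroup_refs))) {
    g <- find_by_oid(study$item_groups, form$itemgroup_refs$oid[gi])
    if (is.null(g))
      stop("reference error: form '", form_oid, "' references missing item ",
           "group '", form$itemgroup_refs$oid[gi], "'", call. = FALSE)
    n_groups <- n_groups + 1L
    for (ii in seq_len(nrow(g$item_refs))) {
      item <- find_by_oid(study$items, g$item_refs$oid[ii])
      if (is.null(item))
        stop("reference error: item group '", g$oid, "' references missing ",
             "item '", g$item_refs$oid[ii], "'", call. = FALSE)
      entries[[length(entries) + 1L]] <- item_to_entry(item, study, config)
      seen_systems <- union(seen_systems, vapply(
        item$semantic_codes, `[[`, character(1), "system"))
    }
  }
  unmapped <- setdiff(seen_systems,
                      c(names(config$code_system_map),
                        names(KNOWN_CODE_SYSTEMS)))
  for (s in unmapped)
    odmcda_notice("vocabulary '", s, "' has no configured code-system OID; ",
                  "using a locally minted OID")
  if (n_groups >= 2L)
    odmcda_notice("form '", form$oid, "': ", n_groups, " item groups ",
                  "flattened into one assessment section; itemgroup ",
                  "boundaries are not represented in CDA")

  section <- cda_section(
    title = form$name,
    section_code = semantic_code("LOINC", "51848-0", "Assessment note"),
    entries = entries
  )
  header_fields <- list(
    document_id = paste0("2.25.", fnv1a32(paste(study$study_oid, form$oid))),
    document_code = config$document_code,
    title = form$name,
    effective_time = config$effective_time,
    confidentiality_code = "N",
    language_code = config$language,
    patient_name = list(given = "Example", family = "Patient"),
    custodian_name = "Metadata conversion placeholder custodian",
    author_name = "odmcda metadata converter"
  )
  header_fields <- modifyList(header_fields, config$header_overrides)
  cda_document(header = do.call(cda_header, header_fields),
               sections = list(section))
}

item_to_entry <- function(item, study, config) {
  code <- if (length(item$semantic_codes) > 0L) {
    first <- item$semantic_codes[[1L]]
    # Alias carried no display name on the ODM side; the item name is the
    # concept's label here (Fig-3 style: C0421451 / "Date of Birth")
    semantic_code(first$system, first$code,
                  first$display_name %||% item$name)
  } else {
    semantic_code("LOCAL",
                  paste0("X", fnv1a32(paste(study$study_oid, item$oid))),
                  item$name)
  }
  translations <- if (length(item$semantic_codes) > 1L)
    item$semantic_codes[-1L] else list()
  has_cl <- !is.null(item$code_list_oid)
  clv <- NULL
  if (has_cl) {
    cl <- find_by_oid(study$code_lists, item$code_list_oid)
    if (is.null(cl))
      stop("reference error: item '", item$oid, "' references missing code ",
           "list '", item$code_list_oid, "'", call. = FALSE)
    clv <- data.frame(
      code = vapply(cl$entries, `[[`, character(1), "coded_value"),
      label = vapply(cl$entries, function(e)
        unname(e$decode[["en"]] %||% e$decode[[1L]] %||% ""), character(1)),
      stringsAsFactors = FALSE)
  }
  cda_entry(code = code,
            value_type = map_item_datatype(item$data_type, has_cl),
            act_class = config$default_act_class,
            code_list_values = clv,
            translations = translations)
}

#' Convert a whole ODM study to CDA documents
#'
#' One CDA document per form, in the study's form order.  A failing form
#' aborts the batch with its OID named.
#'
#' @param study a [study_metadata] object.
#' @param config a [forward_config].
#' @return a list of [cda_document], one per form (possibly empty).
#' @export
odm_to_cda <- function(study, config = forward_config()) {
  stopifnot(inherits(study, "study_metadata"))
  lapply(study$forms, function(f) {
    tryCatch(
      odm_form_to_cda(study, f$oid, config),
      error = function(e) stop("conversion of form '", f$oid, "' failed: ",
                               conditionMessage(e), call. = FALSE)
    )
  })
}
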