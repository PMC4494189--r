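# In-memory model of CDISC ODM 1.3.2 study metadata: a study holds forms,
# forms reference item groups, item groups reference items, items may
# reference code lists.  All cross-references are by OID.  Patient-level
# ClinicalData is out of scope throughout.

#' ODM item data types
#'
#' The closed set of ODM data types this package handles.
#' @export
odm_datatypes <- c("text", "string", "integer", "float",
                   "date", "datetime", "time", "boolean")

#' Construct a semantic code
#'
#' A concept code from a named vocabulary, e.g. UMLS `C0421451`
#' ("Date of Birth").  On the ODM side codes travel as `Alias` elements
#' (`Context` = system, `Name` = code); on the CDA side as `code` elements
#' with `codeSystem`/`displayName`.
#'
#' @param system vocabulary name, e.g. `"UMLS"` or `"LOINC"`.
#' @param code the concept code.
#' @param display_name optional human-readable label.
#' @return an object of class `semantic_code`.
#' @examples
#' semantic_code("UMLS", "C0421451", "Date of Birth")
#' @export
semantic_code <- function(system, code, display_name = NULL) {
  assert_string(system, "system")
  assert_string(code, "code")
  if (!is.null(display_name)) assert_string(display_name, "display_name")
  structure(list(system = system, code = code, display_name = display_name),
            class = "semantic_code")
}

#' @export
print.semantic_code <- function(x, ...) {
  cat(sprintf("<%s %s>%s\n", x$system, x$code,
              if (is.null(x$display_name)) "" else paste0(" ", x$display_name)))
  invisible(x)
}

#' Construct an ODM item definition
#'
#' One CRF data element: a name (e.g. "Patient weight"), an ODM data type,
#' optionally a code list reference and semantic codes.  `mandatory` and
#' `repeating` are always materialized; converted CDA items get the
#' conventional defaults `mandatory = TRUE`, `repeating = FALSE` because a
#' CDA instance cannot tell which elements were optional or repeatable.
#'
#' @param oid unique identifier within the study's items.
#' @param name human-readable item name.
#' @param data_type one of [odm_datatypes].
#' @param code_list_oid optional OID of a [code_list] in the same study.
#' @param question_text optional question text; a bare string is stored under
#'   language key `"en"`, otherwise a named character vector keyed by
#'   language code.
#' @param semantic_codes list of [semantic_code] objects.
#' @param mandatory,repeating logical flags.
#' @return an object of class `item_definition`.
#' @export
item_definition <- function(oid, name, data_type,
                            code_list_oid = NULL,
                            question_text = NULL,
                            semantic_codes = list(),
                            mandatory = TRUE,
                            repeating = FALSE) {
  assert_string(oid, "oid")
  assert_string(name, "name")
  data_type <- match.arg(data_type, odm_datatypes)
  if (!is.null(code_list_oid)) assert_string(code_list_oid, "code_list_oid")
  stopifnot(is.logical(mandatory), length(mandatory) == 1L, !is.na(mandatory),
            is.logical(repeating), length(repeating) == 1L, !is.na(repeating))
  if (!all(vapply(semantic_codes, inherits, logical(1), "semantic_code")))
    stop("semantic_codes must be a list of semantic_code objects", call. = FALSE)
  structure(list(
    oid = oid, name = name, data_type = data_type,
    code_list_oid = code_list_oid,
    question_text = normalize_lang_map(question_text, "question_text"),
    semantic_codes = semantic_codes,
    mandatory = mandatory, repeating = repeating
  ), class = "item_definition")
}

#' Construct an ODM item group definition
#'
#' @param oid unique identifier within the study's item groups.
#' @param name human-readable group name.
#' @param item_refs data.frame with columns `oid` (item OID) and `mandatory`
#'   (logical), in presentation order.
#' @param repeating whether the group repeats.
#' @return an object of class `item_group_definition`.
#' @export
item_group_definition <- function(oid, name, item_refs = ref_frame(),
                                  repeating = FALSE) {
  assert_string(oid, "oid")
  assert_string(name, "name")
  structure(list(oid = oid, name = name,
                 repeating = isTRUE(repeating),
                 item_refs = as_ref_frame(item_refs)),
            class = "item_group_definition")
}

#' Construct an ODM form definition
#'
#' @param oid unique identifier within the study's forms.
#' @param name form (CRF) name.
#' @param itemgroup_refs data.frame with columns `oid` (item group OID) and
#'   `mandatory` (logical), in presentation order.  May be empty; an empty
#'   form converts to an empty assessment section.
#' @return an object of class `form_definition`.
#' @export
form_definition <- function(oid, name, itemgroup_refs = ref_frame()) {
  assert_string(oid, "oid")
  assert_string(name, "name")
  structure(list(oid = oid, name = name,
                 itemgroup_refs = as_ref_frame(itemgroup_refs)),
            class = "form_definition")
}

#' Construct an ODM code list
#'
#' @param oid unique identifier within the study's code lists.
#' @param name code list name.
#' @param data_type ODM data type of the coded values.
#' @param entries list of `list(coded_value = , decode = )` pairs; `decode`
#'   is a per-language character vector (bare strings become `c(en = ...)`).
#'   Coded values must be unique.
#' @return an object of class `code_list`.
#' @export
code_list <- function(oid, name, data_type, entries = list()) {
  assert_string(oid, "oid")
  assert_string(name, "name")
  data_type <- match.arg(data_type, odm_datatypes)
  entries <- lapply(entries, function(e) {
    list(coded_value = assert_string(e$coded_value, "coded_value"),
         decode = normalize_lang_map(e$decode, "decode"))
  })
  cv <- vapply(entries, `[[`, character(1), "coded_value")
  if (anyDuplicated(cv))
    stop("coded values must be unique within a code list", call. = FALSE)
  structure(list(oid = oid, name = name, data_type = data_type,
                 entries = entries),
            class = "code_list")
}

#' Construct ODM study metadata
#'
#' The root of the ODM side: forms structured into item groups, item groups
#' consisting of items, plus the study's code lists.  Referential integrity
#' across the collections is checked by [validate_odm_structure()], not here,
#' so partially built studies can be inspected.
#'
#' @param study_oid study OID.
#' @param study_name human-readable study name.
#' @param metadata_version_oid OID of the single MetaDataVersion.
#' @param forms list of [form_definition].
#' @param item_groups list of [item_group_definition].
#' @param items list of [item_definition].
#' @param code_lists list of [code_list].
#' @return an object of class `study_metadata`.
#' @export
study_metadata <- function(study_oid, study_name,
                           metadata_version_oid = "MDV.1",
                           forms = list(), item_groups = list(),
                           items = list(), code_lists = list()) {
  assert_string(study_oid, "study_oid")
  assert_string(study_name, "study_name")
  assert_string(metadata_version_oid, "metadata_version_oid")
  check_all <- function(xs, cls) {
    if (!all(vapply(xs, inherits, logical(1), cls)))
      stop("expected a list of ", cls, " objects", call. = FALSE)
    xs
  }
  structure(list(
    study_oid = study_oid, study_name = study_name,
    metadata_version_oid = metadata_version_oid,
    forms = check_all(forms, "form_definition"),
    item_groups = check_all(item_groups, "item_group_definition"),
    items = check_all(items, "item_definition"),
    code_lists = check_all(code_lists, "code_list")
  ), class = "study_metadata")
}

#' @export
print.study_metadata <- function(x, ...) {
  cat(sprintf("ODM study metadata '%s' (OID %s)\n", x$study_name, x$study_oid))
  cat(sprintf("  %d form(s), %d item group(s), %d item(s), %d code list(s)\n",
              length(x$forms), length(x$item_groups),
              length(x$items), length(x$code_lists)))
  for (f in x$forms)
    cat(sprintf("  form %s '%s': %d item group ref(s)\n",
                f$oid, f$name, nrow(f$itemgroup_refs)))
  invisible(x)
}

# ---- reference frames -------------------------------------------------------

#' Build a reference table
#'
#' Ordered (OID, mandatory) pairs as used by form -> itemgroup and
#' itemgroup -> item references.
#'
#' @param oid character vector of referenced OIDs.
#' @param mandatory logical vector (recycled) of per-reference mandatory flags.
#' @return a data.frame with columns `oid`, `mandatory`.
#' @export
ref_frame <- function(oid = character(), mandatory = logical(length(oid))) {
  if (length(mandatory) == 1L) mandatory <- rep(mandatory, length(oid))
  data.frame(oid = as.character(oid), mandatory = as.logical(mandatory),
             stringsAsFactors = FALSE)
}

as_ref_frame <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("oid", "mandatory") %in% names(x)))
    out <- data.frame(oid = as.character(x$oid),
                      mandatory = as.logical(x$mandatory),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  stop("refs must be a data.frame with columns oid, mandatory", call. = FALSE)
}

# lookup helpers; return NULL when the OID does not resolve
oid_index <- function(xs) setNames(seq_along(xs), vapply(xs, `[[`, character(1), "oid"))

find_by_oid <- function(xs, oid) {
  i <- match(oid, vapply(xs, `[[`, character(1), "oid"))
  if (is.na(i)) NULL else xs[[i]]
}
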