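# Reading, writing and structural validation of CDISC ODM 1.3.2 study
# metadata.  Only the metadata tree (Study/MetaDataVersion/FormDef/
# ItemGroupDef/ItemDef/CodeList) is modelled; ClinicalData subtrees are
# skipped with a notice.

ODM_NS <- "http://www.cdisc.org/ns/odm/v1.3"

#' Read CDISC ODM study metadata
#'
#' Parses an ODM 1.3.2 document into a [study_metadata] object.  The first
#' `Study` and its first `MetaDataVersion` are read; `ClinicalData`
#' (patient-level) subtrees and unknown extension elements are ignored, the
#' former with a notice.  ODM versions 1.3.x other than 1.3.2 are accepted
#' with a notice.
#'
#' @param source path to an ODM XML file, a literal XML string, or an
#'   `xml2::xml_document`.
#' @return a [study_metadata] object.
#' @seealso [write_odm()], [validate_odm_structure()]
#' @export
read_odm <- function(source) {
  doc <- parse_xml_input(source)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "ODM")
    stop("structure error: root element is <", xml2::xml_name(root),
         ">, expected <ODM>", call. = FALSE)
  ns_uri <- xml2::xml_ns(doc)
  if (!any(grepl("cdisc.org/ns/odm", unlist(ns_uri), fixed = TRUE)))
    odmcda_notice("document does not declare the ODM namespace; reading anyway")
  version <- xml2::xml_attr(root, "ODMVersion")
  if (!is.na(version) && !identical(version, "1.3.2"))
    odmcda_notice("ODM version ", version, " read as 1.3.2")

  # local-name matching from here on; prefixes are serialization artifacts
  doc <- xml2::read_xml(as.character(doc))
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)

  n_clin <- length(xml2::xml_find_all(root, ".//ClinicalData"))
  if (n_clin > 0L)
    odmcda_notice("ignoring ", n_clin, " ClinicalData subtree(s): ",
                  "conversion is metadata-only")

  study <- xml2::xml_find_first(root, "./Study")
  if (inherits(study, "xml_missing"))
    stop("structure error: no <Study> element found", call. = FALSE)
  mdv <- xml2::xml_find_first(study, "./MetaDataVersion")
  if (inherits(mdv, "xml_missing"))
    stop("structure error: Study has no <MetaDataVersion>", call. = FALSE)

  study_name <- xml2::xml_text(
    xml2::xml_find_first(study, "./GlobalVariables/StudyName"))
  if (is.na(study_name) || !nzchar(study_name)) study_name <- "Unnamed study"

  attr_or <- function(node, name, default = "") {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) default else v
  }
  yes <- function(x) identical(x, "Yes")

  read_refs <- function(parent, ref_name, oid_attr) {
    refs <- xml2::xml_find_all(parent, paste0("./", ref_name))
    ref_frame(
      oid = vapply(refs, attr_or, character(1), oid_attr),
      mandatory = vapply(refs, function(r) yes(attr_or(r, "Mandatory", "Yes")),
                         logical(1))
    )
  }

  forms <- lapply(xml2::xml_find_all(mdv, "./FormDef"), function(fd) {
    form_definition(
      oid = attr_or(fd, "OID"), name = attr_or(fd, "Name"),
      itemgroup_refs = read_refs(fd, "ItemGroupRef", "ItemGroupOID")
    )
  })

  igs <- lapply(xml2::xml_find_all(mdv, "./ItemGroupDef"), function(gd) {
    item_group_definition(
      oid = attr_or(gd, "OID"), name = attr_or(gd, "Name"),
      repeating = yes(attr_or(gd, "Repeating", "No")),
      item_refs = read_refs(gd, "ItemRef", "ItemOID")
    )
  })

  # item-level flags live on the refs; fold them back onto the definitions
  # (first ref wins for mandatory, any "Yes" wins for repeating)
  ref_nodes <- xml2::xml_find_all(mdv, "./ItemGroupDef/ItemRef")
  ref_item  <- vapply(ref_nodes, attr_or, character(1), "ItemOID")
  ref_mand  <- vapply(ref_nodes, function(r) yes(attr_or(r, "Mandatory", "Yes")),
                      logical(1))
  ref_rep   <- vapply(ref_nodes, function(r) yes(attr_or(r, "Repeating", "No")),
                      logical(1))

  items <- lapply(xml2::xml_find_all(mdv, "./ItemDef"), function(id) {
    oid <- attr_or(id, "OID")
    clr <- xml2::xml_find_first(id, "./CodeListRef")
    qt_nodes <- xml2::xml_find_all(id, "./Question/TranslatedText")
    qt <- if (length(qt_nodes)) {
      langs <- vapply(qt_nodes, function(t) {
        l <- xml2::xml_attr(t, "lang")
        if (is.na(l) || !nzchar(l)) "en" else l
      }, character(1))
      setNames(vapply(qt_nodes, xml2::xml_text, character(1)), langs)
    }
    codes <- lapply(xml2::xml_find_all(id, "./Alias"), function(a) {
      semantic_code(system = attr_or(a, "Context", "unknown"),
                    code = attr_or(a, "Name", "unknown"))
    })
    hit <- which(ref_item == oid)
    item_definition(
      oid = oid, name = attr_or(id, "Name"),
      data_type = attr_or(id, "DataType", "text"),
      code_list_oid = if (inherits(clr, "xml_missing")) NULL
                      else attr_or(clr, "CodeListOID"),
      question_text = qt,
      semantic_codes = codes,
      mandatory = if (length(hit)) ref_mand[hit[1L]] else TRUE,
      repeating = if (length(hit)) any(ref_rep[hit]) else FALSE
    )
  })

  code_lists <- lapply(xml2::xml_find_all(mdv, "./CodeList"), function(cl) {
    entries <- lapply(xml2::xml_find_all(cl, "./CodeListItem"), function(ci) {
      tt <- xml2::xml_find_all(ci, "./Decode/TranslatedText")
      langs <- vapply(tt, function(t) {
        l <- xml2::xml_attr(t, "lang")
        if (is.na(l) || !nzchar(l)) "en" else l
      }, character(1))
      list(coded_value = attr_or(ci, "CodedValue"),
           decode = setNames(vapply(tt, xml2::xml_text, character(1)), langs))
    })
    code_list(oid = attr_or(cl, "OID"), name = attr_or(cl, "Name"),
              data_type = attr_or(cl, "DataType", "text"), entries = entries)
  })

  out <- study_metadata(
    study_oid = attr_or(study, "OID", "S.1"),
    study_name = study_name,
    metadata_version_oid = attr_or(mdv, "OID", "MDV.1"),
    forms = forms, item_groups = igs, items = items, code_lists = code_lists
  )
  dangling <- validate_odm_structure(out)
  dangling <- dangling[dangling$kind == "dangling-reference", , drop = FALSE]
  if (nrow(dangling) > 0L)
    stop("reference error: dangling OID reference(s): ",
         paste(unique(dangling$subject), collapse = ", "), call. = FALSE)
  out
}

#' Write CDISC ODM study metadata
#'
#' Serializes a [study_metadata] object as namespace-correct ODM 1.3.2 XML.
#' Output is deterministic: element order follows the object, and the file
#' header carries a fixed creation timestamp so equal inputs yield
#' byte-identical output.  Semantic codes serialize as ODM `Alias` elements
#' (`Context` = system, `Name` = code); an alias cannot carry a display
#' name, which is why forward mapping recovers display names from item
#' names.  Per-reference `Mandatory` flags ride on `ItemGroupRef`/`ItemRef`;
#' an item-level `Repeating = TRUE` is emitted as a `Repeating` attribute on
#' its refs (and omitted when `FALSE`, the schema-clean common case).
#'
#' @param study a [study_metadata] object; validated before any output.
#' @param path optional file path; when given the XML is written there and
#'   the path returned invisibly.
#' @return the XML as a character scalar (invisibly when `path` is given).
#' @export
write_odm <- function(study, path = NULL) {
  stopifnot(inherits(study, "study_metadata"))
  findings <- validate_odm_structure(study)
  if (nrow(findings) > 0L)
    stop("validation error: ", nrow(findings), " structural finding(s); ",
         "first: ", findings$message[1L], call. = FALSE)

  doc <- xml2::xml_new_root(
    "ODM", xmlns = ODM_NS,
    FileOID = paste0("FO.", study$study_oid),
    FileType = "Snapshot",
    CreationDateTime = "1970-01-01T00:00:00",
    ODMVersion = "1.3.2"
  )
  st <- xml2::xml_add_child(doc, "Study", OID = study$study_oid)
  gv <- xml2::xml_add_child(st, "GlobalVariables")
  xml2::xml_add_child(gv, "StudyName", study$study_name)
  xml2::xml_add_child(gv, "StudyDescription", study$study_name)
  xml2::xml_add_child(gv, "ProtocolName", study$study_name)
  mdv <- xml2::xml_add_child(st, "MetaDataVersion",
                             OID = study$metadata_version_oid,
                             Name = paste(study$study_name, "metadata"))

  yn <- function(x) if (isTRUE(x)) "Yes" else "No"
  items_by_oid <- oid_index(study$items)

  for (f in study$forms) {
    fd <- xml2::xml_add_child(mdv, "FormDef", OID = f$oid, Name = f$name,
                              Repeating = "No")
    for (i in seq_len(nrow(f$itemgroup_refs)))
      xml2::xml_add_child(fd, "ItemGroupRef",
                          ItemGroupOID = f$itemgroup_refs$oid[i],
                          Mandatory = yn(f$itemgroup_refs$mandatory[i]),
                          OrderNumber = as.character(i))
  }
  for (g in study$item_groups) {
    gd <- xml2::xml_add_child(mdv, "ItemGroupDef", OID = g$oid, Name = g$name,
                              Repeating = yn(g$repeating))
    for (i in seq_len(nrow(g$item_refs))) {
      oid <- g$item_refs$oid[i]
      ref <- xml2::xml_add_child(gd, "ItemRef", ItemOID = oid,
                                 Mandatory = yn(g$item_refs$mandatory[i]),
                                 OrderNumber = as.character(i))
      it <- study$items[[items_by_oid[[oid]]]]
      if (isTRUE(it$repeating)) xml2::xml_set_attr(ref, "Repeating", "Yes")
    }
  }
  for (it in study$items) {
    id <- xml2::xml_add_child(mdv, "ItemDef", OID = it$oid, Name = it$name,
                              DataType = it$data_type)
    if (!is.null(it$question_text)) {
      q <- xml2::xml_add_child(id, "Question")
      for (lang in names(it$question_text)) {
        tt <- xml2::xml_add_child(q, "TranslatedText", it$question_text[[lang]])
        xml2::xml_set_attr(tt, "xml:lang", lang)
      }
    }
    if (!is.null(it$code_list_oid))
      xml2::xml_add_child(id, "CodeListRef", CodeListOID = it$code_list_oid)
    for (sc in it$semantic_codes)
      xml2::xml_add_child(id, "Alias", Context = sc$system, Name = sc$code)
  }
  for (cl in study$code_lists) {
    cln <- xml2::xml_add_child(mdv, "CodeList", OID = cl$oid, Name = cl$name,
                               DataType = cl$data_type)
    for (e in cl$entries) {
      ci <- xml2::xml_add_child(cln, "CodeListItem", CodedValue = e$coded_value)
      dec <- xml2::xml_add_child(ci, "Decode")
      for (lang in names(e$decode)) {
        tt <- xml2::xml_add_child(dec, "TranslatedText", e$decode[[lang]])
        xml2::xml_set_attr(tt, "xml:lang", lang)
      }
    }
  }
  emit_xml(doc, path)
}

#' Structural validation of ODM study metadata
#'
#' Self-contained referential and invariant checks: every referenced OID
#' must resolve exactly once, OIDs must be unique within each collection,
#' data types must come from the closed ODM set.  When `xsd` points to the
#' official ODM 1.3.2 schema (not bundled), the serialized study is
#' additionally schema-validated and violations appended.
#'
#' @param study a [study_metadata] object.
#' @param xsd optional path to an ODM XSD file.
#' @return a data.frame of findings with columns `kind`, `subject`,
#'   `message`; zero rows means conformant.
#' @export
validate_odm_structure <- function(study, xsd = NULL) {
  stopifnot(inherits(study, "study_metadata"))
  f <- list()
  oids_of <- function(xs) vapply(xs, `[[`, character(1), "oid")

  for (coll in c("forms", "item_groups", "items", "code_lists")) {
    oids <- oids_of(study[[coll]])
    for (d in unique(oids[duplicated(oids)]))
      f[[length(f) + 1L]] <- finding("duplicate-oid", d,
        sprintf("OID '%s' occurs more than once in %s", d, coll))
    if (any(!nzchar(oids)))
      f[[length(f) + 1L]] <- finding("empty-oid", coll,
        sprintf("empty OID in %s", coll))
  }

  ig_oids <- oids_of(study$item_groups)
  item_oids <- oids_of(study$items)
  cl_oids <- oids_of(study$code_lists)

  for (form in study$forms)
    for (oid in setdiff(form$itemgroup_refs$oid, ig_oids))
      f[[length(f) + 1L]] <- finding("dangling-reference", oid,
        sprintf("form '%s' references missing item group '%s'", form$oid, oid))
  for (g in study$item_groups)
    for (oid in setdiff(g$item_refs$oid, item_oids))
      f[[length(f) + 1L]] <- finding("dangling-reference", oid,
        sprintf("item group '%s' references missing item '%s'", g$oid, oid))
  for (it in study$items) {
    if (!is.null(it$code_list_oid) && !(it$code_list_oid %in% cl_oids))
      f[[length(f) + 1L]] <- finding("dangling-reference", it$code_list_oid,
        sprintf("item '%s' references missing code list '%s'",
                it$oid, it$code_list_oid))
    if (!(it$data_type %in% odm_datatypes))
      f[[length(f) + 1L]] <- finding("unknown-datatype", it$oid,
        sprintf("item '%s' has data type '%s' outside the ODM set",
                it$oid, it$data_type))
  }

  out <- do.call(bind_findings, f)
  if (!is.null(xsd) && nrow(out) == 0L)
    out <- bind_findings(out, xsd_findings(write_odm(study), xsd))
  out
}

# ---- shared XML plumbing ----------------------------------------------------

parse_xml_input <- function(source) {
  if (inherits(source, "xml_document")) return(source)
  if (is.raw(source)) return(xml2::read_xml(source))
  if (!is_string(source)) stop("source must be a path, XML string, raw ",
                               "vector or xml_document", call. = FALSE)
  tryCatch(
    xml2::read_xml(source),
    error = function(e) stop("parse error: ", conditionMessage(e), call. = FALSE)
  )
}

emit_xml <- function(doc, path = NULL) {
  txt <- as.character(doc)
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(path))
  }
  txt
}

xsd_findings <- function(xml_text, xsd) {
  schema <- xml2::read_xml(xsd)
  ok <- xml2::xml_validate(xml2::read_xml(xml_text), schema)
  if (isTRUE(ok)) return(no_findings())
  msgs <- attr(ok, "errors") %||% "schema validation failed"
  do.call(bind_findings,
          lapply(msgs, function(m) finding("schema-violation", "document", m)))
}
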