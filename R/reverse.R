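# Reverse mapping: CDA documents -> ODM study metadata.  CDA nests its data
# in a variable hierarchy and stores values both as node text and as XML
# attributes; ODM wants a flat list of named items.  The flattener therefore
# concatenates element local names into dotted item names
# ("patient.name.family") and surfaces each attribute as its own item
# ("telecom.attributes.value").  Leaf names are not unique in CDA, so
# repeated names get ordinal suffixes from the second occurrence on.

#' Reverse-mapping configuration
#'
#' @param skip_attributes attribute names never converted.  Defaults to the
#'   serialization-only attributes `xsi:schemaLocation` and `xsi:type`
#'   (namespace declarations are always skipped).
#' @param skip_elements element local names never descended into.
#' @param max_path_depth maximum element depth flattened; deeper content is
#'   ignored.
#' @param group_by_depth number of leading path components that define the
#'   item-group assignment: all items sharing the first `group_by_depth`
#'   components land in one group (default 1, e.g. one group for all
#'   `recordTarget.*` items) — the smallest rule that yields valid,
#'   navigable ODM.
#' @param keep_structural_attributes whether RIM structural attributes
#'   (`classCode`, `moodCode`, `typeCode`) are converted.  They are data in
#'   the same sense as `telecom/@value`, so the default keeps them; set
#'   `FALSE` to exclude them.
#' @param entry_aware when `TRUE` (default), recognizable structured
#'   entries (act-class elements with a concept code) are converted via
#'   their codes and display names instead of being flattened, so a
#'   document generated from ODM converts back to items with the original
#'   names, types and semantic codes.  Set `FALSE` for a purely structural
#'   flattening of the whole tree.
#' @return an object of class `reverse_config`.
#' @export
reverse_config <- function(skip_attributes = c("xsi:schemaLocation",
                                               "xsi:type"),
                           skip_elements = character(),
                           max_path_depth = 64L,
                           group_by_depth = 1L,
                           keep_structural_attributes = TRUE,
                           entry_aware = TRUE) {
  stopifnot(max_path_depth >= 1L, group_by_depth >= 1L)
  if (!keep_structural_attributes)
    skip_attributes <- union(skip_attributes,
                             c("classCode", "moodCode", "typeCode"))
  structure(list(skip_attributes = skip_attributes,
                 skip_elements = skip_elements,
                 max_path_depth = as.integer(max_path_depth),
                 group_by_depth = as.integer(group_by_depth),
                 keep_structural_attributes = keep_structural_attributes,
                 entry_aware = isTRUE(entry_aware)),
            class = "reverse_config")
}

#' Build a unique ODM item name from an element path
#'
#' Joins the element local names with dots, appends
#' `".attributes." + attribute` for attribute-borne values, and appends the
#' sibling ordinal from the second occurrence on — so the first occurrence
#' keeps the plain concatenated name.
#'
#' @param path character vector of element local names, outermost first.
#' @param attribute optional attribute name.
#' @param occurrence how many times this name has been produced in the
#'   current conversion, including this one (>= 1).
#' @return the dotted item name.
#' @examples
#' make_item_name(c("patient", "name", "family"))        # "patient.name.family"
#' make_item_name("telecom", "value")                    # "telecom.attributes.value"
#' make_item_name("telecom", "value", occurrence = 2)    # "telecom.attributes.value.2"
#' @export
make_item_name <- function(path, attribute = NULL, occurrence = 1L) {
  if (length(path) == 0L || any(!nzchar(path)))
    stop("path must be a non-empty vector of element names", call. = FALSE)
  stopifnot(occurrence >= 1L)
  name <- paste(path, collapse = ".")
  if (!is.null(attribute)) name <- paste0(name, ".attributes.", attribute)
  if (occurrence > 1L) name <- paste0(name, ".", occurrence)
  name
}

#' Infer an ODM data type from observed values
#'
#' Checked in order: integer (all values parse as integers), float (all
#' parse as decimal numbers), date / datetime (all match CDA TS timestamp
#' patterns; a time part or zone offset makes it datetime), boolean (all in
#' true/false), otherwise string.  Deterministic and order-independent.
#'
#' @param values non-empty character vector of observed value strings.
#' @return one of [odm_datatypes].
#' @examples
#' infer_datatype("20130324082015+0100")  # "datetime"
#' infer_datatype(c("1", "42"))           # "integer"
#' @export
infer_datatype <- function(values) {
  stopifnot(length(values) > 0L)
  v <- trimws(as.character(values))
  all_match <- function(re) all(grepl(re, v))
  if (all_match("^[+-]?[0-9]+$")) return("integer")
  if (all_match("^[+-]?([0-9]+\\.[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"))
    return("float")
  ts <- "^[0-9]{4,14}(\\.[0-9]+)?([+-][0-9]{4})?$"
  if (all_match(ts)) {
    has_time <- grepl("^[0-9]{9,}", v) | grepl("[+-][0-9]{4}$", v) |
      grepl("\\.", v)
    return(if (any(has_time)) "datetime" else "date")
  }
  if (all(tolower(v) %in% c("true", "false"))) return("boolean")
  "string"
}

#' Flatten a CDA tree into uniquely named items
#'
#' Depth-first, document-order walk over the element tree.  Every element
#' with non-whitespace own text yields one `node_text` item named by its
#' concatenated path; every retained attribute yields one `attribute` item
#' named `path + ".attributes." + attribute`.  Within one element,
#' attributes come first (declaration order), then the text item, then the
#' children.  Names repeated across the document are disambiguated with
#' ordinal suffixes (`".2"`, `".3"`, ...) from the second occurrence on.
#' Paths start at the children of the element passed in, so flattening a
#' fragment rooted above `<patient>` yields `patient.name.given` while a
#' full ClinicalDocument yields
#' `recordTarget.patientRole.patient.name.given`.
#'
#' @param tree a [cda_document] with `raw_tree`, an `xml2` document/node,
#'   a path, or a literal XML string.
#' @param config a [reverse_config].
#' @return a list of `flattened_item` records, each with fields `name`,
#'   `source_kind` (`"node_text"` or `"attribute"`), `source_path`,
#'   `attribute_name`, `example_value`, `inferred_type`.
#' @export
flatten_cda <- function(tree, config = reverse_config()) {
  stopifnot(inherits(config, "reverse_config"))
  root <- flatten_root(tree)
  items <- new.env(parent = emptyenv())
  items$list <- vector("list", 64L)
  items$n <- 0L
  items$seen <- new.env(parent = emptyenv())

  push <- function(path, kind, attribute, value) {
    base <- make_item_name(path, attribute)
    occ <- (get0(base, envir = items$seen, ifnotfound = 0L)) + 1L
    assign(base, occ, envir = items$seen)
    it <- structure(list(
      name = make_item_name(path, attribute, occ),
      source_kind = kind,
      source_path = path,
      attribute_name = attribute,
      example_value = value,
      inferred_type = infer_datatype(value)
    ), class = "flattened_item")
    items$n <- items$n + 1L
    if (items$n > length(items$list))
      items$list <- c(items$list, vector("list", length(items$list)))
    items$list[[items$n]] <- it
  }

  walk <- function(node, path) {
    name <- xml2::xml_name(node)
    if (name %in% config$skip_elements) return(invisible())
    path <- c(path, name)
    if (length(path) > config$max_path_depth) return(invisible())
    attrs <- xml2::xml_attrs(node)
    for (an in names(attrs)) {
      if (grepl("^xmlns", an)) next
      local <- sub("^.*:", "", an)
      if (an %in% config$skip_attributes ||
          local %in% sub("^.*:", "", config$skip_attributes)) next
      push(path, "attribute", local, unname(attrs[[an]]))
    }
    own <- paste(vapply(xml2::xml_find_all(node, "./text()"),
                        xml2::xml_text, character(1)), collapse = "")
    own <- trimws(own)
    if (nzchar(own)) push(path, "node_text", NULL, own)
    for (child in xml2::xml_children(node)) walk(child, path)
    invisible()
  }

  for (child in xml2::xml_children(root)) walk(child, character())
  items$list[seq_len(items$n)]
}

flatten_root <- function(tree) {
  if (inherits(tree, "cda_document")) {
    if (is.null(tree$raw_tree))
      stop("state error: this document was built, not read from XML; ",
           "flattening needs the source tree (use read_cda, or serialize ",
           "with write_cda and re-read)", call. = FALSE)
    tree <- tree$raw_tree
  }
  if (inherits(tree, "xml_node") || inherits(tree, "xml_document")) {
    doc <- xml2::read_xml(as.character(tree))
  } else {
    doc <- parse_xml_input(tree)
    doc <- xml2::read_xml(as.character(doc))
  }
  xml2::xml_ns_strip(doc)
  xml2::xml_root(doc)
}

# reverse of map_item_datatype at the fidelity CDA allows: TS cannot be
# split back into date/datetime/time, so datetime is used
reverse_value_type <- function(value_type, coded_values = NULL) {
  switch(value_type,
         INT = "integer", REAL = "float", ST = "string", TS = "datetime",
         BL = "boolean", ED = "text",
         CD = if (!is.null(coded_values) && length(coded_values))
                infer_datatype(coded_values) else "string",
         "string")
}

#' Convert a CDA document to ODM study metadata
#'
#' Builds one form, named after the document title, from a document that
#' was read from XML.  With `config$entry_aware` (the default), coded
#' entries inside sections become items carrying the entry's display name,
#' reverse-mapped data type, semantic code and (for CD entries) a
#' reconstructed code list, grouped one item group per section; the rest of
#' the tree — header and non-entry body content — is flattened with
#' [flatten_cda()] and grouped by the first `group_by_depth` path
#' components.  Every produced item gets `mandatory = TRUE` and
#' `repeating = FALSE`: a CDA instance cannot tell which elements were
#' optional or repeatable.  Narrative blocks that yield no structured item
#' are skipped with a notice.
#'
#' @param doc a [cda_document] carrying `raw_tree` (i.e. from [read_cda()]).
#' @param config a [reverse_config].
#' @return a [study_metadata] object with one form.
#' @export
cda_to_odm <- function(doc, config = reverse_config()) {
  stopifnot(inherits(doc, "cda_document"), inherits(config, "reverse_config"))
  if (is.null(doc$raw_tree))
    stop("state error: document has no retained source tree; read it from ",
         "XML with read_cda() first", call. = FALSE)

  title <- doc$header$title
  if (!nzchar(title)) title <- "Converted CDA document"

  flat_config <- config
  if (config$entry_aware)
    flat_config$skip_elements <- union(config$skip_elements, "entry")
  flat <- flatten_cda(doc, flat_config)

  used_names <- new.env(parent = emptyenv())
  claim_name <- function(base) {
    occ <- (get0(base, envir = used_names, ifnotfound = 0L)) + 1L
    assign(base, occ, envir = used_names)
    if (occ > 1L) paste0(base, ".", occ) else base
  }

  items <- list(); groups <- list(); code_lists <- list()
  group_key <- character()

  add_group <- function(key, name) {
    i <- match(key, group_key)
    if (!is.na(i)) return(i)
    groups[[length(groups) + 1L]] <<- list(
      oid = paste0("IG.", length(groups) + 1L), name = name,
      item_oids = character())
    group_key <<- c(group_key, key)
    length(groups)
  }
  add_item <- function(group_idx, item) {
    items[[length(items) + 1L]] <<- item
    groups[[group_idx]]$item_oids <<-
      c(groups[[group_idx]]$item_oids, item$oid)
  }

  # flattened items, grouped by leading path components
  for (fi in flat) {
    prefix <- head(fi$source_path, config$group_by_depth)
    gi <- add_group(paste0("path:", paste(prefix, collapse = ".")),
                    paste(prefix, collapse = "."))
    oid <- paste0("I.", length(items) + 1L)
    add_item(gi, item_definition(
      oid = oid, name = claim_name(fi$name),
      data_type = fi$inferred_type,
      question_text = c(en = fi$example_value),
      mandatory = TRUE, repeating = FALSE))
  }

  # structured entries, grouped one item group per section
  if (config$entry_aware) {
    for (si in seq_along(doc$sections)) {
      s <- doc$sections[[si]]
      if (length(s$entries) == 0L) next
      gi <- add_group(paste0("section:", si),
                      if (nzchar(s$title)) s$title else paste("Section", si))
      for (e in s$entries) {
        oid <- paste0("I.", length(items) + 1L)
        cl_oid <- NULL
        if (identical(e$value_type, "CD") && !is.null(e$code_list_values) &&
            nrow(e$code_list_values) > 0L) {
          cl_oid <- paste0("CL.", length(code_lists) + 1L)
          code_lists[[length(code_lists) + 1L]] <- code_list(
            oid = cl_oid,
            name = e$code$display_name %||% e$code$code,
            data_type = infer_datatype(e$code_list_values$code),
            entries = lapply(seq_len(nrow(e$code_list_values)), function(i)
              list(coded_value = e$code_list_values$code[i],
                   decode = c(en = e$code_list_values$label[i]))))
        }
        add_item(gi, item_definition(
          oid = oid,
          name = claim_name(e$code$display_name %||% e$code$code),
          data_type = reverse_value_type(e$value_type,
                                         e$code_list_values$code),
          code_list_oid = cl_oid,
          semantic_codes = c(list(semantic_code(e$code$system, e$code$code,
                                                e$code$display_name)),
                             e$translations),
          mandatory = TRUE, repeating = FALSE))
      }
    }
  }

  n_empty_narrative <- count_unconverted_narratives(doc)
  if (n_empty_narrative > 0L)
    odmcda_notice(n_empty_narrative, " narrative block(s) yielded no ",
                  "structured item and were skipped")

  item_groups <- lapply(groups, function(g)
    item_group_definition(oid = g$oid, name = g$name,
                          item_refs = ref_frame(g$item_oids, TRUE)))
  form <- form_definition(
    oid = "F.1", name = title,
    itemgroup_refs = ref_frame(vapply(groups, `[[`, character(1), "oid"),
                               TRUE))
  study_metadata(
    study_oid = paste0("S.", fnv1a32(paste0("cda:",
      doc$header$document_id %||% "", ":", title))),
    study_name = title,
    metadata_version_oid = "MDV.1",
    forms = list(form), item_groups = item_groups, items = items,
    code_lists = code_lists
  )
}

# narrative <text> blocks whose own text is whitespace-only produce no
# flattened item; count them so the conversion can report what it ignored
count_unconverted_narratives <- function(doc) {
  root <- flatten_root(doc)
  texts <- xml2::xml_find_all(
    root, "./component/structuredBody/component/section/text")
  sum(vapply(texts, function(t) {
    own <- paste(vapply(xml2::xml_find_all(t, "./text()"),
                        xml2::xml_text, character(1)), collapse = "")
    !nzchar(trimws(own))
  }, logical(1)))
}
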