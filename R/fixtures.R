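# Seeded synthetic generators for ODM studies and CDA documents, plus
# defect injectors, so every property test and oracle runs offline.  The
# generators emulate the scale of real material — CRFs of roughly 10-100
# items, CDA documents whose flattening yields hundreds to a few thousand
# items — without reproducing any real study or patient content.

#' Specify a synthetic fixture
#'
#' One spec drives both generators; identical specs produce identical
#' fixtures (full seed determinism).
#'
#' @param seed integer RNG seed.
#' @param n_forms number of forms in a generated ODM study.
#' @param n_itemgroups_per_form integer range (length 1 or 2) of item
#'   groups per form.
#' @param n_items_per_group integer range of items per group.
#' @param datatype_weights named probability vector over [odm_datatypes];
#'   must sum to 1.
#' @param codelist_probability probability an item carries a code list.
#' @param umls_probability probability an item carries a UMLS-style
#'   semantic code.
#' @param cda_depth integer range for the depth of random subtrees in
#'   generated CDA bodies.
#' @param cda_fanout integer range for children per random subtree node.
#' @param attribute_probability probability a random subtree node carries a
#'   data attribute.
#' @param repeated_sibling_probability probability a subtree child repeats
#'   its sibling's element name (exercising the ordinal-suffix naming rule).
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_forms = 3L,
                         n_itemgroups_per_form = c(1L, 4L),
                         n_items_per_group = c(2L, 8L),
                         datatype_weights = setNames(
                           rep(1 / length(odm_datatypes),
                               length(odm_datatypes)), odm_datatypes),
                         codelist_probability = 0.2,
                         umls_probability = 0.3,
                         cda_depth = c(2L, 5L),
                         cda_fanout = c(1L, 3L),
                         attribute_probability = 0.4,
                         repeated_sibling_probability = 0.2) {
  as_range <- function(x, what) {
    x <- as.integer(x)
    if (length(x) == 1L) x <- c(x, x)
    if (length(x) != 2L || any(is.na(x)) || x[1L] > x[2L] || x[1L] < 0L)
      stop(what, " must be a non-negative integer range", call. = FALSE)
    x
  }
  as_prob <- function(p, what) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop(what, " must be a probability in [0, 1]", call. = FALSE)
    p
  }
  if (!is.numeric(datatype_weights) ||
      !setequal(names(datatype_weights), odm_datatypes) ||
      abs(sum(datatype_weights) - 1) > 1e-9)
    stop("datatype_weights must be named over the ODM data types and sum ",
         "to 1", call. = FALSE)
  structure(list(
    seed = as.integer(seed),
    n_forms = as.integer(n_forms),
    n_itemgroups_per_form = as_range(n_itemgroups_per_form,
                                     "n_itemgroups_per_form"),
    n_items_per_group = as_range(n_items_per_group, "n_items_per_group"),
    datatype_weights = datatype_weights[odm_datatypes],
    codelist_probability = as_prob(codelist_probability,
                                   "codelist_probability"),
    umls_probability = as_prob(umls_probability, "umls_probability"),
    cda_depth = as_range(cda_depth, "cda_depth"),
    cda_fanout = as_range(cda_fanout, "cda_fanout"),
    attribute_probability = as_prob(attribute_probability,
                                    "attribute_probability"),
    repeated_sibling_probability = as_prob(repeated_sibling_probability,
                                           "repeated_sibling_probability")
  ), class = "fixture_spec")
}

rint <- function(range) if (range[1L] == range[2L]) range[1L] else
  sample(range[1L]:range[2L], 1L)

FIXTURE_WORDS <- list(
  qualifier = c("Current", "Baseline", "Admission", "Discharge", "Systolic",
                "Diastolic", "Left", "Right", "Initial", "Final"),
  concept = c("Weight", "Height", "Blood Pressure", "Heart Rate",
              "Temperature", "Hemoglobin", "Creatinine", "Diagnosis",
              "Medication Dose", "Pain Score", "Oxygen Saturation",
              "Respiratory Rate"),
  group = c("Vital Signs", "Demographics", "Laboratory", "Medication",
            "Adverse Events", "Medical History", "Physical Examination"),
  form = c("Screening Visit", "Follow Up", "Baseline Assessment",
           "Adverse Event Report", "Discharge Summary Form",
           "Vital Signs Form"),
  given = c("Anna", "Herbert", "Maria", "Paul", "Ida", "Franz"),
  family = c("Mustermann", "Musterfrau", "Example", "Specimen"),
  element = c("organizer", "component", "observationRange", "cluster",
              "region", "detail", "item", "part", "qualifier",
              "interpretation"),
  attribute = c("value", "unit", "code", "extension", "root", "use",
                "determiner")
)

#' Generate a synthetic ODM study
#'
#' Produces a valid [study_metadata] of the configured shape.  All eight
#' ODM data types are exercised when the study has at least eight items;
#' code lists and UMLS-style aliases appear at the configured rates.  Item
#' flags on definitions and refs are kept consistent, and the output always
#' passes [validate_odm_structure()].
#'
#' @param spec a [fixture_spec].
#' @return a [study_metadata] object.
#' @export
generate_odm_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    forms <- list(); item_groups <- list(); items <- list()
    code_lists <- list()
    type_queue <- sample(odm_datatypes)  # coverage first, weights after

    for (fi in seq_len(spec$n_forms)) {
      ig_oids <- character()
      for (gi in seq_len(rint(spec$n_itemgroups_per_form))) {
        item_oids <- character()
        for (ii in seq_len(rint(spec$n_items_per_group))) {
          oid <- paste0("I.", length(items) + 1L)
          if (length(type_queue)) {
            dtype <- type_queue[1L]; type_queue <- type_queue[-1L]
          } else {
            dtype <- sample(names(spec$datatype_weights), 1L,
                            prob = spec$datatype_weights)
          }
          name <- paste(sample(FIXTURE_WORDS$qualifier, 1L),
                        sample(FIXTURE_WORDS$concept, 1L))
          cl_oid <- NULL
          if (runif(1L) < spec$codelist_probability) {
            cl_oid <- paste0("CL.", length(code_lists) + 1L)
            k <- rint(c(2L, 5L))
            code_lists[[length(code_lists) + 1L]] <- code_list(
              oid = cl_oid, name = paste(name, "codes"),
              data_type = "integer",
              entries = lapply(seq_len(k), function(i)
                list(coded_value = as.character(i),
                     decode = c(en = paste("Level", i)))))
          }
          codes <- if (runif(1L) < spec$umls_probability)
            list(semantic_code("UMLS",
                               sprintf("C%07d", sample.int(9999999L, 1L))))
          else list()
          items[[length(items) + 1L]] <- item_definition(
            oid = oid, name = name, data_type = dtype,
            code_list_oid = cl_oid,
            question_text = if (runif(1L) < 0.5)
              c(en = paste0("Please record: ", tolower(name), ".")),
            semantic_codes = codes,
            mandatory = runif(1L) < 0.8, repeating = FALSE)
          item_oids <- c(item_oids, oid)
        }
        g_oid <- paste0("IG.", length(item_groups) + 1L)
        item_groups[[length(item_groups) + 1L]] <- item_group_definition(
          oid = g_oid, name = sample(FIXTURE_WORDS$group, 1L),
          repeating = runif(1L) < 0.2,
          item_refs = ref_frame(item_oids, vapply(
            item_oids, function(o) find_by_oid(items, o)$mandatory,
            logical(1))))
        ig_oids <- c(ig_oids, g_oid)
      }
      forms[[length(forms) + 1L]] <- form_definition(
        oid = paste0("F.", fi),
        name = paste0(sample(FIXTURE_WORDS$form, 1L), " ", fi),
        itemgroup_refs = ref_frame(ig_oids, TRUE))
    }
    study_metadata(
      study_oid = paste0("S.SYN.", spec$seed),
      study_name = paste0("Synthetic study ", spec$seed),
      forms = forms, item_groups = item_groups, items = items,
      code_lists = code_lists)
  })
}

#' Generate a synthetic CDA document
#'
#' Builds a ClinicalDocument with a full mandatory header (including the
#' patient/name/given+family subtree, so the canonical header naming case
#' is always exercised, and a `telecom` element carrying its value as an
#' attribute), and a structured body whose sections hold coded entries plus
#' random nested subtrees at the configured depth, fanout, attribute rate
#' and repeated-sibling rate.  The document is serialized and re-read, so
#' `raw_tree` is set and the result behaves exactly like a document read
#' from disk.  Output always passes [validate_cda_structure()].
#'
#' @param spec a [fixture_spec].
#' @return a [cda_document] with `raw_tree`.
#' @export
generate_cda_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  xml <- with_seed(spec$seed, {
    x <- xml2::xml_new_root("ClinicalDocument", xmlns = CDA_NS,
                            `xmlns:xsi` = XSI_NS)
    xml2::xml_add_child(x, "typeId", root = "2.16.840.1.113883.1.3",
                        extension = "POCD_HD000040")
    xml2::xml_add_child(x, "id",
                        root = paste0("2.25.", sample.int(1e6, 1L)))
    xml2::xml_add_child(x, "code", code = "11490-0",
                        codeSystem = "2.16.840.1.113883.6.1",
                        codeSystemName = "LOINC",
                        displayName = "Physician Discharge summary")
    xml2::xml_add_child(x, "title",
                        paste("Synthetic discharge summary",
                              sample.int(1000L, 1L)))
    xml2::xml_add_child(x, "effectiveTime", value = random_ts())
    xml2::xml_add_child(x, "confidentialityCode", code = "N",
                        codeSystem = "2.16.840.1.113883.5.25")
    xml2::xml_add_child(x, "languageCode", code = "en")

    given <- sample(FIXTURE_WORDS$given, 1L)
    family <- sample(FIXTURE_WORDS$family, 1L)
    rt <- xml2::xml_add_child(x, "recordTarget")
    pr <- xml2::xml_add_child(rt, "patientRole")
    xml2::xml_add_child(pr, "id", root = "1.2.40.0.10",
                        extension = as.character(sample.int(99999L, 1L)))
    xml2::xml_add_child(pr, "telecom",
                        value = paste0("mailto:", tolower(family),
                                       "@mail.example"))
    pat <- xml2::xml_add_child(pr, "patient")
    nm <- xml2::xml_add_child(pat, "name")
    xml2::xml_add_child(nm, "given", given)
    xml2::xml_add_child(nm, "family", family)
    xml2::xml_add_child(pat, "birthTime", value = random_ts(date_only = TRUE))

    au <- xml2::xml_add_child(x, "author")
    xml2::xml_add_child(au, "time", value = random_ts())
    aa <- xml2::xml_add_child(au, "assignedAuthor")
    xml2::xml_add_child(aa, "id", nullFlavor = "NI")
    ap <- xml2::xml_add_child(aa, "assignedPerson")
    xml2::xml_add_child(ap, "name", paste("Dr.", sample(FIXTURE_WORDS$family, 1L)))
    cu <- xml2::xml_add_child(x, "custodian")
    ac <- xml2::xml_add_child(cu, "assignedCustodian")
    co <- xml2::xml_add_child(ac, "representedCustodianOrganization")
    xml2::xml_add_child(co, "id", nullFlavor = "NI")
    xml2::xml_add_child(co, "name", "Synthetic hospital")

    body <- xml2::xml_add_child(xml2::xml_add_child(x, "component"),
                                "structuredBody")
    for (si in seq_len(rint(c(1L, 3L)))) {
      sec <- xml2::xml_add_child(xml2::xml_add_child(body, "component"),
                                 "section")
      xml2::xml_add_child(sec, "code", code = sprintf("1010%d-0", si),
                          codeSystem = "2.16.840.1.113883.6.1",
                          codeSystemName = "LOINC")
      xml2::xml_add_child(sec, "title", paste("Section", si))
      xml2::xml_add_child(sec, "text",
                          paste("Narrative text for section", si, "."))
      for (ei in seq_len(rint(c(1L, 3L)))) {
        en <- xml2::xml_add_child(sec, "entry")
        obs <- xml2::xml_add_child(en, "observation", classCode = "OBS",
                                   moodCode = "EVN")
        xml2::xml_add_child(obs, "code",
                            code = sprintf("C%07d", sample.int(9999999L, 1L)),
                            codeSystem = "2.16.840.1.113883.6.86",
                            codeSystemName = "UMLS",
                            displayName = paste(
                              sample(FIXTURE_WORDS$qualifier, 1L),
                              sample(FIXTURE_WORDS$concept, 1L)))
        vt <- sample(c("INT", "REAL", "TS", "ST", "BL"), 1L)
        vn <- xml2::xml_add_child(obs, "value")
        xml2::xml_set_attr(vn, "xsi:type", vt)
        if (vt != "ST") xml2::xml_set_attr(vn, "value", random_value(vt))
        else xml2::xml_set_text(vn, random_value(vt))
      }
      add_random_subtree(sec, spec, depth = rint(spec$cda_depth))
    }
    as.character(x)
  })
  read_cda(xml)
}

random_ts <- function(date_only = FALSE) {
  d <- sprintf("%04d%02d%02d", sample(1950:2020, 1L), sample.int(12L, 1L),
               sample.int(28L, 1L))
  if (date_only) return(d)
  sprintf("%s%02d%02d%02d+0100", d, sample.int(24L, 1L) - 1L,
          sample.int(60L, 1L) - 1L, sample.int(60L, 1L) - 1L)
}

random_value <- function(type) {
  switch(type,
         INT = as.character(sample.int(500L, 1L)),
         REAL = sprintf("%.1f", runif(1L, 0, 200)),
         TS = random_ts(),
         BL = sample(c("true", "false"), 1L),
         paste(sample(c("normal", "elevated", "stable", "pending"), 1L)))
}

add_random_subtree <- function(parent, spec, depth) {
  if (depth <= 0L) return(invisible())
  node <- xml2::xml_add_child(parent, sample(FIXTURE_WORDS$element, 1L))
  if (runif(1L) < spec$attribute_probability)
    xml2::xml_set_attr(node, sample(FIXTURE_WORDS$attribute, 1L),
                       random_value(sample(c("INT", "REAL", "TS"), 1L)))
  if (depth == 1L) {
    xml2::xml_set_text(node, random_value(sample(c("INT", "REAL", "ST"), 1L)))
    return(invisible())
  }
  n_children <- rint(spec$cda_fanout)
  last_name <- NULL
  for (i in seq_len(max(n_children, 1L))) {
    add_random_subtree(node, spec, depth - 1L)
    kids <- xml2::xml_children(node)
    # repeated siblings: rename this child to its predecessor's name
    if (i > 1L && runif(1L) < spec$repeated_sibling_probability)
      xml2::xml_set_name(kids[[length(kids)]],
                         xml2::xml_name(kids[[length(kids) - 1L]]))
  }
  invisible()
}

#' Inject a single structural defect
#'
#' Returns a copy of a pristine fixture with exactly one defect of the
#' named kind, for validator-soundness (mutation-kill) testing.  Study
#' defects: `dangling-reference` (a form's first item-group ref is pointed
#' at a nonexistent OID), `duplicate-oid` (the second item's OID is set to
#' the first's, with its refs updated so duplication is the only defect).
#' Document defects: `missing-header-field` (effectiveTime blanked),
#' `unknown-value-type` (the first entry's value type set to `"XX"`).
#'
#' @param x a [study_metadata] or [cda_document] fixture.
#' @param defect_kind one of `"dangling-reference"`, `"duplicate-oid"`,
#'   `"missing-header-field"`, `"unknown-value-type"`.
#' @return the mutated copy.
#' @export
inject_defect <- function(x, defect_kind) {
  defect_kind <- match.arg(defect_kind,
                           c("dangling-reference", "duplicate-oid",
                             "missing-header-field", "unknown-value-type"))
  if (inherits(x, "study_metadata")) {
    switch(defect_kind,
      "dangling-reference" = {
        if (length(x$forms) == 0L || nrow(x$forms[[1L]]$itemgroup_refs) == 0L)
          stop("study has no itemgroup refs to break", call. = FALSE)
        x$forms[[1L]]$itemgroup_refs$oid[1L] <- "IG.MISSING"
        x
      },
      "duplicate-oid" = {
        if (length(x$items) < 2L)
          stop("study needs at least two items", call. = FALSE)
        old <- x$items[[2L]]$oid
        new <- x$items[[1L]]$oid
        x$items[[2L]]$oid <- new
        x$item_groups <- lapply(x$item_groups, function(g) {
          g$item_refs$oid[g$item_refs$oid == old] <- new
          g
        })
        x
      },
      stop("defect kind '", defect_kind, "' applies to CDA documents",
           call. = FALSE))
  } else if (inherits(x, "cda_document")) {
    switch(defect_kind,
      "missing-header-field" = {
        x$header$effective_time <- ""
        x
      },
      "unknown-value-type" = {
        found <- FALSE
        for (si in seq_along(x$sections)) {
          if (length(x$sections[[si]]$entries) > 0L) {
            x$sections[[si]]$entries[[1L]]$value_type <- "XX"
            found <- TRUE
            break
          }
        }
        if (!found) stop("document has no entries to corrupt", call. = FALSE)
        x
      },
      stop("defect kind '", defect_kind, "' applies to ODM studies",
           call. = FALSE))
  } else {
    stop("x must be a study_metadata or cda_document", call. = FALSE)
  }
}
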