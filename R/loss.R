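# Round-trip loss accounting.  Both conversion directions are lossy:
# forward, the item-group partition of a form cannot be expressed in a
# single CDA assessment section; backward, the CDA header hierarchy and any
# narrative markup collapse into flat items, so regenerating CDA from the
# converted ODM cannot reproduce the original document.  loss_report makes
# that loss explicit and classified instead of silent.

#' Report what a round-trip conversion lost
#'
#' Compares an original object with its round-tripped counterpart and
#' enumerates the differences, classified by cause.
#'
#' For two [cda_document]s (a CDA -> ODM -> CDA round trip) the comparison
#' is over the multisets of element and attribute paths: paths present in
#' the original but not the regenerated document are classified as
#' `header-dropped` (header subtrees such as `recordTarget`),
#' `narrative-ignored` (section narrative content), or
#' `hierarchy-flattened` (all other body structure); paths only in the
#' regenerated document are reported as `added` (placeholder header,
#' synthesized narrative).
#'
#' For two [study_metadata]s (an ODM -> CDA -> ODM round trip) the report
#' records `itemgroup-lost` entries for every form whose item-group
#' partition is not preserved, plus any item names missing from the round
#' trip.
#'
#' @param original the object before the round trip.
#' @param roundtripped the object after converting there and back.
#' @param ... passed to methods.
#' @return an object of class `odmcda_loss_report` with elements `lost`
#'   (data.frame `path`/`class`), `added` (data.frame `path`), `counts`
#'   (named integer by class) and `identical` (TRUE iff nothing was lost or
#'   added).
#' @export
loss_report <- function(original, roundtripped, ...) {
  UseMethod("loss_report")
}

#' @rdname loss_report
#' @export
loss_report.cda_document <- function(original, roundtripped, ...) {
  stopifnot(inherits(roundtripped, "cda_document"))
  p_orig <- cda_path_multiset(original)
  p_rt <- cda_path_multiset(roundtripped)
  lost <- multiset_diff(p_orig, p_rt)
  added <- multiset_diff(p_rt, p_orig)
  lost_df <- data.frame(path = lost,
                        class = vapply(lost, classify_lost_path, character(1)),
                        stringsAsFactors = FALSE)
  new_loss_report(lost_df, data.frame(path = added, stringsAsFactors = FALSE))
}

#' @rdname loss_report
#' @export
loss_report.study_metadata <- function(original, roundtripped, ...) {
  stopifnot(inherits(roundtripped, "study_metadata"))
  lost <- list()
  rt_names <- vapply(roundtripped$items, `[[`, character(1), "name")
  rt_partition <- partition_signatures(roundtripped)
  for (form in original$forms) {
    orig_sig <- form_partition_signature(original, form)
    if (length(orig_sig) >= 2L && !all(orig_sig %in% rt_partition))
      lost[[length(lost) + 1L]] <- data.frame(
        path = paste0("form:", form$oid),
        class = "itemgroup-lost", stringsAsFactors = FALSE)
  }
  missing_items <- setdiff(
    vapply(original$items, `[[`, character(1), "name"), rt_names)
  for (nm in missing_items)
    lost[[length(lost) + 1L]] <- data.frame(
      path = paste0("item:", nm), class = "item-dropped",
      stringsAsFactors = FALSE)
  lost_df <- if (length(lost)) do.call(rbind, lost)
             else data.frame(path = character(), class = character(),
                             stringsAsFactors = FALSE)
  added <- setdiff(rt_names,
                   vapply(original$items, `[[`, character(1), "name"))
  new_loss_report(lost_df,
                  data.frame(path = if (length(added)) paste0("item:", added)
                                    else character(),
                             stringsAsFactors = FALSE))
}

new_loss_report <- function(lost, added) {
  counts <- if (nrow(lost)) table(lost$class) else table(character())
  structure(list(lost = lost, added = added,
                 counts = setNames(as.integer(counts), names(counts)),
                 identical = nrow(lost) == 0L && nrow(added) == 0L),
            class = "odmcda_loss_report")
}

#' @export
print.odmcda_loss_report <- function(x, ...) {
  if (x$identical) {
    cat("Round trip lossless: no paths lost or added.\n")
    return(invisible(x))
  }
  cat(sprintf("Round-trip loss report: %d path(s) lost, %d added.\n",
              nrow(x$lost), nrow(x$added)))
  for (cl in names(x$counts))
    cat(sprintf("  %-20s %d\n", cl, x$counts[[cl]]))
  invisible(x)
}

# ---- path multisets ---------------------------------------------------------

# Every element path (root child .. element, "/"-joined local names) and
# attribute path (path + "/@" + name) in the document, as a multiset.
# Namespace declarations are serialization artifacts and excluded.
cda_path_multiset <- function(doc) {
  root <- if (inherits(doc, "cda_document") && is.null(doc$raw_tree))
    flatten_root(write_cda(doc)) else flatten_root(doc)
  out <- character()
  walk <- function(node, prefix) {
    path <- if (nzchar(prefix)) paste0(prefix, "/", xml2::xml_name(node))
            else xml2::xml_name(node)
    out[[length(out) + 1L]] <<- path
    for (an in names(xml2::xml_attrs(node))) {
      if (grepl("^xmlns", an)) next
      out[[length(out) + 1L]] <<- paste0(path, "/@", sub("^.*:", "", an))
    }
    for (child in xml2::xml_children(node)) walk(child, path)
  }
  for (child in xml2::xml_children(root)) walk(child, "")
  out
}

multiset_diff <- function(a, b) {
  tb <- table(b)
  out <- character()
  for (p in names(table(a))) {
    extra <- sum(a == p) - if (p %in% names(tb)) tb[[p]] else 0L
    if (extra > 0L) out <- c(out, rep(p, extra))
  }
  out
}

# A group's "signature" is its sorted set of item names; a form's partition
# is preserved iff every original group signature reappears somewhere in the
# round-tripped study.
form_partition_signature <- function(study, form) {
  vapply(form$itemgroup_refs$oid, function(goid) {
    g <- find_by_oid(study$item_groups, goid)
    if (is.null(g)) return("")
    nms <- vapply(g$item_refs$oid, function(io) {
      it <- find_by_oid(study$items, io)
      if (is.null(it)) "" else it$name
    }, character(1))
    paste(sort(nms), collapse = "\x1f")
  }, character(1), USE.NAMES = FALSE)
}

partition_signatures <- function(study) {
  unlist(lapply(study$forms, function(f) form_partition_signature(study, f)))
}

classify_lost_path <- function(path) {
  first <- strsplit(path, "/", fixed = TRUE)[[1L]][1L]
  if (first %in% CDA_HEADER_ELEMENTS) return("header-dropped")
  if (grepl("(^|/)section/text(/|$)", path) ||
      grepl("(^|/)section/text/@", path)) return("narrative-ignored")
  "hierarchy-flattened"
}
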