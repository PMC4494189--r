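# Independent brute-force flattening oracle.  Deliberately implemented on a
# different route than flatten_cda(): elements are enumerated with a single
# XPath query, paths recovered from xml_path(), and name disambiguation done
# vectorized with ave() after the fact.  Used to check item counts and name
# multisets on random trees.

oracle_flatten_names <- function(xml_text,
                                 skip_attributes = c("xsi:schemaLocation",
                                                     "xsi:type"),
                                 max_depth = 64L) {
  doc <- xml2::read_xml(as.character(xml_text))
  xml2::xml_ns_strip(doc)
  skip_local <- sub("^.*:", "", skip_attributes)
  base <- character()
  for (el in xml2::xml_find_all(doc, "/*//*")) {
    segs <- strsplit(gsub("\\[[0-9]+\\]", "", xml2::xml_path(el)),
                     "/", fixed = TRUE)[[1L]]
    segs <- segs[-(1:2)]  # drop leading "" and the root element
    if (length(segs) > max_depth) next
    joined <- paste(segs, collapse = ".")
    attrs <- names(xml2::xml_attrs(el)) %||% character()
    attrs <- attrs[!grepl("^xmlns", attrs)]
    attrs <- attrs[!(attrs %in% skip_attributes |
                       sub("^.*:", "", attrs) %in% skip_local)]
    if (length(attrs))
      base <- c(base, paste0(joined, ".attributes.", sub("^.*:", "", attrs)))
    own <- paste(vapply(xml2::xml_find_all(el, "./text()"),
                        xml2::xml_text, character(1)), collapse = "")
    if (nzchar(trimws(own))) base <- c(base, joined)
  }
  if (length(base) == 0L) return(character())
  occ <- stats::ave(seq_along(base), base, FUN = seq_along)
  ifelse(occ == 1L, base, paste0(base, ".", occ))
}

# raw XML of a document's retained source tree
fixture_xml <- function(doc) as.character(doc$raw_tree)
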