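---
title: "Converting documentation-form metadata between CDISC ODM and HL7 CDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting documentation-form metadata between CDISC ODM and HL7 CDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odmcda)
```

## The problem

Clinical research and clinical care document the same patients in separate
systems with separate standards. Electronic Data Capture (EDC) systems
represent case report forms (CRFs) in CDISC's Operational Data Model (ODM):
a form is structured into item groups, each item group consists of items,
and each item has a name, a data type and optionally a code list.
Electronic Health Record (EHR) systems exchange clinical documents in HL7's
Clinical Document Architecture (CDA): an XML document with a descriptive
header and a body of sections holding narrative text and structured,
coded entries.

`odmcda` converts *metadata* between the two representations — empty forms,
that is, lists of named, typed data elements. Patient-level data
(`ClinicalData` in ODM, real patient content in CDA) is explicitly out of
scope and is skipped with a notice wherever it appears. A documentation
form here is nothing more than a list of data items, each characterized by
a name ("patient weight") and a data type ("float"); layout, skip logic
and rendering are not modelled.

Both directions are *lossy*, for structural reasons that no implementation
can remove, and the package treats making that loss explicit as part of
the conversion contract.

## Forward: ODM form to CDA document

A CRF can be regarded as a patient assessment, so each form becomes one
CDA document whose single section — the generic assessment section —
carries one entry per item reachable through the form's item groups, in
document order. Key rules:

* **One document per form.** A CDA instance is a single clinical document;
  a multi-form study maps to a batch of documents, one per form, in study
  order.
* **Type crosswalk.** `map_item_datatype()` is total over the eight ODM
  types: integer→INT, float→REAL, text/string→ST, date/datetime/time→TS,
  boolean→BL. An item with a code list becomes CD regardless of base type,
  and its permissible values ride on the entry as repeated
  `<value xsi:type="CD">` elements (observation values are 0..* in CDA),
  keeping the output self-contained rather than minting external
  value-set OIDs.
* **Semantic codes.** An item's first semantic code becomes the entry
  code; further codes become `translation` codes under it, CDA's idiom for
  the same concept in another vocabulary. On the ODM side, codes travel as
  `Alias` elements (`Context` = vocabulary, `Name` = code). `Alias`
  cannot carry a display name, so the entry's `displayName` is recovered
  from the item name — which is what the item name *is*: the concept's
  human label.
* **Generated codes.** Items without semantic annotation get a local code
  minted deterministically (an FNV-1a hash of study OID + item OID) under
  a locally derived code-system arc, so repeated conversions are
  reproducible. UMLS maps to its registered OID `2.16.840.1.113883.6.86`;
  unmapped vocabularies fall back to a local arc with a notice.
* **Act classes.** ODM has no act-class notion, so one is generated:
  `observation` in event mood by default, the natural class for a measured
  data element; configurable via `forward_config(default_act_class=)`.
* **Mandatory header.** CDA requires an id, document code, title,
  effective time, record target, author and custodian. A converted form
  has none of these, so deterministic placeholders are used (fixed
  timestamp included, keeping `write_cda()` byte-stable), overridable via
  `forward_config(header_overrides=)`. The default document code is LOINC
  `51848-0` (assessment note), consistent with hosting the items in the
  assessment section; a discharge-summary code would misdescribe a CRF.
* **What is lost.** The item-group partition. All items land in one flat
  section; a form with two or more groups cannot be reconstructed.
  `loss_report()` on the original and round-tripped study records this as
  `itemgroup-lost`.

Outputs are valid CDA *structures*, not HL7-registered templates: no
`templateId` is emitted.

## Reverse: CDA document to ODM study

CDA nests data in a variable hierarchy and stores values both as node text
(`<city>Münster</city>`) and as attributes
(`<telecom value="mailto:..."/>`). `flatten_cda()` walks the tree
depth-first in document order and emits:

* one `node_text` item per element with non-whitespace own text, named by
  the dot-joined element path (`patient.name.family`);
* one `attribute` item per retained attribute, named
  `path + ".attributes." + name` (`telecom.attributes.value`).

Leaf names are not unique in CDA, and no published disambiguation rule
exists, so this package appends ordinal suffixes (`".2"`, `".3"`, ...)
from the *second* occurrence on — the first occurrence keeps the plain
concatenated name, so the canonical printed names above stay exact.
Within one element the order is attributes (declaration order), then the
text item, then children. Whitespace-only text never produces an item;
mixed content contributes its concatenated non-whitespace text.
Namespace prefixes are serialization artifacts and never appear in paths.

Attribute skipping: namespace declarations and the serialization-only
`xsi:schemaLocation` / `xsi:type` are skipped by default. RIM structural
attributes (`classCode`, `moodCode`, `typeCode`) *are* retained — they are
data in the same sense the telecom value is — but
`reverse_config(keep_structural_attributes = FALSE)` excludes them, since
whether they should count as data items is a judgement call.

`cda_to_odm()` builds one form named after the document title. Flattened
items are partitioned into item groups by their first `group_by_depth`
path components (default 1: all `recordTarget.*` items in one group) —
the smallest rule that yields valid, navigable ODM. Every produced item is
`mandatory = TRUE`, `repeating = FALSE`: a CDA instance is one concrete
document and cannot reveal which elements were optional or repeatable.
Data types are inferred from the observed values (`infer_datatype()`:
integer, then float, then CDA TS timestamp patterns, then boolean, else
string — checked in that order, so an all-digit value is an integer and
`20130324082015+0100` is a datetime). The captured example value is stored
in the item's question text (language key `"en"`), keeping the metadata
self-describing without emitting any `ClinicalData`.

**Entry-aware reversal.** A purely structural flattening would turn a
document that *was generated from ODM* into items named
`component.structuredBody...code.attributes.displayName`, destroying the
very names the forward direction preserved. By default
(`reverse_config(entry_aware = TRUE)`) sections' recognizable coded
entries are therefore converted through their codes: the display name
becomes the item name, the value type reverse-maps to an ODM type
(TS→datetime — TS cannot be split back into date/datetime/time), CD
entries get their code list reconstructed, and each section becomes one
item group. The remainder of the tree (header, non-entry body content) is
still flattened structurally. This makes
ODM → CDA → ODM preserve item names, mapped types and semantic codes,
while the item-group partition is still lost. `entry_aware = FALSE` gives
the purely structural behaviour.

**What is lost.** The header hierarchy (a lengthy administrative header is
typical, and most of it has no research value), any narrative markup that
cannot be assigned to structured elements, and the nesting itself.
`loss_report()` compares the element/attribute path multisets of the
original and regenerated documents and classifies every lost path as
`header-dropped`, `narrative-ignored` or `hierarchy-flattened`; it is
never empty for a document with a non-trivial header, and regenerating
the original CDA from converted ODM is explicitly impossible.

## Validation

`validate_odm_structure()` and `validate_cda_structure()` are
self-contained structural checks returning findings as data (never
exceptions): dangling OID references, duplicate OIDs, types outside the
closed sets, missing mandatory header fields. Schema conformance against
the official XSDs is supported but the schemas are *not* bundled (they
are licensed artifacts); pass `xsd =` paths to append full schema
validation. Writers validate before emitting anything.

## The synthetic generators

`generate_odm_fixture()` and `generate_cda_fixture()` exist so that every
property and oracle in the test suite runs offline and seeded.
The ODM generator emits studies of configurable shape (default: 3 forms,
1–4 item groups of 2–8 items each — the scale of routine CRFs, which run
from roughly ten to a hundred items), exercising all eight data types,
code lists at rate 0.2 and UMLS-style aliases at rate 0.3. The CDA
generator always produces the full mandatory header including a
`patient/name/given+family` subtree and an attribute-carrying `telecom`,
so the canonical naming cases are exercised by default, and fills sections
with coded entries plus random nested subtrees (default depth 2–5, fanout
1–3, attribute rate 0.4, repeated-sibling rate 0.2). Large documents —
the tests use a depth-8, fanout-3 configuration flattening to several
thousand items — match the upper scale of real discharge-letter and lab
documents, which reach about three thousand flattened items.

What the fixtures do *not* emulate: clinically meaningful content,
vendor extensions, template-conformant CDA profiles, narrative tables, or
non-UTF-8 encodings. Passing tests therefore demonstrate structural
correctness of the conversion rules, not semantic fidelity on any real
corpus.

`inject_defect()` produces single-defect mutants (dangling reference,
duplicate OID, missing header field, unknown value type) used to show the
validators kill 100% of injected defects.

## Numerical and procedural choices

* Determinism everywhere: writers emit byte-identical XML for equal
  inputs (fixed file-creation timestamps, stable element order); the
  generators restore the caller's RNG state.
* ODM output targets version 1.3.2 exactly; 1.3.x input is accepted with
  a notice. An item-level `Repeating = TRUE` flag is serialized on the
  item's refs (omitted when `FALSE`, keeping the common case
  schema-clean); an item's own mandatory flag is taken from its first ref
  on read.
* Problem sizes in the test suite — up to 200 random trees for the
  flattening oracle, 100 fixtures for the round-trip and defaults
  properties, one ~3000-item document for scale — mirror the corpus sizes
  the conversion is meant for while keeping the default check fast.
* Degenerate inputs are defined, not errors: a form with no item groups
  becomes an empty assessment section with placeholder narrative; a
  document with an empty `structuredBody` yields a study whose items all
  stem from header paths; a built (not read) document cannot be flattened
  and says so.

## Known limitations

* Only the assessment-section layout is generated forward; mapping items
  into other CDA section types is not attempted.
* TS-typed entries reverse to `datetime` even when the origin was a plain
  date or time.
* `Alias` cannot carry display names, so a display name attached to a
  semantic code survives ODM → CDA but not a pass through serialized ODM.
* The flattening keys on local names only; two different-namespace
  elements with the same local name are not distinguished.
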