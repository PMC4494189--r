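Package: odmcda
Title: Convert Documentation-Form Metadata Between CDISC ODM and HL7 CDA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bidirectional, metadata-level conversion between CDISC ODM 1.3.2
    study definitions (forms, item groups, items, code lists) and HL7 CDA R2
    clinical documents. Case report forms become CDA assessment sections with
    one coded entry per item, carrying UMLS-style semantic annotations; CDA
    documents are flattened into uniquely named ODM items by concatenating
    element path names, with XML attributes surfaced as separate items. Both
    directions are lossy by design and the package reports exactly what each
    direction loses (item-group partitions going forward; header hierarchy and
    narrative coming back). Includes structural validators for both formats,
    seeded synthetic generators for ODM studies and CDA trees with defect
    injection, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
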