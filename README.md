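# odmcda

Metadata-level conversion between **CDISC ODM 1.3.2** case-report-form
definitions and **HL7 CDA R2** clinical documents, in both directions,
with an explicit, testable account of what each direction loses.

Clinical research (EDC systems, CDISC standards) and clinical care (EHR
systems, HL7 standards) describe the same data elements — body weight,
date of birth — in incompatible containers. `odmcda` is for informaticians
and study designers who need to move *empty forms* between the two worlds:
a documentation form is a list of items, each with a name, a data type,
optionally a code list and semantic annotations (e.g. UMLS concept codes).
No patient-level data is converted; `ClinicalData` is ignored by design.

## The conversion in brief

**ODM → CDA.** Each form (CRF) becomes one CDA document whose single
assessment section holds one coded entry per item, in document order:

- item → `<entry><observation>` with `code` (first semantic code, or a
  deterministic locally minted code), `displayName` (the item name) and a
  typed `value`;
- type crosswalk: integer→INT, float→REAL, text/string→ST,
  date/datetime/time→TS, boolean→BL; an item with a code list → CD, with
  its permissible (code, label) pairs carried on the entry;
- act classes don't exist in ODM, so they are generated
  (`observation`/EVN by default);
- **lost:** the item-group partition — all items land in one flat section.

**CDA → ODM.** The document's element/attribute hierarchy is flattened
into uniquely named items:

- element text → item named by the dotted path
  (`patient.name.given`, `patient.name.family`);
- attribute → item named `path.attributes.<name>`
  (`telecom.attributes.value`);
- repeated names get ordinal suffixes from the second occurrence on;
- every produced item is `Mandatory = "Yes"`, `Repeating = "No"` — a CDA
  instance can't tell what was optional or repeatable;
- coded entries are recognized and converted through their codes, so a
  document generated from ODM converts back to the original item names,
  types and codes;
- **lost:** the header hierarchy and narrative markup — regenerating the
  original CDA from the converted ODM is impossible, and `loss_report()`
  enumerates and classifies exactly what went missing.

## Worked example

```r
library(odmcda)

study <- study_metadata(
  study_oid = "S.1", study_name = "Demo study",
  forms = list(form_definition("F.1", "Demographics",
                               ref_frame("IG.1", TRUE))),
  item_groups = list(item_group_definition("IG.1", "Demographics",
                                           ref_frame(c("I.1", "I.2"), TRUE))),
  items = list(
    item_definition("I.1", "Date of Birth", "date",
                    semantic_codes = list(semantic_code("UMLS", "C0421451"))),
    item_definition("I.2", "Patient weight", "float")))

doc <- odm_form_to_cda(study, "F.1")
doc
#> CDA document 'Demographics' (code 51848-0, 1 section(s))
#>   section 'Demographics': 2 entries

e <- doc$sections[[1]]$entries[[1]]
cat(e$code$code, "/", e$code$display_name, "->", e$value_type, "\n")
#> C0421451 / Date of Birth -> TS
nrow(validate_cda_structure(doc))   # structural findings
#> [1] 0
```

The Date-of-Birth item became an observation entry coded `C0421451`
(UMLS), displayed as "Date of Birth", valued as a TS (timestamp), and the
document passes structural validation. Converting the written document
back:

```r
back <- cda_to_odm(read_cda(write_cda(doc)))
back
#> ODM study metadata 'Demographics' (OID S.1519640129)
#>   1 form(s), 12 item group(s), 28 item(s), 0 code list(s)
#>   form F.1 'Demographics': 12 item group ref(s)

head(vapply(flatten_cda(read_cda(write_cda(doc))), `[[`, "", "name"), 5)
#> [1] "typeId.attributes.root"      "typeId.attributes.extension"
#> [3] "id.attributes.root"          "code.attributes.code"
#> [5] "code.attributes.codeSystem"
```

The two original items come back with their names, types and codes — plus
26 more items that are nothing but the flattened CDA header and scaffolding
(`typeId.attributes.root`, ...): that asymmetry *is* the documented loss,
and `loss_report(study, back)` / `loss_report(doc, regenerated)` quantify
it per round trip.

A command-line wrapper ships in `inst/cli/odmcda`:

```sh
odmcda odm2cda study.xml -o out/          # one CDA file per form + JSON log
odmcda cda2odm doc.xml -o study.xml       # flattened ODM + JSON log
odmcda validate doc.xml                   # exit 1 on findings
odmcda fixtures cda --seed 7 -o fix.xml   # seeded synthetic fixture
odmcda roundtrip-report doc.xml -o loss.json
```

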