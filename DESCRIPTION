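Package: occaudit
Title: Completeness and Coverage Audits of Species Occurrence Databases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Audits point occurrence databases (GBIF-style opportunistic
    records and systematic survey schemes) for inventory completeness and
    survey coverage bias. Records are filtered with Darwin-Core-style
    criteria, binned into 0.1 degree grid cells, and each cell inventory is
    scored with three completeness metrics: record count, the bias-corrected
    Chao2 completeness index, and the final slope of the species accumulation
    curve. Cells are classified as well-surveyed at low, moderate and high
    threshold tiers, and survey coverage along temporal, spatial and
    environmental gradients is quantified with Kolmogorov-Smirnov D indices
    against the background landscape. A synthetic occurrence generator with
    known ground truth (virtual-ecologist style) makes the whole audit
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
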