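Package: nichemap
Title: Climate-Niche Association Mapping for Wild Nematode Isolates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds climate phenotypes for wild-strain isolation records from
    weather-station observations (nearest-station assignment, station quality
    control, windowed daily aggregation), maps them with a kinship-corrected
    EMMA mixed model, calls and fine-maps QTL by rank correlation of
    moderate/severe-impact variants, and estimates temperature-dependent
    relative fitness from two-strain competition allele counts. Includes a
    synthetic-world generator with planted genetic effects so the whole
    pipeline can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    vcfR,
    optparse
Config/testthat/edition: 3
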