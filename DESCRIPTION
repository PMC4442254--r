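Package: matcite
Title: Extract, Aggregate and Summarise Specimen Data from Taxonomic
    Treatments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with specimen (materials-citation) data
    embedded in taxonomic literature. Reads and writes a compact XML
    dialect for marked-up taxonomic treatments, normalises verbatim
    citation fields (sex counts, individualCount reconciliation,
    collector teams, event dates, elevation bands), exports Darwin Core
    occurrence tables, aggregates specimens, treatments and articles over
    filterable facets (country, institutional collection, collector,
    month, decade, elevation) with an explicit missing-data category,
    builds dashboard chart data, and computes corpus-level biodiversity
    statistics: headline summaries, rarity prevalence (singletons and
    uniques) and the lag between first collection and formal description.
    Includes a seeded synthetic-corpus generator with independent
    ground-truth bookkeeping for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
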