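Package: assemblyaudit
Title: Stewardship Audits of Genome-Assembly Sample Metadata
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits the sample metadata attached to public genome assemblies,
    with a focus on the spatiotemporal records that invasion genomics depends
    on. Parses INSDC-style BioSample attributes (collection_date, geo_loc_name,
    lat_lon and friends) into ordered spatial and temporal granularity levels,
    classifies sample origin (field, laboratory, commercial, managed colony,
    unknown) from a keyword vocabulary, scores per-record completeness,
    applies literature-rescue overrides, classifies field-collected samples
    as native- or expanded-range against a species home-range gazetteer, and
    aggregates cohort-level partitions, per-year trends and income-group
    breakdowns. Includes a seeded synthetic-cohort generator with planted
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
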