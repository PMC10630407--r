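Package: medlineqc
Title: Data Quality Assessment for PubMed/MEDLINE Bibliographic Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing the data quality of PubMed/MEDLINE
    bibliographic records. Stream-parses PubMed-style XML (baseline and
    daily update files, optionally gzip-compressed) into typed records,
    assembles an analysis corpus by applying updates and deletions with
    newest-DateRevised retention, validates persistent identifiers (DOI,
    ORCID, ISNI, GRID) with regular expressions, computes completeness,
    validity and uniqueness metrics and referential integrity against the
    NLM journal list, profiles string fields (length distributions,
    five-number summaries, top-N and extreme-value tables, per-year
    identifier prevalence), and generates seeded synthetic corpora with
    configurable injection of documented MEDLINE data pathologies plus a
    ground-truth manifest for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    tibble,
    dplyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    stringi
Config/testthat/edition: 3
RoxygenNote: 7.3.3
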