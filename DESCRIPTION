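Package: riskterms
Title: Lexicon-Based Audit of Risk-Factor Mentions on Organization Websites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for auditing how organizations discuss
    disease risk factors on their websites. Enumerates the pages of an
    organization's site by same-domain crawling (live, from dated archive
    snapshots, or from local fixture directories), cleans the page set by
    explicit exclusion rules (broken links, undecodable content,
    sponsor/shop/forum pages, non-English pages, per-organization URL
    subsetting), counts occurrences of a categorized term lexicon of breast
    cancer risk factors with word-boundary longest-match semantics, and
    aggregates mentions to per-site tables, a corpus table with
    percent-of-organizations columns, and per-organization average mentions
    per page. A synthetic-website generator with exactly known planted term
    counts makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
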