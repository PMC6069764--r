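Package: meshmir
Title: Semantic MeSH-Term Filtering of miRNA Target Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ontology-based query expansion and multi-round filtering of
    miRNA:target evidence records annotated with MeSH-style disease terms.
    Loads a small is_a hierarchy (OBO subset or edge list), expands a query
    term under Exact-, Broader- or Narrower-Match semantics, filters record
    corpora by publication support and MeSH annotation, excludes miRNAs left
    with zero targets after each round, and reports per-miRNA tallies,
    reduction statistics and a dual-evidence prioritization heuristic.
    Includes a deterministic fixture emulating a published glucocorticoid
    resistance study in pediatric acute lymphoblastic leukemia and a seeded
    generator of randomized corpora for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
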