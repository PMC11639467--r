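Package: renalmine
Title: Comparative Text Mining of Renal Disease Literature Across Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative mining of MEDLINE records on chronic kidney
    disease and renal disease in humans, cats, and dogs. Parses and writes
    MEDLINE flat-format records, annotates corpora against controlled
    category vocabularies (diseases, methods, cells, cytokines, tissues,
    clinical signs, pain types) on MeSH descriptors and abstract text,
    computes capture counts, publication trends, term rankings, proportions,
    three-way overlaps and Fisher exact overlap tests with the category term
    universe as background, and builds term co-occurrence networks with
    first-degree-neighbour sub-network extraction and GraphML/SIF export.
    Includes a synthetic MEDLINE corpus generator with planted term
    associations so the whole pipeline is testable offline with known ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
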