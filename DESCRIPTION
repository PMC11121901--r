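Package: raremesh
Title: Rare-Disease Text Classification from Disease Ontologies and MeSH
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weakly supervised three-class (rare disease, non-rare
    disease, other) text classifiers for biomedical documents. Derives a
    rare-disease term set from a Mondo-style disease ontology cross-referenced
    to Medical Subject Headings (MeSH), directly or through GARD identifiers,
    and expands it through the MeSH tree. Labels MEDLINE/PubMed citation
    records by a deterministic rule cascade over their MeSH headings, samples
    class-balanced train/validation/test splits, trains a transformer-style
    classification head (dropout, dense tanh, dropout, softmax projection)
    with the Adam optimizer, and evaluates with micro- and macro-averaged
    precision/recall/F1 computed with and without the background class.
    Seeded synthetic-fixture generators emulate every external input (MeSH
    XML, ontology JSON, citation XML, news JSONL) so the whole pipeline runs
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
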