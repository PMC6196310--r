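Package: tkrex
Title: Linguistic-Pattern Tree-Kernel Relation Extraction from Biomedical Text
Version: 0.1.0
Authors@R: person("tkrex", "maintainers", email = "tkrex@example.org", role = c("aut", "cre"))
Description: Mines part-of-speech context patterns from relation-candidate
    sentences with an algebraic-invariance score, uses the patterns to prune
    grammatical-relation-centered dependency trees, and classifies
    chemical-protein, chemical-disease and protein-protein relation candidates
    with a smoothed partial tree kernel support vector machine (binary and
    one-vs-all multi-class).  Includes readers and writers for BioCreative-style
    tab-separated corpora and CoNLL-U dependency parses, a deterministic
    fallback tagger and parser, and a synthetic-corpus generator with planted
    relation templates for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
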