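Package: ppistack
Title: Multi-Evidence Protein-Protein Interaction Prediction with a
    Boosted Stacking Meta-Classifier and In-Silico Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale workflow for predicting protein-protein
    interactions (PPIs) from multiple lines of evidence. Four base-level
    detection methods score each candidate pair: primary-sequence
    similarity (pluggable scorer with a k-mer Jaccard fallback), Gene
    Ontology semantic similarity (Pekar lowest-common-subsumer metric
    over the BP, MF and CC branches), domain-domain interaction overlap
    against a known-interaction list, and metabolic-pathway
    co-participation. The six scores form a feature matrix that a
    unit-variance-scaled AdaBoost meta-classifier turns into interaction
    calls, with stratified 10-fold cross-validation reporting. Predicted
    pairs can be screened by an in-silico validation stage: Apriori
    association rules over cellular-component co-occurrence in known
    validated interactions, and lexicon-driven sentence-level text
    mining of interaction evidence with context-exclusion filtering.
    Deterministic generators provide every synthetic input the pipeline
    consumes, so the whole workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    digest,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools,
    parallel
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
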