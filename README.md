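# ppistack

Multi-evidence protein–protein interaction (PPI) prediction with a boosted
stacking meta-classifier, plus an in-silico validation stage for the
predicted pairs.

## The problem

No single line of evidence predicts physical protein interactions
reliably. Sequence similarity, shared Gene Ontology annotation, known
domain–domain contacts and pathway co-membership each capture a different
facet of interaction biology, and each fails on a different subset of
pairs. `ppistack` implements the classic remedy: treat the per-pair scores
of several *detection methods* as base-level predictors of a stacked
generalization scheme and let a boosted meta-classifier learn how to
combine them. Because predicted interactions still need curation, the
package also ships the downstream validation stage: a cellular
co-localization screen built from association rules mined over validated
interactions, and focused sentence-level text mining for interaction
evidence in article text.

The package is aimed at computational biologists who want a transparent,
fully offline, desk-scale implementation of this pipeline — every input it
consumes (annotation records, GO-style DAGs, domain-interaction lists,
validated-pair lists, article text) can be generated synthetically with
planted signal, so the whole workflow is testable without any database
access.

## The model

For a candidate pair (A, B), six evidence scores are computed:

- **Sequence** — a pluggable scorer: precomputed pair scores from an
  external sequence-based predictor, or a self-contained fallback, the
  Jaccard index of the two sequences' 3-mer sets.
- **GO similarity (BP, MF, CC)** — the Pekar edge-based measure. For
  terms t₁, t₂ with shared ancestor *a*:
  sim = depth(a) / (d(t₁,a) + d(t₂,a) + depth(a)),
  maximized over shared ancestors, with depth and distances as minimal
  edge counts in the branch DAG. Term sets are combined by a symmetric
  best-match average; one feature per branch.
- **Domain** — with LDC the known interacting domain pairs (3DID-like)
  and LDP all unordered domain combinations of the pair,
  scoreDomain = |LDC ∩ LDP| / |LDC ∪ LDP|.
- **Pathway** — with V_A, V_B the proteins' pathway sets,
  scorePathway = |V_A ∩ V_B| / |V_A ∪ V_B|.

The feature matrix (rows = pairs, columns = the six scores) is scaled to
unit variance (no centering) and fed to a discrete AdaBoost ensemble of
depth-1 decision stumps (100 rounds by default) — the meta level of the
stack. Training reports stratified 10-fold cross-validation metrics
(accuracy, precision, recall, F1, confusion matrix, ROC/AUC) and refits on
all rows; prediction applies the stored scaling, never refitting it.

Validation stage: cellular-component itemsets of validated pairs are mined
with Apriori under a descending support schedule until the rules cover a
configured set of main compartments; a predicted pair passes the screen
iff some rule links its two proteins' compartments (symmetrically).
Text mining splits article text into sentences, stems and tags tokens,
drops sentences in gene-expression/regulation context via an exclusion
dictionary, and reports sentences where both proteins co-occur with an
interaction term, together with any experimental-method entities found.

## Worked example

```r
library(ppistack)

spec <- fixture_spec(seed = 42, n_pairs = 400)   # planted-signal benchmark
dag  <- generate_go_dag(spec)
ds   <- generate_interaction_dataset(spec, dag)

fm    <- build_feature_matrix(ds$pairs, ds$store, dag, ds$known)
model <- ppi_train(fm, seed = 42)
model
#> <ppi_model: AdaBoost, 100 stumps over 6 features, seed 42>
#> 10-fold CV: accuracy 0.9950, F1 0.9950, AUC 0.9996

round(coef(model), 3)      # boosting weight accumulated per feature
#>     seq   go_bp   go_mf   go_cc  domain pathway
#>   0.224   0.141   0.137   0.227   0.125   0.146

preds <- predict(model, fm)
sum(preds$call)
#> [1] 200

# validation stage 1: co-localization rules from the validated positives
tx    <- build_transactions(ds$pairs[ds$pairs$label == 1, ], ds$store)
rules <- mine_rules(tx, min_support = 0.1, min_confidence = 0.6)
scr   <- filter_pairs_coloc(ds$pairs[preds$call == 1, ], ds$store, rules)
sum(scr$kept)
#> [1] 165

# validation stage 2: sentence-level interaction evidence
corpus <- generate_corpus(ds$pairs[1:2, ], spec)
evaluate_pair(corpus$documents, c(ds$pairs$idA[1], ds$pairs$idB[1]),
              default_lexicons())
#> evidence report for A000001 - B000001
#>   co-mentioned: TRUE; interaction context: TRUE; hits: 3
```

The cross-validated accuracy says the meta-classifier recovers the planted
class separation almost perfectly at this effect size; the feature weights
show no single channel dominating (that is the point of stacking); 165 of
the 200 positive calls sit in compartment pairs that co-occur among
validated interactions, and the text-mining report lists the three planted
evidence sentences for the first pair.

A command-line front end over the same functions is installed at
`inst/scripts/ppistack.R` (`run`, `coloc mine`, `coloc filter`,
`textmine run`, `fixtures make`).

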