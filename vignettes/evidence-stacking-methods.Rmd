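---
title: "Multi-evidence PPI prediction: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-evidence PPI prediction: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppistack)
```

This vignette is the package's own account of its methods: what is
computed, under which assumptions, which knobs matter, and where the
design was genuinely open.

## The prediction pipeline

The pipeline has three stages. *Preprocessing* ingests per-protein
annotation records (GO terms by branch, domain and pathway identifiers,
amino-acid sequence) into a persistent knowledge base keyed by SHA-256
content hashes of a canonical serialization; hashing is what lets a later
experiment skip every protein it has already processed, and what detects a
changed upstream record (`is_stale()`). *Feature generation* turns each
candidate pair into six evidence scores. *Classification* scales the
feature matrix and applies a boosted meta-classifier.

The stacked-generalization reading matters: the six scores are treated as
base-level predictors whose outputs the meta level learns to combine.
None of the base scorers is trained — they are deterministic functions of
the annotations — which is why the only learned component, and the only
randomized one, is the meta-classifier's cross-validation split.

## Evidence scores

**Sequence.** The scorer is pluggable because mature sequence-based
predictors are external tools with their own pipelines; their output plugs
in as a three-column pair-score table. The self-contained fallback is the
Jaccard index of 3-mer sets. k = 3 is the smallest window that captures
local composition beyond dipeptide bias; sequences shorter than k score 0.
The fallback is a weak predictor by design — it exists so the pipeline is
runnable end to end without external tools, not to compete with them.

**GO semantic similarity.** Terms are compared with the Pekar edge-based
measure: for a shared ancestor *a* of terms t₁ and t₂,
`depth(a) / (d1 + d2 + depth(a))`, with depth and distances as minimal
edge counts and the ancestor chosen to maximize the ratio. On a tree this
ancestor is the classic deepest lowest common subsumer. On a multi-parent
DAG the two notions can diverge: a term may reach the root by a short
path while also having an ancestor whose own minimal depth is larger, and
selecting by raw depth would then score a term against itself below 1.
Maximizing the ratio restores the identity property (`sim(t, t) = 1` for
non-root t) while keeping all distances shortest-path. Two root terms
share no information and score 0.

Term *sets* are aggregated by a symmetric best-match average: each term
of A is matched to its best counterpart in B, the directional means are
averaged both ways. No aggregation is canonical in the literature;
best-match average was chosen over all-pairs averaging because all-pairs
dilutes sharp matches between specifically annotated proteins, and over
maximum because a single shared shallow term should not dominate. An
empty side scores 0: missing annotation is treated as absence of
evidence, never imputed, and a per-score missing flag is carried so
reports can distinguish "no evidence" from "evidence against".

**Domain.** The score is the Jaccard overlap between the known
domain-interaction list (LDC) and the pair's unordered domain
combinations (LDP), `|LDC ∩ LDP| / |LDC ∪ LDP|`, computed per pair.
Self-pairs (d, d) arise when both proteins carry the same domain. Two
readings of the denominator are plausible; the printed union form is the
default (`domain_denominator = "union"`), with `"ldp_only"` — the
fraction of the pair's combinations with known interaction — available
because the union form shrinks toward 0 as the reference list grows,
which a user with a large LDC may not want. The choice is a config
switch, not a behavioral fork: tests pin both.

**Pathway.** Plain Jaccard of the two pathway sets; 0 when both are
empty.

## The meta-classifier

Scaling divides each feature column by its sample standard deviation
(n−1), without centering, so zero stays zero — natural for scores whose
zero means "no evidence". Zero-variance columns pass through with a
warning. Test-time matrices are always scaled with the stored training
statistics.

The meta level is discrete AdaBoost over depth-1 decision stumps, 100
rounds, both configurable. Stump search is exhaustive over features,
distinct-value thresholds and polarities, with ties broken by (feature
index, threshold, polarity); boosting stops early on a perfect or a
chance-level stump. The booster contains no randomness at all: given a
fold assignment, the fit is bit-reproducible. The ensemble margin
F(x) = Σ αₘ hₘ(x) / Σ αₘ lies in [−1, 1] and is mapped to a probability
as (F + 1) / 2 — the simplest monotone mapping; the 0.5 threshold is
exactly the ensemble sign rule. ROC curves sweep these probabilities and
AUC is the trapezoid integral, which the tests pin to the normalized
Mann–Whitney statistic.

Cross-validation is stratified 10-fold, shuffled by the experiment seed;
reported metrics pool the out-of-fold predictions, per-fold metrics are
attached, and the final model is refit on all rows. "Model selection"
means exactly this reporting — there is no hyperparameter search.
Training requires at least 20 labeled pairs and both classes.

## The validation stage

**Co-localization.** Transactions are the unions of both proteins'
cellular-component terms across known validated pairs — the union
reading is an explicit decision; the alternative (one transaction per
protein) loses the pair-level co-occurrence the filter is built on.
Apriori mines frequent itemsets and rules at a descending support
schedule (default 0.5, 0.3, 0.2, 0.1, 0.05; confidence 0.6) and stops at
the first level whose rules mention every configured *main component*;
components absent from all transactions are excluded from that check up
front, and an exhausted schedule returns the last level with a warning.
The schedule and confidence defaults are package choices — no canonical
thresholds exist for this construction — and are deliberately
conservative at the top so that the iteration, not the user, finds the
right support.

A pair passes when some rule links one protein's compartments
(antecedent) to the other's (consequent), tested in both orientations:
rule syntax is directional but physical interaction is not, so symmetry
is imposed. Compartment terms are matched literally, without ancestor
expansion — a known fidelity limit when annotations mix granularities.

**Text mining.** The package carries its own small NLP layer: a
deterministic suffix stemmer (irregular map plus
ion/ing/ment/er/ed/es/s stripping) and a lexicon/suffix verb–noun
tagger. These are not research-grade components; they are sufficient
because every dictionary the evidence rules consult is stemmed with the
same stemmer, so lexicon matching happens in a consistent stem space. A
sentence is evidence for a pair iff (i) at least one synonym of each
protein occurs, (ii) no context-exclusion entry fires — single terms or
conjunctive term-sets marking gene-expression/regulation context, the
dominant false-positive mode for interaction verbs like *recruit* and
*bind* — and (iii) an interaction term survives among the kept verbs and
nouns. Whether the interaction term is syntactically linked to the
protein mentions is not checked; same-sentence co-occurrence is the
implemented (and documented) approximation. All dictionaries ship as
editable plain-text defaults.

## The synthetic-data generators

The generators produce every input the pipeline consumes, as pure
functions of a seed: three-branch rooted DAGs (each non-root term with
1–2 parents among earlier terms, acyclic by construction), annotated
proteomes, labeled pair datasets, and labeled corpora.

The pair generator is the study-condition anchor. Its defaults are 2,000
candidate pairs, balanced 50/50 (interleaved labels), with each of the
six evidence channels independently "planted" — made to share — with
probability 0.9 for positives and 0.1 for negatives. Planting copies the
first protein's GO/pathway sets onto the second, derives the second
sequence as a 20%-point-mutated copy of the first, or injects one of the
pair's domain combinations into the known domain-interaction list,
mirroring how each scorer consumes evidence. Per-channel independence is
what makes the fixture informative: a classifier that uses only one
channel is beatable, and the permutation null (labels shuffled, accuracy
≈ 0.5) verifies no signal leaks outside the labels.

Cellular-component annotation is drawn from a small pool of recurrent
*compartment profiles* (default 6 profiles of 2–3 CC terms) rather than
uniformly: real CC annotation is strongly skewed, and proteins occupy
recurrent compartment combinations. Uniform draws would give every
itemset a support near zero, so rule mining — and with it the
co-localization screen — would be vacuous on synthetic data for reasons
that have nothing to do with the method.

The corpus generator emits, per pair: hit sentences (both symbols plus an
interaction verb), excluded sentences (both symbols plus an
expression/regulation phrase, some also carrying an interaction verb to
exercise exclusion precedence), and irrelevant sentences, with a
sentence-level ground-truth manifest. Sentences are built strictly from
the shipped lexicons, which guarantees separability: on such corpora the
miner must reach precision and recall 1.0, and the tests require exactly
that. This is a property of the corpus, not a claim about natural text —
on real articles the same rules inherit every limitation of
same-sentence co-occurrence and literal synonym matching.

What passing on these fixtures shows, and what it does not: the planted
effect sizes are large and the channels clean, so the benchmark verifies
mechanics — score correctness, leak-free cross-validation, determinism,
filter semantics — not real-data performance. Nothing here emulates
realistic GO topology, annotation sparsity, database noise or natural
prose.

## Workflow contracts and numerical choices

Experiments are YAML-configured (train/test mode, datasets, resource
paths, store, jobs, seed) and validated field by field before any
computation. Datasets run as independent jobs; each derives its RNG
stream from (experiment seed, dataset name) via a hash, so parallel and
sequential schedules produce byte-identical outputs — asserted in the
tests, not merely promised. A failing dataset aborts only itself. The
annotation store is read once, shared read-only across jobs, and
re-persisted; a second run over the same proteins ingests nothing.

Sizes used by the shipped checks, chosen as desk-scale defaults: oracle
equivalence on 1,000 random inputs per scorer and 100 random DAGs;
planted-signal recovery and its permutation null at 2,000 pairs;
end-to-end workflow contracts at 1,000 pairs across two datasets.

Degenerate inputs are decided, not accidental: empty annotation sets
score 0; an absent protein zeroes the whole vector with flags and a
warning rather than failing the run; empty transaction sets mine no
rules; an empty corpus yields a report with both summary flags false;
self-pairs (A, A) are scored — proteins can self-interact; duplicate
pairs, including (B, A) duplicates of (A, B), are dropped with a warning.
LCS ties break lexicographically; stump ties break by feature order —
every tie-break exists to make reruns identical.

## Known limitations

Literal CC term matching (no ancestor expansion); same-sentence
co-occurrence instead of syntactic attachment in text mining; the
lightweight stemmer/tagger in place of research-grade NLP; the k-mer
fallback in place of a real sequence predictor; no hyperparameter
search, alternative meta-learners, or probability calibration. Stale
knowledge-base records are kept and flagged, never silently dropped,
because upstream removal semantics are undefined.
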