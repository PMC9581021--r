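test_that("domain score follows the known/candidate pair Jaccard", {
  ldc <- domain_interaction_set(data.frame(a = "d1", b = "d3"))
  expect_equal(domain_score("d1", "d3", ldc), 1.0)
  ldc2 <- domain_interaction_set(data.frame(a = "d1", b = "d2"))
  expect_equal(domain_score("d3", "d4", ldc2), 0.0)
  # LDC = {(d1,d2),(d2,d3)}, LDP = {(d2,d3),(d2,d4)} -> 1/3
  ldc3 <- domain_interaction_set(data.frame(a = c("d1", "d2"),
                                            b = c("d2", "d3")))
  expect_equal(domain_score("d2", c("d3", "d4"), ldc3), 1 / 3)
  # both LDC and LDP empty
  expect_equal(domain_score(character(), character(),
                            domain_interaction_set()), 0)
  # alternative normalization: fraction of candidate combinations known
  expect_equal(domain_score("d2", c("d3", "d4"), ldc3,
                            denominator = "ldp_only"), 1 / 2)
})

test_that("pathway score is the Jaccard of the two pathway sets", {
  expect_equal(pathway_score(c("p1", "p2"), c("p1", "p2")), 1.0)
  expect_equal(pathway_score("p1", "p2"), 0.0)
  expect_equal(pathway_score(c("p1", "p2", "p3"), c("p2", "p3", "p4")), 0.5)
  expect_equal(pathway_score(character(), character()), 0)
})

test_that("fallback sequence score is the 3-mer Jaccard", {
  expect_equal(sequence_score("ACDEFG", "ACDEFG"), 1.0)
  expect_equal(sequence_score("AAAA", "CCCC"), 0.0)
  expect_equal(sequence_score("ACDEF", "CDEFG"), 0.5)  # {ACD,CDE,DEF} vs {CDE,DEF,EFG}
  expect_equal(sequence_score("AC", "ACDEF"), 0)       # below k
  expect_error(sequence_score("ACXDE", "ACDEF"), "position 3")
})

test_that("set-based scores match the brute-force oracle on random inputs", {
  set.seed(11)
  doms <- sprintf("d%02d", 1:12)
  pws <- sprintf("p%02d", 1:10)
  for (i in 1:300) {
    da <- sample(doms, sample(0:4, 1))
    db <- sample(doms, sample(0:4, 1))
    ldc_pairs <- unique(t(replicate(sample(1:6, 1), sort(sample(doms, 2)))))
    known <- domain_interaction_set(as.data.frame(ldc_pairs))
    expect_identical(domain_score(da, db, known),
                     oracle_domain_score(da, db, unclass(known)))
    pa <- sample(pws, sample(0:4, 1)); pb <- sample(pws, sample(0:4, 1))
    expect_identical(pathway_score(pa, pb), oracle_jaccard(pa, pb))
    sa <- paste(sample(strsplit("ACDEFGHIK", "")[[1]], sample(2:12, 1),
                       TRUE), collapse = "")
    sb <- paste(sample(strsplit("ACDEFGHIK", "")[[1]], sample(2:12, 1),
                       TRUE), collapse = "")
    expect_identical(sequence_score(sa, sb), oracle_kmer_jaccard(sa, sb))
  }
})

test_that("lowest common subsumer on the toy chain/sibling DAG", {
  dag <- toy_dag()  # r -> {a, b}; a -> c
  l <- lcs_depth(dag, "c", "c")
  expect_identical(l$lcs, "c")
  expect_equal(c(l$d1, l$d2), c(0, 0))
  l <- lcs_depth(dag, "c", "a")
  expect_identical(l$lcs, "a")
  expect_equal(l$depth, 1)
  expect_equal(c(l$d1, l$d2), c(1, 0))
  l <- lcs_depth(dag, "a", "b")
  expect_identical(l$lcs, "r")
  expect_equal(l$depth, 0)
  expect_equal(c(l$d1, l$d2), c(1, 1))
})

test_that("Pekar similarity: identity, chain, siblings, root degeneracy", {
  dag <- toy_dag()
  expect_equal(pekar_similarity(dag, "c", "c"), 1.0)   # depth 2 term
  expect_equal(pekar_similarity(dag, "c", "a"), 0.5)   # 1/(1+0+1)
  expect_equal(pekar_similarity(dag, "a", "b"), 0.0)   # siblings under root
  expect_equal(pekar_similarity(dag, "r", "r"), 0)     # root-root: no info
})

test_that("cross-branch term queries are rejected", {
  dag <- go_dag(data.frame(child = c("x", "y"), parent = c("rb", "rm")),
                roots = c(BP = "rb", MF = "rm"))
  expect_error(lcs_depth(dag, "x", "y"), "different branches")
  expect_error(pekar_similarity(dag, "x", "y"), "different branches")
})

test_that("Pekar similarity is symmetric, bounded, 1 iff identical non-root", {
  for (seed in 1:5) {
    spec <- fixture_spec(seed = seed, dag_size = 15)
    dag <- generate_go_dag(spec)
    terms <- dag$nodes[dag$branch == "BP"]
    root <- dag$roots[["BP"]]
    set.seed(seed)
    for (k in 1:30) {
      t1 <- sample(terms, 1); t2 <- sample(terms, 1)
      s12 <- pekar_similarity(dag, t1, t2)
      expect_identical(s12, pekar_similarity(dag, t2, t1))
      expect_gte(s12, 0); expect_lte(s12, 1)
      if (identical(t1, t2) && t1 != root) expect_equal(s12, 1)
      if (!identical(t1, t2)) expect_lt(s12, 1)
    }
  }
})

test_that("term-set similarity: identity, empty sides, best-match average", {
  dag <- toy_dag()
  expect_equal(pair_go_similarity(dag, "c", "c", "BP"), 1.0)
  expect_equal(pair_go_similarity(dag, character(), "c", "BP"), 0.0)
  expect_equal(pair_go_similarity(dag, "c", character(), "BP"), 0.0)
  # A = {c}, B = {a, b}: best match for c is a (0.5); B side:
  # a->c = 0.5, b->c = 0 -> mean 0.25; symmetric average 0.375
  sims <- c(pekar_similarity(dag, "c", "a"), pekar_similarity(dag, "c", "b"))
  expect_equal(pair_go_similarity(dag, "c", c("a", "b"), "BP"),
               (max(sims) + mean(sims)) / 2)
})

test_that("term-set similarity is symmetric in its two sets", {
  spec <- fixture_spec(seed = 3, dag_size = 12)
  dag <- generate_go_dag(spec)
  terms <- dag$nodes[dag$branch == "MF"]
  set.seed(9)
  for (k in 1:20) {
    a <- sample(terms, sample(1:4, 1))
    b <- sample(terms, sample(1:4, 1))
    expect_equal(pair_go_similarity(dag, a, b, "MF"),
                 pair_go_similarity(dag, b, a, "MF"))
  }
})

test_that("pathway score is monotone under shared/unshared additions", {
  set.seed(21)
  pws <- sprintf("p%02d", 1:10)
  for (k in 1:50) {
    a <- sample(pws, sample(1:4, 1)); b <- sample(pws, sample(1:4, 1))
    base <- pathway_score(a, b)
    shared <- "pNEW"
    expect_gte(pathway_score(c(a, shared), c(b, shared)), base)
    expect_lte(pathway_score(c(a, "pONLYA"), b), base)
  }
})

test_that("feature vectors assemble the six per-score oracles in order", {
  store <- annotation_store()
  dag <- toy_dag()
  ingest_record(store, list(id = "PA", go_bp = c("c", "a"), domains = "d1",
                            pathways = c("p1", "p2"), sequence = "ACDEF"))
  ingest_record(store, list(id = "PB", go_bp = "c", domains = "d3",
                            pathways = c("p2", "p3"), sequence = "CDEFG"))
  known <- domain_interaction_set(data.frame(a = "d1", b = "d3"))
  fv <- build_feature_vector(c("PA", "PB"), store, dag, known)
  expect_named(fv$scores,
               c("seq", "go_bp", "go_mf", "go_cc", "domain", "pathway"))
  expect_equal(unname(fv$scores[["seq"]]), 0.5)
  expect_equal(unname(fv$scores[["go_bp"]]),
               pair_go_similarity(dag, c("c", "a"), "c", "BP"))
  expect_equal(unname(fv$scores[["go_mf"]]), 0)
  expect_equal(unname(fv$scores[["domain"]]), 1.0)   # LDC == LDP
  expect_equal(unname(fv$scores[["pathway"]]), 1 / 3)
  expect_true(fv$missing[["go_mf"]])
})

test_that("identical fully shared annotations give 1.0 on every set channel", {
  store <- annotation_store()
  dag <- toy_dag()
  shared <- list(go_bp = "c", domains = "d1", pathways = "p1",
                 sequence = "ACDEFGH")
  ingest_record(store, c(list(id = "X1"), shared))
  ingest_record(store, c(list(id = "X2"), shared))
  known <- domain_interaction_set(data.frame(a = "d1", b = "d1"))
  fv <- build_feature_vector(c("X1", "X2"), store, dag, known)
  expect_equal(unname(fv$scores[c("seq", "go_bp", "domain", "pathway")]),
               c(1, 1, 1, 1))
})

test_that("a pair with an absent protein degrades to zeros with flags", {
  store <- annotation_store()
  dag <- toy_dag()
  ingest_record(store, list(id = "PA", go_bp = "c"))
  expect_warning(
    fv <- build_feature_vector(c("PA", "NOPE"), store, dag,
                               domain_interaction_set()),
    "NOPE")
  expect_equal(unname(fv$scores), rep(0, 6))
  expect_true(all(fv$missing))
})

test_that("a precomputed sequence-score table overrides the fallback", {
  store <- annotation_store()
  dag <- toy_dag()
  ingest_record(store, list(id = "PA", sequence = "ACDEF"))
  ingest_record(store, list(id = "PB", sequence = "ACDEF"))
  tbl <- seq_score_table(data.frame(idA = "PB", idB = "PA", score = 0.77))
  fv <- build_feature_vector(c("PA", "PB"), store, dag,
                             domain_interaction_set(), seq_scores = tbl)
  expect_equal(unname(fv$scores[["seq"]]), 0.77)  # unordered lookup
  expect_equal(lookup_seq_score(tbl, "PA", "PB"), 0.77)
  expect_true(is.na(lookup_seq_score(tbl, "PA", "PX")))
})
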