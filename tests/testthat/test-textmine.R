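test_that("markup cleaning strips tags and drops non-body sections", {
  doc <- clean_markup("<p>A binds B.</p>", doc_id = "d1")
  expect_identical(doc$body_paragraphs, "A binds B.")
  refs_only <- clean_markup("<references>Smith 2001. Jones 2002.</references>",
                            doc_id = "d2")
  expect_length(refs_only$body_paragraphs, 0L)
  nested <- clean_markup(paste0(
    "<title>The <i>alpha</i> study</title>",
    "<abstract>X interacts with Y.</abstract>",
    "<p>Main <b>finding</b>: X binds Y.</p>",
    "<fig>Figure 1: a picture of X.</fig>",
    "<ref>Doe et al.</ref>"), doc_id = "d3")
  expect_identical(nested$title, "The alpha study")
  expect_identical(nested$abstract, "X interacts with Y.")
  expect_identical(nested$body_paragraphs, "Main finding: X binds Y.")
})

test_that("preprocessing lowercases, splits, tags and stems deterministically", {
  ps <- preprocess("ProteinA binds ProteinB.", doc_id = "d", section = "body")
  expect_length(ps, 1L)
  expect_true(all(c("proteina", "bind", "proteinb") %in% ps[[1]]$stems))
  expect_true("bind" %in% ps[[1]]$kept$stem)
  expect_length(preprocess("It was. Then it bound."), 2L)
  # stop words and adverbs are dropped from kept tokens
  ps2 <- preprocess("The complex strongly binds the receptor.")[[1]]
  expect_false(any(c("the", "strongly") %in% ps2$kept$token))
  expect_true(all(c("complex", "bind", "receptor") %in% ps2$kept$stem))
  expect_identical(preprocess("ProteinA binds ProteinB."),
                   preprocess("ProteinA binds ProteinB."))
})

test_that("kept tokens of a small fixture paragraph match the hand listing", {
  para <- paste("JUN recruits TLR7.",
                "The assay was performed twice.",
                "Binding was strong and direct.")
  ps <- preprocess(para)
  expect_length(ps, 3L)
  expect_identical(ps[[1]]$kept$stem, c("jun", "recruit", "tlr7"))
  expect_identical(ps[[1]]$kept$pos, c("noun", "verb", "noun"))
  expect_true("bind" %in% ps[[3]]$kept$stem)   # Binding -> bind
})

test_that("context exclusion fires on single terms and full term-sets only", {
  lex <- default_lexicons()
  s_expr <- preprocess("proteina increases expression of proteinb")[[1]]
  expect_true(context_excluded(s_expr, lex))
  # conjunctive set {gene, regulation}: one member alone is not enough
  s_gene <- preprocess("the gene was cloned")[[1]]
  expect_false(context_excluded(s_gene, lex))
  s_both <- preprocess("gene regulation was studied")[[1]]
  expect_true(context_excluded(s_both, lex))
  s_ok <- preprocess("proteina binds proteinb")[[1]]
  expect_false(context_excluded(s_ok, lex))
})

test_that("a hit needs both proteins, an interaction term, and no exclusion", {
  lex <- default_lexicons()
  pair <- c("PA", "PB")  # falls back to lowercase accession as synonym
  hit <- find_pair_evidence(preprocess("pa binds pb directly")[[1]], pair,
                            lex)
  expect_false(is.null(hit))
  expect_identical(hit$interacting_words, "bind")
  expect_null(find_pair_evidence(preprocess("pa binds something else")[[1]],
                                 pair, lex))
  excl <- find_pair_evidence(
    preprocess("pa increases expression of pb")[[1]], pair, lex)
  expect_null(excl)  # expression/regulation context is filtered out
  no_verb <- find_pair_evidence(preprocess("pa and pb were purified")[[1]],
                                pair, lex)
  expect_null(no_verb)
})

test_that("named synonyms and method entities are recognized in hits", {
  lex <- default_lexicons(protein_synonyms = list(P1 = c("jun", "ap-1"),
                                                  P2 = "tlr7"))
  s <- preprocess(
    "jun recruits tlr7 as shown by co-immunoprecipitation.")[[1]]
  hit <- find_pair_evidence(s, c("P1", "P2"), lex)
  expect_false(is.null(hit))
  expect_identical(sort(hit$proteins), c("jun", "tlr7"))
  # method entities are matched (and reported) in stem space
  expect_true(length(hit$method_entities) >= 1L)
})

test_that("pair reports aggregate sentences with consistent summary flags", {
  lex <- default_lexicons()
  docs <- list(
    clean_markup("<p>pa binds pb in vitro. The gel was imaged.</p>", "d1"),
    clean_markup("<p>pa increases expression of pb.</p>", "d2"))
  rep <- evaluate_pair(docs, c("PA", "PB"), lex)
  expect_true(rep$proteins_co_mentioned)
  expect_true(rep$interaction_context_found)
  expect_length(rep$hits, 1L)
  expect_identical(rep$hits[[1]]$doc_id, "d1")
  # both proteins only in excluded sentences: co-mention without context
  rep2 <- evaluate_pair(docs[2], c("PA", "PB"), lex)
  expect_true(rep2$proteins_co_mentioned)
  expect_false(rep2$interaction_context_found)
  # empty corpus
  rep3 <- evaluate_pair(list(), c("PA", "PB"), lex)
  expect_false(rep3$proteins_co_mentioned)
  expect_false(rep3$interaction_context_found)
})

test_that("planted corpus hits are recovered exactly (precision = recall = 1)", {
  pairs <- data.frame(idA = sprintf("QA%02d", 1:5),
                      idB = sprintf("QB%02d", 1:5))
  spec <- fixture_spec(seed = 19, corpus_hits = 3, corpus_excluded = 3,
                       corpus_irrelevant = 4)
  corpus <- generate_corpus(pairs, spec)
  lex <- default_lexicons()
  for (i in seq_len(nrow(pairs))) {
    rep <- evaluate_pair(corpus$documents, c(pairs$idA[i], pairs$idB[i]),
                         lex)
    truth_i <- corpus$truth[corpus$truth$idA == pairs$idA[i], ]
    planted <- truth_i$sentence[truth_i$class == "hit"]
    got <- vapply(rep$hits, `[[`, character(1), "sentence")
    expect_setequal(got, planted)          # recall and precision both 1
    expect_length(rep$hits, 3L)
  }
})

test_that("identical corpus and lexicons give identical reports", {
  pairs <- data.frame(idA = "ZA", idB = "ZB")
  spec <- fixture_spec(seed = 23)
  c1 <- generate_corpus(pairs, spec)
  c2 <- generate_corpus(pairs, spec)
  expect_identical(c1, c2)
  lex <- default_lexicons()
  expect_identical(evaluate_pair(c1$documents, c("ZA", "ZB"), lex),
                   evaluate_pair(c2$documents, c("ZA", "ZB"), lex))
})

test_that("lexicon directories round-trip with the packaged stemmer applied", {
  d <- tempfile(); dir.create(d)
  writeLines(c("binds", "tethers"), file.path(d, "interaction_terms.txt"))
  writeLines(c("expression", "gene, regulation"),
             file.path(d, "context_exclusion.txt"))
  writeLines("pulldown", file.path(d, "method_entities.txt"))
  writeLines("P1\tjun,ap-1", file.path(d, "protein_synonyms.tsv"))
  lex <- read_lexicons(d)
  expect_true(all(stem_tokens(c("binds", "tethers")) %in%
                    lex$interaction_terms))
  expect_true(list("express") %in% lex$context_exclusion ||
                "express" %in% unlist(lex$context_exclusion))
  expect_identical(lex$protein_synonyms$P1, c("jun", "ap-1"))
})
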