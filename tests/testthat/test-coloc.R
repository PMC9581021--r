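cc_store <- function(recs) {
  store <- annotation_store()
  for (r in recs) ingest_record(store, r)
  store
}

test_that("transactions are CC unions; empty/absent pairs are dropped", {
  store <- cc_store(list(
    list(id = "A", go_cc = "nucleus"),
    list(id = "B", go_cc = c("nucleus", "cytosol")),
    list(id = "C", go_cc = "membrane"),
    list(id = "E1", go_cc = character()),
    list(id = "E2", go_cc = character())))
  pairs <- data.frame(idA = c("A", "A", "E1", "A"),
                      idB = c("B", "C", "E2", "GHOST"))
  expect_message(tx <- build_transactions(pairs, store), "dropped")
  expect_length(tx, 2L)
  expect_identical(tx[[1]], c("cytosol", "nucleus"))
  expect_identical(tx[[2]], c("membrane", "nucleus"))
  expect_identical(attr(tx, "dropped"), 2L)
})

test_that("Apriori on the worked three-transaction example", {
  tx <- list(c("A", "B"), c("A", "B"), c("A", "C"))
  db <- mine_rules(tx, 0.6, 0.6)
  expect_equal(nrow(db), 2L)
  # B -> A has confidence 1 and sorts first
  expect_identical(db$antecedent, c("B", "A"))
  expect_identical(db$consequent, c("A", "B"))
  expect_equal(db$support, c(2 / 3, 2 / 3))
  expect_equal(db$confidence, c(1, 2 / 3))
  expect_equal(nrow(mine_rules(tx, 1.0, 0.6)), 0L)  # only {A} frequent
  expect_equal(nrow(mine_rules(list(), 0.5, 0.5)), 0L)
})

test_that("Apriori equals exhaustive enumeration on random fixtures", {
  for (seed in 1:20) {
    tx <- random_itemsets(n_tx = sample(3:20, 1), n_items = sample(3:8, 1),
                          seed = seed)
    ms <- sample(c(0.1, 0.2, 0.3, 0.5), 1)
    mc <- sample(c(0.5, 0.6, 0.8), 1)
    got <- mine_rules(tx, ms, mc)
    want <- oracle_mine_rules(tx, ms, mc)
    expect_equal(as.data.frame(got)[names(want)], want, tolerance = 1e-15)
  }
})

test_that("every subset of a frequent itemset is frequent", {
  tx <- random_itemsets(25, 7, seed = 42)
  freq <- ppistack:::apriori_frequent(tx, 0.15)
  for (key in names(freq)) {
    items <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (length(items) < 2) next
    for (d in seq_along(items)) {
      sub <- paste(items[-d], collapse = "|")
      expect_true(sub %in% names(freq))
      expect_gte(freq[[sub]], freq[[key]])
    }
  }
})

test_that("support lowers along the schedule until coverage", {
  # cytosol|er co-occurrence is rare: only visible at low support
  tx <- c(rep(list(c("nucleus", "cytosol")), 8),
          rep(list(c("cytosol", "er")), 2))
  hi <- mine_rules(tx, 0.5, 0.6)
  expect_false("er" %in% unlist(strsplit(
    c(hi$antecedent, hi$consequent), "|", fixed = TRUE)))
  db <- iterate_until_coverage(tx, c("nucleus", "er"),
                               support_schedule = c(0.5, 0.2),
                               min_confidence = 0.6)
  expect_equal(attr(db, "support_used"), 0.2)
  mentioned <- unique(unlist(strsplit(c(db$antecedent, db$consequent), "|",
                                      fixed = TRUE)))
  expect_true(all(c("nucleus", "er") %in% mentioned))
  # coverage already at the first level -> stops there
  db1 <- iterate_until_coverage(tx, "nucleus",
                                support_schedule = c(0.5, 0.2))
  expect_equal(attr(db1, "support_used"), 0.5)
  # a term in no transaction is excluded from feasibility, with a note
  expect_message(
    db2 <- iterate_until_coverage(tx, c("nucleus", "ribosome"),
                                  support_schedule = c(0.5, 0.2)),
    "ribosome")
  expect_equal(attr(db2, "support_used"), 0.5)
})

test_that("an exhausted schedule warns and returns the last level", {
  tx <- rep(list(c("nucleus", "cytosol")), 4)
  tx <- c(tx, list(c("er", "nucleus")))  # er never clears confidence
  expect_warning(
    db <- iterate_until_coverage(tx, c("er"),
                                 support_schedule = c(0.9, 0.8),
                                 min_confidence = 0.99),
    "exhausted")
  expect_equal(attr(db, "support_used"), 0.8)
})

test_that("the co-localization filter is symmetric and removes unbridged compartments", {
  rules <- mine_rules(rep(list(c("nucleus", "cytosol")), 3), 0.5, 0.5)
  expect_true(passes_coloc("nucleus", "cytosol", rules))
  expect_true(passes_coloc("cytosol", "nucleus", rules))
  # the canonical removed case: nucleus vs extracellular matrix
  expect_false(passes_coloc("nucleus", "extracellular matrix", rules))
  set.seed(8)
  ccs <- c("nucleus", "cytosol", "er", "membrane")
  for (k in 1:25) {
    a <- sample(ccs, sample(1:3, 1)); b <- sample(ccs, sample(1:3, 1))
    expect_identical(passes_coloc(a, b, rules), passes_coloc(b, a, rules))
  }
})

test_that("adding rules never flips a passing pair to failing", {
  base <- mine_rules(rep(list(c("nucleus", "cytosol")), 3), 0.5, 0.5)
  more <- mine_rules(c(rep(list(c("nucleus", "cytosol")), 3),
                       rep(list(c("er", "membrane")), 3)), 0.3, 0.5)
  set.seed(12)
  ccs <- c("nucleus", "cytosol", "er", "membrane", "golgi")
  for (k in 1:30) {
    a <- sample(ccs, sample(1:3, 1)); b <- sample(ccs, sample(1:3, 1))
    if (passes_coloc(a, b, base)) expect_true(passes_coloc(a, b, more))
  }
})

test_that("rule files round-trip and reject malformed input", {
  tx <- list(c("A", "B"), c("A", "B"), c("A", "C"))
  db <- mine_rules(tx, 0.6, 0.6)
  f <- tempfile(fileext = ".tsv")
  write_rules(db, f)
  back <- read_rules(f)
  expect_equal(back$antecedent, db$antecedent)
  expect_equal(back$consequent, db$consequent)
  expect_equal(back$support, db$support, tolerance = 1e-9)
  expect_equal(back$confidence, db$confidence, tolerance = 1e-9)
  # duplicates dedupe with a warning
  writeLines(c("nucleus\tcytosol\t0.5\t0.9", "nucleus\tcytosol\t0.5\t0.9"),
             f)
  expect_warning(d2 <- read_rules(f), "duplicate")
  expect_equal(nrow(d2), 1L)
  # hand-written two-rule file parses to the hand expectation
  writeLines(c("nucleus|er\tcytosol\t0.4\t0.8", "membrane\ter"), f)
  d3 <- read_rules(f)
  expect_identical(d3$antecedent, c("nucleus|er", "membrane"))
  expect_identical(d3$consequent, c("cytosol", "er"))
  expect_true(is.na(d3$support[2]))
  writeLines(c("just-one-column"), f)
  expect_error(read_rules(f), "malformed")
})

test_that("filter_pairs_coloc reports per-pair reasons", {
  store <- cc_store(list(
    list(id = "N1", go_cc = "nucleus"),
    list(id = "C1", go_cc = "cytosol"),
    list(id = "X1", go_cc = "extracellular matrix"),
    list(id = "E0", go_cc = character())))
  rules <- mine_rules(rep(list(c("nucleus", "cytosol")), 3), 0.5, 0.5)
  out <- filter_pairs_coloc(
    data.frame(idA = c("N1", "N1", "E0", "N1"),
               idB = c("C1", "X1", "C1", "GHOST")), store, rules)
  expect_identical(out$kept, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(out$reason[2], "no rule")
  expect_match(out$reason[3], "no cellular-component")
  expect_match(out$reason[4], "missing")
})
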