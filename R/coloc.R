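# Items inside antecedent/consequent are joined by "|"; rules are stored in
# a data.frame so the rule database round-trips through a two-column file.

itemset_key <- function(items) paste(sort(unique(items)), collapse = "|")
split_items <- function(key) if (nzchar(key))
  strsplit(key, "|", fixed = TRUE)[[1L]] else character()

#' Build cellular-component transactions from known validated PPIs
#'
#' One transaction per known pair: the union of both proteins' CC terms.
#' Pairs with either protein absent from the store, or with both CC sets
#' empty, are dropped; the drop count is attached as the `"dropped"`
#' attribute and logged.
#'
#' @param known_pairs data.frame with columns `idA`, `idB`.
#' @param store an `annotation_store`.
#' @return list of character itemsets (class `cc_transactions`).
#' @export
build_transactions <- function(known_pairs, store) {
  known_pairs <- as.data.frame(known_pairs, stringsAsFactors = FALSE)
  tx <- list()
  dropped <- 0L
  for (i in seq_len(nrow(known_pairs))) {
    a <- query_features(store, known_pairs$idA[[i]])
    b <- query_features(store, known_pairs$idB[[i]])
    if (is_absent(a) || is_absent(b)) { dropped <- dropped + 1L; next }
    items <- sort(union(a$go_cc, b$go_cc))
    if (length(items) == 0L) { dropped <- dropped + 1L; next }
    tx[[length(tx) + 1L]] <- items
  }
  if (dropped > 0L)
    message(dropped, " known pair(s) dropped (absent protein or no CC terms)")
  structure(tx, dropped = dropped, class = "cc_transactions")
}

# Level-wise Apriori frequent-itemset generation with candidate pruning.
# Returns a named numeric vector: names are itemset keys, values supports.
apriori_frequent <- function(transactions, min_support) {
  n <- length(transactions)
  if (n == 0L) return(setNames(numeric(), character()))
  support_of <- function(sets) {
    vapply(sets, function(s)
      sum(vapply(transactions, function(t) all(s %in% t), logical(1))) / n,
      numeric(1))
  }
  items <- sort(unique(unlist(transactions, use.names = FALSE)))
  lev <- lapply(items, identity)
  sup <- support_of(lev)
  keep <- sup >= min_support
  frequent <- setNames(sup[keep],
                       vapply(lev[keep], itemset_key, character(1)))
  prev <- lev[keep]
  while (length(prev) > 1L) {
    # join step: union pairs of (k-1)-sets sharing all but the last item
    cand <- list()
    seen <- character()
    for (i in seq_along(prev)) for (j in seq_along(prev)) {
      if (i >= j) next
      u <- sort(union(prev[[i]], prev[[j]]))
      if (length(u) != length(prev[[i]]) + 1L) next
      key <- itemset_key(u)
      if (key %in% seen) next
      # prune: every (k-1)-subset must be frequent
      subs <- vapply(seq_along(u), function(d) itemset_key(u[-d]),
                     character(1))
      if (!all(subs %in% names(frequent))) next
      seen <- c(seen, key)
      cand[[length(cand) + 1L]] <- u
    }
    if (length(cand) == 0L) break
    sup <- support_of(cand)
    keep <- sup >= min_support
    if (!any(keep)) break
    frequent <- c(frequent, setNames(sup[keep],
                  vapply(cand[keep], itemset_key, character(1))))
    prev <- cand[keep]
  }
  frequent
}

empty_rule_db <- function(min_support = NA_real_, min_confidence = NA_real_) {
  structure(data.frame(antecedent = character(), consequent = character(),
                       support = numeric(), confidence = numeric(),
                       stringsAsFactors = FALSE),
            params = list(min_support = min_support,
                          min_confidence = min_confidence),
            class = c("rule_db", "data.frame"))
}

#' Mine cellular-component association rules (Apriori)
#'
#' Classic two-phase Apriori: level-wise frequent-itemset generation using
#' support anti-monotonicity, followed by rule extraction — every partition
#' of a frequent itemset of size >= 2 into non-empty antecedent/consequent
#' whose confidence `support(A ∪ C) / support(A)` clears the threshold.
#' Rules are sorted by (confidence, support, antecedent, consequent)
#' descending on the numeric keys for determinism.
#'
#' @param transactions a `cc_transactions` list (or plain list of character
#'   vectors).
#' @param min_support minimum support in (0, 1].
#' @param min_confidence minimum confidence in (0, 1].
#' @return a `rule_db` data.frame with columns antecedent, consequent
#'   (items `|`-joined), support, confidence.
#' @export
mine_rules <- function(transactions, min_support, min_confidence) {
  stopifnot(min_support > 0, min_support <= 1,
            min_confidence > 0, min_confidence <= 1)
  if (length(transactions) == 0L)
    return(empty_rule_db(min_support, min_confidence))
  frequent <- apriori_frequent(transactions, min_support)
  rows <- list()
  for (key in names(frequent)) {
    items <- split_items(key)
    k <- length(items)
    if (k < 2L) next
    # enumerate non-empty proper subsets as antecedents
    for (mask in seq_len(2L^k - 2L)) {
      sel <- as.logical(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)))
      ant <- items[sel]; con <- items[!sel]
      ant_key <- itemset_key(ant)
      conf <- frequent[[key]] / frequent[[ant_key]]
      if (conf >= min_confidence)
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = ant_key, consequent = itemset_key(con),
          support = frequent[[key]], confidence = conf,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_rule_db(min_support, min_confidence))
  db <- do.call(rbind, rows)
  db <- db[order(-db$confidence, -db$support, db$antecedent, db$consequent), ]
  rownames(db) <- NULL
  structure(db, params = list(min_support = min_support,
                              min_confidence = min_confidence),
            class = c("rule_db", "data.frame"))
}

#' Lower the support threshold until the main components are covered
#'
#' Runs [mine_rules()] at each support level of a strictly descending
#' schedule, stopping at the first level whose rules mention (in antecedent
#' or consequent) every term of `main_components`. Terms that occur in no
#' transaction are excluded from the coverage check up front (they can
#' never be covered). If no level achieves coverage, the final level's
#' rules are returned with a warning.
#'
#' @param transactions a `cc_transactions`.
#' @param main_components character vector of CC terms that must appear
#'   among the mined rules.
#' @param support_schedule strictly descending support levels.
#' @param min_confidence confidence threshold used at every level.
#' @return a `rule_db`; the attribute `"support_used"` records the level.
#' @export
iterate_until_coverage <- function(transactions, main_components,
                                   support_schedule = c(0.5, 0.3, 0.2,
                                                        0.1, 0.05),
                                   min_confidence = 0.6) {
  stopifnot(length(support_schedule) >= 1L,
            all(diff(support_schedule) < 0))
  present <- unique(unlist(transactions, use.names = FALSE))
  feasible <- intersect(unique(main_components), present)
  infeasible <- setdiff(unique(main_components), present)
  if (length(infeasible))
    message("main component(s) absent from every transaction, ",
            "excluded from the coverage check: ",
            paste(infeasible, collapse = ", "))
  db <- empty_rule_db()
  for (s in support_schedule) {
    db <- mine_rules(transactions, s, min_confidence)
    mentioned <- unique(unlist(lapply(
      c(db$antecedent, db$consequent), split_items), use.names = FALSE))
    if (all(feasible %in% mentioned)) {
      attr(db, "support_used") <- s
      return(db)
    }
  }
  warning("support schedule exhausted without covering all main components",
          call. = FALSE)
  attr(db, "support_used") <- support_schedule[[length(support_schedule)]]
  db
}

#' Does a candidate pair pass the co-localization filter?
#'
#' A pair passes when some rule links the two proteins' cellular
#' compartments: one protein's CC terms intersect the antecedent and the
#' other's the consequent. The test is applied in both orientations, so the
#' filter is symmetric — a physical interaction has no direction. A pair in
#' compartments with no bridging rule (e.g. one protein in the nucleus, the
#' other in the extracellular matrix) is removed.
#'
#' @param cc_a,cc_b character vectors of CC terms of the two proteins.
#' @param rules a `rule_db`.
#' @return `TRUE` iff some rule connects the two CC sets.
#' @export
passes_coloc <- function(cc_a, cc_b, rules) {
  if (nrow(rules) == 0L) return(FALSE)
  for (i in seq_len(nrow(rules))) {
    ant <- split_items(rules$antecedent[[i]])
    con <- split_items(rules$consequent[[i]])
    if ((length(intersect(cc_a, ant)) && length(intersect(cc_b, con))) ||
        (length(intersect(cc_b, ant)) && length(intersect(cc_a, con))))
      return(TRUE)
  }
  FALSE
}

#' Screen predicted pairs through the co-localization filter
#'
#' @param pairs data.frame with columns `idA`, `idB`.
#' @param store an `annotation_store`.
#' @param rules a `rule_db`.
#' @return data.frame with `idA`, `idB`, `kept` (logical) and `reason`.
#' @export
filter_pairs_coloc <- function(pairs, store, rules) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  out <- data.frame(idA = pairs$idA, idB = pairs$idB,
                    kept = logical(nrow(pairs)),
                    reason = character(nrow(pairs)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    a <- query_features(store, pairs$idA[[i]])
    b <- query_features(store, pairs$idB[[i]])
    if (is_absent(a) || is_absent(b)) {
      out$reason[[i]] <- "annotation missing"
    } else if (length(a$go_cc) == 0L || length(b$go_cc) == 0L) {
      out$reason[[i]] <- "no cellular-component annotation"
    } else if (passes_coloc(a$go_cc, b$go_cc, rules)) {
      out$kept[[i]] <- TRUE
      out$reason[[i]] <- "co-localization rule matched"
    } else {
      out$reason[[i]] <- "no rule links the two compartments"
    }
  }
  out
}

#' Write / read the rule database as a two-column file
#'
#' Tab-separated: column 1 antecedent items joined by `|`, column 2
#' consequent items, optional columns 3-4 support and confidence. Reading
#' deduplicates repeated (antecedent, consequent) lines with a warning and
#' rejects malformed lines naming their line numbers.
#'
#' @param rules a `rule_db`.
#' @param path file path.
#' @export
write_rules <- function(rules, path) {
  lines <- sprintf("%s\t%s\t%.10g\t%.10g", rules$antecedent,
                   rules$consequent, rules$support, rules$confidence)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_rule_db())
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop(path, ": malformed rule line(s) ", paste(bad, collapse = ", "))
  db <- data.frame(
    antecedent = vapply(parts, `[`, character(1), 1L),
    consequent = vapply(parts, `[`, character(1), 2L),
    support = vapply(parts, function(p)
      if (length(p) >= 3L) as.numeric(p[[3L]]) else NA_real_, numeric(1)),
    confidence = vapply(parts, function(p)
      if (length(p) >= 4L) as.numeric(p[[4L]]) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
  dup <- duplicated(db[c("antecedent", "consequent")])
  if (any(dup)) {
    warning(path, ": ", sum(dup), " duplicate rule line(s) removed",
            call. = FALSE)
    db <- db[!dup, ]
    rownames(db) <- NULL
  }
  structure(db, params = list(), class = c("rule_db", "data.frame"))
}
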