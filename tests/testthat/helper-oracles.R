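# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: brute-force set enumeration, power-set mining,
# rank-statistic AUC, igraph shortest paths.

oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- unique(c(a, b))
  if (length(u) == 0L) return(0)
  length(intersect(a, b)) / length(u)
}

# Domain score by explicit double-loop enumeration of the pair cross
# product, with unordered pairs canonicalized as sorted 2-vectors.
oracle_domain_score <- function(da, db, ldc_keys) {
  da <- unique(da); db <- unique(db)
  ldp <- character()
  for (x in da) for (y in db) {
    p <- sort(c(x, y))
    ldp <- c(ldp, paste(p[1], p[2], sep = "|"))
  }
  oracle_jaccard(ldp, ldc_keys)
}

oracle_kmer_jaccard <- function(sa, sb, k = 3) {
  km <- function(s) {
    if (nchar(s) < k) return(character())
    unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  }
  ka <- km(sa); kb <- km(sb)
  if (length(ka) == 0L || length(kb) == 0L) return(0)
  oracle_jaccard(ka, kb)
}

# Pekar similarity via igraph shortest paths and exhaustive common-ancestor
# search, fully independent of the package's BFS.
oracle_pekar <- function(dag, t1, t2) {
  edges <- do.call(rbind, lapply(dag$nodes, function(n) {
    ps <- dag$parents[[n]]
    if (length(ps)) cbind(n, ps) else NULL
  }))
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(), to = character())
    else data.frame(from = edges[, 1], to = edges[, 2]),
    directed = TRUE, vertices = dag$nodes)
  d <- igraph::distances(g, mode = "out")  # follow child -> parent edges
  root <- dag$roots[[dag$branch[[t1]]]]
  common <- dag$nodes[is.finite(d[t1, dag$nodes]) &
                      is.finite(d[t2, dag$nodes])]
  best <- 0
  for (a in common) {
    depth <- d[a, root]
    den <- d[t1, a] + d[t2, a] + depth
    if (den > 0) best <- max(best, depth / den)
  }
  unname(best)
}

# Exhaustive association-rule mining over the power set of the item
# universe; returns the same data.frame layout as mine_rules(), identically
# sorted.
oracle_mine_rules <- function(transactions, min_support, min_confidence) {
  n <- length(transactions)
  items <- sort(unique(unlist(transactions)))
  stopifnot(length(items) <= 12)
  support <- new.env()
  all_sets <- list()
  for (mask in seq_len(2^length(items) - 1)) {
    sel <- as.logical(bitwAnd(mask, bitwShiftL(1L, seq_along(items) - 1L)))
    s <- items[sel]
    key <- paste(s, collapse = "|")
    sup <- sum(vapply(transactions, function(t) all(s %in% t),
                      logical(1))) / n
    assign(key, sup, envir = support)
    if (sup >= min_support) all_sets[[length(all_sets) + 1L]] <- s
  }
  rows <- list()
  for (s in all_sets) {
    k <- length(s)
    if (k < 2) next
    for (mask in seq_len(2^k - 2)) {
      sel <- as.logical(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)))
      ant <- s[sel]; con <- s[!sel]
      conf <- get(paste(s, collapse = "|"), envir = support) /
        get(paste(ant, collapse = "|"), envir = support)
      if (conf >= min_confidence)
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = paste(ant, collapse = "|"),
          consequent = paste(con, collapse = "|"),
          support = get(paste(s, collapse = "|"), envir = support),
          confidence = conf, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(antecedent = character(), consequent = character(),
                      support = numeric(), confidence = numeric(),
                      stringsAsFactors = FALSE))
  db <- do.call(rbind, rows)
  db <- db[order(-db$confidence, -db$support, db$antecedent,
                 db$consequent), ]
  rownames(db) <- NULL
  db
}

oracle_frequent <- function(transactions, min_support) {
  n <- length(transactions)
  items <- sort(unique(unlist(transactions)))
  out <- numeric(); keys <- character()
  for (mask in seq_len(2^length(items) - 1)) {
    sel <- as.logical(bitwAnd(mask, bitwShiftL(1L, seq_along(items) - 1L)))
    s <- items[sel]
    sup <- sum(vapply(transactions, function(t) all(s %in% t),
                      logical(1))) / n
    if (sup >= min_support) {
      out <- c(out, sup)
      keys <- c(keys, paste(s, collapse = "|"))
    }
  }
  setNames(out, keys)
}

# AUC as the normalized Mann-Whitney U statistic (ties count half).
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  u <- 0
  for (p in pos) u <- u + sum(p > neg) + 0.5 * sum(p == neg)
  u / (length(pos) * length(neg))
}

# Independent canonical serializer for content-hash cross-checks.
oracle_record_hash <- function(rec) {
  fields <- c("id", "go_bp", "go_mf", "go_cc", "domains", "pathways",
              "sequence")
  sets <- c("go_bp", "go_mf", "go_cc", "domains", "pathways")
  out <- "ppistack-record-v1"
  for (f in fields) {
    v <- rec[[f]]
    if (f %in% sets) v <- sort(unique(as.character(v)))
    if (f == "sequence" && (is.null(v) || length(v) == 0L)) v <- ""
    out <- c(out, paste0(f, "=", paste(v, collapse = "\x1f")))
  }
  digest::digest(enc2utf8(paste(out, collapse = "\n")), algo = "sha256",
                 serialize = FALSE)
}

random_record <- function(i) {
  list(id = sprintf("RR%04d", i),
       go_bp = sample(sprintf("GO:BP%03d", 1:30), sample(0:4, 1)),
       go_mf = sample(sprintf("GO:MF%03d", 1:30), sample(0:4, 1)),
       go_cc = sample(sprintf("GO:CC%03d", 1:30), sample(0:4, 1)),
       domains = sample(sprintf("PF%03d", 1:20), sample(0:3, 1)),
       pathways = sample(sprintf("ko%03d", 1:20), sample(0:3, 1)),
       sequence = paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                               sample(c(0, 10:30), 1), replace = TRUE),
                        collapse = ""))
}

random_itemsets <- function(n_tx, n_items, seed) {
  set.seed(seed)
  items <- LETTERS[seq_len(n_items)]
  lapply(seq_len(n_tx), function(i)
    sort(sample(items, sample(seq_len(min(5, n_items)), 1))))
}

# toy chain/sibling DAG used across feature tests:
# root r with children a, b; c is a child of a.
toy_dag <- function() {
  go_dag(data.frame(child = c("a", "b", "c"), parent = c("r", "r", "a")),
         roots = c(BP = "r"))
}
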