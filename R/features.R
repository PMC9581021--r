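FEATURE_COLUMNS <- c("seq", "go_bp", "go_mf", "go_cc", "domain", "pathway")

# Unordered pair in canonical (lexicographic) order, joined by "|".
canonical_pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' Known domain-domain interaction set
#'
#' Stores unordered domain-id pairs (a 3DID-like list) in canonical
#' lexicographic order with duplicates removed; this is the reference list
#' the domain scorer intersects candidate domain combinations against.
#'
#' @param pairs two-column data.frame/matrix of domain ids (may be empty).
#' @return object of class `ddi_set` (character vector of `d1|d2` keys).
#' @export
domain_interaction_set <- function(pairs = NULL) {
  keys <- character()
  if (!is.null(pairs) && NROW(pairs) > 0) {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    keys <- unique(canonical_pair_key(as.character(pairs[[1L]]),
                                      as.character(pairs[[2L]])))
  }
  structure(sort(keys), class = "ddi_set")
}

#' Read a two-column domain-interaction file (tab-separated)
#' @param path file of `domainA<TAB>domainB` lines.
#' @export
read_domain_interactions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(domain_interaction_set())
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop(path, ": malformed line(s) ", paste(bad, collapse = ", "))
  domain_interaction_set(data.frame(
    a = vapply(parts, `[`, character(1), 1L),
    b = vapply(parts, `[`, character(1), 2L)))
}

#' Write a domain-interaction set
#' @param known a `ddi_set`.
#' @param path output file.
#' @export
write_domain_interactions <- function(known, path) {
  parts <- strsplit(unclass(known), "|", fixed = TRUE)
  writeLines(vapply(parts, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

#' Domain-evidence score for a candidate protein pair
#'
#' All unordered combinations of one domain from each protein (LDP,
#' including self-pairs when both proteins carry the same domain) are
#' compared against the known domain-interaction list (LDC) as a Jaccard
#' index `|LDC ∩ LDP| / |LDC ∪ LDP|`. With a large reference list this
#' union denominator keeps scores small; `denominator = "ldp_only"` divides
#' by `|LDP|` instead (fraction of the pair's domain combinations with known
#' interaction) as an alternative normalization.
#'
#' @param domains_a,domains_b character vectors of domain ids.
#' @param known a `ddi_set` of known interacting domain pairs.
#' @param denominator `"union"` (default) or `"ldp_only"`.
#' @return score in `[0, 1]`; 0 when the relevant sets are empty.
#' @export
domain_score <- function(domains_a, domains_b, known,
                         denominator = c("union", "ldp_only")) {
  denominator <- match.arg(denominator)
  da <- unique(as.character(domains_a))
  db <- unique(as.character(domains_b))
  ldp <- if (length(da) && length(db))
    unique(canonical_pair_key(rep(da, times = length(db)),
                              rep(db, each = length(da))))
  else character()
  ldc <- unclass(known)
  if (denominator == "ldp_only") {
    if (length(ldp) == 0L) return(0)
    return(length(intersect(ldc, ldp)) / length(ldp))
  }
  u <- union(ldc, ldp)
  if (length(u) == 0L) return(0)
  length(intersect(ldc, ldp)) / length(u)
}

#' Pathway co-participation score
#'
#' Jaccard index of the two proteins' pathway sets: the fraction of pathways
#' shared among all pathways either protein participates in.
#'
#' @param pathways_a,pathways_b character vectors of pathway ids.
#' @return score in `[0, 1]`; 0 when both sets are empty.
#' @export
pathway_score <- function(pathways_a, pathways_b) {
  va <- unique(as.character(pathways_a))
  vb <- unique(as.character(pathways_b))
  u <- union(va, vb)
  if (length(u) == 0L) return(0)
  length(intersect(va, vb)) / length(u)
}

validate_sequence <- function(seq, who = "sequence") {
  if (is.na(seq) || !nzchar(seq)) return(invisible(seq))
  chars <- strsplit(toupper(seq), "")[[1L]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad))
    stop(sprintf("%s contains non-amino-acid character '%s' at position %d",
                 who, chars[bad[1L]], bad[1L]))
  invisible(seq)
}

kmer_set <- function(seq, k = 3L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Sequence-evidence score for a candidate pair
#'
#' The sequence channel is a pluggable scorer: an external predictor's
#' precomputed pair scores can be supplied (see [seq_score_table()]), and
#' [build_feature_vector()] consults that table first. This function is the
#' self-contained fallback: the Jaccard index of the two sequences' k-mer
#' sets (default k = 3); 0 when either sequence is shorter than k.
#'
#' @param seq_a,seq_b amino-acid strings (20 canonical letters; empty
#'   allowed). A non-alphabet character is rejected with its position.
#' @param k k-mer length.
#' @return score in `[0, 1]`.
#' @export
sequence_score <- function(seq_a, seq_b, k = 3L) {
  validate_sequence(seq_a, "sequence A")
  validate_sequence(seq_b, "sequence B")
  ka <- kmer_set(seq_a, k)
  kb <- kmer_set(seq_b, k)
  if (length(ka) == 0L || length(kb) == 0L) return(0)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Precomputed sequence-score lookup table
#'
#' Wraps a three-column table (idA, idB, score) — e.g. the output of an
#' external sequence-based predictor — as an unordered-pair lookup.
#'
#' @param table data.frame with columns idA, idB, score (names free,
#'   positional), or a path to a tab-separated file of those columns.
#' @return object of class `seq_score_table`; index with
#'   [lookup_seq_score()].
#' @export
seq_score_table <- function(table) {
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.table(table, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE,
                               col.names = c("idA", "idB", "score"))
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  scores <- as.numeric(table[[3L]])
  names(scores) <- canonical_pair_key(as.character(table[[1L]]),
                                      as.character(table[[2L]]))
  structure(scores, class = "seq_score_table")
}

#' Look up a precomputed sequence score for an unordered pair
#' @param table a `seq_score_table`.
#' @param id_a,id_b accessions.
#' @return the score, or `NA_real_` when the pair is not in the table.
#' @export
lookup_seq_score <- function(table, id_a, id_b) {
  if (is.null(table)) return(NA_real_)
  key <- canonical_pair_key(id_a, id_b)
  if (key %in% names(table)) unname(unclass(table)[[key]]) else NA_real_
}

#' Assemble the six evidence scores for one candidate pair
#'
#' Computes, in fixed column order `seq, go_bp, go_mf, go_cc, domain,
#' pathway`, the sequence score (precomputed table first, k-mer fallback
#' otherwise), the three GO-branch Pekar similarities, the domain score and
#' the pathway score. A protein absent from the store degrades gracefully:
#' every score is 0, every missing flag is set, and a warning names the
#' missing accession.
#'
#' @param pair character vector of two accessions.
#' @param store an `annotation_store`.
#' @param dag a `go_dag`.
#' @param known a `ddi_set`.
#' @param seq_scores optional `seq_score_table`.
#' @param domain_denominator passed to [domain_score()].
#' @return list with `pair`, `scores` (named numeric of length 6) and
#'   `missing` (named logical of length 6).
#' @export
build_feature_vector <- function(pair, store, dag, known, seq_scores = NULL,
                                 domain_denominator = "union") {
  a <- query_features(store, pair[[1L]])
  b <- query_features(store, pair[[2L]])
  scores <- setNames(numeric(length(FEATURE_COLUMNS)), FEATURE_COLUMNS)
  missing <- setNames(logical(length(FEATURE_COLUMNS)), FEATURE_COLUMNS)
  if (is_absent(a) || is_absent(b)) {
    gone <- c(if (is_absent(a)) pair[[1L]], if (is_absent(b)) pair[[2L]])
    warning("annotation missing for ", paste(gone, collapse = ", "),
            "; pair scored 0 on every channel", call. = FALSE)
    missing[] <- TRUE
    return(list(pair = pair, scores = scores, missing = missing))
  }
  pre <- lookup_seq_score(seq_scores, a$id, b$id)
  scores[["seq"]] <- if (!is.na(pre)) pre else sequence_score(a$sequence,
                                                              b$sequence)
  missing[["seq"]] <- is.na(pre) &&
    (nchar(a$sequence) < 3L || nchar(b$sequence) < 3L)
  for (br in c(bp = "BP", mf = "MF", cc = "CC")) {
    col <- paste0("go_", tolower(br))
    ta <- a[[col]]; tb <- b[[col]]
    scores[[col]] <- pair_go_similarity(dag, ta, tb, br)
    missing[[col]] <- length(ta) == 0L || length(tb) == 0L
  }
  scores[["domain"]] <- domain_score(a$domains, b$domains, known,
                                     domain_denominator)
  missing[["domain"]] <- length(a$domains) == 0L || length(b$domains) == 0L
  scores[["pathway"]] <- pathway_score(a$pathways, b$pathways)
  missing[["pathway"]] <- length(a$pathways) == 0L ||
    length(b$pathways) == 0L
  list(pair = pair, scores = scores, missing = missing)
}

#' Build the feature matrix for a list of candidate pairs
#'
#' Rows are pairs, columns the six evidence scores in fixed order; this is
#' the base level of the stacked scheme that the meta-classifier consumes.
#'
#' @param pairs data.frame with columns `idA`, `idB` and optionally `label`
#'   (0/1).
#' @inheritParams build_feature_vector
#' @return object of class `feature_matrix`: list with `x` (numeric matrix),
#'   `pairs` (row keys), `labels` (or `NULL`), `missing` (logical matrix).
#' @export
build_feature_matrix <- function(pairs, store, dag, known, seq_scores = NULL,
                                 domain_denominator = "union") {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  n <- nrow(pairs)
  x <- matrix(0, nrow = n, ncol = length(FEATURE_COLUMNS),
              dimnames = list(NULL, FEATURE_COLUMNS))
  miss <- matrix(FALSE, nrow = n, ncol = length(FEATURE_COLUMNS),
                 dimnames = list(NULL, FEATURE_COLUMNS))
  for (i in seq_len(n)) {
    fv <- build_feature_vector(c(pairs$idA[[i]], pairs$idB[[i]]), store, dag,
                               known, seq_scores, domain_denominator)
    x[i, ] <- fv$scores
    miss[i, ] <- fv$missing
  }
  structure(list(x = x,
                 pairs = canonical_pair_key(pairs$idA, pairs$idB),
                 labels = if ("label" %in% names(pairs))
                   as.integer(pairs$label) else NULL,
                 missing = miss),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d pairs x %d features%s>\n", nrow(x$x),
              ncol(x$x), if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}
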