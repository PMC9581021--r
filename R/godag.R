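GO_BRANCHES <- c("BP", "MF", "CC")

#' Build a Gene Ontology style DAG
#'
#' The ontology is held as a child-to-parent edge list over three disjoint
#' rooted branches (BP, MF, CC). Construction validates that the graph is
#' acyclic, that every node reaches its branch root along parent edges, and
#' that no node reaches more than one root.
#'
#' @param edges data.frame/matrix with columns `child`, `parent` (term ids).
#' @param roots named character vector `c(BP=, MF=, CC=)` (any non-empty
#'   subset of branches).
#' @return object of class `go_dag` with fields `nodes`, `parents` (named
#'   list of parent-id vectors), `branch` (named vector), `roots`.
#' @export
go_dag <- function(edges, roots) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0 && !all(c("child", "parent") %in% names(edges)))
    names(edges)[1:2] <- c("child", "parent")
  if (is.null(names(roots)) || !all(names(roots) %in% GO_BRANCHES))
    stop("roots must be a named vector with names among BP, MF, CC")
  nodes <- unique(c(roots, edges$child, edges$parent))
  parents <- split(as.character(edges$parent), factor(edges$child, nodes))
  parents <- lapply(parents, unique)
  for (r in roots)
    if (length(parents[[r]]) > 0)
      stop("root ", r, " has a parent edge")
  dag <- structure(list(nodes = nodes, parents = parents,
                        branch = character(0), roots = roots,
                        cache = new.env(parent = emptyenv())),
                   class = "go_dag")
  dag$branch <- assign_branches(dag)
  check_acyclic(dag)
  dag$depth <- vapply(dag$nodes, function(n) {
    anc <- term_ancestors(dag, n)
    unname(anc[[dag$roots[[dag$branch[[n]]]]]])
  }, integer(1))
  dag
}

# Every node must reach exactly one root; the branch is inherited from it.
assign_branches <- function(dag) {
  branch <- setNames(rep(NA_character_, length(dag$nodes)), dag$nodes)
  for (b in names(dag$roots)) branch[dag$roots[[b]]] <- b
  for (n in dag$nodes) {
    anc <- names(term_ancestors(dag, n))
    hit <- dag$roots[dag$roots %in% anc]
    if (length(hit) != 1L)
      stop("term ", n, " reaches ", length(hit), " branch roots (must be 1)")
    branch[n] <- names(hit)
  }
  branch
}

# Kahn's algorithm over child->parent edges: processing a node only after
# all its parents guarantees a topological order exists iff acyclic.
check_acyclic <- function(dag) {
  indeg <- vapply(dag$nodes, function(n) length(dag$parents[[n]]), integer(1))
  children <- new.env(parent = emptyenv())
  for (n in dag$nodes)
    for (p in dag$parents[[n]])
      assign(p, c(if (exists(p, children)) get(p, children), n), children)
  queue <- dag$nodes[indeg == 0L]
  done <- 0L
  while (length(queue)) {
    n <- queue[[1L]]; queue <- queue[-1L]; done <- done + 1L
    kids <- if (exists(n, children)) get(n, children) else character()
    for (k in kids) {
      indeg[[k]] <- indeg[[k]] - 1L
      if (indeg[[k]] == 0L) queue <- c(queue, k)
    }
  }
  if (done != length(dag$nodes)) stop("the term graph contains a cycle")
  invisible(TRUE)
}

#' Ancestors of a term with minimal edge distances
#'
#' Breadth-first search upward along child-to-parent edges; the term itself
#' is included at distance 0. Distances are minimal edge counts, which is
#' what the Pekar metric uses on a multi-parent DAG.
#'
#' @param dag a `go_dag`.
#' @param term a term id present in the DAG.
#' @return named integer vector of distances, names are ancestor ids.
#' @export
term_ancestors <- function(dag, term) {
  if (!term %in% dag$nodes) stop("unknown term ", term)
  if (!is.null(dag$cache) && exists(term, envir = dag$cache))
    return(get(term, envir = dag$cache))
  dist <- setNames(0L, term)
  frontier <- term
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, names(dist))
    if (length(nxt)) dist[nxt] <- d
    frontier <- nxt
  }
  if (!is.null(dag$cache)) assign(term, dist, envir = dag$cache)
  dist
}

#' Depth of a term: minimal edge distance from its branch root
#' @param dag a `go_dag`.
#' @param term term id.
#' @export
term_depth <- function(dag, term) {
  if (!is.null(dag$depth) && term %in% names(dag$depth))
    return(unname(dag$depth[[term]]))
  anc <- term_ancestors(dag, term)
  root <- dag$roots[[dag$branch[[term]]]]
  unname(anc[[root]])
}

#' Lowest common subsumer of two terms
#'
#' The LCS is the shared ancestor with maximal depth (minimal edge distance
#' from the branch root); among equally deep candidates the lexicographically
#' smallest term id is chosen, so the result is deterministic on DAGs with
#' multiple deepest common ancestors. Terms must lie in the same branch.
#'
#' @param dag a `go_dag`.
#' @param t1,t2 term ids in the same branch.
#' @return list with `lcs`, `depth` (of the LCS), `d1`, `d2` (minimal edge
#'   distances from `t1` / `t2` up to the LCS).
#' @export
lcs_depth <- function(dag, t1, t2) {
  b1 <- dag$branch[[t1]]; b2 <- dag$branch[[t2]]
  if (!identical(b1, b2))
    stop("terms ", t1, " (", b1, ") and ", t2, " (", b2,
         ") are in different branches")
  a1 <- term_ancestors(dag, t1)
  a2 <- term_ancestors(dag, t2)
  common <- intersect(names(a1), names(a2))
  depths <- vapply(common, function(a) term_depth(dag, a), integer(1))
  best <- sort(common[depths == max(depths)])[1L]
  list(lcs = best, depth = unname(depths[[best]]),
       d1 = unname(a1[[best]]), d2 = unname(a2[[best]]))
}

#' Pekar edge-based semantic similarity between two GO terms
#'
#' `depth(a) / (d1 + d2 + depth(a))` over the shared ancestor `a` that
#' maximizes this ratio, where `depth` is the minimal edge distance from
#' the branch root and `d1`, `d2` are the terms' minimal edge distances up
#' to `a`. On a tree this subsumer is the classic deepest LCS; on a
#' multi-parent DAG maximizing the ratio (rather than raw depth) keeps the
#' metric well behaved — identical non-root terms score exactly 1, because
#' the term itself is always a candidate subsumer at distance zero. Two
#' root terms share no information and score 0.
#'
#' @inheritParams lcs_depth
#' @return similarity in `[0, 1]`.
#' @export
pekar_similarity <- function(dag, t1, t2) {
  b1 <- dag$branch[[t1]]; b2 <- dag$branch[[t2]]
  if (!identical(b1, b2))
    stop("terms ", t1, " (", b1, ") and ", t2, " (", b2,
         ") are in different branches")
  a1 <- term_ancestors(dag, t1)
  a2 <- term_ancestors(dag, t2)
  common <- intersect(names(a1), names(a2))
  max(vapply(common, function(a) {
    depth <- term_depth(dag, a)
    den <- a1[[a]] + a2[[a]] + depth
    if (den == 0) 0 else depth / den
  }, numeric(1)))
}

#' Best-match-average GO similarity between two term sets
#'
#' For one branch: each term of A is matched to its most similar term of B
#' (Pekar similarity); the two directional means are averaged, which makes
#' the score symmetric. An empty side (no annotation in this branch) scores
#' 0 — missing annotation is treated as absence of evidence.
#'
#' @param dag a `go_dag`.
#' @param terms_a,terms_b character vectors of term ids.
#' @param branch one of `"BP"`, `"MF"`, `"CC"`; terms outside the branch or
#'   unknown to the DAG are dropped before scoring.
#' @return similarity in `[0, 1]`.
#' @export
pair_go_similarity <- function(dag, terms_a, terms_b, branch) {
  branch <- match.arg(branch, GO_BRANCHES)
  keep <- function(ts) ts[ts %in% dag$nodes & dag$branch[ts] == branch]
  ta <- keep(unique(as.character(terms_a)))
  tb <- keep(unique(as.character(terms_b)))
  if (length(ta) == 0L || length(tb) == 0L) return(0)
  sim <- outer(ta, tb, Vectorize(function(x, y) pekar_similarity(dag, x, y)))
  (mean(apply(sim, 1L, max)) + mean(apply(sim, 2L, max))) / 2
}

#' Read a GO-style DAG from a tab-separated edge list
#'
#' Format: a header line `#roots<TAB>BP=<id>[<TAB>MF=<id>][<TAB>CC=<id>]`
#' followed by `child<TAB>parent` lines.
#'
#' @param path edge-list file.
#' @return a `go_dag`.
#' @export
read_go_dag <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(lines[[1L]], "#roots"))
    stop(path, ": first line must name branch roots (#roots\tBP=...)")
  kv <- strsplit(lines[[1L]], "\t")[[1L]][-1L]
  kv <- strsplit(kv, "=", fixed = TRUE)
  roots <- setNames(vapply(kv, `[`, character(1), 2L),
                    vapply(kv, `[`, character(1), 1L))
  body <- lines[-1L]
  if (length(body)) {
    parts <- strsplit(body, "\t")
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
      stop(path, ": malformed edge line(s) ",
           paste(bad + 1L, collapse = ", "))
    edges <- data.frame(child = vapply(parts, `[`, character(1), 1L),
                        parent = vapply(parts, `[`, character(1), 2L),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(child = character(), parent = character())
  }
  go_dag(edges, roots)
}

#' Write a DAG in the edge-list format read by [read_go_dag()]
#' @param dag a `go_dag`.
#' @param path output file.
#' @export
write_go_dag <- function(dag, path) {
  header <- paste0("#roots\t",
                   paste(names(dag$roots), dag$roots, sep = "=",
                         collapse = "\t"))
  rows <- unlist(lapply(sort(dag$nodes), function(n) {
    ps <- sort(dag$parents[[n]])
    if (length(ps)) paste(n, ps, sep = "\t") else character()
  }), use.names = FALSE)
  writeLines(c(header, rows), path)
  invisible(path)
}
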