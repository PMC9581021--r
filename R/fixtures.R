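#' Specification for the synthetic input generators
#'
#' Bundles every knob of the fixture generators: ontology size, annotation
#' vocabulary sizes, annotation-set size ranges, sequence length range, the
#' planted effect sizes (per-channel probability that an interacting pair
#' is made to share evidence, versus the non-interacting baseline) and the
#' per-pair corpus composition. Defaults emulate a balanced benchmark with
#' strong planted signal: `p_pos = 0.9`, `p_neg = 0.1`, 2,000 pairs, half
#' positive and half negative.
#'
#' @param seed master seed; every generator draw derives from it.
#' @param n_pairs total candidate pairs (balanced 50/50 by label).
#' @param dag_size terms per GO branch.
#' @param n_domains,n_pathways vocabulary sizes.
#' @param terms_per_branch,domains_per_protein,pathways_per_protein
#'   inclusive integer ranges `c(min, max)` for annotation-set sizes.
#' @param seq_len inclusive sequence-length range.
#' @param p_pos,p_neg per-channel planting probability for positive /
#'   negative pairs (`p_pos >= p_neg`).
#' @param cc_profiles,cc_profile_size cellular-component annotation is
#'   drawn from a small pool of recurrent compartment profiles (each a
#'   fixed subset of CC-branch terms), emulating the strong skew and
#'   co-occurrence structure of real CC annotation; `cc_profiles` is the
#'   pool size and `cc_profile_size` the inclusive range of terms per
#'   profile.
#' @param corpus_hits,corpus_excluded,corpus_irrelevant sentences of each
#'   class generated per pair.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_pairs = 2000L, dag_size = 25L,
                         n_domains = 30L, n_pathways = 20L,
                         terms_per_branch = c(1L, 4L),
                         domains_per_protein = c(1L, 3L),
                         pathways_per_protein = c(1L, 3L),
                         seq_len = c(50L, 200L),
                         p_pos = 0.9, p_neg = 0.1,
                         cc_profiles = 6L, cc_profile_size = c(2L, 3L),
                         corpus_hits = 3L, corpus_excluded = 3L,
                         corpus_irrelevant = 4L) {
  stopifnot(p_pos >= 0, p_pos <= 1, p_neg >= 0, p_neg <= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

rint <- function(range) {
  if (range[[1L]] == range[[2L]]) return(range[[1L]])
  sample(seq(range[[1L]], range[[2L]]), 1L)
}

#' Generate a synthetic three-branch GO-style DAG
#'
#' One rooted DAG per branch; each non-root term attaches to 1-2 parents
#' drawn among earlier terms of the same branch, which makes the graph
#' acyclic by construction. Identical seeds give identical edge lists.
#'
#' @param spec a `fixture_spec` (uses `dag_size`, `seed`).
#' @param seed override for the spec seed.
#' @return a `go_dag`.
#' @export
generate_go_dag <- function(spec = fixture_spec(), seed = spec$seed) {
  with_seed(seed, {
    edges <- list()
    roots <- character()
    for (b in GO_BRANCHES) {
      ids <- sprintf("GO:%s%04d", b, seq_len(spec$dag_size))
      roots[[b]] <- ids[[1L]]
      if (spec$dag_size > 1L) for (i in 2:spec$dag_size) {
        np <- min(sample(1:2, 1L), i - 1L)
        for (p in sample(ids[seq_len(i - 1L)], np))
          edges[[length(edges) + 1L]] <- c(ids[[i]], p)
      }
    }
    edge_df <- if (length(edges))
      data.frame(child = vapply(edges, `[`, character(1), 1L),
                 parent = vapply(edges, `[`, character(1), 2L),
                 stringsAsFactors = FALSE)
    else data.frame(child = character(), parent = character())
    go_dag(edge_df, roots)
  })
}

branch_terms <- function(dag, branch) dag$nodes[dag$branch == branch]

# Recurrent compartment combinations: proteins live in a handful of
# compartment profiles, not in uniform random subsets of the CC branch.
make_cc_profiles <- function(spec, dag) {
  pool <- branch_terms(dag, "CC")
  lapply(seq_len(spec$cc_profiles), function(i)
    sort(sample(pool, min(rint(spec$cc_profile_size), length(pool)))))
}

random_record_fields <- function(spec, dag, cc_profiles = NULL) {
  fields <- list()
  for (b in c("BP", "MF")) {
    pool <- branch_terms(dag, b)
    k <- min(rint(spec$terms_per_branch), length(pool))
    fields[[paste0("go_", tolower(b))]] <- sample(pool, k)
  }
  if (is.null(cc_profiles)) {
    pool <- branch_terms(dag, "CC")
    fields$go_cc <- sample(pool, min(rint(spec$terms_per_branch),
                                     length(pool)))
  } else {
    fields$go_cc <- cc_profiles[[sample.int(length(cc_profiles), 1L)]]
  }
  fields$domains <- sample(sprintf("PF%05d", seq_len(spec$n_domains)),
                           min(rint(spec$domains_per_protein),
                               spec$n_domains))
  fields$pathways <- sample(sprintf("ko%05d", seq_len(spec$n_pathways)),
                            min(rint(spec$pathways_per_protein),
                                spec$n_pathways))
  fields$sequence <- paste(sample(AA_ALPHABET, rint(spec$seq_len),
                                  replace = TRUE), collapse = "")
  fields
}

#' Generate a synthetic annotated proteome
#'
#' Each protein receives random GO terms per branch, domains, pathways and
#' an amino-acid sequence, all drawn from the seeded stream; identical
#' seeds give identical stores.
#'
#' @param spec a `fixture_spec`.
#' @param dag a `go_dag` (see [generate_go_dag()]).
#' @param n_proteins number of proteins.
#' @param seed override for the spec seed.
#' @param prefix accession prefix.
#' @return an `annotation_store`.
#' @export
generate_proteins <- function(spec, dag, n_proteins = 50L,
                              seed = spec$seed, prefix = "P") {
  store <- annotation_store()
  with_seed(seed, {
    profiles <- make_cc_profiles(spec, dag)
    for (i in seq_len(n_proteins)) {
      f <- random_record_fields(spec, dag, profiles)
      f$id <- sprintf("%s%05d", prefix, i)
      ingest_record(store, f, source = "fixture")
    }
  })
  store
}

mutate_sequence <- function(seq, rate = 0.2) {
  chars <- strsplit(seq, "")[[1L]]
  hit <- stats::runif(length(chars)) < rate
  chars[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

PLANT_CHANNELS <- c("go_bp", "go_mf", "go_cc", "pathway", "domain", "seq")

#' Generate a labeled candidate-pair dataset with planted evidence signal
#'
#' Builds `n_pairs` candidate pairs (half labeled 1, half 0), each over two
#' freshly generated proteins. Independently per evidence channel, the pair
#' is made to share evidence with probability `p_pos` (positives) or
#' `p_neg` (negatives): GO branches and pathways by copying the first
#' protein's set onto the second, the sequence channel by deriving the
#' second sequence as a point-mutated copy of the first, and the domain
#' channel by injecting one of the pair's domain combinations into the
#' known domain-interaction list. The manifest records every planting
#' event, so downstream expectations can be computed without re-reading
#' generator internals.
#'
#' @param spec a `fixture_spec`.
#' @param dag a `go_dag`.
#' @param seed override for the spec seed.
#' @return list with `pairs` (data.frame idA, idB, label), `store`
#'   (an `annotation_store` holding all pair proteins), `known` (a
#'   `ddi_set`), and `manifest` (logical data.frame of planting events per
#'   channel).
#' @export
generate_interaction_dataset <- function(spec, dag, seed = spec$seed) {
  n <- spec$n_pairs
  labels <- rep(c(1L, 0L), length.out = n)  # interleaved, balanced
  store <- annotation_store()
  ddi <- character()
  rows <- vector("list", n)
  manifest <- matrix(FALSE, nrow = n, ncol = length(PLANT_CHANNELS),
                     dimnames = list(NULL, PLANT_CHANNELS))
  with_seed(seed, {
    profiles <- make_cc_profiles(spec, dag)
    for (i in seq_len(n)) {
      p <- if (labels[[i]] == 1L) spec$p_pos else spec$p_neg
      fa <- random_record_fields(spec, dag, profiles)
      fb <- random_record_fields(spec, dag, profiles)
      plant <- stats::runif(length(PLANT_CHANNELS)) < p
      names(plant) <- PLANT_CHANNELS
      for (ch in c("go_bp", "go_mf", "go_cc"))
        if (plant[[ch]]) fb[[ch]] <- fa[[ch]]
      if (plant[["pathway"]]) fb$pathways <- fa$pathways
      if (plant[["seq"]]) fb$sequence <- mutate_sequence(fa$sequence)
      if (plant[["domain"]])
        ddi <- c(ddi, canonical_pair_key(sample(fa$domains, 1L),
                                         sample(fb$domains, 1L)))
      fa$id <- sprintf("A%06d", i)
      fb$id <- sprintf("B%06d", i)
      ingest_record(store, fa, source = "fixture")
      ingest_record(store, fb, source = "fixture")
      manifest[i, ] <- plant
      rows[[i]] <- data.frame(idA = fa$id, idB = fb$id,
                              label = labels[[i]],
                              stringsAsFactors = FALSE)
    }
  })
  list(pairs = do.call(rbind, rows), store = store,
       known = domain_interaction_set(
         if (length(ddi)) do.call(rbind, strsplit(ddi, "|", fixed = TRUE))
         else NULL),
       manifest = as.data.frame(manifest))
}

# Surface forms used to compose sentences; their stems are guaranteed to
# fall in (hits) or out of (irrelevant) the default lexicons.
HIT_VERBS <- c("binds", "interacts with", "recruits")
EXCLUSION_PHRASES <- c("increases expression of",
                       "activates the promoter of",
                       "enhances transcription of")
IRRELEVANT_SENTENCES <- c(
  "The buffer was prepared at room temperature.",
  "Samples were stored overnight before measurement.",
  "The cohort included twelve healthy volunteers.",
  "Imaging was performed on a confocal microscope.")

#' Generate a labeled evidence corpus for a set of pairs
#'
#' For each pair, emits hit sentences (both protein symbols plus an
#' interaction verb), excluded sentences (both symbols plus an
#' expression/regulation exclusion phrase — some also carrying an
#' interaction verb, reproducing the classic false-positive mode), and
#' irrelevant sentences, grouped into one document per pair. The ground
#' truth records every sentence's class.
#'
#' @param pairs data.frame with `idA`, `idB`.
#' @param spec a `fixture_spec` (corpus counts).
#' @param seed override for the spec seed.
#' @return list with `documents` (list of `document_text`) and `truth`
#'   (data.frame doc_id, sentence, class).
#' @export
generate_corpus <- function(pairs, spec = fixture_spec(),
                            seed = spec$seed) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  docs <- list()
  truth <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(pairs))) {
      a <- tolower(pairs$idA[[i]]); b <- tolower(pairs$idB[[i]])
      doc_id <- sprintf("PMID%06d", i)
      sents <- character(); cls <- character()
      for (k in seq_len(spec$corpus_hits)) {
        sents <- c(sents, sprintf("%s %s %s in vitro.", a,
                                  sample(HIT_VERBS, 1L), b))
        cls <- c(cls, "hit")
      }
      for (k in seq_len(spec$corpus_excluded)) {
        s <- if (k %% 2L == 0L)
          sprintf("%s recruits %s during gene regulation studies of %s.",
                  a, b, sample(EXCLUSION_PHRASES, 1L))
        else sprintf("%s %s %s in tumor tissue.", a,
                     sample(EXCLUSION_PHRASES, 1L), b)
        sents <- c(sents, s)
        cls <- c(cls, "excluded")
      }
      for (k in seq_len(spec$corpus_irrelevant)) {
        sents <- c(sents, sample(IRRELEVANT_SENTENCES, 1L))
        cls <- c(cls, "irrelevant")
      }
      ord <- sample.int(length(sents))
      sents <- sents[ord]; cls <- cls[ord]
      docs[[length(docs) + 1L]] <- structure(
        list(doc_id = doc_id, title = "", abstract = "",
             body_paragraphs = paste(sents, collapse = " ")),
        class = "document_text")
      truth[[length(truth) + 1L]] <- data.frame(
        doc_id = doc_id, sentence = sents, class = cls,
        idA = pairs$idA[[i]], idB = pairs$idB[[i]],
        stringsAsFactors = FALSE)
    }
  })
  list(documents = docs, truth = do.call(rbind, truth))
}

#' Write a complete synthetic input bundle to a directory
#'
#' Emits everything an experiment consumes: the annotation store, the GO
#' DAG edge list, the known domain-interaction file, a labeled pairs file,
#' a corpus directory with one plain-text document per pair, and the
#' planting manifest.
#'
#' @param spec a `fixture_spec`.
#' @param out_dir target directory.
#' @return paths of the written artifacts, invisibly.
#' @export
write_fixture_bundle <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dag <- generate_go_dag(spec)
  ds <- generate_interaction_dataset(spec, dag)
  paths <- list(
    dag = file.path(out_dir, "go_dag.tsv"),
    domains = file.path(out_dir, "domain_interactions.tsv"),
    pairs = file.path(out_dir, "pairs.tsv"),
    store = file.path(out_dir, "store"),
    corpus = file.path(out_dir, "corpus"),
    manifest = file.path(out_dir, "manifest.tsv"))
  write_go_dag(dag, paths$dag)
  write_domain_interactions(ds$known, paths$domains)
  utils::write.table(ds$pairs, paths$pairs, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_store(ds$store, paths$store)
  dir.create(paths$corpus, showWarnings = FALSE)
  corpus <- generate_corpus(ds$pairs[seq_len(min(20L, nrow(ds$pairs))), ],
                            spec)
  for (doc in corpus$documents)
    writeLines(c(paste(doc$doc_id, "body", sep = "\t"),
                 doc$body_paragraphs),
               file.path(paths$corpus, paste0(doc$doc_id, ".txt")))
  utils::write.table(ds$manifest, paths$manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
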