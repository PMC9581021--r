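# Lightweight NLP layer: rule-based suffix stemmer and a lexicon/suffix
# verb-noun tagger. Both are deterministic, and the same stemmer is applied
# to lexicon entries and sentence tokens so matching happens in stem space.

IRREGULAR_STEMS <- c(bound = "bind", binding = "bind", bound. = "bind",
                     signalling = "signal", signaling = "signal")

STOP_WORDS <- c(
  "a", "an", "the", "this", "that", "these", "those", "it", "its", "they",
  "them", "their", "we", "our", "i", "you", "he", "she", "his", "her",
  "of", "in", "on", "at", "by", "for", "with", "to", "from", "into",
  "onto", "via", "through", "between", "among", "and", "or", "but", "nor",
  "not", "no", "is", "are", "was", "were", "be", "been", "being", "am",
  "do", "does", "did", "has", "have", "had", "can", "could", "may",
  "might", "must", "shall", "should", "will", "would", "than", "then",
  "as", "if", "also", "both", "each", "such", "which", "who", "whom",
  "whose", "what", "when", "where", "while", "here", "there", "however",
  "thus", "therefore", "moreover", "furthermore", "respectively")

# Common verbs of the interaction/regulation literature, in stem space:
# used to tag tokens as verbs when the surface form carries no suffix cue.
VERB_STEMS <- c("bind", "interact", "recruit", "signal", "associate",
                "phosphorylate", "activate", "inhibit", "regulate",
                "increase", "decrease", "induce", "suppress", "promote",
                "form", "co-precipitate", "coprecipitate", "complex",
                "modulate", "stabilize", "mediate", "target", "express")

#' Reduce a word to its stem
#'
#' A small deterministic suffix stripper: an irregular-form map is applied
#' first, then the suffixes ion/ing/ment/er/ed/es/s are removed (longest
#' first) when the remaining stem keeps at least three characters. It is
#' not a full morphological stemmer; it is sufficient to put lexicon
#' entries and sentence tokens in the same stem space.
#'
#' @param tokens character vector of lowercase tokens.
#' @return character vector of stems.
#' @export
stem_tokens <- function(tokens) {
  vapply(tokens, function(tok) {
    if (tok %in% names(IRREGULAR_STEMS)) return(IRREGULAR_STEMS[[tok]])
    for (suf in c("ional", "ation", "ions", "ion", "ings", "ing", "ments",
                  "ment", "ers", "er", "ed", "ies", "es", "s")) {
      if (endsWith(tok, suf) && nchar(tok) - nchar(suf) >= 3L) {
        stem <- substr(tok, 1L, nchar(tok) - nchar(suf))
        if (suf == "ies") stem <- paste0(stem, "y")
        return(stem)
      }
    }
    tok
  }, character(1), USE.NAMES = FALSE)
}

#' Split a section of text into sentences
#'
#' Splits at `.`, `!` or `?` followed by whitespace (or end of text);
#' abbreviation handling is deliberately minimal.
#'
#' @param text character scalar.
#' @return character vector of trimmed sentences.
#' @export
split_sentences <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  parts <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1L]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

tokenize <- function(sentence) {
  toks <- strsplit(tolower(sentence), "[^a-z0-9'-]+")[[1L]]
  toks[nzchar(toks)]
}

# verb/noun tag: verbs by stem lexicon or surface suffix; adverbs (-ly)
# dropped; everything else kept as a noun.
tag_token <- function(token, stem) {
  if (endsWith(token, "ly")) return("adv")
  if (stem %in% VERB_STEMS) return("verb")
  if (endsWith(token, "ing") || endsWith(token, "ed")) return("verb")
  "noun"
}

#' Preprocess a section of cleaned text into sentences and tokens
#'
#' Pipeline: sentence split, tokenize, lowercase, part-of-speech tag, drop
#' stop words, keep verbs and nouns, stem every retained token. All steps
#' are deterministic, so the same text always yields the same processed
#' sentences.
#'
#' @param text cleaned section text.
#' @param doc_id document identifier carried into each sentence.
#' @param section `"abstract"` or `"body"`.
#' @return list of `processed_sentence` objects: `doc_id`, `section`,
#'   `text`, `tokens`, `stems`, `kept` (data.frame token/stem/pos of the
#'   surviving verbs and nouns).
#' @export
preprocess <- function(text, doc_id = "", section = "body") {
  lapply(split_sentences(text), function(s) {
    toks <- tokenize(s)
    stems <- stem_tokens(toks)
    keep <- !(toks %in% STOP_WORDS)
    pos <- character(length(toks))
    pos[keep] <- mapply(tag_token, toks[keep], stems[keep])
    keep <- keep & pos %in% c("verb", "noun")
    structure(list(doc_id = doc_id, section = section, text = s,
                   tokens = toks, stems = stems,
                   kept = data.frame(token = toks[keep], stem = stems[keep],
                                     pos = pos[keep],
                                     stringsAsFactors = FALSE)),
              class = "processed_sentence")
  })
}

#' Strip markup from a raw document
#'
#' Removes reference, acknowledgment and figure-caption blocks, keeps
#' `<title>`, `<abstract>` and `<p>` body paragraphs, and strips any
#' remaining tags. Input without tags is treated as a single body
#' paragraph.
#'
#' @param raw document text, possibly with simplified article markup.
#' @param doc_id document identifier.
#' @return object of class `document_text` with `doc_id`, `title`,
#'   `abstract`, `body_paragraphs`.
#' @export
clean_markup <- function(raw, doc_id = "") {
  raw <- paste(raw, collapse = "\n")
  grab <- function(tag) {
    m <- regmatches(raw, gregexpr(sprintf("<%s>(.*?)</%s>", tag, tag),
                                  raw))[[1L]]
    gsub(sprintf("</?%s>", tag), "", m)
  }
  # drop non-body sections entirely
  for (tag in c("ref", "references", "ack", "acknowledgments", "fig",
                "figure", "caption"))
    raw <- gsub(sprintf("<%s>.*?</%s>", tag, tag), "", raw)
  title <- grab("title")
  abstract <- grab("abstract")
  body <- grab("p")
  if (length(title) == 0L && length(abstract) == 0L && length(body) == 0L &&
      !grepl("<[a-zA-Z]+>", raw)) {
    body <- trimws(raw)
    body <- body[nzchar(body)]
  }
  strip <- function(x) trimws(gsub("<[^>]*>", "", x))
  structure(list(doc_id = doc_id,
                 title = if (length(title)) strip(title)[[1L]] else "",
                 abstract = if (length(abstract)) strip(abstract)[[1L]]
                            else "",
                 body_paragraphs = strip(body)),
            class = "document_text")
}

#' Read a corpus directory into document texts
#'
#' Each file is one document. `.xml` files go through [clean_markup()];
#' `.txt` files are cleaned plain text whose first line is a
#' `doc_id<TAB>section` header (`section` is `abstract` or `body`) followed
#' by the section's text.
#'
#' @param dir corpus directory.
#' @return list of `document_text` objects.
#' @export
read_corpus <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(txt|xml)$",
                           full.names = TRUE))
  docs <- list()
  for (f in files) {
    lines <- readLines(f, warn = FALSE, encoding = "UTF-8")
    if (grepl("\\.xml$", f)) {
      doc <- tryCatch(clean_markup(lines,
                                   doc_id = tools::file_path_sans_ext(
                                     basename(f))),
                      error = function(e) {
                        message("skipping unparseable document ", f, ": ",
                                conditionMessage(e))
                        NULL
                      })
      if (!is.null(doc)) docs[[length(docs) + 1L]] <- doc
    } else {
      header <- strsplit(lines[[1L]], "\t")[[1L]]
      if (length(header) < 2L)
        stop(f, ": first line must be 'doc_id<TAB>section'")
      text <- paste(lines[-1L], collapse = " ")
      doc <- structure(list(doc_id = header[[1L]], title = "",
                            abstract = if (header[[2L]] == "abstract") text
                                       else "",
                            body_paragraphs = if (header[[2L]] == "body")
                              text else character()),
                       class = "document_text")
      docs[[length(docs) + 1L]] <- doc
    }
  }
  docs
}

#' Lexicons driving the evidence rules
#'
#' Four dictionaries, all matched in stem space: interaction terms (verbs
#' and nouns indicating an interaction context), context-exclusion entries
#' (single terms, or term-sets that must all co-occur, marking gene
#' expression / regulation context rather than physical interaction),
#' experimental-method entities, and a protein-accession-to-symbol synonym
#' map. Entries are stemmed on construction with the package stemmer.
#'
#' @param interaction_terms character vector of surface terms.
#' @param context_exclusion list of character vectors (length-1 entries are
#'   single exclusion terms; longer entries are conjunctive term-sets).
#' @param method_entities character vector of surface terms.
#' @param protein_synonyms named list: accession -> character vector of
#'   symbols.
#' @return object of class `lexicons`.
#' @export
lexicons <- function(interaction_terms, context_exclusion, method_entities,
                     protein_synonyms) {
  structure(list(
    interaction_terms = unique(stem_tokens(tolower(interaction_terms))),
    context_exclusion = lapply(context_exclusion, function(e)
      unique(stem_tokens(tolower(e)))),
    method_entities = unique(stem_tokens(tolower(method_entities))),
    protein_synonyms = lapply(protein_synonyms, function(s)
      unique(tolower(s)))),
    class = "lexicons")
}

#' Built-in default lexicons
#'
#' Editable seed dictionaries: interaction verbs/nouns (bind, interact,
#' recruit, signal, ...), expression/regulation exclusion context
#' (expression, promoter, transcription, ...), and common experimental
#' method entities (two-hybrid, co-immunoprecipitation, ...). The synonym
#' map is empty; supply one per experiment.
#'
#' @param protein_synonyms named list accession -> symbols.
#' @return a `lexicons` object.
#' @export
default_lexicons <- function(protein_synonyms = list()) {
  lexicons(
    interaction_terms = c("bind", "binds", "binding", "interact",
                          "interacts", "interaction", "recruit", "recruits",
                          "signaling", "signals", "associates",
                          "association", "complex", "coprecipitates",
                          "phosphorylates"),
    context_exclusion = list("expression", "promoter", "transcription",
                             "mrna", "exome",
                             c("gene", "regulation"),
                             c("profiling", "regulated")),
    method_entities = c("two-hybrid", "coimmunoprecipitation",
                        "co-immunoprecipitation", "pulldown", "pull-down",
                        "crosslinking", "colocalization", "spr",
                        "immunoblotting"),
    protein_synonyms = protein_synonyms)
}

#' Read lexicons from a directory of plain-text lists
#'
#' Files: `interaction_terms.txt`, `context_exclusion.txt` (comma-joined
#' term-sets, one per line), `method_entities.txt`, and
#' `protein_synonyms.tsv` (`accession<TAB>sym1,sym2,...`). Missing files
#' fall back to the built-in defaults for that dictionary.
#'
#' @param dir lexicon directory.
#' @return a `lexicons` object.
#' @export
read_lexicons <- function(dir) {
  defaults <- default_lexicons()
  read_list <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) return(NULL)
    ln <- readLines(p, warn = FALSE)
    trimws(ln[nzchar(trimws(ln)) & !startsWith(ln, "#")])
  }
  it <- read_list("interaction_terms.txt")
  ce <- read_list("context_exclusion.txt")
  me <- read_list("method_entities.txt")
  syn <- NULL
  sp <- file.path(dir, "protein_synonyms.tsv")
  if (file.exists(sp)) {
    ln <- readLines(sp, warn = FALSE)
    ln <- ln[nzchar(trimws(ln))]
    parts <- strsplit(ln, "\t")
    syn <- setNames(lapply(parts, function(p)
      trimws(strsplit(p[[2L]], ",")[[1L]])),
      vapply(parts, `[`, character(1), 1L))
  }
  lex <- defaults
  if (!is.null(it)) lex$interaction_terms <- unique(stem_tokens(tolower(it)))
  if (!is.null(ce)) lex$context_exclusion <- lapply(
    strsplit(ce, ","), function(e) unique(stem_tokens(tolower(trimws(e)))))
  if (!is.null(me)) lex$method_entities <- unique(stem_tokens(tolower(me)))
  if (!is.null(syn)) lex$protein_synonyms <- lapply(syn, tolower)
  lex
}

#' Is a sentence in an excluded (non-interaction) regulatory context?
#'
#' `TRUE` when any single exclusion term — or every member of any
#' conjunctive exclusion term-set — occurs among the sentence's stems.
#' This is the guard against the classic false-positive mode: sentences
#' about gene expression and regulation that still contain interaction
#' verbs.
#'
#' @param sentence a `processed_sentence`.
#' @param lex a `lexicons` object.
#' @export
context_excluded <- function(sentence, lex) {
  for (entry in lex$context_exclusion)
    if (all(entry %in% sentence$stems)) return(TRUE)
  FALSE
}

match_synonyms <- function(sentence, syns) {
  hits <- character()
  toks <- sentence$tokens
  for (s in syns) if (s %in% toks) hits <- c(hits, s)
  hits
}

#' Evidence hit for one pair in one sentence
#'
#' A hit requires all three of: (i) at least one synonym of each pair
#' member present in the sentence, (ii) the sentence not context-excluded,
#' (iii) at least one interaction term among the kept verb/noun stems. The
#' hit records the matched interacting words, the matched protein mentions
#' and any experimental-method entities present.
#'
#' @param sentence a `processed_sentence`.
#' @param pair character vector of two accessions (must be present in the
#'   synonym map).
#' @param lex a `lexicons` object.
#' @return a hit record (list), or `NULL` when the sentence is not
#'   evidence.
#' @export
find_pair_evidence <- function(sentence, pair, lex) {
  syn_a <- lex$protein_synonyms[[pair[[1L]]]] %||% tolower(pair[[1L]])
  syn_b <- lex$protein_synonyms[[pair[[2L]]]] %||% tolower(pair[[2L]])
  hits_a <- match_synonyms(sentence, syn_a)
  hits_b <- match_synonyms(sentence, syn_b)
  if (length(hits_a) == 0L || length(hits_b) == 0L) return(NULL)
  if (context_excluded(sentence, lex)) return(NULL)
  words <- intersect(sentence$kept$stem, lex$interaction_terms)
  if (length(words) == 0L) return(NULL)
  methods <- intersect(sentence$stems, lex$method_entities)
  list(doc_id = sentence$doc_id, section = sentence$section,
       sentence = sentence$text, interacting_words = words,
       proteins = c(hits_a[[1L]], hits_b[[1L]]),
       method_entities = methods)
}

#' Are both pair members mentioned in a sentence?
#' @inheritParams find_pair_evidence
#' @export
pair_co_mentioned <- function(sentence, pair, lex) {
  syn_a <- lex$protein_synonyms[[pair[[1L]]]] %||% tolower(pair[[1L]])
  syn_b <- lex$protein_synonyms[[pair[[2L]]]] %||% tolower(pair[[2L]])
  length(match_synonyms(sentence, syn_a)) > 0L &&
    length(match_synonyms(sentence, syn_b)) > 0L
}

#' Evidence report for one protein pair over a document corpus
#'
#' Aggregates [find_pair_evidence()] over every sentence (abstract and body)
#' of every document. The report lists the hit sentences with their
#' interacting words, matched proteins and experimental-method entities,
#' plus two summary flags: `proteins_co_mentioned` and
#' `interaction_context_found` (which implies the former; the implication
#' is asserted on every report).
#'
#' @param documents list of `document_text` (see [read_corpus()]).
#' @param pair character vector of two accessions.
#' @param lex a `lexicons` object.
#' @return object of class `evidence_report`.
#' @export
evaluate_pair <- function(documents, pair, lex) {
  hits <- list()
  co_any <- FALSE
  for (doc in documents) {
    sections <- c(list(list(text = doc$abstract, tag = "abstract")),
                  lapply(doc$body_paragraphs, function(p)
                    list(text = p, tag = "body")))
    for (sec in sections) {
      if (!nzchar(sec$text)) next
      for (s in preprocess(sec$text, doc_id = doc$doc_id,
                           section = sec$tag)) {
        co_any <- co_any || pair_co_mentioned(s, pair, lex)
        h <- find_pair_evidence(s, pair, lex)
        if (!is.null(h)) hits[[length(hits) + 1L]] <- h
      }
    }
  }
  rep <- structure(list(pair = pair, hits = hits,
                        proteins_co_mentioned = co_any,
                        interaction_context_found = length(hits) > 0L),
                   class = "evidence_report")
  stopifnot(!rep$interaction_context_found || rep$proteins_co_mentioned)
  rep
}

#' @export
print.evidence_report <- function(x, ...) {
  cat(sprintf("evidence report for %s - %s\n", x$pair[[1L]], x$pair[[2L]]))
  cat(sprintf("  co-mentioned: %s; interaction context: %s; hits: %d\n",
              x$proteins_co_mentioned, x$interaction_context_found,
              length(x$hits)))
  for (h in x$hits)
    cat(sprintf("  [%s/%s] %s\n    words: %s%s\n", h$doc_id, h$section,
                h$sentence, paste(h$interacting_words, collapse = ", "),
                if (length(h$method_entities))
                  paste0("; methods: ",
                         paste(h$method_entities, collapse = ", ")) else ""))
  invisible(x)
}

#' Write an evidence report as JSON
#' @param report an `evidence_report`.
#' @param path output file.
#' @export
write_evidence_report <- function(report, path) {
  jsonlite::write_json(list(pair = report$pair,
                            proteins_co_mentioned =
                              report$proteins_co_mentioned,
                            interaction_context_found =
                              report$interaction_context_found,
                            hits = report$hits),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
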