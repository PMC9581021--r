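# Derive a per-dataset 31-bit seed from the experiment seed and the dataset
# name, so the result of a job is independent of scheduling order.
derive_seed <- function(seed, name) {
  h <- digest::digest(paste(seed, name, sep = "\r"), algo = "sha256",
                      serialize = FALSE)
  strtoi(substr(h, 1L, 7L), base = 16L)
}

#' Read a candidate-pair file
#'
#' Tab-separated `idA<TAB>idB[<TAB>label]`, label in {0, 1}. `(A, B)` and
#' `(B, A)` denote the same unordered pair; duplicates under
#' canonicalization are dropped with a warning. Self-pairs `(A, A)` are
#' allowed — a protein can self-interact.
#'
#' @param path pairs file.
#' @return data.frame with `idA`, `idB` and `label` when present.
#' @export
read_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop(path, ": malformed pair line(s) ", paste(bad, collapse = ", "))
  df <- data.frame(idA = vapply(parts, `[`, character(1), 1L),
                   idB = vapply(parts, `[`, character(1), 2L),
                   stringsAsFactors = FALSE)
  has_label <- all(lengths(parts) >= 3L)
  if (has_label) {
    df$label <- as.integer(vapply(parts, `[`, character(1), 3L))
    if (any(is.na(df$label)) || !all(df$label %in% 0:1))
      stop(path, ": labels must be 0 or 1")
  }
  key <- canonical_pair_key(df$idA, df$idB)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(path, ": ", sum(dup), " duplicate pair(s) removed",
            call. = FALSE)
    df <- df[!dup, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Load and validate an experiment configuration
#'
#' YAML with top-level keys: `mode` (train/test), `seed`, `jobs`, `store`
#' (store directory), `model` (model archive path: written in train mode
#' when given, required and existing in test mode), `resources` (`dag`,
#' `domains`, optional `records`, `seq_scores`), and `datasets` — a list of
#' `{name, pairs}` entries. Every referenced path is checked before any
#' computation starts, and problems are reported field by field.
#'
#' @param path YAML configuration file.
#' @return object of class `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  problems <- character()
  need <- function(cond, msg) if (!isTRUE(cond))
    problems <<- c(problems, msg)
  need(!is.null(cfg$mode) && cfg$mode %in% c("train", "test"),
       "mode: must be 'train' or 'test'")
  cfg$seed <- cfg$seed %||% 1L
  cfg$jobs <- cfg$jobs %||% 1L
  need(is.numeric(cfg$jobs) && cfg$jobs >= 1,
       "jobs: must be an integer >= 1")
  need(!is.null(cfg$resources$dag) && file.exists(cfg$resources$dag),
       sprintf("resources.dag: missing file '%s'",
               cfg$resources$dag %||% ""))
  need(!is.null(cfg$resources$domains) &&
         file.exists(cfg$resources$domains),
       sprintf("resources.domains: missing file '%s'",
               cfg$resources$domains %||% ""))
  for (opt in c("records", "seq_scores"))
    if (!is.null(cfg$resources[[opt]]))
      need(file.exists(cfg$resources[[opt]]),
           sprintf("resources.%s: missing file '%s'", opt,
                   cfg$resources[[opt]]))
  need(!is.null(cfg$store), "store: required")
  need(length(cfg$datasets) >= 1L, "datasets: at least one entry required")
  for (i in seq_along(cfg$datasets)) {
    d <- cfg$datasets[[i]]
    need(!is.null(d$name), sprintf("datasets[%d].name: required", i))
    need(!is.null(d$pairs) && file.exists(d$pairs),
         sprintf("datasets[%d].pairs: missing file '%s'", i,
                 d$pairs %||% ""))
  }
  if (identical(cfg$mode, "test"))
    need(!is.null(cfg$model) && file.exists(cfg$model),
         "model: test mode requires an existing trained-model path")
  if (identical(cfg$mode, "train"))
    for (i in seq_along(cfg$datasets)) {
      d <- cfg$datasets[[i]]
      if (!is.null(d$pairs) && file.exists(d$pairs)) {
        # a file that fails to parse is deferred to its own job, so one
        # malformed dataset cannot veto the whole run
        pr <- tryCatch(read_pairs(d$pairs), error = function(e) e)
        if (!inherits(pr, "error"))
          need("label" %in% names(pr),
               sprintf("datasets[%d].pairs: train mode requires labels", i))
      }
    }
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  structure(cfg, class = "experiment_config")
}

run_one_dataset <- function(d, cfg, shared, out_dir) {
  ds_dir <- file.path(out_dir, d$name)
  dir.create(ds_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- derive_seed(cfg$seed, d$name)
  pairs <- read_pairs(d$pairs)
  fm <- build_feature_matrix(pairs, shared$store, shared$dag, shared$known,
                             seq_scores = shared$seq_scores)
  feat <- data.frame(pair = fm$pairs, fm$x, check.names = FALSE)
  utils::write.table(feat, file.path(ds_dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (cfg$mode == "train") {
    model <- ppi_train(fm, seed = seed)
    save_ppi_model(model, file.path(ds_dir, "model.json"))
    rep <- model$report
    jsonlite::write_json(
      list(accuracy = rep$accuracy, precision = rep$precision,
           recall = rep$recall, f1 = rep$f1, auc = rep$auc,
           confusion = as.vector(rep$confusion),
           folds = lapply(rep$folds, function(f)
             list(accuracy = f$accuracy, f1 = f$f1))),
      file.path(ds_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    list(name = d$name, status = "ok", mode = "train",
         accuracy = rep$accuracy, n = nrow(pairs))
  } else {
    preds <- predict(shared$model, fm)
    utils::write.table(preds, file.path(ds_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(attr(preds, "positives"),
               file.path(ds_dir, "positive_pairs.txt"))
    list(name = d$name, status = "ok", mode = "test",
         n_positive = sum(preds$call), n = nrow(pairs))
  }
}

#' Run a configured experiment end to end
#'
#' Loads the shared resources once (annotation store, GO DAG, known
#' domain interactions, optional precomputed sequence scores and model),
#' then processes each dataset as an independent job: feature generation
#' followed by training (with its cross-validation report) or prediction.
#' Jobs run in parallel up to `config$jobs`; because each dataset's RNG
#' stream derives from (seed, dataset name), the outputs are identical to
#' a sequential run. A failing dataset aborts only its own job. The shared
#' store is re-persisted after the run, so later experiments over the same
#' proteins skip re-ingestion.
#'
#' @param config an `experiment_config` or a path to one.
#' @param out_dir output directory (one subdirectory per dataset plus a
#'   `manifest.json` run summary).
#' @return run summary list (per-dataset status and counts), invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  cfg <- if (inherits(config, "experiment_config")) config
         else load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  store <- if (dir.exists(cfg$store)) read_store(cfg$store)
           else annotation_store()
  baseline <- store$n_ingested
  if (!is.null(cfg$resources$records))
    read_records(store, cfg$resources$records)
  new_ingests <- store$n_ingested - baseline
  shared <- list(
    store = store,
    dag = read_go_dag(cfg$resources$dag),
    known = read_domain_interactions(cfg$resources$domains),
    seq_scores = if (!is.null(cfg$resources$seq_scores))
      seq_score_table(cfg$resources$seq_scores),
    model = if (identical(cfg$mode, "test")) load_ppi_model(cfg$model))
  jobs <- max(1L, as.integer(cfg$jobs))
  results <- parallel::mclapply(cfg$datasets, function(d) {
    tryCatch(run_one_dataset(d, cfg, shared, out_dir),
             error = function(e)
               list(name = d$name %||% "?", status = "failed",
                    error = conditionMessage(e)))
  }, mc.cores = jobs)
  if (identical(cfg$mode, "train") && !is.null(cfg$model) &&
      length(cfg$datasets) == 1L) {
    src <- file.path(out_dir, cfg$datasets[[1L]]$name, "model.json")
    if (file.exists(src)) file.copy(src, cfg$model, overwrite = TRUE)
  }
  write_store(store, cfg$store)
  summary <- list(mode = cfg$mode, seed = cfg$seed,
                  new_ingests = new_ingests,
                  datasets = results)
  jsonlite::write_json(summary, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
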