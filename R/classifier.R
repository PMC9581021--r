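# Run code under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Scale feature columns to unit variance
#'
#' Each column is divided by its sample standard deviation (n-1 denominator);
#' no mean centering is applied, so the zero point of every evidence score
#' is preserved. Zero-variance columns pass through unchanged with a
#' warning. The scale statistics are returned for test-time reuse: a test
#' matrix must be scaled with the training statistics, never refit.
#'
#' @param x numeric matrix (rows = pairs, columns = features).
#' @param scale optional previously computed statistics; when supplied they
#'   are applied as-is.
#' @return list with `x` (scaled matrix) and `scale` (named divisor vector).
#' @export
normalize_unit_variance <- function(x, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(scale)) {
    scale <- apply(x, 2L, stats::sd)
    flat <- !is.finite(scale) | scale == 0
    if (any(flat)) {
      warning("zero-variance column(s) left unscaled: ",
              paste(colnames(x)[flat], collapse = ", "), call. = FALSE)
      scale[flat] <- 1
    }
    names(scale) <- colnames(x)
  }
  list(x = sweep(x, 2L, scale, "/"), scale = scale)
}

# ---- discrete AdaBoost with exhaustive decision stumps -----------------

# Best weighted stump over all features/thresholds/polarities.
# h(x) = polarity * (+1 if x[, feature] > threshold else -1).
# Ties broken by (feature index, threshold, polarity) for determinism.
fit_stump <- function(x, y, w) {
  n <- nrow(x)
  best <- list(err = Inf)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ord <- order(v)
    vs <- v[ord]; ys <- y[ord]; ws <- w[ord]
    cpos <- cumsum(ws * (ys > 0))
    cneg <- cumsum(ws * (ys < 0))
    wpos <- cpos[n]; wneg <- cneg[n]
    # candidate cut after position i (i = 0..n); only distinct-value gaps
    cuts <- c(0L, which(vs[-n] != vs[-1L]), n)
    for (i in cuts) {
      ep <- (if (i == 0L) 0 else cpos[i]) + (wneg - if (i == 0L) 0 else
        cneg[i])                               # polarity +1 error
      thr <- if (i == 0L) vs[1L] - 1 else if (i == n) vs[n] + 1 else
        (vs[i] + vs[i + 1L]) / 2
      for (pol in c(1, -1)) {
        e <- if (pol > 0) ep else (wpos + wneg) - ep
        if (e < best$err - 1e-12) {
          best <- list(feature = j, threshold = thr, polarity = pol, err = e)
        }
      }
    }
  }
  best
}

predict_stump <- function(stump, x) {
  stump$polarity * ifelse(x[, stump$feature] > stump$threshold, 1, -1)
}

# y in {-1, +1}. Returns stumps, alphas. Deterministic (no RNG).
adaboost_fit <- function(x, y, n_rounds = 100L) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric()
  for (m in seq_len(n_rounds)) {
    s <- fit_stump(x, y, w)
    err <- max(min(s$err, 1 - 1e-10), 1e-10)
    if (s$err >= 0.5 - 1e-12) break        # no better than chance: stop
    alpha <- 0.5 * log((1 - err) / err)
    h <- predict_stump(s, x)
    stumps[[length(stumps) + 1L]] <- s[c("feature", "threshold", "polarity")]
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
    if (s$err <= 1e-10) break              # perfect stump: ensemble done
  }
  if (length(stumps) == 0L) {              # degenerate: constant majority
    maj <- if (sum(y > 0) >= sum(y < 0)) 1 else -1
    stumps <- list(list(feature = 1L, threshold = if (maj > 0)
      min(x[, 1L]) - 1 else max(x[, 1L]) + 1, polarity = 1))
    alphas <- 1
  }
  list(stumps = stumps, alphas = alphas)
}

# Normalized ensemble margin in [-1, 1].
adaboost_margin <- function(ensemble, x) {
  if (nrow(x) == 0L) return(numeric())
  f <- numeric(nrow(x))
  for (m in seq_along(ensemble$stumps))
    f <- f + ensemble$alphas[[m]] * predict_stump(ensemble$stumps[[m]], x)
  f / sum(ensemble$alphas)
}

# ---- evaluation ---------------------------------------------------------

#' ROC curve and area by probability-threshold sweep
#'
#' Sweeps every distinct probability as a decision threshold, records
#' (false-positive rate, true-positive rate) points and integrates by the
#' trapezoid rule. Identical probabilities for every row give the chance
#' diagonal (AUC 0.5).
#'
#' @param probabilities numeric scores in `[0, 1]`.
#' @param truth 0/1 labels.
#' @return list with `points` (data.frame fpr, tpr) and `auc`.
#' @export
roc_curve <- function(probabilities, truth) {
  truth <- as.integer(truth)
  np <- sum(truth == 1L); nn <- sum(truth == 0L)
  if (np == 0L || nn == 0L)
    return(list(points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                auc = NA_real_))
  thr <- sort(unique(probabilities), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(probabilities >= t & truth == 1L) / np,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(probabilities >= t & truth == 0L) / nn,
                numeric(1))
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Evaluation report for a set of interaction calls
#'
#' Computes the confusion matrix, accuracy, precision, recall, F1 and the
#' ROC/AUC from the probability sweep. The confusion-matrix identities
#' (counts sum to n, accuracy = (TP+TN)/n, F1 = harmonic mean of precision
#' and recall) are asserted on every report. Precision/recall/F1 are 0 when
#' undefined (empty denominator).
#'
#' @param calls 0/1 predicted labels.
#' @param probabilities numeric scores aligned to `calls`.
#' @param truth 0/1 reference labels.
#' @return object of class `ppi_eval`.
#' @export
evaluate_predictions <- function(calls, probabilities, truth) {
  if (length(calls) != length(truth) ||
      length(probabilities) != length(truth))
    stop("calls, probabilities and truth must have equal length (",
         length(calls), ", ", length(probabilities), ", ", length(truth), ")")
  calls <- as.integer(calls); truth <- as.integer(truth)
  tp <- sum(calls == 1L & truth == 1L)
  fp <- sum(calls == 1L & truth == 0L)
  fn <- sum(calls == 0L & truth == 1L)
  tn <- sum(calls == 0L & truth == 0L)
  n <- length(truth)
  accuracy <- if (n > 0) (tp + tn) / n else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  roc <- roc_curve(probabilities, truth)
  rep <- structure(list(
    accuracy = accuracy, precision = precision, recall = recall, f1 = f1,
    confusion = matrix(c(tp, fp, fn, tn), nrow = 2L,
                       dimnames = list(truth = c("pos", "neg"),
                                       call = c("pos", "neg"))),
    roc_points = roc$points, auc = roc$auc, n = n), class = "ppi_eval")
  stopifnot(sum(rep$confusion) == n,
            n == 0 || isTRUE(all.equal(rep$accuracy, (tp + tn) / n)))
  rep
}

#' @export
print.ppi_eval <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f  AUC %s  (n=%d)\n",
    x$accuracy, x$precision, x$recall, x$f1,
    if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc), x$n))
  cat("confusion matrix (rows = truth, cols = call):\n")
  print(x$confusion)
  invisible(x)
}

# ---- the meta-classifier ------------------------------------------------

stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Train the boosted meta-classifier on an evidence feature matrix
#'
#' The meta level of the stacked scheme: the six base-level evidence scores
#' are scaled to unit variance, stratified 10-fold cross-validation is run
#' to estimate out-of-sample performance, and a final AdaBoost ensemble
#' (discrete boosting over depth-1 decision stumps) is refit on all rows.
#' The whole procedure is deterministic given `seed`.
#'
#' @param features a `feature_matrix` with labels, or a plain numeric
#'   matrix combined with `labels`.
#' @param labels 0/1 vector when `features` is a plain matrix.
#' @param n_rounds boosting rounds (default 100).
#' @param n_folds cross-validation folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @return object of class `ppi_model` with the scale statistics, the
#'   fitted ensemble, the feature column order, the seed, the aggregated
#'   CV report (`$report`, with `$report$folds` per fold) and the
#'   training-set predictions (`$training`).
#' @export
ppi_train <- function(features, labels = NULL, n_rounds = 100L,
                      n_folds = 10L, seed = 1L) {
  if (inherits(features, "feature_matrix")) {
    x <- features$x
    labels <- features$labels
  } else x <- as.matrix(features)
  if (is.null(labels)) stop("training requires 0/1 labels")
  labels <- as.integer(labels)
  if (nrow(x) < 20L)
    stop("training requires at least 20 labeled pairs, got ", nrow(x))
  if (length(unique(labels)) < 2L)
    stop("training requires both classes; labels contain only ",
         unique(labels))
  norm <- normalize_unit_variance(x)
  y <- ifelse(labels == 1L, 1, -1)
  folds <- stratified_folds(labels, n_folds, seed)
  prob <- numeric(nrow(x))
  fold_reports <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    ens <- adaboost_fit(norm$x[tr, , drop = FALSE], y[tr], n_rounds)
    pf <- (adaboost_margin(ens, norm$x[te, , drop = FALSE]) + 1) / 2
    prob[te] <- pf
    fold_reports[[f]] <- evaluate_predictions(as.integer(pf >= 0.5), pf,
                                              labels[te])
  }
  report <- evaluate_predictions(as.integer(prob >= 0.5), prob, labels)
  report$folds <- fold_reports
  ensemble <- adaboost_fit(norm$x, y, n_rounds)
  tr_prob <- (adaboost_margin(ensemble, norm$x) + 1) / 2
  structure(list(scale = norm$scale, ensemble = ensemble,
                 columns = colnames(x), n_rounds = as.integer(n_rounds),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 report = report,
                 training = data.frame(probability = tr_prob,
                                       call = as.integer(tr_prob >= 0.5))),
            class = "ppi_model")
}

#' @export
print.ppi_model <- function(x, ...) {
  cat(sprintf(
    "<ppi_model: AdaBoost, %d stumps over %d features, seed %d>\n",
    length(x$ensemble$stumps), length(x$columns), x$seed))
  if (!is.null(x$report))
    cat(sprintf("%d-fold CV: accuracy %.4f, F1 %.4f, AUC %.4f\n",
                x$n_folds, x$report$accuracy, x$report$f1, x$report$auc))
  invisible(x)
}

#' @export
summary.ppi_model <- function(object, ...) {
  print(object)
  cat("\nfeature importance (total |alpha| per feature):\n")
  print(round(coef(object), 4))
  cat("\npooled cross-validation report:\n")
  print(object$report)
  invisible(object)
}

#' Feature importance of a trained meta-classifier
#'
#' Total boosting weight (sum of alpha) accumulated by stumps splitting on
#' each feature, normalized to sum to 1.
#' @param object a `ppi_model`.
#' @param ... unused.
#' @export
coef.ppi_model <- function(object, ...) {
  imp <- setNames(numeric(length(object$columns)), object$columns)
  for (m in seq_along(object$ensemble$stumps)) {
    j <- object$ensemble$stumps[[m]]$feature
    imp[j] <- imp[j] + object$ensemble$alphas[[m]]
  }
  imp / sum(imp)
}

#' Predict interaction calls for new pairs
#'
#' The new matrix is scaled with the model's stored statistics (never
#' refit) and pushed through the boosted ensemble. Columns must match the
#' model's recorded feature order; a mismatch is rejected naming the
#' discrepancy. An empty matrix yields empty outputs.
#'
#' @param object a `ppi_model`.
#' @param newdata a `feature_matrix` or numeric matrix with the model's
#'   columns.
#' @param threshold probability cut for a positive call (default 0.5).
#' @param ... unused.
#' @return data.frame with `pair` (if available), `probability` and `call`;
#'   the attribute `"positives"` lists positively predicted pair keys in
#'   input row order.
#' @export
predict.ppi_model <- function(object, newdata, threshold = 0.5, ...) {
  if (inherits(newdata, "feature_matrix")) {
    x <- newdata$x
    keys <- newdata$pairs
  } else {
    x <- as.matrix(newdata)
    keys <- rownames(x) %||% rep(NA_character_, nrow(x))
  }
  if (!identical(colnames(x), object$columns))
    stop("feature columns (", paste(colnames(x), collapse = ","),
         ") do not match the model's recorded order (",
         paste(object$columns, collapse = ","), ")")
  scaled <- normalize_unit_variance(x, scale = object$scale)$x
  prob <- (adaboost_margin(object$ensemble, scaled) + 1) / 2
  call <- as.integer(prob >= threshold)
  out <- data.frame(pair = keys[seq_along(prob)], probability = prob,
                    call = call, stringsAsFactors = FALSE)
  attr(out, "positives") <- out$pair[out$call == 1L]
  out
}

#' Plot the cross-validation ROC curve of a trained model
#' @param x a `ppi_model`.
#' @param ... passed to [plot()].
#' @export
plot.ppi_model <- function(x, ...) {
  pts <- x$report$roc_points
  plot(pts$fpr, pts$tpr, type = "l", xlab = "false positive rate",
       ylab = "true positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$report$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

# ---- persistence --------------------------------------------------------

#' Save / load a trained model archive
#'
#' The archive is a single JSON file holding the scale statistics, the
#' ensemble parameters (stump feature/threshold/polarity and alphas), the
#' feature column order, the seed and a format-version field.
#'
#' @param model a `ppi_model`.
#' @param path file path.
#' @export
save_ppi_model <- function(model, path) {
  obj <- list(format_version = 1L,
              scale = as.list(model$scale),
              columns = model$columns,
              n_rounds = model$n_rounds, n_folds = model$n_folds,
              seed = model$seed,
              alphas = model$ensemble$alphas,
              stumps = model$ensemble$stumps)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_ppi_model
#' @param path file written by [save_ppi_model()].
#' @export
load_ppi_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop(path, ": unsupported model format version")
  stumps <- lapply(obj$stumps, function(s)
    list(feature = as.integer(s$feature), threshold = as.numeric(s$threshold),
         polarity = as.numeric(s$polarity)))
  structure(list(scale = unlist(obj$scale), columns = obj$columns,
                 ensemble = list(stumps = stumps,
                                 alphas = as.numeric(obj$alphas)),
                 n_rounds = as.integer(obj$n_rounds),
                 n_folds = as.integer(obj$n_folds),
                 seed = as.integer(obj$seed), report = NULL,
                 training = NULL),
            class = "ppi_model")
}
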