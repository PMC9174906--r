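# k-fold cross-validated comparison of preprocessing x feature x algorithm
# pipelines. The protocol: split all windows into k equal stratified folds;
# train on k-1, predict the held-out fold; every window is predicted exactly
# once; per-fold confusion matrices are summed into a total confusion matrix
# from which accuracy, precision, recall and F1 are computed one-vs-rest.

#' Stratified fold assignment
#'
#' Assigns every window to exactly one of \code{k} folds, stratified by
#' label so each fold holds a near-equal share of each class. Seeded and
#' reusable across pipelines for paired comparisons.
#'
#' @param labels factor of window labels.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return Integer vector in \code{1..k}, one entry per window.
#' @export
make_folds <- function(labels, k = 5, seed = 1L) {
  labels <- as.factor(labels)
  if (min(table(droplevels(labels))) < k)
    stop(sprintf("need at least %d windows per class for %d-fold CV", k, k),
         call. = FALSE)
  with_seed(seed, {
    idx_list <- caret::createFolds(labels, k = k)
    folds <- integer(length(labels))
    for (i in seq_along(idx_list)) folds[idx_list[[i]]] <- i
    folds
  })
}

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest precision \eqn{TP/(TP+FP)}, recall \eqn{TP/(TP+FN)} and
#' \eqn{F1 = 2PR/(P+R)} per class, plus overall accuracy
#' \eqn{trace/total}. Rows are truth, columns prediction. Divisions by zero
#' (a class never predicted and/or never present) return 0 by convention,
#' with a note attached.
#'
#' @param confusion square nonnegative count matrix, rows = truth.
#' @return List with \code{accuracy}, \code{per_class} (data.frame of
#'   precision/recall/f1 and TP/FP/FN counts), and \code{notes}.
#' @export
compute_metrics <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m) || any(m < 0) || any(!is.finite(m)))
    stop("confusion must be a square nonnegative matrix", call. = FALSE)
  classes <- rownames(m)
  if (is.null(classes)) classes <- paste0("class_", seq_len(nrow(m)))
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  div0 <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- div0(tp, tp + fp)
  recall <- div0(tp, tp + fn)
  f1 <- div0(2 * precision * recall, precision + recall)
  notes <- character(0)
  if (any(tp + fp == 0) || any(tp + fn == 0))
    notes <- sprintf(
      "class(es) %s had no predictions and/or no true instances; metrics set to 0",
      paste(classes[tp + fp == 0 | tp + fn == 0], collapse = ", "))
  list(accuracy = if (sum(m) > 0) sum(tp) / sum(m) else 0,
       per_class = data.frame(class = classes, tp = tp, fp = fp, fn = fn,
                              precision = precision, recall = recall,
                              f1 = f1, row.names = NULL),
       notes = notes)
}

#' Cross-validate one pipeline
#'
#' Runs the full protocol for one (preprocessing, feature scheme, algorithm)
#' pipeline over a fixed set of windows: per-window preprocessing (FOD/LS)
#' and feature extraction, stratified k-fold assignment, training on k-1
#' folds and predicting the held-out fold, so every window is predicted
#' exactly once. Per-fold confusion matrices are summed into the total
#' confusion matrix. For the HPF pipeline, pass windows segmented from a
#' series already filtered with \code{\link{preprocess_series}}.
#'
#' @param windows list of \code{\link{window_sample}} objects.
#' @param preprocessing \code{"none"}, \code{"fod"}, \code{"ls"},
#'   \code{"hpf"}.
#' @param scheme \code{"fdf"} or \code{"tdsf"}.
#' @param algorithm \code{"xgb"}, \code{"knn"}, \code{"svm"}, \code{"dt"},
#'   or a \code{\link{classifier_config}}.
#' @param k number of folds (default 5).
#' @param seed integer seed (fold assignment and learners).
#' @param folds optional precomputed fold vector (for paired comparisons
#'   across pipelines); overrides \code{k}/\code{seed}-based assignment.
#' @return An object of class \code{eval_report}.
#' @export
cross_validate <- function(windows, preprocessing = "ls", scheme = "fdf",
                           algorithm = "xgb", k = 5, seed = 1L,
                           folds = NULL) {
  fm <- window_feature_matrix(windows, preprocessing, scheme)
  labels <- fm$labels
  if (is.null(folds)) folds <- make_folds(labels, k = k, seed = seed)
  if (length(folds) != length(windows))
    stop("folds must assign every window", call. = FALSE)
  k <- max(folds)
  config <- if (inherits(algorithm, "classifier_config")) algorithm
            else classifier_config(algorithm)

  lv <- levels(labels)
  total <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  per_fold_acc <- numeric(k)
  predicted <- factor(rep(NA_character_, length(labels)), levels = lv)
  for (i in seq_len(k)) {
    test <- folds == i
    model <- behavior_classifier(fm$x[!test, , drop = FALSE], labels[!test],
                                 config = config, seed = seed + i)
    pred <- predict(model, fm$x[test, , drop = FALSE], type = "class")
    pred <- factor(as.character(pred), levels = lv)
    predicted[test] <- pred
    cm <- table(truth = labels[test], prediction = pred)
    total <- total + as.matrix(cm)
    per_fold_acc[i] <- sum(diag(as.matrix(cm))) / sum(cm)
  }
  metrics <- compute_metrics(total)
  structure(
    list(pipeline = list(preprocessing = toupper(preprocessing),
                         scheme = toupper(scheme),
                         algorithm = toupper(config$algorithm),
                         window_seconds =
                           length(windows[[1]]$values) /
                             windows[[1]]$sampling_rate,
                         k = k, seed = seed),
         per_fold_accuracy = per_fold_acc,
         accuracy_mean = mean(per_fold_acc),
         accuracy_sd = stats::sd(per_fold_acc),
         overall_accuracy = metrics$accuracy,
         total_confusion = total,
         per_class = metrics$per_class,
         notes = metrics$notes,
         folds = folds,
         predicted = predicted,
         truth = labels),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  p <- x$pipeline
  cat(sprintf("<eval_report> %s + %s + %s, %g s windows, %d-fold CV\n",
              p$preprocessing, p$scheme, p$algorithm, p$window_seconds, p$k))
  cat(sprintf("  accuracy: %.3f +/- %.3f (folds: %s)\n",
              x$accuracy_mean, x$accuracy_sd,
              paste(sprintf("%.3f", x$per_fold_accuracy), collapse = " ")))
  invisible(x)
}

#' @export
summary.eval_report <- function(object, ...) {
  print(object)
  cat("  total confusion (rows = truth):\n")
  print(object$total_confusion)
  cat("  per-class metrics:\n")
  print(object$per_class, digits = 3)
  invisible(object)
}

#' Compare pipelines over preprocessing, feature scheme, and algorithm
#'
#' Evaluates every (preprocessing, scheme, algorithm) cell with the same
#' stratified fold assignment (a paired comparison: every cell sees
#' identical test sets). HPF cells use windows segmented from the
#' high-pass-filtered series; all other cells use the raw segmentation.
#' Segmentation is identical in count and position either way, so fold
#' sharing is well defined.
#'
#' @param series_list list of labeled \code{\link{pressure_series}}.
#' @param window_seconds window duration, seconds (default 10).
#' @param preprocessing_methods character vector of methods.
#' @param schemes character vector of feature schemes.
#' @param algorithms character vector of algorithms.
#' @param k folds (default 5).
#' @param seed integer seed.
#' @return An object of class \code{comparison_table}: list with
#'   \code{reports} (named list of \code{eval_report}), \code{summary}
#'   (data.frame, rows = preprocessing + scheme, columns = algorithms,
#'   entries "mean +/- sd"), and \code{accuracy} (numeric version).
#' @export
run_comparison <- function(series_list, window_seconds = 10,
                           preprocessing_methods = c("none", "fod", "ls", "hpf"),
                           schemes = c("fdf", "tdsf"),
                           algorithms = c("knn", "svm", "dt", "xgb"),
                           k = 5, seed = 1L) {
  raw_windows <- segment_windows_multi(series_list, window_seconds)
  if (length(raw_windows) == 0L)
    stop("no pure windows at this window size", call. = FALSE)
  hpf_windows <- if ("hpf" %in% tolower(preprocessing_methods)) {
    segment_windows_multi(lapply(series_list, preprocess_series, method = "hpf"),
                          window_seconds)
  } else NULL
  labels <- vapply(raw_windows, function(w) as.character(w$label), character(1))
  folds <- make_folds(factor(labels, levels = behavior_labels()), k, seed)

  reports <- list()
  for (m in tolower(preprocessing_methods)) {
    wins <- if (m == "hpf") hpf_windows else raw_windows
    for (s in tolower(schemes)) {
      for (a in tolower(algorithms)) {
        id <- paste(m, s, a, sep = "_")
        reports[[id]] <- cross_validate(wins, m, s, a, k = k, seed = seed,
                                        folds = folds)
      }
    }
  }
  row_ids <- as.vector(t(outer(tolower(preprocessing_methods),
                               tolower(schemes), paste, sep = "_")))
  fmt <- function(r) sprintf("%.3f ± %.3f", r$accuracy_mean, r$accuracy_sd)
  summary_df <- data.frame(pipeline = toupper(row_ids))
  acc <- matrix(NA_real_, length(row_ids), length(algorithms),
                dimnames = list(toupper(row_ids), toupper(algorithms)))
  for (a in tolower(algorithms)) {
    summary_df[[toupper(a)]] <- vapply(row_ids, function(rid) {
      fmt(reports[[paste(rid, a, sep = "_")]])
    }, character(1))
    acc[, toupper(a)] <- vapply(row_ids, function(rid) {
      reports[[paste(rid, a, sep = "_")]]$accuracy_mean
    }, numeric(1))
  }
  structure(list(reports = reports, summary = summary_df, accuracy = acc,
                 folds = folds),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("<comparison_table> 5-fold CV accuracy (mean ± sd)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Window-size sweep
#'
#' Evaluates one pipeline at several window durations, reporting CV accuracy
#' and wall-clock execution time normalized per 1000 windows (feature
#' extraction + cross-validation). Timing is hardware-dependent and reported
#' for information only.
#'
#' @param series_list list of labeled \code{\link{pressure_series}}.
#' @param sizes window durations in seconds (default \code{c(5, 10, 15, 20, 30)}).
#' @param preprocessing,scheme,algorithm the pipeline to evaluate.
#' @param k folds.
#' @param seed integer seed.
#' @return data.frame with one row per size: \code{window_seconds},
#'   \code{n_windows}, \code{accuracy_mean}, \code{accuracy_sd},
#'   \code{time_per_1k_samples_s}.
#' @export
window_size_sweep <- function(series_list, sizes = c(5, 10, 15, 20, 30),
                              preprocessing = "ls", scheme = "fdf",
                              algorithm = "xgb", k = 5, seed = 1L) {
  src <- if (tolower(preprocessing) == "hpf")
    lapply(series_list, preprocess_series, method = "hpf") else series_list
  rows <- lapply(sizes, function(ws) {
    windows <- segment_windows_multi(src, ws)
    t0 <- proc.time()[["elapsed"]]
    rep <- cross_validate(windows, preprocessing, scheme, algorithm,
                          k = k, seed = seed)
    elapsed <- proc.time()[["elapsed"]] - t0
    data.frame(window_seconds = ws, n_windows = length(windows),
               accuracy_mean = rep$accuracy_mean,
               accuracy_sd = rep$accuracy_sd,
               time_per_1k_samples_s = 1000 * elapsed / length(windows))
  })
  do.call(rbind, rows)
}
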