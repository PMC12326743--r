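# Episode-level and aggregate evaluation: pooled confusion matrices,
# macro-averaged precision/recall/F1, ROC-AUC, and the 2-way 8-shot episodic
# test harness.

#' Round half away from zero
#'
#' Reporting convention for printed metrics (R's `round` rounds half to
#' even, which would turn 0.8525 into 0.852 instead of 0.853).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a confusion matrix from pooled predictions
#'
#' @param true_labels,predicted_labels Equal-length vectors of class ids.
#' @param labels Ordered class ids covering all observed values (rows =
#'   true class, columns = predicted class).
#' @return An object of class `confusion_matrix` wrapping the integer count
#'   matrix.
#' @export
confusion_from_predictions <- function(true_labels, predicted_labels,
                                       labels = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("true and predicted label vectors must have equal length")
  }
  if (is.null(labels)) labels <- sort(unique(c(true_labels, predicted_labels)))
  if (!all(true_labels %in% labels) || !all(predicted_labels %in% labels)) {
    stop("label outside the provided label set")
  }
  counts <- table(factor(true_labels, levels = labels),
                  factor(predicted_labels, levels = labels))
  counts <- matrix(as.integer(counts), length(labels), length(labels),
                   dimnames = list(true = as.character(labels),
                                   predicted = as.character(labels)))
  structure(list(labels = labels, counts = counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (rows = true, cols = predicted)\n")
  print(x$counts)
  invisible(x)
}

#' Macro-averaged metrics from a confusion matrix
#'
#' Accuracy is `trace / total`. Per class `k` (one-vs-rest):
#' precision `TP_k / (TP_k + FP_k)` (defined as 0, with a warning, when the
#' class is never predicted), recall `TP_k / (TP_k + FN_k)`, F1 their
#' harmonic mean. The macro values are unweighted means across classes --
#' the averaging convention consistent with the reported reference tables.
#'
#' @param cm A [confusion_from_predictions()] result, or a square count
#'   matrix.
#' @return An object of class `metrics_report` with fields `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1`, `per_class` (data
#'   frame), `n` (total queries); `auc` unset.
#' @export
macro_metrics_from_counts <- function(cm) {
  counts <- if (inherits(cm, "confusion_matrix")) cm$counts else as.matrix(cm)
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square")
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix")
  labels <- rownames(counts)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(counts)) - 1L)
  tp <- diag(counts)
  fp <- colSums(counts) - tp
  fn <- rowSums(counts) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  if (any(tp + fp == 0)) {
    warning("class never predicted; its precision is reported as 0")
  }
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(
    list(accuracy = sum(tp) / total,
         macro_precision = mean(prec), macro_recall = mean(rec),
         macro_f1 = mean(f1), auc = NULL,
         per_class = data.frame(class = labels, tp = tp, fp = fp, fn = fn,
                                precision = prec, recall = rec, f1 = f1,
                                row.names = NULL),
         n = total, n_tasks = NA_integer_),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d%s\n", x$n,
              if (!is.na(x$n_tasks)) sprintf(" tasks=%d", x$n_tasks) else ""))
  cat(sprintf("  accuracy: %.1f%%  macro precision: %.3f  recall: %.3f  F1: %.3f\n",
              round_half_away(100 * x$accuracy, 1),
              round_half_away(x$macro_precision, 3),
              round_half_away(x$macro_recall, 3),
              round_half_away(x$macro_f1, 3)))
  if (!is.null(x$auc)) cat(sprintf("  AUC: %.3f\n", round_half_away(x$auc, 3)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midranks for tied scores: the
#' probability that a random positive is scored above a random negative,
#' counting ties as one half.
#'
#' @param scores Positive-class scores or probabilities.
#' @param labels Binary true labels (0/1 or logical; 1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels must align")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores) # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a checkpoint with episodic test tasks
#'
#' Samples `n_tasks` n-way k-shot episodes from the held-out-class index,
#' classifies the queries with the checkpoint's backbone (evaluation mode,
#' deterministic), pools all predictions -- mapped back to global class
#' ids -- into one confusion matrix, and derives the macro metrics. For
#' 2-way tasks the ROC-AUC is computed over the pooled query probabilities
#' of the positive class, taken as the larger global class id.
#'
#' @param checkpoint A `checkpoint` (or a bare backbone).
#' @param test_index Dataset index holding only the held-out classes.
#' @param n_tasks Number of episodes (default 100).
#' @param n_way,k_shot,n_query Episode geometry (default 2-way 8-shot,
#'   10 queries per class).
#' @param rng An [rng_stream()].
#' @param cfg Optional [train_config()] supplying preprocessing settings
#'   (`target_depth`, `augment$out_size`); defaults match [train_config()].
#' @return A `metrics_report` whose `confusion` field holds the pooled
#'   [confusion_from_predictions()] matrix.
#' @export
evaluate_model <- function(checkpoint, test_index, n_tasks = 100L,
                           n_way = 2L, k_shot = 8L, n_query = 10L,
                           rng = rng_stream(0L), cfg = NULL) {
  net <- if (inherits(checkpoint, "checkpoint")) checkpoint$net else checkpoint
  if (is.null(cfg)) cfg <- train_config()
  emb_cache <- new.env(parent = emptyenv())
  true_all <- integer(0)
  pred_all <- integer(0)
  pos_scores <- numeric(0)
  pos_truth <- integer(0)
  for (t in seq_len(n_tasks)) {
    ep <- sample_episode(test_index, n_way, k_shot, n_query, rng)
    ids <- c(ep$support_ids, ep$query_ids)
    emb <- embed_with_cache(net, test_index, ids, cfg, emb_cache)
    ns <- length(ep$support_ids)
    protos <- compute_prototypes(emb[seq_len(ns), , drop = FALSE],
                                 ep$support_labels)
    cls <- classify_queries(protos, emb[-seq_len(ns), , drop = FALSE])
    true_all <- c(true_all, ep$class_map[ep$query_labels + 1L])
    pred_all <- c(pred_all, ep$class_map[cls$pred + 1L])
    if (ep$n_way == 2L) {
      # positive class = larger global id; class_map is ascending
      pos_scores <- c(pos_scores, cls$probs[, 2])
      pos_truth <- c(pos_truth, as.integer(ep$query_labels == 1L))
    }
  }
  cmat <- confusion_from_predictions(true_all, pred_all,
                                     labels = index_classes(test_index))
  rep <- macro_metrics_from_counts(cmat)
  rep$n_tasks <- as.integer(n_tasks)
  rep$confusion <- cmat
  if (length(pos_scores) > 0 && length(unique(pos_truth)) == 2) {
    rep$auc <- roc_auc(pos_scores, pos_truth)
  }
  rep
}

#' Write a metrics report to JSON and CSV
#'
#' Writes `metrics.json` (scalar metrics, both raw and at the printed
#' rounding), `per_class.csv` and, when present, `confusion.csv` into
#' `dir`.
#'
#' @param report A `metrics_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_metrics <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scalars <- list(
    accuracy = report$accuracy,
    accuracy_percent = round_half_away(100 * report$accuracy, 1),
    macro_precision = report$macro_precision,
    macro_recall = report$macro_recall,
    macro_f1 = report$macro_f1,
    auc = report$auc,
    n = report$n, n_tasks = report$n_tasks
  )
  jsonlite::write_json(scalars[!vapply(scalars, is.null, logical(1))],
                       file.path(dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(report$per_class, file.path(dir, "per_class.csv"),
                   row.names = FALSE)
  if (!is.null(report$confusion)) {
    utils::write.csv(as.data.frame(report$confusion$counts),
                     file.path(dir, "confusion.csv"))
  }
  invisible(dir)
}
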