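#' Train the one-classifier-per-sensor ensemble pool
#'
#' Trains one ELM per sensor source on that sensor's feature rows only.
#' Member k of the pool corresponds to bit k of every subset mask. Member
#' seeds are derived deterministically from the master seed, so two pools
#' built from the same data and master seed predict identically, while
#' different members see different random input layers (diversity by
#' randomness).
#'
#' @param features a normalized `feature_table` of training rows.
#' @param hidden,activation ELM configuration shared by all members.
#' @param seed master RNG seed.
#' @return an object of class `ensemble_pool`: list with `sensor_ids`
#'   (mask order), `models` (one `elm` per sensor), `class_labels`.
#' @export
train_pool <- function(features, hidden = 50, activation = "sigmoid", seed = 1) {
  sensors <- sort(unique(features$sensor))
  models <- vector("list", length(sensors))
  classes <- sort(unique(as.character(features$activity)))
  for (k in seq_along(sensors)) {
    rows <- features[features$sensor == sensors[k], ]
    if (length(unique(rows$activity)) < 2L)
      stop_glowsel("sensor %s has training data for a single class", sensors[k])
    models[[k]] <- train_elm(rows[feature_names], rows$activity,
                             hidden = hidden, activation = activation,
                             seed = derive_seed(seed, k))
  }
  structure(list(sensor_ids = sensors, models = models,
                 class_labels = classes, hidden = hidden,
                 activation = activation, seed = as.integer(seed)),
            class = "ensemble_pool")
}

#' Per-member predictions of a pool on a feature table
#'
#' @param pool an `ensemble_pool`.
#' @param features feature rows; member k predicts the rows of its own
#'   sensor, aligned across members by (subject, activity, window).
#' @return list with `predictions` (members x samples character matrix),
#'   `truth` (length-samples label vector), `class_labels`.
#' @export
pool_predictions <- function(pool, features) {
  ref <- features[features$sensor == pool$sensor_ids[1L], ]
  ref <- ref[order(ref$subject, ref$activity, ref$window), ]
  n <- nrow(ref)
  P <- matrix(NA_character_, nrow = length(pool$sensor_ids), ncol = n)
  for (k in seq_along(pool$sensor_ids)) {
    rows <- features[features$sensor == pool$sensor_ids[k], ]
    rows <- rows[order(rows$subject, rows$activity, rows$window), ]
    if (nrow(rows) != n)
      stop_glowsel("sensor %s has %d windows but sensor %s has %d: unbalanced table",
                   pool$sensor_ids[k], nrow(rows), pool$sensor_ids[1L], n)
    P[k, ] <- predict(pool$models[[k]], rows[feature_names])
  }
  list(predictions = P, truth = as.character(ref$activity),
       class_labels = pool$class_labels)
}

#' Fuse member predictions by majority vote
#'
#' For every sample the most frequent label among the members selected by
#' the mask wins; ties are broken toward the smallest label in class order,
#' which keeps fusion deterministic and seed-free.
#'
#' @param predictions members x samples character matrix of member labels.
#' @param mask binary vector (length = members) selecting the voting
#'   members; must have at least one bit set.
#' @param class_order ordered class labels used for tie-breaking (defaults
#'   to the sorted labels present).
#' @return character vector of fused labels.
#' @export
majority_vote <- function(predictions, mask = rep(1L, nrow(predictions)),
                          class_order = NULL) {
  mask <- as.integer(mask)
  if (length(mask) != nrow(predictions))
    stop_glowsel("mask length %d does not match %d members",
                 length(mask), nrow(predictions))
  sel <- which(mask == 1L)
  if (!length(sel)) stop_glowsel("empty mask: at least one member must vote (0 < m <= M)")
  if (is.null(class_order))
    class_order <- sort(unique(as.character(predictions[sel, , drop = FALSE])))
  counts <- vote_counts(predictions, sel, class_order)
  class_order[max.col(t(counts), ties.method = "first")]
}

# classes x samples vote count matrix for the selected members
vote_counts <- function(predictions, sel, class_order) {
  sub <- predictions[sel, , drop = FALSE]
  out <- matrix(0L, nrow = length(class_order), ncol = ncol(predictions))
  for (c in seq_along(class_order)) {
    out[c, ] <- colSums(sub == class_order[c])
  }
  out
}

#' Classification metrics from true and predicted labels
#'
#' Accuracy is the share of correctly classified samples (the trace of the
#' confusion matrix over its total, which for two classes reduces to
#' (TP + TN) / (TP + TN + FP + FN)). Precision, recall and F1 are computed
#' one-vs-rest per class as TP/(TP+FP), TP/(TP+FN) and their harmonic mean;
#' rates with a zero denominator are defined as 0. The single reported F1
#' is the macro average by default (micro also returned).
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param class_order ordered class labels (defaults to sorted union).
#' @return object of class `har_metrics`: list with `accuracy`, `confusion`
#'   (rows = true, columns = predicted), `per_class` data frame (tp, tn, fp,
#'   fn, precision, recall, f1), `macro_f1`, `micro_f1`, `macro_precision`,
#'   `macro_recall`.
#' @export
compute_metrics <- function(y_true, y_pred, class_order = NULL) {
  if (length(y_true) == 0L) stop_glowsel("empty label vectors")
  if (length(y_true) != length(y_pred))
    stop_glowsel("y_true and y_pred differ in length")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(class_order)) class_order <- sort(unique(c(y_true, y_pred)))
  ft <- factor(y_true, levels = class_order)
  fp_ <- factor(y_pred, levels = class_order)
  confusion <- table(true = ft, predicted = fp_)
  total <- sum(confusion)
  acc <- sum(diag(confusion)) / total

  per <- lapply(class_order, function(cl) {
    tp <- confusion[cl, cl]
    fp <- sum(confusion[, cl]) - tp
    fn <- sum(confusion[cl, ]) - tp
    tn <- total - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, tp = tp, tn = tn, fp = fp, fn = fn,
               precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  tp_all <- sum(per$tp); fp_all <- sum(per$fp); fn_all <- sum(per$fn)
  micro_p <- if (tp_all + fp_all > 0) tp_all / (tp_all + fp_all) else 0
  micro_r <- if (tp_all + fn_all > 0) tp_all / (tp_all + fn_all) else 0
  micro_f1 <- if (micro_p + micro_r > 0) 2 * micro_p * micro_r / (micro_p + micro_r) else 0

  structure(list(accuracy = acc,
                 confusion = unclass(confusion),
                 per_class = per,
                 macro_precision = mean(per$precision),
                 macro_recall = mean(per$recall),
                 macro_f1 = mean(per$f1),
                 micro_f1 = micro_f1),
            class = "har_metrics")
}

#' @export
print.har_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro-F1 %.4f | micro-F1 %.4f | %d classes\n",
              x$accuracy, x$macro_f1, x$micro_f1, nrow(x$per_class)))
  invisible(x)
}

#' Write a confusion matrix as labeled CSV (rows = true, columns = predicted)
#'
#' @param metrics a `har_metrics` object.
#' @param path file path.
#' @export
write_confusion_csv <- function(metrics, path) {
  m <- as.data.frame.matrix(metrics$confusion)
  write.csv(cbind(true = rownames(m), m), path, row.names = FALSE)
  invisible(path)
}
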