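#' Split a labeled dataset into train / validation / test sets
#'
#' An unstratified random permutation under the given seed, cut into the
#' requested fractions. Sizes are `floor(n * train)` and `floor(n * val)`,
#' with the rounding remainder going to the test (hold-out) split — so 1587
#' labeled articles at 70/15/15 give 1110/238/239.
#'
#' @param labeled A data frame (any columns) to split by row.
#' @param fractions Numeric length-3 vector `(train, val, test)` summing to
#'   1 (default `c(0.70, 0.15, 0.15)`).
#' @param seed Integer seed for the permutation.
#' @return A list of three disjoint, exhaustive data frames: `train`,
#'   `validation`, `test`.
#' @export
split_dataset <- function(labeled, fractions = c(0.70, 0.15, 0.15), seed = 1) {
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    config_error("`fractions` must be three non-negative numbers summing to 1.")
  }
  n <- nrow(labeled)
  if (n < 3) config_error("Need at least 3 items to split.")
  n_train <- floor(n * fractions[1])
  n_val <- floor(n * fractions[2])
  n_test <- n - n_train - n_val
  set.seed(seed)
  perm <- sample.int(n)
  list(
    train = labeled[perm[seq_len(n_train)], , drop = FALSE],
    validation = labeled[perm[n_train + seq_len(n_val)], , drop = FALSE],
    test = labeled[perm[n_train + n_val + seq_len(n_test)], , drop = FALSE]
  )
}

#' Confusion counts from gold and predicted labels
#'
#' An article describing a resource ("positive") that is classified positive
#' is a true positive; classified negative, a false negative. A negative
#' article classified negative is a true negative; classified positive, a
#' false positive.
#'
#' @param gold,predicted Character vectors of `"positive"`/`"negative"`
#'   labels of equal length.
#' @return A named list `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(gold, predicted) {
  stopifnot(length(gold) == length(predicted))
  ok <- c("positive", "negative")
  if (!all(gold %in% ok) || !all(predicted %in% ok)) {
    validation_error('Labels must be "positive" or "negative".')
  }
  list(
    TP = sum(gold == "positive" & predicted == "positive"),
    FP = sum(gold == "negative" & predicted == "positive"),
    TN = sum(gold == "negative" & predicted == "negative"),
    FN = sum(gold == "positive" & predicted == "negative")
  )
}

#' Precision, recall, and F1 from confusion counts
#'
#' Precision is the share of predicted positives that are truly positive,
#' `TP / (TP + FP)`; recall is the share of true positives recovered,
#' `TP / (TP + FN)`; F1 is their harmonic mean
#' `2 * P * R / (P + R)` (0 when both P and R are 0). A zero denominator
#' for precision or recall raises a classed error rather than silently
#' returning 0, because silent zeros corrupt model selection.
#'
#' @param counts A list with `TP`, `FP`, `TN`, `FN` (see
#'   [confusion_counts()]).
#' @return A list `precision`, `recall`, `f1`, each in `[0, 1]`.
#' @export
#' @examples
#' classification_metrics(list(TP = 8, FP = 2, TN = 0, FN = 8))
classification_metrics <- function(counts) {
  stopifnot(all(c("TP", "FP", "FN") %in% names(counts)))
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  if (any(c(tp, fp, fn) < 0)) validation_error("Counts must be non-negative.")
  if (tp + fp == 0) {
    abort("Precision is undefined: no predicted positives (TP + FP = 0).",
          class = "bioinventory_undefined_metric")
  }
  if (tp + fn == 0) {
    abort("Recall is undefined: no gold positives (TP + FN = 0).",
          class = "bioinventory_undefined_metric")
  }
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1)
}

#' Partial-match entity-level metrics for named-entity recognition
#'
#' A predicted entity counts as a partial match when it overlaps at least
#' one token of a gold entity of the same kind. Pairing is greedy
#' left-to-right over the predictions, and each gold entity can credit at
#' most one prediction. Precision is computed over predicted entities,
#' recall over gold entities, F1 as their harmonic mean.
#'
#' @param gold,predicted Tibbles of entities with columns `start`, `end`
#'   (inclusive token indices on the same tokenization) and `kind`.
#' @return A list `precision`, `recall`, `f1`.
#' @export
ner_partial_metrics <- function(gold, predicted) {
  for (d in list(gold, predicted)) {
    stopifnot(all(c("start", "end", "kind") %in% names(d)))
  }
  ng <- nrow(gold); np <- nrow(predicted)
  if (np == 0) {
    abort("Precision is undefined: no predicted entities.",
          class = "bioinventory_undefined_metric")
  }
  if (ng == 0) {
    abort("Recall is undefined: no gold entities.",
          class = "bioinventory_undefined_metric")
  }
  pred <- predicted[order(predicted$start, predicted$end), , drop = FALSE]
  gold_used <- rep(FALSE, ng)
  matched <- 0
  for (i in seq_len(np)) {
    overlap <- !gold_used &
      gold$kind == pred$kind[i] &
      gold$start <= pred$end[i] &
      gold$end >= pred$start[i]
    j <- which(overlap)[1]
    if (!is.na(j)) {
      gold_used[j] <- TRUE
      matched <- matched + 1
    }
  }
  p <- matched / np
  r <- matched / ng
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1)
}

#' Inter-annotator agreement
#'
#' The fraction of items on which two curators assigned the same label. The
#' two label sets must cover exactly the same item ids.
#'
#' @param labels_a,labels_b Tibbles with columns `id` and `label`.
#' @return A proportion in `[0, 1]`.
#' @export
agreement <- function(labels_a, labels_b) {
  for (d in list(labels_a, labels_b)) {
    stopifnot(all(c("id", "label") %in% names(d)))
  }
  if (!setequal(labels_a$id, labels_b$id) ||
      nrow(labels_a) != nrow(labels_b) ||
      anyDuplicated(labels_a$id) || anyDuplicated(labels_b$id)) {
    validation_error("Both label sets must cover exactly the same item ids.")
  }
  b <- labels_b$label[match(labels_a$id, labels_b$id)]
  mean(labels_a$label == b)
}

#' Select the best model from per-model validation metrics
#'
#' Model selection follows the task: precision for article classification
#' (to minimize false positives flowing into the inventory), F1 for
#' named-entity recognition. Ties are broken by list order, with a warning.
#'
#' @param metrics Named list of metric lists (each with `precision`,
#'   `recall`, `f1`), one per model, in preference order for tie-breaks.
#' @param task `"classification"` or `"ner"`.
#' @return The selected model's name.
#' @export
select_model <- function(metrics, task = c("classification", "ner")) {
  task <- match.arg(task)
  if (length(metrics) == 0) config_error("No models to select from.")
  if (is.null(names(metrics)) || any(!nzchar(names(metrics)))) {
    config_error("`metrics` must be a named list.")
  }
  key <- if (task == "classification") "precision" else "f1"
  vals <- purrr::map_dbl(metrics, key)
  best <- which.max(vals)
  if (sum(vals == vals[best]) > 1) {
    warn(paste0("Model-selection tie on ", key, " (",
                paste(names(vals)[vals == vals[best]], collapse = ", "),
                "); keeping the first listed: ", names(vals)[best], "."))
  }
  names(vals)[best]
}
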