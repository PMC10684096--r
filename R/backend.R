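#' Model backends for classification and named-entity tagging
#'
#' Prediction is pluggable: anything that can score a title+abstract string
#' and emit token-level BIO labels with probabilities can drive the pipeline.
#' A backend is a list with class `"model_backend"` holding two functions:
#'
#' * `classify(text)` returning `list(score = <probability>)` — probability
#'   that the article describes a biodata resource;
#' * `tag(text)` returning a tibble of token predictions with columns
#'   `token`, `word_index`, `label` (one of `B-COM`, `I-COM`, `B-FUL`,
#'   `I-FUL`, `O`) and `prob` in `[0, 1]`.
#'
#' Backends must be deterministic for a fixed state and input.
#'
#' @param classify,tag Functions as described above.
#' @return A `model_backend` object.
#' @export
model_backend <- function(classify, tag) {
  stopifnot(is.function(classify), is.function(tag))
  structure(list(classify = classify, tag = tag), class = "model_backend")
}

#' The five admissible BIO token labels
#'
#' `B-COM`/`I-COM` mark the start/continuation of a common (short) resource
#' name, `B-FUL`/`I-FUL` of a full (expanded) name, and `O` tokens outside
#' any name.
#' @export
BIO_LABELS <- c("B-COM", "I-COM", "B-FUL", "I-FUL", "O")

#' Default cue phrases for the rule backend classifier
#'
#' Phrases typical of database-announcement abstracts; an article containing
#' any of them (case-insensitively) is scored positive.
#' @export
default_cues <- function() {
  c(
    "freely available at http",
    "is available at http",
    "database is accessible",
    "web resource for",
    "repository of curated"
  )
}

#' A deterministic rule-based backend
#'
#' A transparent stand-in for a fine-tuned transformer, used to exercise the
#' full pipeline offline. Classification looks for cue phrases; tagging does
#' a longest-match dictionary lookup of known resource names over
#' whitespace tokens (trailing punctuation on a token is ignored when
#' matching) and emits the configured per-token probability for each matched
#' name.
#'
#' @param dictionary Tibble with columns `text` (the surface name), `kind`
#'   (`"common"` or `"full"`), and `prob` (per-token probability emitted for
#'   that name).
#' @param cues Character vector of cue phrases for classification.
#' @param positive_score,negative_score Scores returned for articles with /
#'   without a cue.
#' @param o_prob Probability emitted for `O` tokens.
#' @return A [model_backend()].
#' @export
rule_backend <- function(dictionary, cues = default_cues(),
                         positive_score = 0.99, negative_score = 0.01,
                         o_prob = 0.999) {
  stopifnot(all(c("text", "kind", "prob") %in% names(dictionary)))
  stopifnot(all(dictionary$kind %in% c("common", "full")))
  # pre-split dictionary entries into word vectors, longest first
  entries <- dictionary[order(-stringr::str_count(dictionary$text, "\\S+")), ]
  entry_words <- stringr::str_split(entries$text, "\\s+")

  classify <- function(text) {
    hit <- any(stringr::str_detect(
      stringr::str_to_lower(text),
      stringr::fixed(stringr::str_to_lower(cues))
    ))
    list(score = if (hit) positive_score else negative_score)
  }

  tag <- function(text) {
    tokens <- stringr::str_split(stringr::str_trim(text), "\\s+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    n <- length(tokens)
    if (n == 0) {
      return(tibble::tibble(token = character(), word_index = integer(),
                            label = character(), prob = double()))
    }
    bare <- stringr::str_remove(tokens, "[.,;:!?)\\]}]+$")
    labels <- rep("O", n)
    probs <- rep(o_prob, n)
    i <- 1
    while (i <= n) {
      matched <- FALSE
      for (e in seq_along(entry_words)) {
        w <- entry_words[[e]]
        len <- length(w)
        if (i + len - 1 <= n && labels[i] == "O" &&
            all(bare[i:(i + len - 1)] == w)) {
          kind_tag <- if (entries$kind[e] == "common") "COM" else "FUL"
          labels[i] <- paste0("B-", kind_tag)
          if (len > 1) labels[(i + 1):(i + len - 1)] <- paste0("I-", kind_tag)
          probs[i:(i + len - 1)] <- entries$prob[e]
          i <- i + len
          matched <- TRUE
          break
        }
      }
      if (!matched) i <- i + 1
    }
    tibble::tibble(token = tokens, word_index = seq_len(n) - 1L,
                   label = labels, prob = probs)
  }

  model_backend(classify, tag)
}

#' Classify one article as describing a biodata resource or not
#'
#' Feeds the prepared title+abstract string to the backend and thresholds
#' its probability score: positive iff `score >= threshold`.
#'
#' @param text Non-empty classification-input string (see [prepare_text()]).
#' @param backend A [model_backend()].
#' @param threshold Decision threshold on the backend score (default 0.5).
#' @return A list with `label` (`"positive"`/`"negative"`) and `score`.
#' @export
classify_article <- function(text, backend, threshold = 0.5) {
  stopifnot(inherits(backend, "model_backend"))
  if (!is.character(text) || length(text) != 1 || !nzchar(text)) {
    validation_error("`text` must be a single non-empty string.")
  }
  res <- tryCatch(backend$classify(text), error = function(e) {
    abort(paste0("Backend classification failed: ", conditionMessage(e)),
          class = "bioinventory_inference_error")
  })
  score <- res$score
  if (!is_scalar_prob(score)) {
    abort("Backend returned a score outside [0, 1].",
          class = "bioinventory_inference_error")
  }
  list(label = if (score >= threshold) "positive" else "negative", score = score)
}

#' Fine-tuning harness with checkpoint selection
#'
#' Runs a pluggable trainer for up to `max_epochs` epochs, records per-epoch
#' validation metrics, and keeps the checkpoint that maximizes precision
#' (classification task) or F1 (named-entity task); the earliest epoch wins
#' ties. The selected backend is serialized to `checkpoint_path` so it can
#' be reloaded for prediction.
#'
#' The trainer is `function(epoch, state)` returning
#' `list(backend = <model_backend>, metrics = list(precision, recall, f1),
#' state = <opaque carry-over>)`. Trainers that wrap a real model fit one
#' epoch per call; trainers used in tests may simply replay a metric
#' history.
#'
#' @param trainer Trainer function (see Details).
#' @param task `"classification"` (select on precision) or `"ner"` (select
#'   on F1).
#' @param max_epochs Upper bound on epochs (default 10).
#' @param seed Integer seed set before the epoch loop for determinism.
#' @param checkpoint_path Where to serialize the selected backend
#'   (default: a tempfile).
#' @return A list with `backend`, `best_epoch`, `history` (tibble of
#'   per-epoch metrics), and `checkpoint_path`.
#' @export
finetune <- function(trainer, task = c("classification", "ner"),
                     max_epochs = 10, seed = 1,
                     checkpoint_path = tempfile(fileext = ".rds")) {
  task <- match.arg(task)
  stopifnot(is.function(trainer), max_epochs >= 1, max_epochs <= 10)
  metric <- if (task == "classification") "precision" else "f1"
  set.seed(seed)
  state <- NULL
  history <- vector("list", max_epochs)
  backends <- vector("list", max_epochs)
  for (epoch in seq_len(max_epochs)) {
    fit <- trainer(epoch, state)
    stopifnot(inherits(fit$backend, "model_backend"))
    state <- fit$state
    backends[[epoch]] <- fit$backend
    history[[epoch]] <- tibble::tibble(
      epoch = epoch,
      precision = fit$metrics$precision %||% NA_real_,
      recall = fit$metrics$recall %||% NA_real_,
      f1 = fit$metrics$f1 %||% NA_real_
    )
  }
  history <- dplyr::bind_rows(history)
  best_epoch <- which.max(history[[metric]])
  saveRDS(backends[[best_epoch]], checkpoint_path)
  list(
    backend = backends[[best_epoch]],
    best_epoch = best_epoch,
    history = history,
    checkpoint_path = checkpoint_path
  )
}

#' Reload a serialized backend checkpoint
#'
#' @param path Path written by [finetune()].
#' @return The stored [model_backend()].
#' @export
load_checkpoint <- function(path) {
  backend <- readRDS(path)
  stopifnot(inherits(backend, "model_backend"))
  backend
}
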