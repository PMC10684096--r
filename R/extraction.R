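#' Decode BIO token predictions into name mentions
#'
#' Reassembles a token-classifier's output into resource-name mentions. A
#' mention is a maximal run starting at a `B-COM`/`B-FUL` token (or at an
#' orphan `I-` token that does not continue a same-kind run — lenient
#' decoding that preserves recall) and continuing through same-kind `I-`
#' tokens. A `B-` label always opens a new mention, so adjacent entities are
#' never merged. Sub-word tokens sharing a `word_index` are merged into one
#' word (a leading `##` wordpiece marker is dropped); words are joined with
#' single spaces. The mention's confidence is the arithmetic mean of the
#' probabilities of every member token. Trailing sentence punctuation is
#' stripped from the mention text; mentions that become empty are discarded.
#'
#' @param preds Tibble of token predictions with columns `token`,
#'   `word_index` (non-decreasing), `label` (one of [BIO_LABELS]), `prob`.
#' @return Tibble of mentions: `text`, `kind` (`"common"`/`"full"`),
#'   `confidence`, plus `start`/`end` token indices (0-based, inclusive) for
#'   evaluation.
#' @export
#' @examples
#' preds <- tibble::tibble(
#'   token = c("Protein", "Data", "Bank"), word_index = 0:2,
#'   label = c("B-FUL", "I-FUL", "I-FUL"), prob = c(0.9, 0.8, 0.7)
#' )
#' decode_mentions(preds)
decode_mentions <- function(preds) {
  stopifnot(all(c("token", "word_index", "label", "prob") %in% names(preds)))
  if (nrow(preds) == 0) return(empty_mentions())
  if (!all(preds$label %in% BIO_LABELS)) {
    validation_error("Token labels must be drawn from the five-value BIO set.")
  }
  if (any(preds$prob < 0 | preds$prob > 1)) {
    validation_error("Token probabilities must lie in [0, 1].")
  }
  if (is.unsorted(preds$word_index)) {
    validation_error("`word_index` must be non-decreasing within a sequence.")
  }

  lab <- preds$label
  kind_of <- function(l) {
    if (l == "O") NA_character_
    else if (endsWith(l, "COM")) "common" else "full"
  }
  n <- length(lab)
  runs <- list()
  i <- 1
  while (i <= n) {
    k <- kind_of(lab[i])
    if (is.na(k)) { i <- i + 1; next }
    # a run starts here (B- always; I- reaches here only as an orphan)
    j <- i
    icont <- paste0("I-", if (k == "common") "COM" else "FUL")
    while (j < n && lab[j + 1] == icont) j <- j + 1
    runs[[length(runs) + 1]] <- list(start = i, end = j, kind = k)
    i <- j + 1
  }
  if (length(runs) == 0) return(empty_mentions())

  rows <- purrr::map(runs, function(r) {
    idx <- r$start:r$end
    tibble::tibble(
      text = assemble_words(preds$token[idx], preds$word_index[idx]),
      kind = r$kind,
      confidence = mean(preds$prob[idx]),
      start = preds$word_index[r$start],
      end = preds$word_index[r$end]
    )
  })
  out <- dplyr::bind_rows(rows)
  out$text <- strip_trailing_punct(out$text)
  out[nzchar(out$text), , drop = FALSE]
}

empty_mentions <- function() {
  tibble::tibble(text = character(), kind = character(),
                 confidence = double(), start = integer(), end = integer())
}

# merge sub-word tokens by word index, join words with spaces
assemble_words <- function(tokens, word_index) {
  pieces <- stringr::str_remove(tokens, "^##")
  words <- vapply(split(pieces, factor(word_index, levels = unique(word_index))),
                  paste0, character(1), collapse = "")
  paste(words, collapse = " ")
}

strip_trailing_punct <- function(x) {
  stringr::str_remove(x, "[.,;:!?]+$")
}

#' Select the best common, full, and overall name from decoded mentions
#'
#' Multiple mentions of the same surface string are consolidated to their
#' maximum confidence before comparison. The best name of each kind is the
#' per-kind confidence argmax; the overall best name is whichever of the two
#' has the higher confidence, preferring the common name on an exact tie
#' (common names are the most reliably identified kind).
#'
#' @param mentions Tibble from [decode_mentions()].
#' @return A list with `best_common`, `best_full`, `best_name`, each either
#'   `NULL` or a list with `text`, `kind`, `confidence`.
#' @export
#' @examples
#' m <- tibble::tibble(
#'   text = c("ESTHER", "Hydrolase"), kind = c("common", "full"),
#'   confidence = c(0.9933, 0.7105)
#' )
#' select_best_names(m)$best_name$text
select_best_names <- function(mentions) {
  stopifnot(all(c("text", "kind", "confidence") %in% names(mentions)))
  pick <- function(k) {
    sub <- mentions[mentions$kind == k, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    # consolidate duplicate surface strings at their max confidence
    sub <- sub |>
      dplyr::group_by(.data$text) |>
      dplyr::summarise(confidence = max(.data$confidence), .groups = "drop")
    best <- sub[which.max(sub$confidence), ]
    list(text = best$text, kind = k, confidence = best$confidence)
  }
  best_common <- pick("common")
  best_full <- pick("full")
  best_name <-
    if (is.null(best_full)) best_common
    else if (is.null(best_common)) best_full
    else if (best_common$confidence >= best_full$confidence) best_common
    else best_full
  list(best_common = best_common, best_full = best_full, best_name = best_name)
}

# matches a scheme'd URL or a bare www. host; excludes whitespace and
# closing delimiters, then strips trailing sentence punctuation/brackets
URL_PATTERN <- "(?:https?://|www\\.)[^\\s<>\"']+"

#' Extract URLs from an abstract
#'
#' A regular-expression extraction: a match must carry an `http`/`https`
#' scheme or start with `www.`; trailing sentence punctuation and closing
#' brackets are stripped. Each distinct URL is reported once, in order of
#' first appearance.
#'
#' @param abstract Character scalar (the raw, unprepared abstract).
#' @return Character vector of URLs (possibly empty).
#' @export
#' @examples
#' extract_urls("Freely available at http://appris-tools.org.")
extract_urls <- function(abstract) {
  stopifnot(is.character(abstract), length(abstract) == 1)
  hits <- stringr::str_extract_all(abstract, URL_PATTERN)[[1]]
  hits <- stringr::str_remove(hits, "[.,;:!?)\\]}]+$")
  hits <- hits[nzchar(hits)]
  unique(hits)
}

#' Run classification, tagging, and URL extraction over a corpus
#'
#' For every article: classify the prepared title+abstract; for positive
#' articles, tag tokens, decode mentions, and select best names; extract
#' URLs from the raw abstract. The per-article results feed
#' [apply_prediction_filters()].
#'
#' @param articles Tibble of article records.
#' @param backend A [model_backend()].
#' @param threshold Classification decision threshold (default 0.5).
#' @return Tibble with one row per article: `pmid`, `label`, `score`,
#'   list-columns `mentions` and `best_names`, list-column `urls`, plus
#'   `title_abstract` and `pub_date`.
#' @export
predict_articles <- function(articles, backend, threshold = 0.5) {
  stopifnot(inherits(backend, "model_backend"))
  rows <- purrr::pmap(
    articles[, c("pmid", "title", "abstract", "pub_date")],
    function(pmid, title, abstract, pub_date) {
      text <- prepare_text(title, abstract)
      cls <- classify_article(text, backend, threshold)
      if (cls$label == "positive") {
        mentions <- decode_mentions(backend$tag(text))
        best <- select_best_names(mentions)
      } else {
        mentions <- empty_mentions()
        best <- list(best_common = NULL, best_full = NULL, best_name = NULL)
      }
      tibble::tibble(
        pmid = pmid, label = cls$label, score = cls$score,
        mentions = list(mentions), best_names = list(best),
        urls = list(extract_urls(abstract)),
        title_abstract = text, pub_date = pub_date
      )
    }
  )
  dplyr::bind_rows(rows)
}
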