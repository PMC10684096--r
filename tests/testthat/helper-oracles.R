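# Independent oracles and small builders shared across tests.

# Brute-force BIO decoder: enumerates every candidate interval [i, j] and
# keeps it iff it satisfies the entity predicate directly. Deliberately
# naive and structured nothing like the package's single-pass decoder.
brute_decode <- function(preds) {
  lab <- preds$label
  n <- length(lab)
  kind_of <- function(l) {
    if (l == "O") return(NA_character_)
    if (grepl("COM$", l)) "common" else "full"
  }
  out <- list()
  for (i in seq_len(n)) {
    k <- kind_of(lab[i])
    if (is.na(k)) next
    icont <- if (k == "common") "I-COM" else "I-FUL"
    for (j in i:n) {
      inner_ok <- j == i || all(lab[(i + 1):j] == icont)
      if (!inner_ok) next
      right_maximal <- j == n || lab[j + 1] != icont
      # i starts an entity iff it is a B- tag, or an I- tag that does not
      # continue a same-kind run
      starts <- grepl("^B-", lab[i]) ||
        (grepl("^I-", lab[i]) &&
           (i == 1 || !(lab[i - 1] %in% c(sub("I-", "B-", icont), icont))))
      if (right_maximal && starts) {
        words <- tapply(sub("^##", "", preds$token[i:j]),
                        factor(preds$word_index[i:j],
                               levels = unique(preds$word_index[i:j])),
                        paste0, collapse = "")
        text <- sub("[.,;:!?]+$", "", paste(words, collapse = " "))
        if (nzchar(text)) {
          out[[length(out) + 1]] <- data.frame(
            text = text, kind = k, confidence = mean(preds$prob[i:j]),
            start = preds$word_index[i], end = preds$word_index[j]
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(text = character(), kind = character(),
                      confidence = double(), start = integer(),
                      end = integer()))
  }
  do.call(rbind, out)
}

random_preds <- function(len, tokens = NULL) {
  labels <- sample(BIO_LABELS, len, replace = TRUE)
  if (is.null(tokens)) tokens <- paste0("w", seq_len(len))
  tibble::tibble(
    token = tokens,
    word_index = seq_len(len) - 1L,
    label = labels,
    prob = round(runif(len), 3)
  )
}

# Brute-force metric recomputation straight from raw label vectors.
brute_metrics <- function(gold, predicted) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(gold)) {
    if (predicted[i] == "positive" && gold[i] == "positive") tp <- tp + 1
    if (predicted[i] == "positive" && gold[i] == "negative") fp <- fp + 1
    if (predicted[i] == "negative" && gold[i] == "positive") fn <- fn + 1
  }
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  list(precision = p, recall = r,
       f1 = if (p + r == 0) 0 else 2 * p * r / (p + r))
}

mention_tbl <- function(text, kind, confidence) {
  tibble::tibble(text = text, kind = kind, confidence = confidence)
}

candidate_tbl <- function(best_name, url, pmid,
                          best_prob = 0.99, pub_date = "2020-01-01",
                          best_common = best_name, best_full = NA_character_,
                          text = "some abstract") {
  tibble::tibble(
    pmid = pmid, best_name = best_name, best_common = best_common,
    best_full = best_full, best_prob = best_prob,
    urls = purrr::map(url, identity), title_abstract = text,
    pub_date = pub_date
  )
}

query_file <- function(text = '("database") AND (ABSTRACT:"http")') {
  f <- tempfile(fileext = ".txt")
  writeLines(text, f)
  f
}

# scripted HTTP client: replays a fixed vector of responses (NA = timeout)
# and records every call's url/timeout
scripted_http <- function(responses) {
  env <- new.env(parent = emptyenv())
  env$calls <- list()
  env$i <- 0
  client <- function(url, timeout) {
    env$i <- env$i + 1
    env$calls[[env$i]] <- list(url = url, timeout = timeout)
    responses[[min(env$i, length(responses))]]
  }
  list(client = client, env = env)
}
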