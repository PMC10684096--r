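#' Load a literature-search query from a file
#'
#' The corpus retrieval step is driven by a user-provided query file rather
#' than a hard-coded search string, so the same pipeline can be rerun with a
#' different year range or topical focus. The file is read as UTF-8 plain
#' text holding one query expression; line endings are normalized and
#' trailing whitespace stripped. A light syntax smoke-test checks that double
#' quotes and parentheses are balanced before the query is sent anywhere.
#'
#' @param path Path to a UTF-8 text file containing the query.
#' @return A `query` object: a list with `text` and `source_path`.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines('("database") AND (ABSTRACT:"http")', f)
#' load_query(f)$text
load_query <- function(path) {
  if (!file.exists(path)) {
    config_error(paste0("Query file does not exist: ", path))
  }
  raw <- readChar(path, file.size(path), useBytes = TRUE)
  Encoding(raw) <- "UTF-8"
  text <- stringr::str_replace_all(raw, "\r\n|\r", "\n")
  text <- stringr::str_trim(text)
  text <- stringr::str_replace_all(text, "[ \t]+\n", "\n")
  if (!nzchar(text)) {
    config_error(paste0("Query file is empty (after trimming whitespace): ", path))
  }
  check_query_syntax(text)
  structure(list(text = text, source_path = path), class = "query")
}

# paired quotes / parentheses smoke test
check_query_syntax <- function(text) {
  n_quote <- stringr::str_count(text, '"')
  if (n_quote %% 2 != 0) {
    config_error("Query has an unpaired double quote.")
  }
  depth <- 0
  for (ch in strsplit(text, "", fixed = TRUE)[[1]]) {
    if (ch == "(") depth <- depth + 1
    if (ch == ")") depth <- depth - 1
    if (depth < 0) config_error("Query has an unmatched closing parenthesis.")
  }
  if (depth != 0) config_error("Query has an unmatched opening parenthesis.")
  invisible(TRUE)
}

#' @export
print.query <- function(x, ...) {
  cat("<query> ", x$text, "\n", sep = "")
  invisible(x)
}

#' Construct an article record
#'
#' One publication as retrieved from a literature API: identifier, title,
#' abstract, publication date, language, and the raw metadata blob the API
#' returned (kept opaque so downstream enrichment can reuse it).
#'
#' @param pmid Optional identifier (`NA` when the article has none).
#' @param title,abstract Character scalars (possibly empty).
#' @param pub_date ISO date string (`"YYYY-MM-DD"`) or `NA`.
#' @param language Language tag (e.g. `"eng"`) or `NA`.
#' @param raw Arbitrary metadata list.
#' @return A one-row tibble with a `raw` list-column.
#' @export
article_record <- function(pmid = NA_character_, title = "", abstract = "",
                           pub_date = NA_character_, language = NA_character_,
                           raw = list()) {
  stopifnot(is.character(title), is.character(abstract))
  if (!is.na(pmid) && !nzchar(pmid)) {
    validation_error("`pmid`, when present, must be non-empty.")
  }
  tibble::tibble(
    pmid = as.character(pmid),
    title = title,
    abstract = abstract,
    pub_date = as.character(pub_date),
    language = as.character(language),
    raw = list(raw)
  )
}

#' Retrieve all articles matching a query from a literature API client
#'
#' Pages through the client with cursor-based pagination until the cursor is
#' exhausted, retrying each page up to three times with exponential backoff.
#' Hits seen more than once across pages (same PMID) are kept only at their
#' first appearance. Records without a language tag are kept; records whose
#' tag disagrees with `language` are dropped.
#'
#' A client is a function `function(query_text, cursor, page_size)` returning
#' `list(records = <tibble of article records>, next_cursor = <string or NULL>)`.
#' [fixture_services()] provides an offline client over a synthetic corpus.
#'
#' @param query A `query` object from [load_query()].
#' @param client A literature-API client function (see Details).
#' @param page_size Number of hits per page request (default 1000).
#' @param max_records Optional cap on the number of records returned.
#' @param language Language tag to keep, or `NULL` to keep everything.
#' @param retries Attempts per page before failing (default 3).
#' @param backoff_base Seconds for the first backoff pause (default 0.5);
#'   doubled on each further retry. Set to 0 in tests.
#' @return A tibble of article records (possibly zero rows).
#' @export
fetch_articles <- function(query, client, page_size = 1000, max_records = Inf,
                           language = NULL, retries = 3, backoff_base = 0.5) {
  stopifnot(inherits(query, "query"), is.function(client))
  cursor <- "*"
  pages <- list()
  seen <- character(0)
  total <- 0
  repeat {
    page <- fetch_page_with_retry(client, query$text, cursor, page_size,
                                  retries, backoff_base)
    recs <- page$records
    if (!is.null(recs) && nrow(recs) > 0) {
      dup <- !is.na(recs$pmid) & recs$pmid %in% seen
      recs <- recs[!dup, , drop = FALSE]
      seen <- c(seen, recs$pmid[!is.na(recs$pmid)])
      if (!is.null(language)) {
        keep <- is.na(recs$language) | recs$language == language
        recs <- recs[keep, , drop = FALSE]
      }
      if (total + nrow(recs) > max_records) {
        recs <- head(recs, max_records - total)
      }
      total <- total + nrow(recs)
      pages[[length(pages) + 1]] <- recs
    }
    cursor <- page$next_cursor
    if (is.null(cursor) || total >= max_records) break
  }
  if (length(pages) == 0) {
    return(article_record()[0, ])
  }
  dplyr::bind_rows(pages)
}

fetch_page_with_retry <- function(client, query_text, cursor, page_size,
                                  retries, backoff_base) {
  last <- NULL
  for (attempt in seq_len(retries)) {
    page <- tryCatch(client(query_text, cursor, page_size), error = identity)
    if (!inherits(page, "error")) return(page)
    last <- page
    if (attempt < retries && backoff_base > 0) {
      Sys.sleep(backoff_base * 2^(attempt - 1))
    }
  }
  abort(
    paste0("Literature API request failed after ", retries, " attempts: ",
           conditionMessage(last)),
    class = "bioinventory_retrieval_error"
  )
}

#' Drop article records lacking a PMID
#'
#' Articles without a PMID tend to carry metadata too thin for downstream
#' enrichment, so they are removed before prediction. Order is preserved and
#' the number of dropped records is reported via a message.
#'
#' @param articles Tibble of article records.
#' @return The subset with non-missing `pmid`, with attribute `dropped`
#'   holding the number removed.
#' @export
drop_missing_pmid <- function(articles) {
  keep <- !is.na(articles$pmid) & nzchar(articles$pmid)
  dropped <- sum(!keep)
  if (dropped > 0) {
    inform(paste0("Dropped ", dropped, " article(s) without a PMID."))
  }
  out <- articles[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Prepare classification input text from a title and abstract
#'
#' Concatenates title and abstract with a single space, strips XML/HTML tags,
#' and re-inserts a space after sentence punctuation where tag removal glued
#' words together (a period directly followed by a letter). Runs of
#' whitespace collapse to one space; the result is trimmed. The operation is
#' idempotent.
#'
#' @param title,abstract Character scalars (either may be empty).
#' @return A single cleaned string.
#' @export
#' @examples
#' prepare_text("PDB update", "<i>New</i> structures.Next release soon.")
prepare_text <- function(title, abstract) {
  stopifnot(is.character(title), is.character(abstract))
  clean <- function(x) {
    x <- stringr::str_replace_all(x, "<[^>]*?>", "")
    # glued-word repair: punctuation immediately followed by a letter
    x <- stringr::str_replace_all(x, "([.,;:!?])(?=[A-Za-z])", "\\1 ")
    x <- stringr::str_squish(x)
    x
  }
  stringr::str_squish(paste(clean(title), clean(abstract)))
}

#' Write or read a corpus cache as JSON Lines
#'
#' One article record per line with fields `pmid`, `title`, `abstract`,
#' `pubDate`, `language`. The `raw` list-column is not round-tripped.
#'
#' @param articles Tibble of article records.
#' @param path Output (or input) file path.
#' @return `write_corpus()` returns `path` invisibly; `read_corpus()` a
#'   tibble of article records.
#' @export
write_corpus <- function(articles, path) {
  lines <- purrr::pmap_chr(
    articles[, c("pmid", "title", "abstract", "pub_date", "language")],
    function(pmid, title, abstract, pub_date, language) {
      jsonlite::toJSON(
        list(pmid = pmid, title = title, abstract = abstract,
             pubDate = pub_date, language = language),
        auto_unbox = TRUE, na = "null"
      )
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) config_error(paste0("Corpus file not found: ", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- purrr::map(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    article_record(
      pmid = x$pmid %||% NA_character_,
      title = x$title %||% "",
      abstract = x$abstract %||% "",
      pub_date = x$pubDate %||% NA_character_,
      language = x$language %||% NA_character_
    )
  })
  dplyr::bind_rows(rows)
}
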