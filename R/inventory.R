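#' Inventory configuration
#'
#' Tunables governing candidate filtering and review flagging. The review
#' threshold of 0.978 is the average confidence of correctly predicted names
#' in a curator-scored 10% sample of predictions; best names with confidence
#' strictly below it are flagged for manual review. The URL-count cap of 2
#' removes abstracts covering multiple distinct resources, and the minimum
#' name length of 2 characters removes single-letter artifacts.
#'
#' @param review_threshold Probability below which (strictly) a record is
#'   flagged `low_prob` (default 0.978).
#' @param max_urls Maximum number of extracted URLs a candidate may carry
#'   (default 2).
#' @param min_name_length Minimum character length of the best name
#'   (default 2).
#' @return An `inventory_config` list.
#' @export
inventory_config <- function(review_threshold = 0.978, max_urls = 2,
                             min_name_length = 2) {
  if (!is_scalar_prob(review_threshold) || review_threshold <= 0 ||
      review_threshold >= 1) {
    config_error("`review_threshold` must lie strictly between 0 and 1.")
  }
  stopifnot(max_urls >= 1, min_name_length >= 1)
  structure(
    list(review_threshold = review_threshold, max_urls = max_urls,
         min_name_length = min_name_length),
    class = "inventory_config"
  )
}

#' Filter per-article predictions down to inventory candidates
#'
#' A candidate must be classified positive, have at least one decoded name,
#' have a best name at least `min_name_length` characters long, and carry
#' between 1 and `max_urls` extracted URLs. Per-rule drop counts are
#' returned as the `drops` attribute (and reported via a message).
#'
#' @param predictions Output of [predict_articles()].
#' @param config An [inventory_config()].
#' @return Tibble of candidate records: `pmid`, `best_name`, `best_common`,
#'   `best_full`, `best_prob`, `urls` (list-column), `title_abstract`,
#'   `pub_date`; attribute `drops` holds the per-rule counts.
#' @export
apply_prediction_filters <- function(predictions, config = inventory_config()) {
  stopifnot(inherits(config, "inventory_config"))
  n0 <- nrow(predictions)
  pos <- predictions[predictions$label == "positive", , drop = FALSE]
  drop_negative <- n0 - nrow(pos)

  has_name <- purrr::map_lgl(pos$best_names, ~ !is.null(.x$best_name))
  drop_no_name <- sum(!has_name)
  pos <- pos[has_name, , drop = FALSE]

  best <- purrr::map(pos$best_names, "best_name")
  name_ok <- purrr::map_lgl(best, ~ nchar(.x$text) >= config$min_name_length)
  drop_short_name <- sum(!name_ok)
  pos <- pos[name_ok, , drop = FALSE]
  best <- best[name_ok]

  n_urls <- purrr::map_int(pos$urls, length)
  url_ok <- n_urls >= 1 & n_urls <= config$max_urls
  drop_url_count <- sum(!url_ok)
  pos <- pos[url_ok, , drop = FALSE]
  best <- best[url_ok]

  drops <- c(negative = drop_negative, no_name = drop_no_name,
             short_name = drop_short_name, url_count = drop_url_count)
  inform(paste0("Filtered ", n0, " predictions to ", nrow(pos),
                " candidates (dropped: ",
                paste(names(drops), drops, sep = "=", collapse = ", "), ")."))

  out <- tibble::tibble(
    pmid = pos$pmid,
    best_name = purrr::map_chr(best, "text"),
    best_common = purrr::map_chr(pos$best_names,
                                 ~ .x$best_common$text %||% NA_character_),
    best_full = purrr::map_chr(pos$best_names,
                               ~ .x$best_full$text %||% NA_character_),
    best_prob = purrr::map_dbl(best, "confidence"),
    urls = pos$urls,
    title_abstract = pos$title_abstract,
    pub_date = pos$pub_date
  )
  attr(out, "drops") <- drops
  out
}

#' Normalize a URL to a deduplication key
#'
#' Two URLs that differ only in scheme (`http:` vs `https:`) or a trailing
#' slash refer to the same resource for deduplication purposes. The key
#' strips the scheme, strips trailing slashes, and lowercases the host part;
#' the path is preserved as written. The original URL is kept separately for
#' display.
#'
#' @param url Character vector of URLs.
#' @return Character vector of comparison keys.
#' @export
#' @examples
#' normalize_url(c("http://x.org/", "https://x.org"))  # both "x.org"
normalize_url <- function(url) {
  if (any(is.na(url) | !nzchar(url))) {
    abort("Cannot normalize a missing or empty URL.",
          class = "bioinventory_normalization_error")
  }
  key <- stringr::str_remove(url, "^[A-Za-z][A-Za-z0-9+.-]*://")
  key <- stringr::str_remove(key, "/+$")
  if (any(!nzchar(key) | stringr::str_detect(key, "\\s"))) {
    abort("Not a normalizable URL.", class = "bioinventory_normalization_error")
  }
  host <- stringr::str_extract(key, "^[^/]+")
  rest <- stringr::str_remove(key, "^[^/]+")
  paste0(stringr::str_to_lower(host), rest)
}

#' Deduplicate candidate records into resource records
#'
#' Candidates agreeing on the exact (case-sensitive) best name *and* the
#' normalized URL key of their first URL merge into one resource record
#' holding the union of member PMIDs and the title-abstract text and
#' publication date of the most recently published member article (first
#' encountered on a date tie). Name comparison is deliberately
#' case-sensitive: surface variants such as "Seed" and "SEED" are distinct
#' resources. The operation is idempotent and order-invariant up to row
#' order.
#'
#' @param candidates Tibble from [apply_prediction_filters()] (or a resource
#'   tibble from a previous call).
#' @return Tibble of resource records: `resource_id`, `best_name`,
#'   `best_common`, `best_full`, `url`, `url_key`, `pmids` (list-column),
#'   `best_prob`, `latest_title_abstract`, `latest_date`, `flags`
#'   (list-column, empty until [flag_for_review()]), sorted by
#'   (`best_name`, `url_key`).
#' @export
deduplicate <- function(candidates) {
  if (nrow(candidates) == 0) return(empty_resources())
  url1 <- if ("url" %in% names(candidates)) {
    candidates$url
  } else {
    purrr::map_chr(candidates$urls, 1)
  }
  pmids <- if ("pmids" %in% names(candidates)) {
    candidates$pmids
  } else {
    purrr::map(candidates$pmid, identity)
  }
  text_col <- if ("latest_title_abstract" %in% names(candidates)) {
    candidates$latest_title_abstract
  } else {
    candidates$title_abstract
  }
  date_col <- if ("latest_date" %in% names(candidates)) {
    candidates$latest_date
  } else {
    candidates$pub_date
  }
  df <- tibble::tibble(
    best_name = candidates$best_name,
    best_common = candidates$best_common,
    best_full = candidates$best_full,
    url = url1,
    url_key = normalize_url(url1),
    pmids = pmids,
    best_prob = candidates$best_prob,
    text = text_col,
    date = date_col
  )
  merged <- df |>
    dplyr::group_by(.data$best_name, .data$url_key) |>
    dplyr::group_modify(function(g, key) {
      ord <- order(as.Date(g$date), decreasing = TRUE)
      latest <- ord[1]  # first encountered wins a date tie (stable order)
      tibble::tibble(
        best_common = first_non_na(g$best_common),
        best_full = first_non_na(g$best_full),
        url = g$url[latest],
        pmids = list(unique(unlist(g$pmids))),
        best_prob = max(g$best_prob),
        latest_title_abstract = g$text[latest],
        latest_date = g$date[latest]
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$best_name, .data$url_key)
  tibble::tibble(
    resource_id = resource_id(merged$best_name, merged$url_key),
    best_name = merged$best_name,
    best_common = merged$best_common,
    best_full = merged$best_full,
    url = merged$url,
    url_key = merged$url_key,
    pmids = merged$pmids,
    best_prob = merged$best_prob,
    latest_title_abstract = merged$latest_title_abstract,
    latest_date = merged$latest_date,
    flags = rep(list(character(0)), nrow(merged))
  )
}

first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_character_ else x[1]
}

empty_resources <- function() {
  tibble::tibble(
    resource_id = character(), best_name = character(),
    best_common = character(), best_full = character(),
    url = character(), url_key = character(), pmids = list(),
    best_prob = double(), latest_title_abstract = character(),
    latest_date = character(), flags = list()
  )
}

#' Flag resource records for selective manual review
#'
#' Three additive, machine-computed flags: `low_prob` iff the best-name
#' confidence is strictly below the review threshold; `duplicate_names` iff
#' two or more records share the exact best name (but different URLs);
#' `duplicate_urls` iff two or more records share the normalized URL key
#' (but different names). Flags are never hand-set — the review file is the
#' only human input downstream.
#'
#' @param resources Tibble from [deduplicate()].
#' @param config An [inventory_config()].
#' @return `resources` with the `flags` list-column populated.
#' @export
flag_for_review <- function(resources, config = inventory_config()) {
  stopifnot(inherits(config, "inventory_config"))
  if (nrow(resources) == 0) return(resources)
  dup_name <- resources$best_name %in%
    names(which(table(resources$best_name) >= 2))
  dup_url <- resources$url_key %in%
    names(which(table(resources$url_key) >= 2))
  low <- resources$best_prob < config$review_threshold
  resources$flags <- purrr::pmap(
    list(low, dup_name, dup_url),
    function(l, dn, du) {
      as.character(c(if (l) "low_prob", if (dn) "duplicate_names",
                     if (du) "duplicate_urls"))
    }
  )
  resources
}

REVIEW_ACTIONS <- c("keep", "remove", "merge", "partial_merge")

#' Validate and apply manual-review decisions to a flagged inventory
#'
#' Review decisions come from a curator as a closed vocabulary: `keep`,
#' `remove`, `merge:<target_id>`, or `partial_merge:<target_id>` (the last
#' moving only the PMIDs listed in the decision's `pmids` field to the
#' target). Validation runs first: every decision's action must be in the
#' vocabulary, every referenced id (including merge targets) must exist, and
#' every flagged record must have a decision. Predicted names and URLs are
#' never edited — all surviving values remain machine output.
#'
#' @param resources Flagged tibble from [flag_for_review()].
#' @param decisions Tibble with columns `resource_id`, `action`, and
#'   optionally `pmids` (`;`-separated, for `partial_merge`).
#' @return The final inventory tibble (same columns as `resources`).
#' @export
validate_and_apply_review <- function(resources, decisions) {
  stopifnot(all(c("resource_id", "action") %in% names(decisions)))
  parsed <- parse_review_actions(decisions)
  unknown_ids <- setdiff(parsed$resource_id, resources$resource_id)
  if (length(unknown_ids) > 0) {
    validation_error(paste0("Review decision references unknown resource_id: ",
                            paste(unknown_ids, collapse = ", ")))
  }
  targets <- parsed$target[!is.na(parsed$target)]
  missing_targets <- setdiff(targets, resources$resource_id)
  if (length(missing_targets) > 0) {
    validation_error(paste0("Merge target does not exist: ",
                            paste(missing_targets, collapse = ", ")))
  }
  flagged <- resources$resource_id[lengths(resources$flags) > 0]
  undecided <- setdiff(flagged, parsed$resource_id)
  if (length(undecided) > 0) {
    validation_error(paste0("Flagged record(s) without a review decision: ",
                            paste(undecided, collapse = ", ")))
  }

  out <- resources
  rownames(out) <- NULL
  for (i in seq_len(nrow(parsed))) {
    d <- parsed[i, ]
    src <- match(d$resource_id, out$resource_id)
    if (is.na(src)) next  # already consumed by an earlier merge
    if (d$verb == "keep") next
    if (d$verb == "remove") {
      out <- out[-src, , drop = FALSE]
    } else if (d$verb == "merge") {
      tgt <- match(d$target, out$resource_id)
      if (is.na(tgt)) validation_error(paste0("Merge target already removed: ",
                                              d$target))
      out$pmids[[tgt]] <- unique(c(out$pmids[[tgt]], out$pmids[[src]]))
      out <- out[-src, , drop = FALSE]
    } else if (d$verb == "partial_merge") {
      tgt <- match(d$target, out$resource_id)
      if (is.na(tgt)) validation_error(paste0("Merge target already removed: ",
                                              d$target))
      move <- d$pmids[[1]]
      if (length(move) == 0) {
        validation_error(paste0("partial_merge for ", d$resource_id,
                                " lists no PMIDs to move."))
      }
      out$pmids[[tgt]] <- unique(c(out$pmids[[tgt]], move))
      out$pmids[[src]] <- setdiff(out$pmids[[src]], move)
      if (length(out$pmids[[src]]) == 0) out <- out[-src, , drop = FALSE]
    }
  }
  out
}

parse_review_actions <- function(decisions) {
  verb <- stringr::str_extract(decisions$action, "^[a-z_]+")
  target <- stringr::str_match(decisions$action, "^[a-z_]+:(.+)$")[, 2]
  bad <- is.na(verb) | !(verb %in% REVIEW_ACTIONS) |
    (verb %in% c("merge", "partial_merge") & is.na(target)) |
    (verb %in% c("keep", "remove") & !is.na(target))
  if (any(bad)) {
    validation_error(paste0(
      "Invalid review action(s): ",
      paste0(decisions$resource_id[bad], "='", decisions$action[bad], "'",
             collapse = ", "),
      ". Allowed: keep, remove, merge:<id>, partial_merge:<id>."
    ))
  }
  if (anyDuplicated(decisions$resource_id)) {
    validation_error("Duplicate review decisions for the same resource_id.")
  }
  pmids <- if ("pmids" %in% names(decisions)) {
    purrr::map(decisions$pmids, ~ if (is.na(.x) || !nzchar(.x)) character(0)
               else stringr::str_split(.x, ";")[[1]])
  } else {
    rep(list(character(0)), nrow(decisions))
  }
  tibble::tibble(resource_id = decisions$resource_id, verb = verb,
                 target = target, pmids = pmids)
}

# inventory CSV IO -------------------------------------------------------------

#' Read and write inventory and review files
#'
#' The inventory CSV has the documented column order `best_name`,
#' `best_common`, `best_full`, `url`, `url_key`, `pmids` (`;`-separated),
#' `best_prob`, `flags` (`;`-separated), `latest_date`, preceded by
#' `resource_id`. The review CSV has columns `resource_id`, `action`, and
#' optionally `pmids`; it is validated strictly on application.
#'
#' @param resources Resource tibble.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return tibbles.
#' @export
write_inventory <- function(resources, path) {
  flat <- tibble::tibble(
    resource_id = resources$resource_id,
    best_name = resources$best_name,
    best_common = resources$best_common,
    best_full = resources$best_full,
    url = resources$url,
    url_key = resources$url_key,
    pmids = purrr::map_chr(resources$pmids, paste, collapse = ";"),
    best_prob = resources$best_prob,
    flags = purrr::map_chr(resources$flags, paste, collapse = ";"),
    latest_date = resources$latest_date
  )
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

#' @rdname write_inventory
#' @export
read_inventory <- function(path) {
  flat <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c",
                                                  best_prob = "d"))
  split_field <- function(x) {
    purrr::map(x, ~ if (is.na(.x) || !nzchar(.x)) character(0)
               else stringr::str_split(.x, ";")[[1]])
  }
  tibble::tibble(
    resource_id = flat$resource_id,
    best_name = flat$best_name,
    best_common = flat$best_common,
    best_full = flat$best_full,
    url = flat$url,
    url_key = flat$url_key,
    pmids = split_field(flat$pmids),
    best_prob = flat$best_prob,
    latest_title_abstract = NA_character_,
    latest_date = flat$latest_date,
    flags = split_field(flat$flags)
  )
}

#' @rdname write_inventory
#' @export
read_review <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}
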