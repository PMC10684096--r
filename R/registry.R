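#' Clean a resource name for registry comparison
#'
#' Trims leading/trailing whitespace (spaces, tabs, newlines); internal
#' content — including case — is untouched, since registry comparison does
#' not lowercase names the way it lowercases URLs.
#'
#' @param name Character vector.
#' @return Trimmed character vector.
#' @export
clean_name <- function(name) {
  stringr::str_trim(name)
}

#' Clean a URL for registry comparison
#'
#' Strips the scheme, strips trailing slashes, and lowercases the whole
#' remainder. Idempotent.
#'
#' @param url Character vector.
#' @return Character vector of comparison keys.
#' @export
#' @examples
#' clean_url("HTTPS://X.org/DB/")  # "x.org/db"
clean_url <- function(url) {
  key <- stringr::str_remove(url, "^[A-Za-z][A-Za-z0-9+.-]*://")
  key <- stringr::str_remove(key, "/+$")
  stringr::str_to_lower(key)
}

#' Read a registry export
#'
#' Registry exports are consumed from local CSV files with columns `source`,
#' `name`, `url`, `subjects` (`;`-separated category tags).
#'
#' @param path CSV file path.
#' @return Tibble with `source`, `name`, `url`, and list-column `subjects`.
#' @export
read_registry <- function(path) {
  flat <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  stopifnot(all(c("source", "name", "url") %in% names(flat)))
  subjects <- flat$subjects %||% rep(NA_character_, nrow(flat))
  tibble::tibble(
    source = flat$source,
    name = flat$name,
    url = flat$url,
    subjects = purrr::map(subjects,
                          ~ if (is.na(.x) || !nzchar(.x)) character(0)
                            else stringr::str_split(.x, ";")[[1]])
  )
}

#' Subset a re3data export to inventory-comparable records
#'
#' Keeps records categorized "life sciences" that have a URL, and removes
#' the generalist categories ("institutional", "other") so that only
#' resources specifically dedicated to the life sciences remain. Matching of
#' category tags is case-insensitive.
#'
#' @param records Registry tibble from [read_registry()].
#' @return The filtered tibble.
#' @export
filter_re3data <- function(records) {
  stopifnot("subjects" %in% names(records))
  tags <- purrr::map(records$subjects, stringr::str_to_lower)
  keep <- purrr::map_lgl(tags, ~ "life sciences" %in% .x) &
    !purrr::map_lgl(tags, ~ any(c("institutional", "other") %in% .x)) &
    !is.na(records$url) & nzchar(records$url)
  records[keep, , drop = FALSE]
}

#' Overlap between the inventory and registry records
#'
#' Matches are computed independently on three channels — cleaned common
#' name, cleaned full name, and cleaned URL — then merged; a pair matching
#' on both a name channel and the URL channel collapses to a single match.
#' Returns the matched pairs with their channels and the number of distinct
#' inventory resources matched.
#'
#' @param inventory Resource tibble (needs `resource_id`, `best_common`,
#'   `best_full`, `url`).
#' @param registry Registry tibble from [read_registry()] (rows are matched
#'   by position; a `registry_id` column is derived from row number and
#'   `source`).
#' @return A list with `pairs` (tibble `resource_id`, `registry_source`,
#'   `registry_row`, `channels`) and `n_matched` (distinct inventory
#'   resources matched).
#' @export
overlap <- function(inventory, registry) {
  reg <- tibble::tibble(
    registry_row = seq_len(nrow(registry)),
    registry_source = registry$source,
    name_key = clean_name(registry$name),
    url_key = clean_url_safe(registry$url)
  )
  inv <- tibble::tibble(
    resource_id = inventory$resource_id,
    common_key = clean_name(inventory$best_common),
    full_key = clean_name(inventory$best_full),
    url_key = clean_url_safe(inventory$url)
  )
  channel_match <- function(inv_key, reg_key, channel) {
    ok_inv <- !is.na(inv_key) & nzchar(inv_key)
    ok_reg <- !is.na(reg_key) & nzchar(reg_key)
    hits <- dplyr::inner_join(
      tibble::tibble(resource_id = inv$resource_id[ok_inv],
                     key = inv_key[ok_inv]),
      tibble::tibble(registry_row = reg$registry_row[ok_reg],
                     registry_source = reg$registry_source[ok_reg],
                     key = reg_key[ok_reg]),
      by = "key", relationship = "many-to-many"
    )
    hits$channel <- channel
    hits[, c("resource_id", "registry_source", "registry_row", "channel")]
  }
  all_hits <- dplyr::bind_rows(
    channel_match(inv$common_key, reg$name_key, "common_name"),
    channel_match(inv$full_key, reg$name_key, "full_name"),
    channel_match(inv$url_key, reg$url_key, "url")
  )
  pairs <- all_hits |>
    dplyr::group_by(.data$resource_id, .data$registry_source,
                    .data$registry_row) |>
    dplyr::summarise(channels = paste(sort(unique(.data$channel)),
                                      collapse = ";"),
                     .groups = "drop")
  list(pairs = pairs, n_matched = dplyr::n_distinct(pairs$resource_id))
}

clean_url_safe <- function(url) {
  out <- rep(NA_character_, length(url))
  ok <- !is.na(url) & nzchar(url)
  out[ok] <- clean_url(url[ok])
  out
}

#' Write an overlap report
#'
#' @param result Result of [overlap()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_overlap <- function(result, path) {
  readr::write_csv(result$pairs, path, na = "")
  invisible(path)
}
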