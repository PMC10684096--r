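#' Retrieve article metadata for enrichment
#'
#' Queries a metadata client PMID by PMID for author affiliations, author
#' names, grant IDs, funding agency names, and citation counts. A PMID the
#' client does not know yields an entry with all-absent fields and a
#' warning, not an error.
#'
#' A metadata client is `function(pmid)` returning a list with any of
#' `affiliations`, `authors`, `grant_ids`, `agencies` (character vectors)
#' and `cited_by` (count), or `NULL` for unknown PMIDs.
#'
#' @param pmids Non-empty character vector of PMIDs.
#' @param client Metadata client function.
#' @param retries Attempts per PMID before failing (default 3).
#' @return Tibble with one row per PMID: `pmid`, list-columns
#'   `affiliations`, `authors`, `grant_ids`, `agencies`, and `cited_by`.
#' @export
augment_metadata <- function(pmids, client, retries = 3) {
  if (length(pmids) == 0) config_error("`pmids` must be non-empty.")
  rows <- purrr::map(pmids, function(p) {
    md <- NULL
    last <- NULL
    for (attempt in seq_len(retries)) {
      md <- tryCatch(client(p), error = identity)
      if (!inherits(md, "error")) break
      last <- md
    }
    if (inherits(md, "error")) {
      abort(paste0("Metadata retrieval failed for PMID ", p, ": ",
                   conditionMessage(last)),
            class = "bioinventory_enrichment_error")
    }
    if (is.null(md)) {
      warn(paste0("No metadata found for PMID ", p, "."))
      md <- list()
    }
    tibble::tibble(
      pmid = p,
      affiliations = list(md$affiliations %||% character(0)),
      authors = list(md$authors %||% character(0)),
      grant_ids = list(md$grant_ids %||% character(0)),
      agencies = list(md$agencies %||% character(0)),
      cited_by = md$cited_by %||% NA_integer_
    )
  })
  dplyr::bind_rows(rows)
}

#' Check whether a URL is still alive
#'
#' Link-rot audit: a URL is tested up to three times, each attempt allowing
#' `timeout` seconds for a response. The second attempt follows immediately
#' after the first; the third after a one-second delay. The first definitive
#' HTTP status ends the protocol. A URL is alive iff a status in the 2xx
#' (successful) or 3xx (redirection) series was obtained within the three
#' attempts. Failures are data, not errors.
#'
#' An HTTP client is `function(url, timeout)` returning an integer status
#' code, or `NA` on timeout/connection failure.
#'
#' @param url The URL to test.
#' @param client HTTP client function.
#' @param timeout Seconds allowed per attempt (default 5).
#' @param sleep_fn Function used for the pre-third-attempt pause (default
#'   [Sys.sleep()]; injectable for tests).
#' @return A list: `url`, `attempts` (1..3), `status_code` (or `NA`),
#'   `alive`, `checked_at` (POSIXct).
#' @export
check_url <- function(url, client, timeout = 5, sleep_fn = Sys.sleep) {
  stopifnot(is.function(client))
  status <- NA_integer_
  attempts <- 0
  for (attempt in 1:3) {
    if (attempt == 3) sleep_fn(1)
    attempts <- attempt
    got <- tryCatch(client(url, timeout), error = function(e) NA_integer_)
    if (!is.na(got)) {
      status <- as.integer(got)
      break
    }
  }
  list(
    url = url,
    attempts = attempts,
    status_code = status,
    alive = !is.na(status) && status >= 200 && status < 400,
    checked_at = Sys.time()
  )
}

#' Look up (or request) a web-archive snapshot for a URL
#'
#' Returns the most recent archived-snapshot URL if the archive has one.
#' Live URLs that are not yet archived are submitted for archiving exactly
#' once and the resulting snapshot URL recorded; dead, unarchived URLs yield
#' nothing.
#'
#' An archive client is a list of two functions: `lookup(url)` returning the
#' most recent snapshot URL or `NULL`, and `submit(url)` issuing an
#' archiving request and returning the new snapshot URL (or `NULL`).
#'
#' @param url The URL to look up.
#' @param archive_client Archive client (see Details).
#' @param alive Logical: is the URL currently live (from [check_url()])?
#' @return Snapshot URL string, or `NA_character_` when none exists.
#' @export
wayback_lookup <- function(url, archive_client, alive = FALSE) {
  snap <- tryCatch(archive_client$lookup(url), error = function(e) {
    warn(paste0("Archive lookup failed for ", url, ": ", conditionMessage(e)))
    NULL
  })
  if (!is.null(snap)) return(snap)
  if (!alive) return(NA_character_)
  snap <- tryCatch(archive_client$submit(url), error = function(e) {
    warn(paste0("Archive submission failed for ", url, ": ",
                conditionMessage(e)))
    NULL
  })
  snap %||% NA_character_
}

#' Geolocate a live URL's host IP address
#'
#' Only URLs whose last observed HTTP status is below 400 are geolocated
#' (calling this on a failed URL is a precondition violation). The host name
#' is resolved to an IP, then the configured providers are queried in order;
#' the first that answers supplies the country and coordinates.
#'
#' A resolver is `function(host)` returning an IP string or `NULL`. A
#' provider is `function(ip)` returning
#' `list(country =, alpha3 =, lat =, lon =)` or `NULL`.
#'
#' @param url_status Result of [check_url()] (must have `status_code < 400`).
#' @param providers Named list of provider functions, queried in order.
#' @param resolver Host-to-IP resolver function.
#' @return A list `(source = "ip", country, alpha3, lat, lon, provider)`, or
#'   `NULL` if resolution/geolocation failed everywhere.
#' @export
geolocate_ip <- function(url_status, providers, resolver) {
  if (is.na(url_status$status_code) || url_status$status_code >= 400) {
    validation_error("geolocate_ip() requires a URL status below 400.")
  }
  host <- url_host(url_status$url)
  ip <- tryCatch(resolver(host), error = function(e) NULL)
  if (is.null(ip)) return(NULL)
  for (name in names(providers)) {
    ans <- tryCatch(providers[[name]](ip), error = function(e) NULL)
    if (!is.null(ans)) {
      return(list(source = "ip", country = ans$country, alpha3 = ans$alpha3,
                  lat = ans$lat %||% NA_real_, lon = ans$lon %||% NA_real_,
                  provider = name))
    }
  }
  NULL
}

url_host <- function(url) {
  key <- stringr::str_remove(url, "^[A-Za-z][A-Za-z0-9+.-]*://")
  stringr::str_extract(key, "^[^/:]+")
}

#' The bundled ISO-3166-1 country table
#'
#' @return Tibble with columns `name`, `alpha2`, `alpha3` (one row per
#'   alpha-3 code).
#' @export
iso3166_table <- function() {
  path <- system.file("extdata", "iso3166.csv", package = "bioinventory")
  # na = "" so Namibia's alpha-2 code "NA" survives parsing
  readr::read_csv(path, show_col_types = FALSE, na = "",
                  col_types = readr::cols(.default = "c"))
}

#' Match ISO-3166-1 countries in free text
#'
#' Finds every ISO-3166-1 country occurring in a text (e.g. an author
#' affiliation). Country names match as case-insensitive substrings — which
#' reproduces the known idiosyncrasies of affiliation mining: "New Mexico,
#' USA" also matches Mexico, while "South Korea" misses "Republic of Korea"
#' because the ISO name never appears. Alpha-3 codes match only as
#' standalone uppercase tokens, since substring matching of three-letter
#' codes is pathologically noisy. An optional word-boundary mode restricts
#' name matches to whole words.
#'
#' @param text Character scalar.
#' @param iso Country table (default [iso3166_table()]).
#' @param word_boundary If `TRUE`, country names must match at word
#'   boundaries (off by default for fidelity to substring behavior).
#' @return Tibble with columns `country`, `alpha3`, one row per distinct
#'   country found, in table order.
#' @export
#' @examples
#' \dontrun{match_countries("Univ. of Tokyo, Japan")}
match_countries <- function(text, iso = iso3166_table(),
                            word_boundary = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(country = character(), alpha3 = character()))
  }
  name_pattern <- if (word_boundary) {
    paste0("\\b\\Q", iso$name, "\\E\\b")
  } else {
    stringr::fixed(iso$name, ignore_case = TRUE)
  }
  name_hit <- if (word_boundary) {
    stringr::str_detect(text, stringr::regex(name_pattern, ignore_case = TRUE))
  } else {
    stringr::str_detect(text, name_pattern)
  }
  code_hit <- stringr::str_detect(
    text, paste0("(?<![A-Za-z])", iso$alpha3, "(?![A-Za-z])")
  )
  hit <- name_hit | code_hit
  tibble::tibble(country = iso$name[hit], alpha3 = iso$alpha3[hit])
}

#' Funder frequency across resources
#'
#' Counts, for each verbatim agency name, the number of distinct resources
#' whose member articles report it (an agency repeated across several
#' articles of one resource counts once for that resource). No name
#' normalization is applied — agency strings are left as reported. Agencies
#' below `min_count` resources are dropped.
#'
#' @param resources Resource tibble (needs `resource_id` and `pmids`).
#' @param metadata Tibble from [augment_metadata()].
#' @param min_count Minimum number of resources for an agency to be
#'   reported (default 3).
#' @return Tibble `agency`, `n_resources`, sorted by decreasing count then
#'   agency name.
#' @export
funder_frequency <- function(resources, metadata, min_count = 3) {
  pairs <- purrr::map2(resources$resource_id, resources$pmids,
                       function(rid, pmids) {
    md <- metadata[metadata$pmid %in% pmids, , drop = FALSE]
    agencies <- unique(unlist(md$agencies))
    if (length(agencies) == 0) return(NULL)
    tibble::tibble(resource_id = rid, agency = agencies)
  })
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(agency = character(), n_resources = integer()))
  }
  pairs |>
    dplyr::distinct(.data$resource_id, .data$agency) |>
    dplyr::count(.data$agency, name = "n_resources") |>
    dplyr::filter(.data$n_resources >= min_count) |>
    dplyr::arrange(dplyr::desc(.data$n_resources), .data$agency)
}

#' Enrich a finalized inventory
#'
#' Adds, per resource: HTTP status and liveness of its URL, the most recent
#' web-archive snapshot, IP geolocation (for live URLs), countries matched
#' in member-article affiliations, aggregated agency names, and total
#' citation count.
#'
#' @param resources Final inventory tibble.
#' @param services A service bundle as returned by [fixture_services()] —
#'   a list with `metadata_client`, `http_client`, `archive_client`,
#'   `resolver`, `geo_providers`.
#' @param config An [inventory_config()] (unused today; reserved).
#' @return `resources` with added columns `http_status`, `url_alive`,
#'   `wayback_url`, `ip_country`, `ip_lat`, `ip_lon`,
#'   `affiliation_countries` (`;`-separated alpha-3), `agencies`
#'   (`;`-separated), `cited_by_total`.
#' @export
enrich_inventory <- function(resources, services, config = inventory_config()) {
  if (nrow(resources) == 0) {
    return(resources)
  }
  metadata <- suppressWarnings(
    augment_metadata(unique(unlist(resources$pmids)), services$metadata_client)
  )
  iso <- iso3166_table()
  enriched <- purrr::pmap(
    list(resources$url, resources$pmids),
    function(url, pmids) {
      status <- check_url(url, services$http_client, sleep_fn = function(s) NULL)
      snap <- wayback_lookup(url, services$archive_client,
                             alive = status$alive)
      geo <- if (!is.na(status$status_code) && status$status_code < 400) {
        geolocate_ip(status, services$geo_providers, services$resolver)
      } else NULL
      md <- metadata[metadata$pmid %in% pmids, , drop = FALSE]
      affil <- paste(unlist(md$affiliations), collapse = "; ")
      countries <- match_countries(affil, iso)
      tibble::tibble(
        http_status = status$status_code,
        url_alive = status$alive,
        wayback_url = snap,
        ip_country = geo$country %||% NA_character_,
        ip_lat = geo$lat %||% NA_real_,
        ip_lon = geo$lon %||% NA_real_,
        affiliation_countries = paste(countries$alpha3, collapse = ";"),
        agencies = paste(unique(unlist(md$agencies)), collapse = ";"),
        cited_by_total = sum(md$cited_by, na.rm = TRUE)
      )
    }
  )
  dplyr::bind_cols(resources, dplyr::bind_rows(enriched))
}
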