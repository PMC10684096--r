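fixture_metadata_client <- function(tbl) {
  function(pmid) {
    row <- tbl[tbl$pmid == pmid, ]
    if (nrow(row) == 0) return(NULL)
    list(affiliations = row$affiliations[[1]], authors = row$authors[[1]],
         grant_ids = row$grant_ids[[1]], agencies = row$agencies[[1]],
         cited_by = row$cited_by)
  }
}

md_tbl <- tibble::tibble(
  pmid = c("1", "2", "3"),
  affiliations = list("Inst A, Japan", "Inst B, France", "Inst C, Japan"),
  authors = list("X", "Y", "Z"),
  grant_ids = list("G1", "G2", "G3"),
  agencies = list(c("NIH", "NIH"), "Wellcome Trust", c("NIH", "ERC")),
  cited_by = c(5L, 2L, 9L)
)

test_that("augment_metadata returns one entry per PMID, absent fields on misses", {
  client <- fixture_metadata_client(md_tbl)
  got <- augment_metadata(c("1", "2"), client)
  expect_equal(nrow(got), 2)
  expect_equal(got$agencies[[1]], c("NIH", "NIH"))
  expect_equal(got$cited_by, c(5L, 2L))

  expect_warning(miss <- augment_metadata(c("1", "999"), client),
                 "No metadata")
  expect_equal(miss$agencies[[2]], character(0))
  expect_true(is.na(miss$cited_by[2]))

  expect_error(augment_metadata(character(0), client),
               class = "bioinventory_config_error")
  failing <- function(pmid) stop("boom")
  expect_error(augment_metadata("1", failing),
               class = "bioinventory_enrichment_error")
})

test_that("check_url follows the three-attempt protocol with a pre-third delay", {
  # immediate success: one attempt, no sleeping
  m <- scripted_http(list(200L))
  sleeps <- c()
  st <- check_url("http://x.org", m$client, sleep_fn = function(s) sleeps <<- c(sleeps, s))
  expect_true(st$alive)
  expect_equal(st$attempts, 1)
  expect_equal(st$status_code, 200L)
  expect_length(sleeps, 0)
  expect_equal(m$env$calls[[1]]$timeout, 5)

  # timeout, timeout, then a redirect: alive on attempt 3, one 1-s delay
  m2 <- scripted_http(list(NA, NA, 301L))
  sleeps2 <- c()
  st2 <- check_url("http://y.org", m2$client,
                   sleep_fn = function(s) sleeps2 <<- c(sleeps2, s))
  expect_true(st2$alive)
  expect_equal(st2$attempts, 3)
  expect_equal(st2$status_code, 301L)
  expect_equal(sleeps2, 1)

  # persistent 404: not alive, status recorded, stops at first definitive code
  m3 <- scripted_http(list(404L, 404L, 404L))
  st3 <- check_url("http://z.org", m3$client, sleep_fn = function(s) NULL)
  expect_false(st3$alive)
  expect_equal(st3$status_code, 404L)
  expect_equal(st3$attempts, 1)

  # never more than three network attempts even when everything times out
  m4 <- scripted_http(list(NA, NA, NA, NA, NA))
  st4 <- check_url("http://w.org", m4$client, sleep_fn = function(s) NULL)
  expect_equal(length(m4$env$calls), 3)
  expect_equal(st4$attempts, 3)
  expect_false(st4$alive)
  expect_true(is.na(st4$status_code))
})

test_that("wayback_lookup returns snapshots and submits live unarchived URLs once", {
  services <- fixture_services(
    snapshots = c("http://known.org" = "https://web.archive.org/web/1/known")
  )
  expect_equal(wayback_lookup("http://known.org", services$archive_client),
               "https://web.archive.org/web/1/known")
  # dead and unknown: absent, nothing submitted
  expect_true(is.na(wayback_lookup("http://dead.org", services$archive_client,
                                   alive = FALSE)))
  expect_length(services$submitted(), 0)
  # live and unknown: submitted exactly once
  snap <- wayback_lookup("http://live.org", services$archive_client,
                         alive = TRUE)
  expect_match(snap, "web.archive.org")
  expect_equal(services$submitted(), "http://live.org")
})

test_that("geolocate_ip respects provider order and the status gate", {
  status_ok <- list(url = "http://x.org", status_code = 200L, alive = TRUE)
  calls <- character(0)
  providers <- list(
    first = function(ip) {
      calls <<- c(calls, "first")
      list(country = "Japan", alpha3 = "JPN", lat = 35, lon = 139)
    },
    second = function(ip) {
      calls <<- c(calls, "second")
      list(country = "France", alpha3 = "FRA")
    }
  )
  got <- geolocate_ip(status_ok, providers, resolver = function(h) "10.0.0.1")
  expect_equal(got$country, "Japan")
  expect_equal(got$provider, "first")
  expect_equal(calls, "first")

  # first provider fails -> second answers
  providers$first <- function(ip) NULL
  got2 <- geolocate_ip(status_ok, providers, resolver = function(h) "10.0.0.1")
  expect_equal(got2$country, "France")
  expect_equal(got2$provider, "second")

  status_404 <- list(url = "http://x.org", status_code = 404L, alive = FALSE)
  expect_error(geolocate_ip(status_404, providers, function(h) "10.0.0.1"),
               class = "bioinventory_validation_error")
})

test_that("match_countries reproduces substring behavior, hits and misses alike", {
  got <- match_countries("Univ. of Tokyo, Japan")
  expect_equal(got$alpha3, "JPN")

  # the documented false positive: New Mexico matches Mexico; USA via alpha-3
  nm <- match_countries("Albuquerque, New Mexico, USA")
  expect_true("MEX" %in% nm$alpha3)
  expect_true("USA" %in% nm$alpha3)

  # ISO names that never appear verbatim are missed
  kr <- match_countries("Seoul, South Korea")
  expect_false("KOR" %in% kr$alpha3)

  # word-boundary mode suppresses the New Mexico false positive
  nm_wb <- match_countries("Albuquerque, New Mexico", word_boundary = TRUE)
  expect_true("MEX" %in% nm_wb$alpha3)  # "Mexico" is still a whole word
  expect_false("MEX" %in%
                 match_countries("NewMexico compound", word_boundary = TRUE)$alpha3)

  # alpha-3 codes only match as standalone uppercase tokens
  expect_false("JPN" %in% match_countries("the jpn value")$alpha3)
  expect_false("AND" %in% match_countries("salt AND pepper portions")$country)
})

test_that("match_countries output is a deterministic subset of the ISO table", {
  iso <- iso3166_table()
  texts <- c("Heidelberg, Germany and Cambridge, United Kingdom",
             "CNRS, Paris, France; EMBL-EBI, Hinxton", "")
  for (t in texts) {
    a <- match_countries(t)
    b <- match_countries(t)
    expect_identical(a, b)
    expect_true(all(a$alpha3 %in% iso$alpha3))
  }
})

test_that("funder_frequency counts distinct resources, not articles", {
  resources <- tibble::tibble(
    resource_id = c("r1", "r2", "r3"),
    pmids = list(c("1", "3"), "2", "3")
  )
  md <- suppressWarnings(augment_metadata(c("1", "2", "3"),
                                          fixture_metadata_client(md_tbl)))
  # NIH: appears on pmids 1 and 3 (twice on 1) -> resources r1, r3 = 2
  out_all <- funder_frequency(resources, md, min_count = 1)
  expect_equal(out_all$n_resources[out_all$agency == "NIH"], 2)
  # same agency twice on one article still counts once per resource
  expect_equal(out_all$n_resources[out_all$agency == "Wellcome Trust"], 1)
  # min_count filter
  out3 <- funder_frequency(resources, md, min_count = 3)
  expect_equal(nrow(out3), 0)
})

test_that("enrich_inventory adds status, archive, geo, and metadata columns", {
  spec <- corpus_spec(n_articles = 20, positive_fraction = 0.5, seed = 17)
  corpus <- generate_corpus(spec)
  backend <- rule_backend(truth_dictionary(corpus$truth))
  run <- suppressMessages(run_pipeline(
    load_query(query_file()),
    fixture_services(corpus)$literature_client, backend))
  dead_url <- run$resources$url[1]
  services <- fixture_services(corpus,
                               url_status = setNames(404L, dead_url))
  enriched <- suppressWarnings(enrich_inventory(run$resources, services))
  expect_true(all(c("http_status", "url_alive", "wayback_url", "ip_country",
                    "affiliation_countries", "agencies", "cited_by_total")
                  %in% names(enriched)))
  expect_false(enriched$url_alive[enriched$url == dead_url])
  expect_true(all(enriched$url_alive[enriched$url != dead_url]))
  # live URLs got geolocated; the dead one did not
  expect_true(is.na(enriched$ip_country[enriched$url == dead_url]))
  expect_true(all(!is.na(enriched$ip_country[enriched$url != dead_url])))
})
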