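best_names_of <- function(common = NULL, full = NULL) {
  bc <- if (!is.null(common)) list(text = common[[1]], kind = "common",
                                   confidence = common[[2]])
  bf <- if (!is.null(full)) list(text = full[[1]], kind = "full",
                                 confidence = full[[2]])
  bn <- if (is.null(bf)) bc else if (is.null(bc)) bf
        else if (bc$confidence >= bf$confidence) bc else bf
  list(best_common = bc, best_full = bf, best_name = bn)
}

prediction_row <- function(pmid, label = "positive", best = NULL,
                           urls = "http://x.org", score = 0.99,
                           pub_date = "2020-01-01") {
  tibble::tibble(
    pmid = pmid, label = label, score = score,
    mentions = list(NULL), best_names = list(best),
    urls = list(urls), title_abstract = "text", pub_date = pub_date
  )
}

test_that("apply_prediction_filters enforces the candidacy rules", {
  preds <- dplyr::bind_rows(
    prediction_row("1", best = best_names_of(common = list("PDB", 0.99))),
    prediction_row("2", best = best_names_of(common = list("SCOP", 0.99)),
                   urls = c("http://a.org", "http://b.org", "http://c.org")),
    prediction_row("3", best = best_names_of(common = list("X", 0.99))),
    prediction_row("4", label = "negative", best = NULL),
    prediction_row("5", best = list(best_common = NULL, best_full = NULL,
                                    best_name = NULL)),
    prediction_row("6", best = best_names_of(common = list("KEGG", 0.9)),
                   urls = character(0))
  )
  out <- suppressMessages(apply_prediction_filters(preds))
  expect_equal(out$pmid, "1")
  drops <- attr(out, "drops")
  expect_equal(unname(drops["negative"]), 1)
  expect_equal(unname(drops["no_name"]), 1)
  expect_equal(unname(drops["short_name"]), 1)
  expect_equal(unname(drops["url_count"]), 2)
})

test_that("a two-character name passes the minimum-length rule", {
  preds <- prediction_row("1", best = best_names_of(common = list("Xy", 0.99)))
  out <- suppressMessages(apply_prediction_filters(preds))
  expect_equal(nrow(out), 1)
})

test_that("normalize_url collapses scheme and trailing-slash variants only", {
  expect_equal(normalize_url("http://x.org/"), "x.org")
  expect_equal(normalize_url("https://x.org"), "x.org")
  expect_equal(normalize_url("HTTP://X.ORG/"), "x.org")
  # different hosts stay distinct even when they share a predicted name
  expect_false(normalize_url("http://appris.bioinfo.cnio.es") ==
                 normalize_url("http://appris-tools.org"))
  # path content and case are preserved
  expect_equal(normalize_url("http://X.org/A/b"), "x.org/A/b")
  expect_error(normalize_url(""), class = "bioinventory_normalization_error")
  expect_error(normalize_url("not a url"),
               class = "bioinventory_normalization_error")
})

test_that("deduplicate merges same-name same-URL records, keeping the latest text", {
  cands <- dplyr::bind_rows(
    candidate_tbl("PDB", "http://pdb.org/", "1", best_prob = 0.99,
                  pub_date = "2019-03-01", text = "older"),
    candidate_tbl("PDB", "https://pdb.org", "2", best_prob = 0.98,
                  pub_date = "2021-07-01", text = "newer")
  )
  out <- deduplicate(cands)
  expect_equal(nrow(out), 1)
  expect_setequal(out$pmids[[1]], c("1", "2"))
  expect_equal(out$latest_title_abstract, "newer")
  expect_equal(out$latest_date, "2021-07-01")
  expect_equal(out$best_prob, 0.99)
})

test_that("name matching in dedup is case-sensitive: Seed and SEED stay apart", {
  cands <- dplyr::bind_rows(
    candidate_tbl("Seed", "http://seed.org", "1"),
    candidate_tbl("SEED", "http://seed.org", "2")
  )
  out <- deduplicate(cands)
  expect_equal(nrow(out), 2)
  expect_setequal(out$best_name, c("Seed", "SEED"))
})

test_that("deduplicate is idempotent and order-invariant", {
  set.seed(31)
  cands <- dplyr::bind_rows(
    candidate_tbl("A", "http://a.org", "1", pub_date = "2018-01-01"),
    candidate_tbl("A", "https://a.org/", "2", pub_date = "2020-01-01"),
    candidate_tbl("B", "http://b.org", "3"),
    candidate_tbl("B", "http://b.org/x", "4"),
    candidate_tbl("C", "http://c.org", "5")
  )
  once <- deduplicate(cands)
  expect_identical(deduplicate(once), once)
  for (rep in 1:20) {
    shuffled <- cands[sample(nrow(cands)), ]
    got <- deduplicate(shuffled)
    got$pmids <- lapply(got$pmids, sort)
    ref <- once
    ref$pmids <- lapply(ref$pmids, sort)
    expect_identical(got, ref)
  }
})

test_that("flag_for_review applies the strict 0.978 threshold and duplicate flags", {
  cands <- dplyr::bind_rows(
    candidate_tbl("LowDB", "http://low.org", "1", best_prob = 0.90),
    candidate_tbl("EdgeDB", "http://edge.org", "2", best_prob = 0.978),
    candidate_tbl("FANTOM", "http://fantom.org", "3", best_prob = 0.99),
    candidate_tbl("FANTOM5", "https://fantom.org", "4", best_prob = 0.99),
    candidate_tbl("APPRIS", "http://appris-tools.org", "5", best_prob = 0.99),
    candidate_tbl("APPRIS", "http://appris.bioinfo.cnio.es", "6",
                  best_prob = 0.95)
  )
  res <- flag_for_review(deduplicate(cands))
  by_name <- function(n) res$flags[res$best_name == n & !duplicated(res$best_name)][[1]]
  expect_equal(res$flags[[match("LowDB", res$best_name)]], "low_prob")
  expect_equal(res$flags[[match("EdgeDB", res$best_name)]], character(0))
  # FANTOM / FANTOM5 share a normalized URL
  expect_true(all(c("duplicate_urls") %in% res$flags[[match("FANTOM", res$best_name)]]))
  expect_true(all(c("duplicate_urls") %in% res$flags[[match("FANTOM5", res$best_name)]]))
  # the two APPRIS hosts share a best name; one is also low-probability
  appris_flags <- res$flags[res$best_name == "APPRIS"]
  expect_true(all(vapply(appris_flags, function(f) "duplicate_names" %in% f, TRUE)))
  expect_true(any(vapply(appris_flags, function(f) "low_prob" %in% f, TRUE)))
})

flagged_fixture <- function() {
  cands <- dplyr::bind_rows(
    candidate_tbl("A", "http://a.org", "1", best_prob = 0.99),
    candidate_tbl("B", "http://b.org", "2", best_prob = 0.90),
    candidate_tbl("C", "http://c.org", c("3"), best_prob = 0.95)
  )
  res <- deduplicate(cands)
  res$pmids[[match("C", res$best_name)]] <- c("3", "4")
  flag_for_review(res, inventory_config())
}

test_that("review decisions remove, merge, and keep as directed", {
  res <- flagged_fixture()
  ids <- setNames(res$resource_id, res$best_name)
  dec <- tibble::tibble(
    resource_id = c(ids[["B"]], ids[["C"]]),
    action = c("remove", paste0("merge:", ids[["A"]]))
  )
  final <- validate_and_apply_review(res, dec)
  expect_equal(nrow(final), 1)
  expect_equal(final$best_name, "A")
  expect_setequal(final$pmids[[1]], c("1", "3", "4"))
})

test_that("review validation rejects bad vocabulary, ids, and missing decisions", {
  res <- flagged_fixture()
  ids <- setNames(res$resource_id, res$best_name)
  expect_error(
    validate_and_apply_review(res, tibble::tibble(
      resource_id = c(ids[["B"]], ids[["C"]]), action = c("delete", "keep")
    )),
    class = "bioinventory_validation_error"
  )
  expect_error(
    validate_and_apply_review(res, tibble::tibble(
      resource_id = c("doesnotexist", ids[["B"]], ids[["C"]]),
      action = c("keep", "keep", "keep")
    )),
    class = "bioinventory_validation_error"
  )
  # flagged C has no decision
  expect_error(
    validate_and_apply_review(res, tibble::tibble(
      resource_id = ids[["B"]], action = "keep"
    )),
    class = "bioinventory_validation_error"
  )
})

test_that("partial_merge moves only the listed PMIDs", {
  res <- flagged_fixture()
  ids <- setNames(res$resource_id, res$best_name)
  dec <- tibble::tibble(
    resource_id = c(ids[["B"]], ids[["C"]]),
    action = c("keep", paste0("partial_merge:", ids[["A"]])),
    pmids = c(NA, "4")
  )
  final <- validate_and_apply_review(res, dec)
  expect_setequal(final$pmids[[match("A", final$best_name)]], c("1", "4"))
  expect_equal(final$pmids[[match("C", final$best_name)]], "3")
})

test_that("review conserves the PMID multiset minus removed records", {
  res <- flagged_fixture()
  ids <- setNames(res$resource_id, res$best_name)
  dec <- tibble::tibble(
    resource_id = c(ids[["B"]], ids[["C"]]),
    action = c("remove", paste0("merge:", ids[["A"]]))
  )
  final <- validate_and_apply_review(res, dec)
  removed_pmids <- res$pmids[[match("B", res$best_name)]]
  expect_setequal(unlist(final$pmids),
                  setdiff(unlist(res$pmids), removed_pmids))
})

test_that("inventory CSV round-trips records and flags", {
  res <- flag_for_review(deduplicate(dplyr::bind_rows(
    candidate_tbl("A", "http://a.org", "1", best_prob = 0.90),
    candidate_tbl("B", "http://b.org", "2", best_prob = 0.99)
  )))
  f <- tempfile(fileext = ".csv")
  write_inventory(res, f)
  back <- read_inventory(f)
  expect_equal(back$resource_id, res$resource_id)
  expect_equal(back$best_name, res$best_name)
  expect_equal(back$url_key, res$url_key)
  expect_equal(back$pmids, res$pmids)
  expect_equal(back$flags, res$flags)
  expect_equal(back$best_prob, res$best_prob)
})

test_that("run_pipeline reports monotone stage counts and is reproducible", {
  spec <- corpus_spec(n_articles = 50, positive_fraction = 0.4, dup_pairs = 2,
                      noise_level = 0, seed = 99)
  corpus <- generate_corpus(spec)
  backend <- rule_backend(truth_dictionary(corpus$truth))
  q <- load_query(query_file())
  run1 <- suppressMessages(run_pipeline(
    q, fixture_services(corpus)$literature_client, backend))
  counts <- run1$stage_counts
  after_cls <- counts[c("classified_positive", "with_name", "candidates",
                        "deduplicated")]
  expect_true(all(diff(after_cls) <= 0))
  # rerun is identical
  run2 <- suppressMessages(run_pipeline(
    q, fixture_services(corpus)$literature_client, backend))
  expect_identical(run1$stage_counts, run2$stage_counts)
  expect_identical(run1$resources, run2$resources)
  # planted duplicates collapse to the intended distinct-resource count
  expect_equal(nrow(run1$resources), nrow(corpus$truth$resources))
})
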