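#' Run the inventory pipeline up to the manual-review pause
#'
#' Executes the automated stages in order — fetch, classify, tag/decode,
#' filter, deduplicate, flag — and reports a per-stage count table in
#' pipeline order: articles retrieved, articles with a PMID, articles
#' classified positive, positives with at least one decoded name, candidates
#' surviving the URL/name-length filters, resources after deduplication, and
#' resources carrying at least one review flag. Counts from classification
#' onward are monotonically non-increasing. The pipeline pauses here; after
#' a curator fills in the review file, [validate_and_apply_review()] resumes
#' and finalizes the inventory.
#'
#' @param query A `query` object from [load_query()].
#' @param client Literature-API client (see [fetch_articles()]).
#' @param backend A [model_backend()].
#' @param config An [inventory_config()].
#' @param page_size Page size for corpus retrieval.
#' @return A list with `resources` (flagged, pre-review inventory),
#'   `predictions`, `candidates`, and `stage_counts` (named integer vector).
#' @export
run_pipeline <- function(query, client, backend, config = inventory_config(),
                         page_size = 100) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "bioinventory_pipeline_error")
    })
  }
  articles <- stage("fetch",
                    fetch_articles(query, client, page_size = page_size,
                                   backoff_base = 0))
  with_pmid <- stage("pmid_filter", suppressMessages(drop_missing_pmid(articles)))
  predictions <- stage("predict", predict_articles(with_pmid, backend))
  positives <- sum(predictions$label == "positive")
  named <- sum(predictions$label == "positive" &
                 purrr::map_lgl(predictions$best_names,
                                ~ !is.null(.x$best_name)))
  candidates <- stage("filter",
                      suppressMessages(apply_prediction_filters(predictions,
                                                                config)))
  resources <- stage("dedup", deduplicate(candidates))
  resources <- stage("flag", flag_for_review(resources, config))
  stage_counts <- c(
    retrieved = nrow(articles),
    with_pmid = nrow(with_pmid),
    classified_positive = positives,
    with_name = named,
    candidates = nrow(candidates),
    deduplicated = nrow(resources),
    flagged = sum(lengths(resources$flags) > 0)
  )
  list(resources = resources, predictions = predictions,
       candidates = candidates, stage_counts = stage_counts)
}
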