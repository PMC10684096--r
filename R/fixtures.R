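#' Specification for a synthetic article corpus
#'
#' Describes a corpus with known ground truth: how many articles, what
#' fraction describe a (planted) biodata resource, which name pairs and URL
#' templates to plant, how many duplicate-article pairs share one resource,
#' how often positives carry a second URL, and how often the emitted
#' "model" output is corrupted. Everything downstream of the spec is fully
#' determined by `seed`.
#'
#' Fixture token probabilities straddle the 0.978 review threshold
#' meaningfully: correctly planted names carry per-token probabilities drawn
#' uniformly from (0.98, 1.0); corrupted ones from (0.5, 0.95), so every
#' corrupted record either drops out at a filter or lands in the flagged
#' set.
#'
#' @param n_articles Number of articles (>= 1).
#' @param positive_fraction Fraction of articles describing a resource.
#' @param name_vocab Tibble with columns `common`, `full` (one pair per
#'   plantable resource); default [default_name_vocab()].
#' @param url_templates Character vector of URL templates containing
#'   `{slug}`.
#' @param dup_pairs Number of planted duplicate-article pairs (two articles,
#'   same name and URL, distinct PMIDs and dates).
#' @param multi_url_fraction Fraction of positives carrying a second URL.
#' @param noise_level Probability that a planted mention's emitted model
#'   output is corrupted.
#' @param seed Integer seed.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_articles, positive_fraction = 0.3,
                        name_vocab = default_name_vocab(),
                        url_templates = c("http://{slug}.example.org",
                                          "https://{slug}-db.example.net"),
                        dup_pairs = 0, multi_url_fraction = 0.1,
                        noise_level = 0, seed = 1) {
  stopifnot(n_articles >= 1)
  for (p in list(positive_fraction, multi_url_fraction, noise_level)) {
    if (!is_scalar_prob(p)) config_error("Fractions must lie in [0, 1].")
  }
  if (positive_fraction > 0 &&
      (is.null(name_vocab) || nrow(name_vocab) == 0)) {
    config_error("`name_vocab` must be non-empty when positives are requested.")
  }
  structure(
    list(n_articles = n_articles, positive_fraction = positive_fraction,
         name_vocab = name_vocab, url_templates = url_templates,
         dup_pairs = dup_pairs, multi_url_fraction = multi_url_fraction,
         noise_level = noise_level, seed = seed),
    class = "corpus_spec"
  )
}

#' Default synthetic resource-name vocabulary
#'
#' Deterministically enumerates plausible (common, full) name pairs, e.g.
#' `("GenBank7", "Genomic Annotation Database 7")`-style combinations built
#' from fixed word pools. All names are at least two characters and unique.
#'
#' @param n Number of pairs (default 120).
#' @return Tibble with columns `common`, `full`.
#' @export
default_name_vocab <- function(n = 120) {
  pre <- c("Gen", "Bio", "Prot", "Meta", "Chem", "Cell", "Gene", "Path",
           "Tax", "Micro")
  suf <- c("DB", "Base", "Bank", "Hub", "Atlas", "Net", "Pedia", "Map")
  adj <- c("Genomic", "Proteomic", "Metabolic", "Cellular", "Microbial",
           "Phylogenetic", "Structural", "Functional", "Clinical", "Marine")
  noun <- c("Annotation", "Interaction", "Expression", "Pathway", "Variant",
            "Sequence", "Phenotype", "Taxonomy", "Structure", "Ontology")
  i <- seq_len(n)
  common <- paste0(pre[(i - 1) %% 10 + 1], suf[((i - 1) %/% 10) %% 8 + 1],
                   ifelse(i > 80, (i - 1) %/% 80, ""))
  full <- paste(adj[(i - 1) %% 10 + 1],
                noun[((i - 1) %/% 10) %% 10 + 1],
                "Database",
                ifelse(i > 100, (i - 1) %/% 100, ""))
  full <- stringr::str_trim(full)
  tibble::tibble(common = common, full = full)
}

#' Generate a synthetic corpus with ground truth
#'
#' Positive articles embed one (common, full) name pair and 1-2 URLs inside
#' database-announcement sentence templates (including a cue phrase the rule
#' backend recognizes); negative articles contain URLs but no resource
#' description cues and no planted names. `dup_pairs` resources are
#' described by two articles each (distinct PMIDs and publication dates), so
#' the intended distinct-resource count is `n_positives - dup_pairs`.
#'
#' The ground truth records, for every occurrence of every planted mention,
#' its emitted surface form, kind, token span (0-based, on the whitespace
#' tokens of the prepared title+abstract), fixture probability, and whether
#' it was corrupted; plus the intended final resource set and a per-article
#' table.
#'
#' @param spec A [corpus_spec()].
#' @return A list with `articles` (article-record tibble) and `truth` (list
#'   of tibbles `mentions`, `resources`, `articles`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  n <- spec$n_articles
  n_pos <- round(n * spec$positive_fraction)
  if (spec$dup_pairs > n_pos %/% 2) {
    config_error("`dup_pairs` cannot exceed half the number of positives.")
  }
  n_res <- n_pos - spec$dup_pairs
  if (n_pos > 0 && nrow(spec$name_vocab) < n_res) {
    config_error(paste0("`name_vocab` has ", nrow(spec$name_vocab),
                        " pairs but ", n_res, " distinct resources are needed."))
  }

  # article -> resource assignment: first `dup_pairs` resources get 2 articles
  res_of_article <- if (n_pos > 0) {
    c(rep(seq_len(spec$dup_pairs), each = 2),
      seq_len(n_res)[seq_len(n_res) > spec$dup_pairs])
  } else integer(0)

  # resource table
  resources <- if (n_res > 0) {
    vocab <- spec$name_vocab[seq_len(n_res), ]
    slug <- stringr::str_to_lower(vocab$common)
    tmpl <- spec$url_templates[(seq_len(n_res) - 1) %%
                                 length(spec$url_templates) + 1]
    url <- stringr::str_replace(tmpl, stringr::fixed("{slug}"), slug)
    tibble::tibble(resource = seq_len(n_res), common = vocab$common,
                   full = vocab$full, url = url,
                   url_key = normalize_url(url))
  } else {
    tibble::tibble(resource = integer(), common = character(),
                   full = character(), url = character(),
                   url_key = character())
  }

  is_positive <- c(rep(TRUE, n_pos), rep(FALSE, n - n_pos))
  pmid <- sprintf("3%06d", seq_len(n))
  # dates spread over 2011-2021; dup-pair articles get distinct dates
  dates <- as.Date("2011-01-15") + (seq_len(n) * 97) %% 3900
  multi_url <- runif(n) < spec$multi_url_fraction
  corrupt_common <- runif(n) < spec$noise_level
  corrupt_full <- runif(n) < spec$noise_level

  filler <- c(
    "The underlying data were generated across multiple laboratories.",
    "Records are updated on a quarterly release cycle.",
    "An application programming interface supports bulk retrieval.",
    "Cross-references to external archives are maintained by curators.",
    "Version histories are retained for all deposited entries."
  )

  art_rows <- vector("list", n)
  mention_rows <- list()
  for (i in seq_len(n)) {
    if (is_positive[i]) {
      r <- resources[res_of_article[i], ]
      urls <- r$url
      if (multi_url[i]) urls <- c(urls, paste0(r$url, "/mirror"))
      title <- paste0(r$common, ": the ", r$full)
      abstract <- paste0(
        r$full, ", commonly known as ", r$common, ", is a curated collection ",
        "of primary experimental records. ",
        filler[(i - 1) %% length(filler) + 1], " ",
        "The database is freely available at ", urls[1],
        if (multi_url[i]) paste0(" with a mirror at ", urls[2]) else "", "."
      )
      prepared <- prepare_text(title, abstract)
      toks <- stringr::str_split(prepared, "\\s+")[[1]]
      bare <- stringr::str_remove(toks, "[.,;:!?)\\]}]+$")
      for (kind in c("common", "full")) {
        planted <- if (kind == "common") r$common else r$full
        emit <- planted
        corrupt_this <- if (kind == "common") corrupt_common[i] else
          corrupt_full[i]
        if (corrupt_this) {
          # corrupted output: a full name truncates to its first word, a
          # common name degrades to the stray token "the"
          emit <- if (kind == "full") {
            stringr::str_split(planted, "\\s+")[[1]][1]
          } else "the"
        }
        # correct mentions draw from (0.98, 1), with common names in the
        # upper half-range (they are the most reliably identified kind, and
        # this pins down the intended best name); corrupted mentions fall
        # well below the 0.978 review threshold
        prob <- if (corrupt_this) {
          runif(1, 0.5, 0.95)
        } else if (kind == "common") {
          runif(1, 0.99, 1.0)
        } else {
          runif(1, 0.98, 0.99)
        }
        spans <- find_token_spans(bare, emit)
        mention_rows[[length(mention_rows) + 1]] <- tibble::tibble(
          pmid = pmid[i], resource = r$resource, planted = planted,
          text = emit, kind = kind, start = spans[, 1], end = spans[, 2],
          prob = prob, corrupted = corrupt_this
        )
      }
    } else {
      j <- i - n_pos
      title <- paste0("Comparative analysis of expression profiles, study ", j)
      abstract <- paste0(
        "We analyzed transcriptomic measurements collected from published ",
        "experiments. ", filler[(i - 1) %% length(filler) + 1], " ",
        "Supplementary scripts are hosted at http://lab", j,
        ".example.edu/code."
      )
    }
    art_rows[[i]] <- article_record(
      pmid = pmid[i], title = title, abstract = abstract,
      pub_date = as.character(dates[i]), language = "eng"
    )
  }

  articles <- dplyr::bind_rows(art_rows)
  mentions <- if (length(mention_rows) > 0) {
    dplyr::bind_rows(mention_rows)
  } else {
    tibble::tibble(pmid = character(), resource = integer(),
                   planted = character(), text = character(),
                   kind = character(), start = integer(), end = integer(),
                   prob = double(), corrupted = logical())
  }
  truth_articles <- tibble::tibble(
    pmid = pmid, positive = is_positive,
    resource = c(res_of_article, rep(NA_integer_, n - n_pos))
  )
  resources$pmids <- purrr::map(resources$resource,
                                ~ pmid[which(res_of_article == .x)])
  list(articles = articles,
       truth = list(mentions = mentions, resources = resources,
                    articles = truth_articles))
}

# 0-based token spans of every occurrence of `text` in bare tokens
find_token_spans <- function(bare_tokens, text) {
  words <- stringr::str_split(text, "\\s+")[[1]]
  len <- length(words)
  n <- length(bare_tokens)
  hits <- list()
  s <- 1
  while (s <= n - len + 1) {
    if (all(bare_tokens[s:(s + len - 1)] == words)) {
      hits[[length(hits) + 1]] <- c(s - 1L, s + len - 2L)
      s <- s + len
    } else {
      s <- s + 1
    }
  }
  if (length(hits) == 0) {
    return(matrix(NA_integer_, nrow = 1, ncol = 2))
  }
  do.call(rbind, hits)
}

#' Build a tagging dictionary from a corpus ground truth
#'
#' One row per distinct emitted surface form and kind, at its maximum
#' fixture probability — the dictionary a [rule_backend()] needs to replay
#' the planted annotations.
#'
#' @param truth The `truth` element of [generate_corpus()].
#' @return Tibble with columns `text`, `kind`, `prob`.
#' @export
truth_dictionary <- function(truth) {
  truth$mentions |>
    dplyr::group_by(.data$text, .data$kind) |>
    dplyr::summarise(prob = max(.data$prob), .groups = "drop")
}

#' Truth-driven fixture backend
#'
#' A [model_backend()] that answers from the ground truth: classification by
#' cue phrases (as [rule_backend()]), tagging by looking the input text up
#' against the generated articles and emitting exactly the planted mention
#' spans with their fixture probabilities. Unlike a global dictionary, this
#' reproduces per-article corruption, so it is the backend of choice for
#' noisy corpora.
#'
#' @param corpus Result of [generate_corpus()].
#' @param cues Cue phrases for classification.
#' @return A [model_backend()].
#' @export
truth_backend <- function(corpus, cues = default_cues()) {
  prepared <- purrr::map2_chr(corpus$articles$title, corpus$articles$abstract,
                              prepare_text)
  by_text <- setNames(corpus$articles$pmid, prepared)
  mentions <- corpus$truth$mentions

  classify <- function(text) {
    hit <- any(stringr::str_detect(
      stringr::str_to_lower(text),
      stringr::fixed(stringr::str_to_lower(cues))
    ))
    list(score = if (hit) 0.99 else 0.01)
  }
  tag <- function(text) {
    tokens <- stringr::str_split(stringr::str_trim(text), "\\s+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    n <- length(tokens)
    labels <- rep("O", n)
    probs <- rep(0.999, n)
    pmid <- by_text[text]
    if (!is.na(pmid)) {
      m <- mentions[mentions$pmid == pmid & !is.na(mentions$start), ,
                    drop = FALSE]
      for (k in seq_len(nrow(m))) {
        idx <- (m$start[k]:m$end[k]) + 1
        tagk <- if (m$kind[k] == "common") "COM" else "FUL"
        labels[idx[1]] <- paste0("B-", tagk)
        if (length(idx) > 1) labels[idx[-1]] <- paste0("I-", tagk)
        probs[idx] <- m$prob[k]
      }
    }
    tibble::tibble(token = tokens, word_index = seq_len(n) - 1L,
                   label = labels, prob = probs)
  }
  model_backend(classify, tag)
}

#' Offline stand-ins for every network service
#'
#' Returns a bundle of injectable clients that answer from the ground truth
#' and from explicit configuration, so the full pipeline runs with no
#' downloads: a paging literature-API client over the synthetic articles, a
#' metadata client with deterministic affiliations/agencies/citations, an
#' HTTP checker answering from a URL-to-status map (default: planted URLs
#' are live with 200), an archive client that records snapshot submissions,
#' a host resolver, and two geolocation providers queried in order.
#'
#' @param corpus Result of [generate_corpus()] (or `NULL` for a bundle with
#'   empty corpus services).
#' @param url_status Named integer vector mapping URL to HTTP status (`NA`
#'   for timeout); URLs not listed return 200.
#' @param snapshots Named character vector mapping URL to a known archived
#'   snapshot URL.
#' @param countries Character vector of country names cycled over articles
#'   for fixture affiliations.
#' @param agencies Character vector of funding-agency names cycled over
#'   articles.
#' @return A list of clients: `literature_client`, `metadata_client`,
#'   `http_client`, `archive_client`, `resolver`, `geo_providers`, plus
#'   `submitted()` returning URLs submitted for archiving.
#' @export
fixture_services <- function(corpus = NULL, url_status = integer(),
                             snapshots = character(),
                             countries = c("France", "Japan", "United States",
                                           "Germany", "Brazil"),
                             agencies = c("National Science Agency",
                                          "Wellcome Trust",
                                          "European Research Council",
                                          "National Institutes of Health")) {
  articles <- if (is.null(corpus)) article_record()[0, ] else corpus$articles

  literature_client <- function(query_text, cursor, page_size) {
    start <- if (identical(cursor, "*")) 1L else as.integer(cursor)
    if (start > nrow(articles)) {
      return(list(records = articles[0, ], next_cursor = NULL))
    }
    end <- min(start + page_size - 1L, nrow(articles))
    nxt <- if (end < nrow(articles)) as.character(end + 1L) else NULL
    list(records = articles[start:end, , drop = FALSE], next_cursor = nxt)
  }

  metadata_client <- function(pmid) {
    i <- match(pmid, articles$pmid)
    if (is.na(i)) return(NULL)
    country <- countries[(i - 1) %% length(countries) + 1]
    list(
      affiliations = paste0("Department of Computational Biology, ",
                            "University ", i %% 7 + 1, ", ", country),
      authors = paste0("Author ", i),
      grant_ids = paste0("G-", 1000 + i),
      agencies = agencies[(i - 1) %% length(agencies) + 1],
      cited_by = (i * 13) %% 50
    )
  }

  http_client <- function(url, timeout) {
    if (url %in% names(url_status)) return(url_status[[url]])
    200L
  }

  archive_env <- new.env(parent = emptyenv())
  archive_env$snapshots <- snapshots
  archive_env$submitted <- character(0)
  archive_client <- list(
    lookup = function(url) {
      if (url %in% names(archive_env$snapshots)) {
        archive_env$snapshots[[url]]
      } else NULL
    },
    submit = function(url) {
      archive_env$submitted <- c(archive_env$submitted, url)
      snap <- paste0("https://web.archive.org/web/2/", url)
      archive_env$snapshots[url] <- snap
      snap
    }
  )

  resolver <- function(host) {
    paste0("10.0.", sum(utf8ToInt(host)) %% 256, ".",
           nchar(host) %% 256)
  }
  geo_of <- function(ip) {
    octet <- as.integer(stringr::str_split(ip, "\\.")[[1]][3])
    iso <- iso3166_table()
    pool <- iso[iso$name %in% countries, , drop = FALSE]
    row <- pool[octet %% nrow(pool) + 1, ]
    list(country = row$name, alpha3 = row$alpha3,
         lat = (octet %% 120) - 60, lon = (octet * 3) %% 360 - 180)
  }
  geo_providers <- list(
    ipinfo = function(ip) geo_of(ip),
    ipapi = function(ip) geo_of(ip)
  )

  list(
    literature_client = literature_client,
    metadata_client = metadata_client,
    http_client = http_client,
    archive_client = archive_client,
    resolver = resolver,
    geo_providers = geo_providers,
    submitted = function() archive_env$submitted
  )
}
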