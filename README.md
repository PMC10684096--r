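# bioinventory

Build an inventory of **biodata resources** — online sources of structured
biological data such as PDB or FlyBase — from the titles and abstracts of
life-sciences articles.

Resource announcements follow a recognizable pattern ("*GenDB: the Genomic
Annotation Database … freely available at http://gendb.example.org*"), and
this package turns that pattern into structured records at corpus scale. It
is written for the people who need a global view of this infrastructure —
research funders, registry curators, and informaticians studying link rot
and resource sustainability — and for anyone who wants to rerun or extend
the inventory with their own query, model, or registry exports.

## What it does

The pipeline has three phases:

1. **Predict.** Retrieve a query-driven corpus from a literature API (any
   client with cursor paging; offline fixtures included), classify each
   article as describing a biodata resource or not, and decode token-level
   BIO predictions (`B-COM`/`I-COM`/`B-FUL`/`I-FUL`/`O`) into name
   *mentions*. Each mention's confidence is the mean probability of its
   member tokens; per article the best *common* name (e.g. `PDB`) and best
   *full* name (e.g. `Protein Data Bank`) are compared to pick the overall
   **best name**. URLs are extracted from the raw abstract by regular
   expression. Classification and tagging sit behind a pluggable
   `model_backend()` contract, with deterministic rule-based backends
   bundled.
2. **Consolidate.** Filter candidates (positive label, ≥ 1 name, name
   length ≥ 2, 1–2 URLs), deduplicate on exact case-sensitive best name +
   normalized URL, and flag records for manual review: `low_prob` when the
   best-name confidence is strictly below 0.978, `duplicate_names` /
   `duplicate_urls` for suspected duplicates that exact matching must not
   merge on its own (*Seed* ≠ *SEED*; *FANTOM* vs *FANTOM5*). A curator's
   decisions (`keep` / `remove` / `merge:<id>` / `partial_merge:<id>`) are
   validated strictly and applied without ever editing predicted names or
   URLs.
3. **Enrich and compare.** Add article metadata (affiliations, funders,
   citations), URL liveness via a three-attempt/5-second/1-second-delay
   HTTP protocol (alive = 2xx/3xx), web-archive snapshots, IP geolocation,
   ISO-3166 country matching in affiliations, funder frequencies by
   distinct resource, and overlap counts against registry exports
   (re3data/FAIRsharing-style CSVs) on name and URL channels.

Evaluation utilities cover the supporting methodology: seeded 70/15/15
dataset splits, precision/recall/F1 from confusion counts, partial-match
entity-level NER metrics, inter-annotator agreement, and per-task model
selection (precision for classification, F1 for NER).

A synthetic-corpus generator (`generate_corpus()`) plants resources with
known ground truth and drives every network service through offline
stand-ins (`fixture_services()`), so the full pipeline runs and is tested
with no downloads.

## Worked example

Generate a 60-article corpus (30% planted positives, 2 duplicate-article
pairs), run the automated pipeline with the dictionary rule backend, and
inspect the result:

```r
library(bioinventory)

spec   <- corpus_spec(n_articles = 60, positive_fraction = 0.3,
                      dup_pairs = 2, seed = 11)
corpus <- generate_corpus(spec)
backend <- rule_backend(truth_dictionary(corpus$truth))

run <- run_pipeline(
  query  = load_query(system.file("extdata", "example_query.txt",
                                  package = "bioinventory")),
  client = fixture_services(corpus)$literature_client,
  backend = backend
)
run$stage_counts
#>           retrieved           with_pmid classified_positive           with_name
#>                  60                  60                  18                  18
#>          candidates        deduplicated             flagged
#>                  18                  16                   0

run$resources[1:3, c("resource_id", "best_name", "url", "best_prob")]
#> # A tibble: 3 × 4
#>   resource_id best_name url                             best_prob
#>   <chr>       <chr>     <chr>                               <dbl>
#> 1 b6362200    BioBase   https://biobase-db.example.net      0.995
#> 2 032e1800    BioDB     https://biodb-db.example.net        0.998
#> 3 fd4de750    CellBase  https://cellbase-db.example.net     0.992
```

The counts read in pipeline order: 60 articles retrieved, all with PMIDs,
18 classified as describing a resource, all 18 with at least one decoded
name and a usable URL, and 16 resources after the two planted duplicate
pairs merge. Nothing is flagged because the fixture names were planted
without noise, so every best-name confidence clears the 0.978 review
threshold.

The decoding and selection primitives work standalone:

```r
decode_mentions(tibble::tibble(
  token = c("Protein", "Data", "Bank"), word_index = 0:2,
  label = c("B-FUL", "I-FUL", "I-FUL"), prob = c(0.9, 0.8, 0.7)
))
#> # A tibble: 1 × 5
#>   text              kind  confidence start   end
#> 1 Protein Data Bank full         0.8     0     2

best <- select_best_names(tibble::tibble(
  text = c("ESTHER", "Hydrolase"), kind = c("common", "full"),
  confidence = c(0.9933, 0.7105)
))
best$best_name$text
#> [1] "ESTHER"
```

A thin command-line front end over the same functions is installed at
`inst/cli/bioinventory.R` (subcommands `simulate`, `fetch`, `predict`,
`build`, `apply-review`, `enrich`, `compare`).

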