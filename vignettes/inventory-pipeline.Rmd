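---
title: "Mining biodata resources from article titles and abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining biodata resources from article titles and abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioinventory)
```

## The problem

Biodata resources — online sources of structured biological data with a
distinct name and interface — are created continuously, announced in journal
articles, and then drift: URLs rot, funding lapses, registries fall behind.
Assembling an inventory of these resources by hand does not scale, but the
announcement articles themselves are a rich, programmatically accessible
signal: a title like "PDB: the Protein Data Bank" plus an abstract ending in
"freely available at http://..." is close to a structured record already.

`bioinventory` implements a pipeline that turns such articles into an
inventory: retrieve a query-driven corpus from a literature API, classify
each article as describing a biodata resource or not, extract the resource's
common name (e.g. *PDB*) and full name (e.g. *Protein Data Bank*) as
separate entity kinds, pull URLs from the abstract with a regular
expression, filter and deduplicate the candidates, flag uncertain records
for a human pass, apply the curator's decisions, and enrich the survivors
with article metadata, URL liveness, web-archive snapshots, and geolocation.

## Prediction model and its interface

Name extraction is a token-classification task over the BIO scheme with
five labels: `B-COM`/`I-COM` (start/continuation of a common name),
`B-FUL`/`I-FUL` (full name), and `O`. The package deliberately does not
bundle a neural model. Prediction is specified as a *backend contract*
(`model_backend()`): anything that can score a title+abstract string and
emit per-token labels with probabilities can drive the pipeline. In
production that backend would wrap a fine-tuned transformer; in this package
two deterministic backends are provided:

* `rule_backend()` — classification by cue-phrase lookup, tagging by
  longest-match dictionary search. Transparent and fast; used throughout the
  tests.
* `truth_backend()` — replays the ground truth of a synthetic corpus,
  including per-article corruption, which a global dictionary cannot
  express.

`finetune()` retains the training-loop semantics a model backend needs:
at most 10 epochs, per-epoch validation metrics, and checkpoint selection by
the task's criterion — validation precision for classification (false
positives propagate into the inventory, so precision is what matters),
validation F1 for the name-extraction task. Ties keep the earliest epoch.
The trainer itself is injected, so the harness is exercised with toy
trainers and metric replays.

## From token probabilities to a "best name"

The decoder (`decode_mentions()`) turns label runs into mentions. Decoding
is lenient where the label sequence is malformed: an orphan `I-` tag (no
preceding same-kind run) *opens* a mention rather than being discarded,
which preserves recall and matches common BIO-repair practice; a `B-` tag
always opens a new mention, so adjacent entities never merge. Sub-word
tokens sharing a word index are merged (a leading `##` marker is dropped),
and trailing sentence punctuation is stripped from the mention text.

Each mention's **confidence** is the arithmetic mean of its member tokens'
probabilities — always inside the min/max of those probabilities, a property
the tests assert. Per article, `select_best_names()` consolidates repeated
surface strings at their maximum confidence, takes the per-kind argmax, and
declares the overall best name the higher-confidence of the two. An exact
tie goes to the common name: short names are empirically the more reliably
extracted kind, and the tie-break must be deterministic.

## Filtering, deduplication, flagging

`inventory_config()` carries the three tunables that matter:

* `review_threshold` (probability, default **0.978**) — the confidence below
  which (strictly) a record is flagged `low_prob` for manual review. The
  default is the average confidence of names a curator judged correct in a
  10% audit of predictions; a record at exactly the threshold is *not*
  flagged.
* `max_urls` (count, default **2**) — abstracts with more than two URLs
  usually describe collections of resources rather than one, and are dropped
  rather than guessed at.
* `min_name_length` (characters, default **2**) — single-character "names"
  are artifacts.

Deduplication merges records agreeing on the *exact, case-sensitive* best
name and the normalized URL key (scheme stripped, trailing slash stripped,
host lowercased, path preserved). Case sensitivity is deliberate: *Seed*
and *SEED* are different resources. Merged records keep the union of member
PMIDs and the title/abstract and date of the most recent member; a date tie
keeps the first record encountered (documented, deterministic). Requiring
*both* keys to agree is conservative by design — *FANTOM* vs *FANTOM5* on
one URL, or one name across two hosts, are plausible duplicates but also
plausible distinct resources, so they are only *flagged*
(`duplicate_names`, `duplicate_urls`) for a human decision, never merged
automatically.

Review decisions form a closed vocabulary (`keep`, `remove`, `merge:<id>`,
`partial_merge:<id>`) validated strictly before anything is applied, and
the machinery never edits predicted names or URLs: every value in the final
inventory is machine output, every removal or merger is human input, and
the two provenances stay separable.

## Enrichment and its failure modes

URL liveness uses a fixed protocol: up to three attempts, five seconds
each, the second immediately after the first, the third after a one-second
pause; alive means a 2xx or 3xx status. GET without automatic
redirect-following is assumed of the injected client so that 3xx is
observable. Geolocation runs only for URLs with status < 400 (enforced as a
precondition), resolving the host and querying providers in configured
order, first answer wins.

Affiliation mining (`match_countries()`) is a case-insensitive substring
search over a bundled ISO-3166-1 table, and it inherits that method's known
idiosyncrasies on purpose: "New Mexico, USA" also matches *Mexico*, and
"South Korea" misses *Republic of Korea* because the ISO name never appears
verbatim. An opt-in `word_boundary` mode tightens name matching; alpha-3
codes only ever match as standalone uppercase tokens, because substring
matching of three-letter codes is pathologically noisy. Funder summaries
(`funder_frequency()`) count distinct *resources* per verbatim agency
string — deliberately no name normalization, since agency strings are
free-text and silent canonicalization would manufacture false aggregations.

Registry comparison cleans names by trimming whitespace only (case
preserved — the cleaning rules lowercase URLs, not names) and matches on
three independent channels (common name, full name, URL), collapsing pairs
that match on more than one channel.

## The synthetic corpus: what it does and does not show

`generate_corpus()` builds a corpus with exact ground truth: positives
embed one (common, full) name pair and one or two URLs inside
database-announcement sentence templates; negatives carry URLs but no
announcement cues; a configurable number of duplicate-article pairs share a
resource under distinct PMIDs and dates. Everything is a deterministic
function of the seed.

Fixture token probabilities are chosen to make the review threshold
meaningful: correctly planted mentions draw from (0.98, 1.0) — common names
from the upper half-range (0.99, 1.0), pinning down the intended best name
and mirroring the observation that common names are the more reliably
extracted kind — while corrupted mentions draw from (0.5, 0.95), safely
below 0.978. Corruption truncates a full name to its first word or degrades
a common name to a stray token, emulating the boundary errors token
classifiers actually make. Consequently a noisy record either loses its
wrong name at a filter or arrives flagged; it can never carry a wrong name
above the threshold. The default study conditions used by the acceptance
script are 200 articles, 30% positives, 5 duplicate pairs, 10% two-URL
abstracts, and noise 0 (noise 0.3 for the flagging check) — small enough to
run in seconds, large enough that every pipeline stage is exercised.

What passing on this corpus does *not* show: real abstracts are not built
from five sentence templates, real names are ambiguous and inconsistently
used, and a fine-tuned transformer's error distribution is richer than
truncate-or-degrade corruption. The synthetic runs validate the *pipeline
algebra* — decoding, selection, filtering, dedup, flagging, review — not
the linguistic difficulty of the task.

## Numerical and design choices

* Dataset splitting is unstratified: `floor(n * 0.70)` to train,
  `floor(n * 0.15)` to validation, remainder to test, under a seeded
  permutation — 1587 labeled items yield 1110/238/239.
* Undefined metrics (zero denominators) raise a classed condition instead
  of returning 0; silent zeros would corrupt model selection.
* F1 is defined as 0 when precision and recall are both exactly 0 (the one
  0/0 case with an unambiguous limit).
* Partial-match NER scoring credits a prediction that overlaps ≥ 1 token of
  a same-kind gold entity; pairing is greedy left-to-right with at most one
  credit per gold entity. The pairing rule is an explicit assumption — the
  metric family does not dictate one — chosen for determinism and
  testability.
* `resource_id` is a 32-bit FNV-1a hash of (best name, URL key): stable
  across runs, sessions, and machines.
* Tag removal targets any `<...>` span non-greedily; the glued-word repair
  inserts a space after `. , ; : ! ?` only when a letter follows directly,
  so decimals and URLs survive. The repair is idempotent.
* The URL regex requires an `http`/`https` scheme or a leading `www.`, then
  excludes whitespace, angle brackets, and quotes; trailing sentence
  punctuation and closing brackets are stripped afterwards.

## Known limitations

* Only the first URL of a candidate participates in resource identity, so a
  two-URL abstract whose *second* URL is canonical dedupes under the first.
* English-only: language filtering trusts the API's language tag and keeps
  untagged records.
* Exact-match deduplication will not catch renamed or migrated resources;
  that gap is the reason the duplicate flags and the manual review stage
  exist.
* The fixture corpus cannot measure real-world extraction quality; it
  measures that the pipeline is faithful to its own rules.
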