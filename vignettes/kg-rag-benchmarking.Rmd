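---
title: "Benchmarking knowledge-graph grounded generation for drug mechanisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking knowledge-graph grounded generation for drug mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechrag)
```

## The problem and the measurement design

A language model asked "which gene mediates how drug X treats disease Y?"
will answer confidently whether or not it knows. `mechrag` measures how much
explicit knowledge-graph evidence changes that answer quality, using a
paired design: every question is answered twice by the same deterministic
model configuration — once from the question alone (*LLM-only*), once with
retrieved, verbalized graph evidence prepended (*RAG*) — and the two runs
are compared item by item. Paired designs are essential here because
question difficulty varies enormously; the informative quantities are the
discordant counts *b* (baseline wrong, RAG right) and *c* (baseline right,
RAG wrong), not the marginal accuracies.

The pipeline has five stages, each an independent module with an injectable
contract at its boundary (resolver, transport, embedder, backend), so every
stage can run against deterministic offline stand-ins.

## Benchmark construction from mechanism paths

Input records follow the curated drug-mechanism convention: a record holds
an ordered node list (CURIE, category label, display name) and directed
predicate links, running from a drug node through intermediate biological
entities to a disease node. `parse_drugmechdb()` validates structure
(non-empty CURIEs and names, unique node CURIEs per path, link endpoints
resolving to nodes, disease reachable from drug along directed links);
malformed records fail loudly by default, or can be skipped with a warning.

Three filters derive the benchmarks:

- **Gene**: exactly one *internal* node (neither endpoint) labeled as a gene
  entity, whose CURIE resolves to exactly one HGNC symbol. The gene-label
  set defaults to `c("Gene", "Protein")`: mechanism curation frequently
  annotates the protein product where the mechanistic actor is the gene, and
  a protein CURIE still resolves to its gene symbol. The set is an explicit
  argument because the narrower `"Gene"`-only reading is defensible; with
  the bundled synthetic data either choice recovers the planted counts.
  Resolution is an injected contract: zero symbols models a deprecated
  identifier, two or more an ambiguous one, and both exclude the path.
- **Metabolite**: paths whose links are all taxonomic (by default, any
  predicate containing the substring `"subclass"`) are removed, indications
  (drug-disease CURIE pairs) represented by more than one record are removed
  (multiplicity is assessed on the input collection, before the other
  filters), and the path must contain exactly one internal `CHEBI:`-prefixed
  node (case-sensitive prefix match). We apply the "internal node" reading
  uniformly to this filter for consistency with the gene filter.
- **Drug**: exactly one `BiologicalProcess`-labeled node anywhere on the
  path, and a drug CURIE starting with one of the resolvable-identifier
  prefixes (default `c("DB", "MESH")`).

Questions are rendered from fixed templates with the entity names in double
quotes; deduplication keys on the case-folded (asked entity, disease, gold
answer) triple, keeps the first occurrence in input order (a deterministic
tie-break; nothing deeper is implied by it), and merges the provenance path
ids of dropped duplicates. Item ids are zero-padded ordinals assigned after
deduplication, and output is sorted by id so serialized benchmarks are
byte-stable.

One subtlety the property tests respect: the metabolite filter is *not*
monotone under arbitrary path removal. Deleting one of two records that
share an indication legitimately promotes the survivor, because the
single-record-per-indication rule no longer excludes it. Monotonicity holds
for the gene and drug filters, and for metabolite removals that do not break
up a multi-path indication.

## Retrieval, verbalization, and context selection

Retrieval uses one-hop TRAPI query graphs: a pinned node carrying the input
CURIE and category, a free node carrying the requested output category, one
connecting edge, and no predicate constraint by default (retrieve
everything; filtering happens later by similarity). Per benchmark, the query
plan is: gene — drug and disease each queried for `biolink:Gene` and
`biolink:Protein` (two requests, unioned); metabolite — drug and disease for
`biolink:ChemicalEntity`; drug — disease and biological process for
`biolink:ChemicalEntity`. The exact output categories are configuration, not
dogma: the roles (which entities are queried, which category comes back) are
what matter.

Requests serialize canonically (recursively sorted keys), and the cache key
is the SHA-256 digest of those canonical bytes, so equal specs share a cache
file under `<cache>/<first2>/<digest>.json`. Responses are cached verbatim —
original key order — so replay is byte-faithful; offline mode treats a cache
miss as an error before any transport is touched. Edges referencing nodes
absent from the response's node map are dropped with a counted warning
rather than failing the run: federated sources vary in quality, and one
malformed edge should not abort a benchmark sweep.

Each retained edge becomes one declarative statement:
`<subject name> <humanized predicate> <object name> (source: <primary source>)`,
where predicate humanization strips the `biolink:` prefix, replaces
underscores, and lowercases (idempotently). The source parenthetical is our
placement choice — provenance belongs next to the claim it supports — and is
omitted when no primary source is recorded. Node display names fall back to
the CURIE.

Context selection is rank-based, not interpolated: with *n* statements and
percentile *p*, `drop_bottom` discards the `floor(pn/100)` lowest-scoring
statements and `keep_top` retains the `n − ceiling(pn/100)` statements
ranked strictly above the *p*-th percentile position. Rank semantics are
exact, reproducible, and tie-stable (ties break by original statement order,
earlier outranking later). Percentiles are computed per question — each
question's own context distribution — rather than globally across the
benchmark; this is an interpretation choice, made because pruning is meant
to remove *that question's* least relevant evidence. Token budgeting
estimates `ceiling(characters/4)` tokens per statement and drops from the
lowest-score end; exact tokenizers are backend-specific and out of contract.

## Inference

Prompts pair a per-(benchmark, mode) system text — instructing a structured
single-key JSON response — with a user text that is either the question
alone or the retained statements (one per line, retained order), a blank
line, and the question. The registry texts are this package's own wording
and are override-able per run. Backends are functions
`(system_text, user_text, config) -> text` with `temperature = 0` in the
config; the scripted test backend is exactly reproducible, and live adapters
are out of scope for the core (a transport/backend contract is the
integration point).

Answer parsing never throws: a direct JSON parse yields status `ok`; a
repair pass (strip code fences, take the first balanced `{...}` substring)
yields `repaired`; otherwise `failed`. Parse failures score as incorrect in
the binary regime and as similarity 0 in the score regime — a deliberate,
recorded policy so the choice is auditable: a model that cannot follow the
output contract has not answered.

## Evaluation statistics

- **Binary regime**: exact case-insensitive matching after trimming and
  unquoting. The paired 2×2 table (a, b, c, d) feeds McNemar's test. The
  default variant is the exact two-sided binomial on the discordant pairs,
  `min(1, 2·P(X ≤ min(b,c)))`, `X ~ Binomial(b+c, ½)` — flip counts can be
  small in sub-analyses, where the chi-square approximation is poor; the
  chi-square statistic `(b−c)²/(b+c)` (no continuity correction) is reported
  alongside. Both return p = 1 when b + c = 0. Net gain is
  `(b − c)/n × 100`, reported to one decimal, and equals the accuracy
  difference by construction.
- **Score regime**: cosine similarity between embeddings of prediction and
  gold. The paired difference is summarized by its mean with a seeded
  percentile-bootstrap CI (default 10,000 replicates; the CI method is our
  choice and is stated rather than hidden), a Wilcoxon signed-rank test, and
  Cliff's δ between the two runs' score vectors (the group-level pair-count
  definition) with a CI from Cliff's consistent variance estimate and normal
  quantiles, clipped to [−1, 1]. The Wilcoxon implementation drops zero
  differences, uses the exact distribution for n ≤ 25 — computed by
  generating-function convolution over doubled midranks, which remains exact
  under ties — and otherwise a normal approximation with tie and continuity
  corrections. Threshold-sensitivity tables count scores **at or above**
  each cutoff (τ ∈ {0.85, 0.90, 0.95} by default): "surpassing a threshold"
  is read inclusively, and the high-fidelity zone is score ≥ 0.90; the
  reading is exposed as the `thresholds` argument rather than hard-coded.
  Distribution summaries report rank-ordered scores and left-closed bins
  over [0, 1] (last bin closed; negative similarities are clamped into the
  first bin with a warning, since embedding similarities below zero carry no
  extra meaning at this resolution).

Fractions are reported to one decimal and relative increases to the nearest
integer (full precision kept in an attribute), matching the precision at
which such results are conventionally printed.

## What the synthetic fixtures do and do not show

`generate_mini_drugmechdb()` plants, per config: the exact number of paths
eligible for each benchmark, explicit negatives for every exclusion rule
(multi-gene, taxonomic-only, multi-path indication, unresolvable drug
prefix, ambiguous and deprecated gene identifiers), and optional duplicate
records that must be merged by deduplication. The companion mock transport
answers the benchmark query plans with planted neighborhoods in which the
gold entity appears among distractors, the hash embedder provides a
deterministic stand-in geometry (seeded trigram hashing, L2-normalized), and
the scripted backend can plant exact contingency cells, accuracies,
malformed-response rates, and — through a closed-vocabulary scorer that
realizes prescribed prediction-gold cosines — exact similarity shifts.

These fixtures verify the *machinery*: filters recover planted counts,
statistics recover planted effects, and the whole pipeline is bit-identical
across reruns. They deliberately do not emulate the statistics of real
biomedical text, real embedding-model geometry, or the noise profile of
federated knowledge sources — so a passing suite says the harness measures
correctly, not that any particular model or knowledge graph performs well.
Entity names come from a bundled synthetic vocabulary; no external lookup is
ever required.

## Problem sizes and numerical choices

The test suite exercises: planted-count recovery over 100 seeded configs of
10–14 paths; statistical oracle sweeps (all b + c ≤ 20 for exact McNemar;
score vectors up to length 200 for Cliff's δ pair counting; exhaustive
2^n sign-flip enumeration for Wilcoxon up to n = 10); pruning oracles across
p ∈ {10, …, 90}; scripted contingency runs at n = 798 and similarity-shift
runs at n = 201; and bootstrap-CI coverage over 500 simulated Gaussian
datasets (n = 30, 1,000 replicates each) against a 93% floor at nominal
95% — sizes chosen to make each property decisive while keeping the suite
brisk. Cosine similarities are clipped to [−1, 1] against rounding; zero
vectors are rejected rather than silently scored; the empty statement list,
the empty benchmark, the all-zero difference vector, and b + c = 0 all have
defined, tested behavior.

## Known limitations

- Live TRAPI endpoints and hosted chat-completion services are integration
  points behind the transport/backend contracts; the package ships no
  network client, so headline accuracies of real models are out of its
  scope by design.
- Single-hop retrieval only; multi-hop traversal and result ranking are
  non-goals.
- One gold entity per question; real mechanisms can involve several
  interacting entities, and the exact-match regime cannot credit partially
  correct multi-entity answers.
- The 4-characters-per-token estimate is a budgeting heuristic, not a
  tokenizer.
- No multiple-testing correction across benchmarks: comparisons are
  reported per benchmark, as is conventional for paired evaluations of this
  kind.
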