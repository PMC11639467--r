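---
title: "Methods: comparative mining of renal-disease literature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mining of renal-disease literature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalmine)
```

## The problem and the approach

Chronic kidney disease is heavily studied in humans and comparatively
under-studied in cats and dogs. The package implements a comparative
text-mining design: retrieve (or simulate) one corpus of MEDLINE records per
species, annotate each record against controlled category vocabularies
(diseases, methods, cells, cytokines, tissues, clinical signs, pain types),
and compare what each species' literature discusses — capture overlaps,
publication trends, term rankings, mention proportions, and term
co-occurrence networks.

The design rests on one modelling assumption: terms co-mentioned within a
record are treated as positively associated. No negation or context
detection is attempted — "no vomiting was observed" counts as a mention of
vomiting. At corpus scale this noise is tolerable for trend-finding, but
individual low-count co-occurrences should not be over-read, and causality
or directionality can never be inferred from co-mention counts.

## Matching rules

Two matching surfaces exist, chosen per category:

* **MeSH surface** (all categories): a vocabulary term matches a record if
  its canonical form (lowercased, whitespace-collapsed) equals the canonical
  descriptor name of any MeSH heading; subheadings (`/veterinary`) and the
  major-topic marker (`*`) are stripped before comparison. This
  normalization is what lets a qualified heading like
  `Kidney Failure, Chronic/*veterinary` match the plain vocabulary term.
* **Abstract surface** (clinical signs and pain types only): case-insensitive
  whole-phrase matching at word boundaries. A boundary is any transition
  between alphanumeric and non-alphanumeric text, so *painstaking* never
  matches *pain*, while hyphens and line-wrap artefacts act as separators
  (*neck-pain* matches *neck pain*). This is the minimal tokenizer-free rule
  that avoids substring artefacts; it is deliberately simple and documented
  rather than linguistically ambitious.

Titles are not searched: the mining surfaces are the MeSH list and the
abstract text. Records without MeSH indexing are kept — they simply match
nothing on the MeSH surface. Within a corpus, duplicate PMIDs keep the first
occurrence; the same PMID may appear in different species corpora, which are
analysed independently.

Spelling variants are folded through an explicit synonym table
(*anemia* → *anaemia*, etc.), applied to both the vocabulary and the record
side. No stemming, no thesaurus expansion: the package matches exactly what
the vocabulary says, which keeps the term universe well-defined for the
overlap test below.

An important interaction between nested vocabulary terms and the abstract
surface: if one abstract-searchable term contains another as a whole phrase
(*abdominal pain* contains *pain*), every abstract mention of the longer
term is also a mention of the shorter. This is linguistically correct but
means observed counts for nested terms exceed what an independence model of
the two terms would predict; quantitative recovery checks therefore use
non-nested term sets (see `recovery_study_config()`).

## The category-overlap test

For each category, the capture set of a corpus is the set of vocabulary
terms matched by at least one record. With a term universe of size $N$
(the full category vocabulary — `universe_size`), corpus A capturing $n_A$
terms, corpus B capturing $n_B$, and $n_{AB}$ captured by both, the 2×2
table $(n_{AB},\; n_A-n_{AB},\; n_B-n_{AB},\; N-n_A-n_B+n_{AB})$ is tested
with Fisher's exact test, conditioning on the margins.

Two conventions are implemented:

* `fisher_overlap_test()` defaults to the one-sided upper tail
  (`alternative = "greater"`): the scientific question is whether the two
  capture sets overlap *more* than independent capture would produce, and
  this is the convention under which published capture-count tables for
  this comparison reproduce (e.g. clinical signs human–cat: $N=28$,
  $27/23/23$ captured/captured/common gives $p = 0.179$; cytokines
  human–cat $p = 0.201$).
* `two_sided_fisher()` implements the standard two-sided point-probability
  rule — all tables whose point probability does not exceed the observed
  table's, within a relative slack of $10^{-7}$ (the convention of standard
  exact-test implementations, against which it is cross-checked).

All hypergeometric mass is computed through `lgamma`. This matters: the
disease-category comparisons produce p-values near $10^{-313}$, below the
smallest normal double, where naive linear-space summation underflows to
zero. Every result therefore carries both `p` (capped to $[0,1]$, may
underflow for extreme tables) and `log10_p` (always finite for feasible
tables).

Choices a user can vary:

| Parameter | Default | Meaning |
|---|---|---|
| `alternative` | `"greater"` | overlap enrichment; `"two.sided"` available |
| `denominator` (proportions) | `records_with_any_hit` | share of sign-reporting records; `corpus_size` available |
| Venn overlap denominator | union of the three capture sets | `triple_over_universe` also reported |
| `min_count`, `k` (rankings) | 10, 10 | "top 10 terms with ≥ 10 records" convention |

The triple-overlap percentage has two defensible denominators (union of the
capture sets, or the whole universe); `three_way_overlap()` reports both
rather than privileging one silently.

Ranking ties are broken alphabetically, making every table deterministic.
P-values are printed at three significant figures; tests against published
values compare at the precision those values were printed with.

## Co-occurrence networks

Nodes are (term, category) pairs — the same string can legitimately be both
a clinical sign and a pain type — weighted by record count; an edge's weight
is the number of records mentioning both endpoints, each record contributing
at most 1 regardless of how many surfaces matched. Cross-category edges are
kept; self-pairs are excluded; no weight threshold is applied by default
(`min_weight` exists for display parity with thresholded figures).
Sub-networks around a seed node are *induced* subgraphs on the seed plus its
first-degree neighbours, so neighbour–neighbour edges are retained —
matching the behaviour of interactive network tools when a node and its
neighbours are selected. Exports: GraphML (full fidelity, round-trippable),
SIF and a TSV edge table, all directly loadable in Cytoscape.

## The synthetic-corpus generator

`generate_corpus()` draws each record's terms independently from per-term
marginal probabilities, then applies planted pair boosts: a pair
$(t_1, t_2, \rho)$ adds both terms with probability $\rho$, so the joint
occurrence probability is exactly $\rho + (1-\rho)p_1p_2$. The mixture
construction was chosen over log-odds-style models precisely because this
closed form makes `expected_pair_count()` an exact binomial oracle.
Marginals of planted terms follow $1-(1-p)\prod_i(1-\rho_i)$
(`expected_term_count()`).

Generated records are MEDLINE-valid: `mesh_only` terms are written as MH
headings (a fraction dressed with a `/veterinary` qualifier and a `*`
major-topic marker, so descriptor normalization is exercised);
clinical-sign and pain terms are emitted into templated abstract sentences
and/or the MeSH list with probability `abstract_emission` (default 0.5).
One decoy sentence per configured term embeds the term inside a longer word
(`pseudo...oid`) somewhere in the corpus, so a substring-matching bug would
be caught, not masked. Publication years are sampled from a linearly
increasing weight ramp over 1945–2023, emulating literature growth.
Generation is seed-deterministic to the byte, and the global RNG state is
restored afterwards.

What the generator does **not** emulate: real MeSH indexing depth and
hierarchy, realistic abstract language, negated mentions, inter-term
correlations beyond the planted pairs, and the extreme corpus-size imbalance
of the real literatures. Passing recovery tests therefore demonstrate that
the pipeline's counting and statistics are correct, not that the matching
rules capture everything a human indexer would.

### Study sizes

The default species configurations use 3000 (human), 800 (dog) and 400
(cat) records — preserving the human-dominated ordering of the real corpora
at a scale where every stage runs in seconds. The recovery benchmark
(`recovery_study_config()`) uses 2000 records with six planted pairs at
$\rho \in \{0.05, 0.2\}$ over 18 non-nested terms; verification runs ten
seeds and requires each planted edge weight and each marginal count to fall
within 4 binomial standard deviations of its closed form. Null calibration
simulates independent capture over a universe of $N = 802$ terms with
capture probabilities 0.75 and 0.33 — the scale of the methods category,
where hypergeometric discreteness is negligible and the exact test's size
should sit near its nominal level — over 2000 replicates.

## Numerical and degenerate-input conventions

* Point-probability comparisons in the two-sided rule use a $1+10^{-7}$
  relative slack, so ties at machine precision are included.
* A zero margin (one corpus captured nothing, or everything so the margins
  force the table) yields $p = 1$; an all-zero table yields $p = 1$.
  Negative or non-integer cells are errors.
* Records without a parseable publication year are kept but excluded from
  per-year trends, with their count reported alongside.
* Empty corpora annotate to empty (not errors); a zero denominator in
  proportion tables warns and returns an empty table.
* An empty vocabulary file, inconsistent capture counts (negative implied
  cell) and unknown categories or seed terms are errors naming the offender.

## Known limitations

* Shipped vocabularies: the clinical-sign (28 terms) and pain lists cover
  the signs this comparative design centres on, but several entries beyond
  the core set are reconstructed placeholders, and the disease / method /
  cell / cytokine / tissue lists are small samples intended for synthetic
  studies and examples. For real corpora, drop in full published term lists
  — the loaders accept any one-term-per-line file.
* Exact matching without MeSH-tree expansion undercounts concepts indexed
  under narrower headings.
* Abstract matching has no negation or hedging detection.
* The Fisher overlap test conditions on capture counts and ignores *which*
  terms overlap; it answers "more overlap than chance?", not "which
  overlaps are surprising?".
* `fetch_pubmed()` depends on NCBI availability and returns whatever the
  current database state holds; corpus sizes and all downstream counts from
  live queries drift over time, which is why analyses here run on seeded
  synthetic corpora and on published count tables.
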