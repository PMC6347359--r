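---
title: "Screening drug combinations for synthetic-lethal mechanisms"
author: "synletScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening drug combinations for synthetic-lethal mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synletScreen)
```

## The problem

Two genes are synthetic lethal (SL) when a cell tolerates the loss of
either one but not of both. A drug combination in which each compound
inhibits one partner of an SL pair should act more than additively, which
makes systematically mined SL pairs a rational source of combination
therapies. `synletScreen` implements that mining pipeline end to end:
build a human SL pair resource from yeast double-knockout screens, extend
it with a network-feature classifier, then screen clinical-trial drug
combinations against it and rank novel proposals.

This vignette documents the model and every convention the implementation
fixes where the underlying procedure leaves a choice open.

## From a yeast screen to human SL pairs

A screen record carries a genetic-interaction (epistasis) score
$\varepsilon$ and a p-value. Strongly negative $\varepsilon$ at low p is
the operational definition of an aggravating, SL-like interaction.
`filterNegativeInteractions()` retains records with
$p < 0.05$ and $\varepsilon < -0.08$ by default.

* **Strictness.** Both inequalities are strict. The cutoffs are quoted in
  the source screens as threshold values without an explicit
  $\le$ / $<$; we fix strict inequalities and expose both thresholds as
  arguments, so the choice is visible and reversible.
* **Canonical pairs.** All pair containers store unordered pairs with
  `gene_a` preceding `gene_b` under byte-wise lexicographic order
  (locale-independent, hence reproducible across platforms). Reversed
  query/array duplicates collapse to one pair and self-pairs are dropped.
  Deduplication happens both before and after ortholog mapping: whether
  the original procedure deduplicated reciprocal measurements before or
  after mapping is unstated, and deduplicating at both stages is the only
  order-insensitive choice.
* **Orthology.** `mergeOrthologSources()` takes the union over resources:
  a yeast gene's human image is everything any resource asserts. A yeast
  pair maps to a human pair only if *both* endpoints have at least one
  ortholog; one-to-many orthology expands to the full cross-product of
  human pairs (consistent with the large human pair counts such pipelines
  report relative to the yeast input). Human self-pairs arising from a
  shared ortholog are excluded.
* Gene identifiers are opaque case-sensitive strings; any symbol
  normalisation belongs to ingestion, not to the core logic.

## Pair features

`buildPairFeatures()` produces a 10-component vector in a frozen order
(5 Dice values, 4 endpoint-mean node statistics, shortest path). The
order is versioned (`slFeatureVersion()`, currently `slfeat/1`), carried
on every feature table, and checked at prediction time so a trained model
can never be silently applied to reordered features.

**Dice coefficients.** For term sets $A, B$ of the two endpoints in one
annotation namespace, $D = 2|A \cap B| / (|A| + |B|)$. Five namespaces
are used: KEGG pathways, PANTHER pathways, a GO slim, MeSH disease
associations, and drug associations. $D(\varnothing, \varnothing)$ is
defined as 0, not 1: two genes about which nothing is known carry no
evidence of similarity.

**Node statistics.** Computed once per network by `nodeStatistics()`:

* *degree* — edge count;
* *betweenness* — unnormalized Freeman count of dependent shortest-path
  pairs, endpoints excluded, each unordered pair counted once (the middle
  node of a 3-node path scores exactly 1);
* *closeness* — component-restricted: $(n_c - 1) / \sum_u d(v, u)$ over
  the node's connected component of size $n_c$, 0 for isolated nodes;
  this keeps the value finite on disconnected networks and in $[0, 1]$;
* *clustering* — local clustering coefficient, 0 for degree < 2.

Betweenness and closeness conventions vary across tools; only *relative*
values reach the classifier, so the package fixes one documented
convention rather than offering options.

**Shortest path.** Hop count (the procedure's "shortest paths" is read as
unweighted; no edge weights are available on the input network). For a
disconnected pair the sentinel equals the number of network nodes — one
more than any realizable path, keeping the feature finite and ordinal
("farther than any real path").

**Annotation eligibility.** The modelling universe is restricted to genes
annotated in *all five* namespaces (`eligibleNodes()`), mirroring the
restriction of such pipelines to highly annotated nodes. A `permissive`
mode treats missing namespaces as empty term sets for exploratory use.

## The classifier

Training instances are balanced: the known SL pairs as positives, and an
equal number of negatives drawn by `sampleNegativePairs()` uniformly
among pairs of eligible genes that take part in **no** known SL
interaction. The split is 2/3 training, 1/3 test, stratified by class
(`splitTrainTest()`), and the instance counts per class never differ by
more than one.

`trainClassifier()` fits a random forest. The only tuned hyperparameter
is the ensemble size, selected by stratified 10-fold cross-validated
accuracy over the grid {25, 50, 93, 150, 300}; 93 is included because it
is the ensemble size such pipelines have reported as final, and ties go
to the smallest size. Per-tree settings are the `randomForest` defaults
and are recorded with the model; the original tuning protocol beyond the
ensemble size is unstated, so we deliberately tune nothing else.
Prediction calls a pair SL when the positive-class vote fraction reaches
0.5 (configurable). A fully constant feature matrix cannot be split by
any tree; training still succeeds (with a warning) by breaking the
degeneracy with an infinitesimal seeded jitter, yielding an honest
chance-level model.

`evaluateClassifier()` reports accuracy, precision, recall, F1,
specificity and AUC. Ratios with zero denominators are reported as `NA`
("not applicable"), never silently 0. AUC uses the rank-statistic
(Mann–Whitney) formulation with midranks for ties; the test suite
cross-checks it against an independent implementation (`pROC`).

The candidate universe for prediction is supplied by the caller (all
unordered pairs of eligible genes not already known, by default in the
benchmark). Published pipelines are ambiguous about their candidate
universe — the number of genes among predictions can exceed the number
of fully annotated genes — so the package exposes it as configuration
rather than hard-coding a resolution.

`mergeSLSets()` forms the union of the yeast-derived and predicted sets;
a pair supported by both routes keeps both provenance tags, and
$|A \cup B| = |A| + |B| - |A \cap B|$ holds by construction.

## Screening drug combinations

`filterTrials()` retains trials that are (i) phase III or IV, (ii)
interventional, (iii) carry at least one condition string equal —
case-insensitively and **exactly**, not as a substring — to one of six
controlled ovarian-cancer condition terms (`slConditionTerms()`), and
(iv) have at least one arm combining two or more drugs/biologicals.
Exact matching on the controlled terms is what excludes, say, a
hypertension trial that merely enrols ovarian-cancer patients.

`extractTestedCombinations()` resolves arm entries through a
case-insensitive name/synonym index; unresolvable names warn but never
abort, and an arm survives while at least two resolvable drugs remain.
Combinations are counted per distinct drug-id set with the number of
trials studying each. Regimens of more than two drugs are expanded to
all $\binom{n}{2}$ pairs (`expandPairwise()`).

A drug pair *addresses* an SL pair when one drug targets one partner and
the other drug the other partner, **and no single drug targets both**.
That exclusion is scoped to the whole tested-drug universe with protein
targets, not just the pair under evaluation — "no single drug available"
is read against the full drug set under study. Drugs without protein
targets (DNA cross-linkers and the like) cannot address an SL pair and
are excluded up front. Target directionality (inhibitor vs substrate) is
ignored. A drug pair may address several SL pairs; each match is a
separate row.

`proposeNovelCombinations()` applies the same matching to every untested
pair of the same drugs. `rankByAnnotationDegree()` scores each match by
the sum of the two partner genes' disease-specific publication counts
and sorts non-increasingly; ties break lexicographically on
(`gene_a`, `gene_b`, `drug_a`, `drug_b`) so output files are
deterministic. Genes missing from the count table score 0 with a
warning.

## The synthetic world

The generators in `generateWorld()` emulate the *statistical structure*
the classifier assumes — SL pairs share more annotation and sit closer
in the network — not any real database's marginals:

* a G(n, p) background network with extra edges planted on SL pairs
  (direct edge with probability `topology_boost`, otherwise a shared
  neighbour);
* per-gene, per-namespace random term sets, with extra *shared* terms on
  SL pairs at mean rate `annotation_overlap_boost` (0 gives a null world
  in which SL and non-SL Dice distributions coincide);
* a yeast screen in which planted pairs pass the default cutoffs and
  fillers mostly fail, with the exact pass-set recorded for oracle
  testing;
* ortholog tables that map the planted yeast pairs back to their human
  counterparts, split across three emulated resources;
* a drug/trial corpus with `n_planted_trials` combinations planted to
  address SL pairs (with the guarantee that no corpus drug covers both
  partners of a planted pair) and distractor trials that each violate at
  least one filter rule.

Default sizes — 200 genes, 40 SL pairs, 20 drugs, 30 trials — run the
full pipeline in seconds. The classifier benchmark
(`slBenchmarkConfig()`) uses 600 genes with 1,000 SL pairs confined to
one half of the genes, full annotation coverage, and 2,000 balanced
instances, a size at which one cross-validated grid search completes in
well under a minute; the SL-free half supplies the negatives. Everything
is deterministic under the master seed, and every generator records its
ground truth.

What passing tests on these worlds shows is that the pipeline recovers
planted structure of the kind it assumes; what they cannot show is
performance on real interactomes and annotation corpora, whose term
distributions are heavy-tailed and correlated across namespaces in ways
the generator does not imitate. Accuracy on the planted-signal benchmark
(≈ 0.99) is therefore a recovery check, not an estimate of real-world
accuracy; published figures on real corpora are substantially lower.

## Numerical and degenerate-input choices

* Canonical ordering is byte-wise lexicographic; all set operations key
  on it.
* The disconnected-path sentinel is the node count of the network.
* Empty-versus-empty Dice is 0.
* Cross-validation folds are stratified by class; fold assignment and
  tree growing are seeded, and the seeded pipeline is byte-identical
  across reruns.
* Rows with p-values outside $[0, 1]$, non-finite scores, or empty gene
  identifiers are rejected with a report of the offending rows rather
  than silently dropped.

## Known limitations

* SL transfer assumes yeast SL relations persist between human
  orthologs; cross-product expansion of one-to-many orthology
  over-generates pairs by design.
* Annotation-degree ranking is biased toward well-studied genes;
  enrichment-style corrections are out of scope here.
* The trial filter operates on structured condition strings; free-text
  registry exports would need upstream normalisation.
* Drug-name resolution is synonym-table driven; names absent from the
  table are warned about and skipped, never fuzzily matched.
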