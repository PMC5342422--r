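---
title: "Ranking candidate synthetic-lethal gene pairs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking candidate synthetic-lethal gene pairs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slrank)
```

## The problem

Two genes are *synthetic lethal* (SL) when losing either alone leaves a cell
viable but losing both kills it. In oncology this is a targeting principle:
a tumor that has already lost gene A through somatic mutation can be
attacked selectively with a drug against its SL partner B, sparing normal
cells that retain A. Genome-wide knock-down screens can find such pairs but
are slow and expensive in human cells, so computational pre-screening of
candidate pairs from tumor sequencing cohorts is attractive.

slrank implements a semi-supervised ranking pipeline for this pre-screening.
Its inputs are a binary gene-by-sample somatic mutation matrix and a paired
expression matrix from one cohort, a protein-interaction edge list, a list
of cancer biomarker genes used to filter that network, and a set of known
(positive) SL pairs. Its output is a ranking of screened candidate pairs by
their similarity, in a three-dimensional feature space, to the known
positives.

## Candidate screening

Mutation-based evidence for synthetic lethality is *mutual exclusivity*:
because simultaneous loss is lethal, tumors carrying both mutations should
be rarer than independence predicts. The screen works on the 2x2 per-pair
contingency of sample counts — `M` (both genes mutated), `N` (first only),
`X` (second only), `Y` (neither) — and applies three filters:

1. **Mutation-rate cutoff.** Only genes mutated in at least 1% of samples
   (`mutation_rate_cutoff`, inclusive) seed candidate pairs; each candidate
   gene is paired with every cancer-network gene present in the mutation
   matrix.
2. **Independence test.** A Pearson chi-square test on the 2x2 table with
   the Yates continuity correction (`max(0, |O - E| - 1/2)` before
   squaring); pairs with p-value at most `chi2_p_max = 0.05` (inclusive)
   are kept. The correction default matches the standard corrected 2x2
   routine in mainstream statistics libraries and can be disabled
   (`continuity = FALSE`).
3. **Exclusivity.** `(X + N) / (M + N + X)`, the fraction of mutated
   samples carrying exactly one of the two mutations, must reach
   `exclusivity_min = 0.8` (inclusive).

Pairs whose statistics are undefined — a zero row or column marginal for
the test, or no mutated sample at all for exclusivity — are excluded, not
imputed, and their count is reported. No multiple-testing correction is
applied at this stage: the screen is a recall-oriented prefilter whose
false positives are handled by the downstream ranking, not a hypothesis
test whose rejections are reported.

## The three features

Each screened candidate pair and each positive pair is described by three
quantities.

**Pair mutation coverage** — the fraction of samples mutated in at least
one member, `(M + N + X) / n`. Frequently hit pairs matter more
therapeutically and their exclusivity estimates are better supported.

**Driver score** — how strongly the pair's mutations are tied to expression
changes. A dedicated driver-discovery tool can be plugged in via
`driver_external` (a per-gene p-value table); the built-in scorer is a
deliberately simple greedy event cover:

* an *outlier event* is a (gene, sample) cell whose expression deviates
  from the gene's cohort mean by at least `outlier_z = 2` SDs (per-gene
  mean and SD, denominator n-1; inclusive threshold; zero-variance genes
  yield no events);
* a mutated gene *covers* an event in a mutated sample when the event gene
  is itself or one of its neighbors in the cancer network (the only
  interaction graph in scope, so it doubles as the influence graph);
* genes are selected greedily by uncovered-event coverage (ties broken
  lexicographically) until no event is coverable;
* each selected gene gets a permutation p-value with the add-one estimator
  `p = (1 + #{null coverage >= observed}) / (1 + permutations)` over
  `permutations = 100` relabelings of the mutation-matrix rows; unselected
  genes get p = 1. Observed and null coverage are both measured against the
  *full* event set — the greedy pass only decides which genes are scored —
  so the two sides of the comparison are exchangeable under the null.

The pair's score is `-log10` of the smaller of its two genes' p-values,
with p floored at `1e-16` (capping the score at 16). Note that with 100
permutations the smallest attainable p is about 0.01, so scores from the
built-in scorer top out near 2; the floor matters only for external input.
The scorer rewards genes whose mutation profile explains outlying
expression in their network neighborhood; because a widely mutated gene can
cover many events by profile size alone, the score partly tracks mutation
frequency — acceptable for a feature, but not a calibrated driver test.

**Network information centrality** — the system-level cost of deleting the
pair, mimicking the double knock-out. With network efficiency

$$E(G) = \frac{1}{N(N-1)} \sum_{i \ne j} \frac{1}{d_{ij}},$$

where $d_{ij}$ is the shortest-path length when j is reachable from i and
$D(G) + 1$ (network diameter plus one) otherwise, the centrality of a pair
is the relative efficiency drop after removing both genes:

$$C = \left| \frac{E(G) - E(G')}{E(G)} \right|.$$

Conventions, all forced by continuity of the definition and flagged here:
the diameter of a disconnected graph is the maximum over components (keeps
the penalty finite); $E(G')$ is evaluated with the *original* network's
penalty $D(G) + 1$, because a penalty recomputed on $G'$ would jump
discontinuously when a deletion disconnects the graph (the alternative is
available via `recompute_diameter = TRUE`); removing a gene absent from the
network is a no-op, so a pair with neither gene in the network scores 0;
a graph with fewer than two nodes has efficiency 0, so a removal that
empties the network scores exactly 1.

Each feature is min-max normalized to [0, 1] over the **union** of
positives and candidates. The ranker compares positives with candidates by
similarity, so both label groups must share one scale; normalizing per
group would erase exactly the differences the ranking exploits. A constant
feature maps to all zeros.

## Manifold ranking

Let $x_1 \dots x_q$ be the normalized feature triples of the positive pairs
and $x_{q+1} \dots x_n$ those of the candidates, with initial scores
$y = (1, \dots, 1, 0, \dots, 0)$. The affinity between points is cosine
similarity, $W_{ij} = \cos(x_i, x_j)$, $W_{ii} = 0$ — non-negative here
because the features are non-negative. (The defining phrase "one minus the
cosine distance" is ambiguous between similarity and distance; similarity
is the reading consistent with an affinity's role as a *relevance*, and the
opposite reading is available as `affinity = "cosine_distance"`.) A point
with zero norm — all three features at the minimum — has no direction and
gets zero affinity to everything.

With $L = D^{-1/2} W D^{-1/2}$ ($D$ the diagonal row-sum matrix; zero-sum
rows stay zero), scores diffuse by
$f^{t+1} = \alpha L f^t + (1 - \alpha) y$ from $f^0 = y$, converging for
$\alpha \in [0, 1)$ to

$$f^{*} = (1 - \alpha)(I - \alpha L)^{-1} y.$$

The closed form is the default solver (`solve` on $I - \alpha L$, which is
nonsingular because the spectral radius of $L$ is at most 1); the iteration
(tolerance `1e-9` on the max absolute change, capped at 10,000 steps) is
kept as an independent implementation and the two agree to `1e-6` in the
test suite. Zero-degree points receive $f^*_i = (1 - \alpha) y_i$, as the
update forces. For the repeated solves of cross-validation the package
eigendecomposes $L$ once and evaluates
$(I - \alpha L)^{-1} = V \operatorname{diag}\!\big(1/(1-\alpha\lambda_i)\big) V^\top$
per alpha and fold; the spectral route agrees with the direct solve to
`1e-9` in the tests.

Candidates are ranked by decreasing $f^*$; ties break on the canonical pair
identifier, making the ranking independent of input order. Known positives
are labeled, not ranked (a screened candidate identical to a positive is
re-labeled, so no pair is both); set `relabel_positives = FALSE` to rank
them instead.

## Evaluation

**NDCG@p.** With binary relevance $rel_i$ (held-out positive or not) down
the ranked list,

$$\mathrm{NDCG@}p = Z \sum_{i=1}^{p} \frac{2^{rel_i} - 1}{\log_2(i + 1)},$$

where $Z$ is the reciprocal of the ideal DCG obtained by placing
$\min(\text{total relevant}, p)$ relevant items at ranks $1, 2, \dots$ —
the ideal list is truncated, so a perfect ranking scores exactly 1.
Logarithms are base 2 throughout and $Z$ is exactly the reciprocal of the
truncated ideal; published NDCG variants normalize differently, so
cross-package comparisons should check conventions. This implementation is
verified against a brute-force evaluation of the definition on random
relevance lists.

**Hypergeometric enrichment.** For `N` ranked pairs containing `M`
positives, the probability of the observed count `k` of positives in the
top `n` is

$$p = 1 - \sum_{x=0}^{k} \frac{\binom{M}{x}\binom{N-M}{n-x}}{\binom{N}{n}},$$

the strictly-greater tail $P(K > k)$. That is the formula as commonly
printed in ranking-evaluation write-ups and it is the default; note it is 0
whenever every positive is captured, and the conventional tail
$P(K \ge k)$ is one flag away (`enrichment_tail = "geq"`).

**Cross-validation.** Positives are split into `cv_folds = 5` segments; in
turn each segment is held out and merged into the unlabeled set, the rest
train the diffusion, and NDCG@p plus enrichment (with n = p, N = the
evaluation-list size, M = the held-out count) measure where the held-out
positives land. The split is reshuffled `cv_shuffles = 10` times and all 50
fold evaluations are averaged. The depth p defaults to the held-out count —
the natural "could all held-out pairs be on top" depth — and can be pinned
with `top_k`. `optimize_alpha()` repeats this at every grid alpha
(default 0 to 0.99, step 0.01) on the *same* folds and returns the alpha
maximizing mean NDCG, ties to the smallest; the final model then trains on
all positives at that alpha.

Two validation utilities accompany the ranking: a one-sided Welch t test
comparing drug sensitivity between partner-mutated and wild-type cell lines
(orientation set by whether the readout grows or shrinks with sensitivity —
PIC50 up, z-scored GI50 down; the test behind published group comparisons
of this kind is rarely named, so the Welch default is a documented choice),
and the treated-to-placebo relative-growth ratio for knock-down
experiments.

## The synthetic cohort generator

Real inputs of this pipeline are controlled-access tumor cohorts and
licensed interaction/biomarker databases, so the package ships a seeded
generator that reproduces the *statistical structure* the pipeline relies
on, making every stage testable offline.

| parameter | default | what it emulates |
|---|---|---|
| `n_samples` | 200 | a mid-sized tumor cohort with both assays |
| `n_genes` | 300 | the screened gene universe |
| `background_rate` | 0.02 | sparse passenger mutations |
| `n_planted_pairs` | 10 | the known SL pairs |
| `exclusivity_level` | 0.9 | fraction of pair events hitting one member |
| `planted_rate` | 0.45 | per-gene mutation rate of planted members |
| `driver_effect` | 3 SD | expression shift on neighbors of mutated drivers |
| `n_net_genes`, `pa_edges` | 100, 2 | preferential-attachment interaction net |
| `biomarker_fraction` | 0.8 | biomarker list covering part of the network |

Planted exclusivity is generated constructively rather than by rejection:
per sample a pair-level event occurs with rate
`planted_rate / (1 - exclusivity_level/2)`, hitting exactly one member
(50/50) with probability `exclusivity_level` and both otherwise. This gives
direct control of `M`, `N`, `X`: the pair's empirical exclusivity
concentrates on the configured level and its co-mutation count sits far
below the independence expectation.

The planted per-gene rate of 0.45 deserves a comment. The chi-square screen
detects exclusivity as a *deficit* of co-mutation, and for a cohort of 200
samples the independence expectation `rate^2 x n` only rises far enough
above the constructive co-mutation count when the marginal rate is roughly
0.35 or higher. The default therefore emulates pairs of frequently mutated
driver genes (rates seen for the most recurrently mutated tumor
suppressors), which is also the regime where exclusivity analysis is
informative in real cohorts; at passenger-like rates the 2x2 test has
essentially no power at this cohort size, whatever the generator does.

What the generator does **not** emulate: mutational signatures and
hypermutators, copy-number loss (a major real source of second hits),
subclonality, correlated expression programs, batch effects, and the
degree structure of curated interaction databases. One interaction of the
defaults is worth knowing: with 45% of samples mutated, the mean shift on
a driver's neighbors inflates the neighbor gene's own SD enough that the
z-score outlier layer cannot flag the shifted samples (the attainable |z|
plateaus near 1.1), so on the default cohort the driver feature separates
planted pairs through profile-size effects rather than through the planted
expression link; the expression-driven path is exercised by dedicated
low-mutation-rate constructions in the test suite. Passing tests on this
cohort therefore demonstrate the pipeline's mechanics and its behavior
under the stated statistical structure — not performance on real tumor
data.

## Numerical choices and degenerate inputs

* Threshold comparisons in the screen are inclusive on both sides, as the
  operator symbols state.
* Driver p-values use the add-one permutation estimator, so p = 0 is
  unattainable; external p-values are floored at `1e-16` before `-log10`.
* Tables with a zero marginal, pairs with no mutated sample, and
  constant-expression genes produce no statistic rather than an imputed
  one.
* An empty biomarker-filtered network, an empty sample intersection, and
  an empty post-screen candidate set are errors, not silent empties.
* All randomness (cohort generation, CV shuffles, permutation nulls, the
  label-permuted baseline) derives from explicit integer seeds; reruns with
  the same configuration and seed are byte-identical, including the ranked
  output files, which are written with a fixed numeric format.
* Rank ties (identical $f^*$) break on the lexicographic pair identifier.

## Problem sizes used for validation

The shipped test and validation runs use the default 200 x 300 cohort
(roughly 150-170 screened candidates from ~19,000 raw pairs), 100 random
diffusion problems up to n = 200, exhaustive hypergeometric checks up to
N = 12, and 50 random graphs up to 30 nodes against a hand-written BFS
oracle — sizes at which every oracle is exact and the full suite runs in
about a minute.

## Known limitations

* With few positives the CV depth p (= held-out count) is small; NDCG at
  depth 2 is high-variance, and alpha optimization against it can select an
  over-diffuse alpha on some datasets. With positive sets of realistic size
  (tens to hundreds of pairs) the depth grows and the optimization
  stabilizes. A fixed `top_k` is the escape hatch for small positive sets.
* The built-in driver scorer is a feature generator, not a calibrated
  driver-discovery method; plug in a dedicated tool's per-gene p-values via
  `driver_external` when available.
* Screening p-values are not corrected for multiple testing by design; do
  not interpret them as cohort-level discoveries.
* Gene symbols are matched case-sensitively after whitespace stripping, and
  mutation matrices must be binarized upstream; no identifier translation
  or variant-annotation parsing is attempted.
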