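---
title: "Correlation-based semantic networks from verbal fluency data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-based semantic networks from verbal fluency data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

A timed semantic verbal-fluency task ("name as many animals as you can in
one minute") yields an ordered word list per subject. `fluencynet` turns the
lists of a whole group into a single semantic network and provides the
statistical machinery to compare two groups' networks — the design used to
compare children with cochlear implants (CI) against normal-hearing (NH)
peers, where group-level network structure, not raw word counts, is the
quantity of interest.

The pipeline:

1. **Incidence coding.** Responses become a binary subjects × words matrix:
   cell $(i, j) = 1$ iff subject $i$ produced word $j$ (repetitions collapse;
   order is stored but not analyzed). The vocabulary is sorted
   lexicographically so every later tie-break is reproducible.
2. **Word correlations.** Association between words $i$ and $j$ is the
   Pearson correlation of their binary response profiles across subjects —
   equivalently the phi coefficient of the $2 \times 2$ co-occurrence
   table. Words produced by every subject or by none have undefined
   correlations; they are excluded and reported, never silently kept.
3. **PMFG filtering.** The complete weighted correlation graph is reduced
   to its Planar Maximally Filtered Graph: candidate edges are ranked by
   correlation (descending) and inserted whenever the graph stays planar,
   stopping at the maximal planar edge count $3(N-2)$. Edges are then
   binarized to weight 1. The PMFG is always connected, so path metrics are
   well defined.
4. **Small-world statistics.** $N$, average shortest path length $L$,
   diameter $D$, mean local clustering $CC$, mean degree
   $\langle k \rangle = 6(N-2)/N$ (forced by the PMFG edge count), the
   Erdős–Rényi reference values $CC_{rand}, L_{rand}$ at matched size and
   density, and small-world-ness
   $S = (CC/CC_{rand}) / (L/L_{rand})$, with $S > 1$ read as small-world.
5. **Inference.** Three group-comparison instruments: (a) empirical
   p-values of each observed metric against 10,000 matched $G(n,p)$
   realizations; (b) a bootstrap over random word subsets, rebuilding each
   group's partial PMFG per draw and comparing metric distributions with
   pooled t-tests; (c) leave-one-word-out *impact scores*
   $WC(i) = L_{-i} - L$, compared between groups word by word.

Two vocabularies are supported: sample-matched networks (SMCN; each group's
full lexicon) and word-matched networks (WMCN; words produced by at least
`min_subjects = 2` subjects in *each* group), the latter enabling direct
comparison because both groups share node sets.

## Planarity testing

PMFG construction needs a planarity oracle at every candidate edge. The
package implements the left-right (de Fraysseix–Rosenstiehl) criterion in
C++, linear in graph size, so a 132-word network filters in well under a
second. The test suite cross-checks it against a brute-force
Kuratowski-subdivision search (reduce by smoothing low-degree vertices,
then exhaustively search for $K_5$/$K_{3,3}$ subdivisions) on hundreds of
random graphs, and verifies PMFG maximality by confirming that every absent
edge breaks planarity.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_subjects` | 2 | per-group production threshold for the word-matched vocabulary |
| edge ranking | signed | PMFG ranks by signed correlation, descending; negative correlations enter only if needed to reach $3(N-2)$ edges |
| tie-breaking | lexicographic | binary profiles from 27 subjects produce many exactly tied correlations; ties resolve by word pair, making the network a deterministic function of the data |
| `er_realizations` | 10,000 | null-model draws per network |
| `disconnection` | largest_component | sparse $G(n,p)$ draws are disconnected with non-negligible probability (≈ 16 % at $n = 75$, $p = 219/2775$); path metrics then use the largest component, and the affected fraction is reported. A `resample` policy (condition on connectivity) is available; both give practically identical means |
| `subset_size` | 40 | bootstrap words per partial network; when the vocabulary is smaller than 75 the pipeline keeps the 40-of-75 ratio instead |
| `subsets` | shared | one subset per realization, used for both groups (removes between-group subset noise); `independent` and `exhaustive` modes exist |
| `reference` | mean | $CC_{rand}, L_{rand}$ average 100 seeded ER draws rather than a single realization — more stable; `single` reproduces the one-draw convention |

## Numerical and statistical conventions

- **ASPL** is the mean over unordered pairs of distinct nodes. Note that a
  widely used Matlab connectivity toolbox of the study's era averaged the
  full distance matrix *including the zero diagonal*, i.e. reported
  $\frac{n-1}{n} L$. At $n = 75$ the matched-null ASPL mean is 2.61 by the
  distinct-pair definition and $2.61 \times 74/75 = 2.58$ under that
  convention — exactly the published reference value. The acceptance tests
  compare through this convention; the package API keeps the standard
  definition.
- **Clustering** of a degree-< 2 node is 0 (cannot occur inside a PMFG with
  $N \ge 4$, but the metric is general-purpose). The reference null sd of
  CC at $n = 75$ is ≈ 0.016 under every ensemble we simulated ($G(n,p)$,
  fixed edge count, connected-only); the published 0.01 is not recoverable
  and is left as a documented discrepancy.
- **Empirical p-values** use add-one smoothing,
  $(1 + \#\{\text{as extreme}\}) / (R + 1)$, so an observation beyond all
  10,000 draws reports $1/10001 < 0.001$, never 0.
- **t-tests** are pooled-variance independent two-sample tests
  ($df = n_x + n_y - 2$; 75-word impact vectors give $df = 148$). Both the
  bootstrap comparison (which treats bootstrap replicates of two *fixed*
  datasets as independent observations) and the impact comparison (75
  correlated words per group) violate the independence assumption. Under
  exchangeable groups drawn from identical generator settings we measured
  type-I error well above nominal (impact ≈ 0.4, bootstrap L/CC ≈ 0.3 at
  $\alpha = 0.05$ over 50 replicates). The tests are reported as-printed
  for comparability, and their p-values should be read as descriptive; the
  corresponding nominal-calibration acceptance test is deliberately left
  failing as a record of this property.
- **Impact scores** default to *rebuild* semantics: the word is removed
  from the correlation matrix and the PMFG is re-filtered from scratch.
  Re-filtering can recover alternative routes, so a bridging word's removal
  is partly compensated; under the non-canonical `subgraph` mode (plain
  node deletion) planted bridge words rank in the top impact decile in
  20/20 seeded constructions, while under rebuild they do so only about 60
  % of the time. Choose the mode to match the question: lexicon change
  (rebuild) versus pure topology (subgraph).
- **Zero-variance words** after vocabulary restriction are excluded per
  group; the word-matched pipeline then intersects the two groups'
  surviving vocabularies so all comparisons stay word-aligned.

## The synthetic generator

No raw responses are distributed with the study design this package
implements, so a clustering-and-switching generator supplies test data.
Each subject knows a personal subset of a structured lexicon (12 animal-like
subcategories, 194 words; knowledge probability decays with within-category
frequency rank as `p_know * rank^-know_decay`), then emits words by a walk:
sample within the current subcategory proportionally to Zipf-like weights
(`rank^-zipf_exponent`, without replacement), switch subcategories with
probability `p_switch` after each emission or on exhaustion, stop at a
Gaussian per-subject retrieval length. The walk makes subjects who produce
one member of a subcategory likely to produce its neighbours — precisely the
co-occurrence correlation the analysis assumes.

The shipped profiles encode the behavioural group difference as coverage
plus retrieval length only (NH-like: `p_know` 0.95, 16 ± 4 words; CI-like:
`p_know` 0.75, 10 ± 3 words) and were calibrated once so 27-subject groups
produce on the order of 132 and 106 distinct words (± 25 % over 20 seeds).
No claim is made that a particular parameter regime reproduces the
direction of the published group differences in L or D — that is an
empirical output of a run, not an assertion.

What the generator does *not* emulate, hence what passing tests do not show
about real data: words never belong to two subcategories (no polysemous
bridges), knowledge is independent across subjects given rank, there are no
perseverations or intrusions, and the shared ≥ 2-subjects-per-group
vocabulary plateaus near ~45 words — smaller than the 75 of the real study
relative to lexicon size. Distribution-level conclusions about real fluency
data should not be read off synthetic runs.

## Problem sizes in the shipped checks

The test suite exercises full study-scale networks where the quantity is
cheap (PMFG invariants up to 132 nodes, including a complete
absent-edge maximality scan; the 10,000-realization null at $n = 75$) and
reduced sizes where it is not (bootstrap toy enumeration on 6 words;
null-calibration replicates with 16-subject groups over a 50-word lexicon
and 50 bootstrap draws). The analysis scripts default to 10,000 null
realizations and 2,000 bootstrap realizations.

## Known limitations

- Association is phi only; co-occurrence-adjacency or Jaccard schemes are
  explicit non-features, as are TMFG/threshold filters, weighted-path
  metrics and degree-preserving nulls.
- The PMFG edge-ranking and tie-breaking conventions are package decisions
  (signed ranking, lexicographic ties); the source analyses did not state
  theirs, so exact edge sets need not coincide even on identical data.
- Group comparisons inherit the anticonservative as-printed t-test designs
  discussed above.
- Spelling-variant merging is exact-match after trimming and case-folding
  unless a user-supplied variant table is given.
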