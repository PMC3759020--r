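# fluencynet

Semantic-network analysis of timed verbal-fluency data in R: from
per-subject word lists to planar filtered word networks, small-world
statistics, random-graph null models, bootstrapped group comparison and
node-removal word-impact scores.

## The problem

In a semantic fluency task, subjects name as many members of a category
(classically *animals*) as they can in 60 seconds. Clinical and
developmental researchers use such data to ask whether two groups — e.g.
children with cochlear implants versus normal-hearing peers — differ not
just in how *many* words they produce but in how their mental lexicon is
*organized*. `fluencynet` implements a correlation-based network approach
to that question for anyone comparing the group-level semantic structure of
two samples.

## The method

For each group, responses are coded into a binary subjects × words matrix
(`1` iff subject *i* produced word *j*). The association between two words
is the Pearson correlation of their response profiles,

    C(i, j) = cor(x_i, x_j)        (the phi coefficient for binary profiles)

which defines a complete weighted word graph. That graph is filtered to its
**Planar Maximally Filtered Graph** (PMFG): edges are inserted in
descending correlation order whenever planarity is preserved, giving a
connected planar backbone with exactly 3(N − 2) edges, then binarized. Each
network is summarized by its average shortest path length *L*, diameter
*D*, clustering coefficient *CC*, mean degree ⟨k⟩ = 6(N − 2)/N, and
small-world-ness

    S = (CC / CC_rand) / (L / L_rand),   S > 1  =>  small-world,

with CC_rand, L_rand from Erdős–Rényi graphs matched in size and density.
Group inference uses (a) empirical p-values against 10,000 matched G(n, p)
realizations, (b) a bootstrap over random word subsets with the partial
PMFG rebuilt per draw, and (c) leave-one-word-out impact scores
WC(i) = L(−i) − L compared across groups. A clustering-and-switching
generator (subcategory walks over a Zipf-weighted lexicon) produces
realistic two-group synthetic datasets, since raw fluency responses are
rarely shareable.

The planarity test behind the PMFG — the left-right
(de Fraysseix–Rosenstiehl) criterion — is implemented in C++ and verified
against a brute-force Kuratowski-subdivision oracle in the test suite.

## Worked example

The `analysis/` directory holds the full workflow as numbered scripts
(`01_simulate.R` … `06_impact.R`), each a thin driver over the package.
Running them in order writes every table under `results/`. Abridged output
of a run with the shipped profiles (seed 1):

```
$ Rscript analysis/01_simulate.R
group NH: 27 subjects, 120 distinct words, 14.9 words/subject
group CI: 27 subjects, 98 distinct words, 9.4 words/subject

$ Rscript analysis/02_networks.R
word-matched vocabulary: 38 words common to both groups
group CI: PMFG with 38 nodes, 108 edges (mean degree 5.68)
group NH: PMFG with 38 nodes, 108 edges (mean degree 5.68)

$ Rscript analysis/03_metrics.R
CI: N=38 L=2.684 D=6 CC=0.638 <k>=5.68 CCrand=0.142 Lrand=2.242 S=3.75  (small-world)
NH: N=38 L=2.593 D=6 CC=0.614 <k>=5.68 CCrand=0.142 Lrand=2.242 S=3.74  (small-world)

$ Rscript analysis/04_null_er.R
CI: observed L=2.684 D=6 CC=0.638 -> empirical p = 0.0005 / 0.012 / 0.0001
NH: observed L=2.593 D=6 CC=0.614 -> empirical p = 0.003 / 0.011 / 0.0001

$ Rscript analysis/06_impact.R
CI: mean impact -0.0283, 10/38 words positive, strongest |wc| = ocean02
NH: mean impact -0.0008, 14/38 words positive, strongest |wc| = fish03
group comparison: t(74) = -1.559, p = 0.123
```

Reading: both synthetic groups form small-world networks (S ≈ 3.7, CC far
above the matched random reference), their clustering and path lengths sit
well outside the Erdős–Rényi null, and — as expected for two draws from
similar generator settings — the word-impact comparison finds no reliable
group difference. The same functions accept real data via
`read_fluency()` on a long-format CSV/JSON (`group, subject, order, word`).

Equivalently, `run_pipeline(pipeline_config(seed = 1))` executes all stages
in one call and writes the same bundle plus a reproducibility manifest.

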