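---
title: "Predicting drug-target interactions over a bipartite similarity network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-target interactions over a bipartite similarity network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketpath)
library(dplyr)
```

## The model

pocketpath implements a comparative-docking strategy for target
identification. The driving assumption is transitivity of molecular
recognition: structurally similar binding pockets bind chemically similar
ligands. Instead of docking a query compound into every candidate pocket,
the method organizes all available evidence into one weighted bipartite
network and reads predictions off shortest paths:

* **Ligand partition.** Small molecules observed in complexes, filtered for
  drug-likeness (wQED &ge; 0.35, the weighted quantitative estimate of
  drug-likeness, consumed as an input column). Edges between compounds carry
  the probability, from a random-forest pair classifier, that the two
  molecules bind the same kind of pocket.
* **Binding-site partition.** Ligand-binding pockets (a pocket is a residue
  set around a bound ligand), connected when a structural pocket comparison
  reports a similarity Z-score strictly above 2.
* **Interaction edges.** A ligand and a pocket are joined when they have
  been observed together in a solved complex. These cross the partitions;
  similarity edges never do.

Each sub-network is condensed before assembly: mutually similar nodes
collapse into one cluster vertex, and a cluster pair inherits the
**maximum** similarity over its crossing member edges. Two cluster
definitions are provided because the two natural readings of "a group in
which every pair is similar" differ: `clique` mode (default; a greedy
maximal-clique cover, largest clique first, lexicographic tie-break) makes
that property literally true inside every cluster, while `kcore` mode
(connected components of the k-core, default k = 2) reproduces the looser
degree-based definition sometimes used for the same purpose. Both modes
produce a partition — overlaps are resolved greedily and deterministically —
because path semantics need each compound to live in exactly one vertex.

Modeled pockets of the target proteome enter through a filter cascade:
model quality &ge; 1.1 (a ModPipe-style composite), site sequence **and**
structure identity to some known pocket both strictly above 40% (structure
identity: fraction of C&alpha; atoms within 4 &Aring; after superposition),
at least 6 residues, and no more than 80% sequence identity to an
already-kept site (scanned by descending residue count, then id, so the
result is order-independent and deterministic). Survivors attach to the
site partition with edges for comparisons with Z &gt; 1, weighted by the
normalized Z-score.

Query compounds attach to the ligand partition through the pair
classifier: per ligand cluster only the best-probability member link is
kept; a query identical to a network compound (canonical SMILES equality)
gets similarity exactly 1, which the benchmark's identity-exclusion rule
later removes.

## Scoring

Every similarity *s* becomes a distance *1/s* (clamped into
(10^-6^, 1]), so each hop costs at least 1 and high-similarity hops are
cheap. From each query, a distance-bounded Dijkstra search (default bound
`d_max = 10`) finds the shortest path to every reachable modeled pocket.
Ties are broken toward fewer hops, then the lexicographically smallest node
sequence, so reported paths are reproducible. A hit's raw score is

> s = 1 / (sum of edge distances along the path), in (0, 1],

optionally min-max normalized over the run (the default; Z-scores are
invariant to this affine choice, only the reported normalized column
changes). Two standardizations give the scores their meaning:

* **Global Z** — s standardized by the mean and population standard
  deviation of all scores in the run: how good is this hit compared with
  everything the network proposes.
* **Local Z** — s standardized within the score population of one target
  site (or protein, configurable): flags promiscuous pockets, which collect
  many moderate hits and inflate their local mean.

Zero-spread groups yield Z = 0 with a warning. Per-protein results
aggregate by the best pocket (maximum score over the protein's sites).

A random-forest meta-classifier turns (s, Gz, Lz) into a binder /
non-binder call (500 trees, probability forest, inclusive 0.5 threshold;
all configurable). Two variants are trained: an *anonymous* model using
only the three scores, and an *identity-aware* model that additionally
receives the query compound identity as a hashed categorical feature
(64 buckets, outcome-ordered factor splits). The identity-aware model can
calibrate away per-compound score offsets and memorize per-compound base
rates, so it outperforms the anonymous one whenever the same compounds
appear in training and test — which is exactly why the anonymous variant is
the honest estimate for never-seen compounds. Performance is estimated by
stratified 10-fold cross-validation (precision, recall, AUC per fold);
single-score baselines are evaluated as single-feature forests under the
identical protocol, so all comparisons are like for like.

## The synthetic universe

Nothing in the pipeline requires external databases: `generate_universe()`
draws a complete input set with the statistical structure the method
assumes. Compounds belong to scaffold families (similarity within a family
~ Beta(16, 4), across ~ Beta(4, 16), plus Gaussian jitter, sd 0.05);
pockets belong to classes (within-class Z ~ N(4, 1), across ~ N(0, 1));
each class is bound by one or two scaffolds and each candidate complex is
observed with probability 0.9. Queries are new members of existing
families. Planted truth is the set of (query, modeled-target) pairs
connected through family/class co-membership, restricted to targets that
survive the integration filters (the generator re-derives the survivor set
arithmetically, which doubles as an independent check of the pipeline's
cascade). Generated SMILES (decorated scaffold cores) exercise the real
chemistry path; precomputed similarity tables exercise the bypass path.

Three deliberate imperfection mechanisms make the synthetic benchmark
behave like the method's intended regime rather than a noiseless toy:

* `cross_class_noise` (default 0.05) replaces that fraction of cross-family
  comparisons with spurious borderline similarities — ligand draws
  Beta(6, 10), site Z draws N(2.5, 1) truncated at 3.5. False matches sit
  near the detection threshold, as false positives of similarity searches
  do; raising the knob monotonically degrades recovery.
* every modeled pocket has a base accuracy (Z offset ~ N(4, 0.8), shared by
  all of its comparisons), giving each target a systematic score offset —
  the situation the local Z-score exists to cancel;
* every query has a representation-quality factor (U(0.90, 1.05) on its
  similarities), giving each compound a systematic offset — the situation
  the identity-aware classifier exists to calibrate.

A fifth of pocket classes are promiscuous: their modeled sites draw
spurious similarity from all classes at an elevated rate (+0.4), creating
the promiscuous-pocket confusions the local Z-score is designed to flag.
At these defaults (8 scaffolds x 6 ligands, 10 classes x 5 sites, 30
queries, seed 7) the problem sizes keep a full pipeline run in a few
seconds, which is what the test suite and the acceptance script use.

What passing on this universe does **not** show: real chemical similarity
is not scaffold-block-structured, real pocket comparisons have heavier
tails, interaction data are far sparser and biased toward well-studied
targets, and real wQED values correlate with structure rather than being
drawn independently. The synthetic results validate the machinery and its
qualitative behaviour, not absolute real-data performance.

## Numerical and design choices

* Distance clamp 10^-6^: near-zero similarities become effectively
  unreachable rather than infinite.
* `normalize_z(z) = z / (z + z_ref)`: the literature reports "normalized
  Z-score" weights without a formula; this map is bounded, strictly
  increasing, parameter-light, and equals 0.5 at the acceptance threshold
  of its context (z_ref = 2 within the known-site network, 1 for modeled
  sites). It is exposed as a function so users can substitute their own.
* Interaction edges carry distance exactly 1: an observed complex is a
  maximal-confidence hop; no weight is defined for it by the similarity
  machinery.
* `d_max = 10` allows roughly four to five moderate-similarity hops; the
  bound exists to keep proteome-scale searches fast and to stop similarity
  evidence from propagating arbitrarily far.
* Symmetric duplicate similarity rows resolve to the maximum, consistent
  with the max-weight cluster-edge convention.
* Z-scores use the population (divide-by-n) standard deviation: the run's
  predictions are the population being standardized, not a sample.
* Local Z defaults to per-site statistics; per-protein pooling is a flag
  (`local_by = "protein"`), since either granularity is defensible.
* Degenerate inputs: empty prediction sets are fatal; single-member or
  constant score groups give Z = 0 with a warning; an empty network
  serializes and round-trips.
* The classification threshold is inclusive at 0.5 (a documented tie
  rule); ROC sweeps use every distinct score value plus infinite
  endpoints, so AUC is exact, and truth pairs never reached by a
  prediction enter the ranking at -Inf as false negatives.
* Benchmark truth matching is protein-level by default (positives are
  drug-protein pairs; a site hit counts for its parent protein), with a
  strict site-level mode available.

## Limitations

* The pair classifier shipped here is trained on synthetic or
  user-supplied labels; reproducing a production compound-pair classifier
  requires its original training corpus.
* Clique cover and k-core condensation are heuristics; neither optimizes
  any global objective, and cluster identity can shift when edges near the
  similarity threshold flip.
* The bounded search returns one shortest path per target; near-optimal
  alternative paths (which might carry complementary evidence) are not
  aggregated.
* Scores are comparable only within a run: min-max normalization and both
  Z-scores are population-relative by construction.
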