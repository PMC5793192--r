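---
title: "ShewEETNet: methods, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ShewEETNet: methods, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ShewEETNet implements a network-based search for the proteins that switch
state when *Shewanella oneidensis* MR-1 activates extracellular electron
transfer (EET). This vignette is the package's own account of the methods:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the decisions taken
where the design was genuinely open.

# Active-protein identification

## Model

The input is a protein × 6 abundance matrix over an ordered aerobic →
anaerobic time course: samples S1–S3 are steady states under high oxygen,
S4–S6 under low oxygen. The EET activation happens between S3 and S4, so the
proteins of interest are those whose trajectory steps sharply there.

Three steps:

1. **Zero filtering** (`filterUnexpressed`). Rows that are exactly zero in
   all six samples are never-expressed proteins and are removed. Only the
   all-zero pattern is treated as missing; no other missing-value mechanism
   is modelled.
2. **Row standardization** (`standardizeProfiles`). Each trajectory is
   scaled to mean 0, sd 1, the canonical preprocessing for soft clustering
   of expression profiles: cluster membership should be driven by trajectory
   *shape*, not absolute copy number. Constant rows cannot be standardized
   and are dropped with a warning. A consequence worth knowing: a protein
   whose true trajectory is flat is reduced to pure noise by this transform,
   so flat proteins scatter over clusters rather than forming one. The
   sharp-cluster selection below is robust to this (a few flat proteins ride
   along in each cluster; the sharp proteins themselves are what the rule
   keys on), but *overall* per-protein label recovery in benchmarks should
   be read with that in mind.
3. **Fuzzy c-means** (`fuzzyCMeans`). Standard alternating optimization on
   Euclidean distance, memberships $u_{ij} \propto (1/d_{ij}^2)^{1/(m-1)}$
   normalized per protein, centroids as $u^m$-weighted means, objective
   $J = \sum_{ij} u_{ij}^m d_{ij}^2$. Defaults $c = 4$ and $m = 1.5$ are the
   standard settings for four expected archetypes over six samples; $m$
   close to 1 keeps memberships crisp enough for meaningful hard labels
   while still exposing gradations.

## Numerical choices

* Initialization: k-means++-style seeding on the standardized rows, driven
  by the user seed — reproducible and resistant to degenerate starts.
* `nstart = 5` independent restarts; the run with the lowest final objective
  wins. Fuzzy c-means is a local optimizer and single starts occasionally
  merge two archetypes; five restarts make that failure mode negligible at
  this problem size while staying cheap.
* Convergence: objective change below `tol = 1e-6`, cap `maxIter = 1000`,
  warning (not error) on non-convergence.
* A point falling exactly on a centroid (distance 0, as happens with
  noiseless data) receives membership 1 there — the standard singularity
  rule of fuzzy c-means.
* Hard-label ties break to the lowest cluster index, for determinism.

## The sharp-transition rule

`identifyActiveClusters` quantifies "sharp change between S3 and S4": a
cluster is sharp iff the |S3→S4| step of its centroid is (a) its largest
consecutive step and (b) more than `sharpRatio` times its largest *other*
consecutive step. `sharpRatio = 2` separates the step archetypes (whose
other steps are near 0) from the gradual ones (whose steps are roughly
equal); it is exposed because "sharp" is a judgment call, and the error
message lists all centroid steps so a caller can recalibrate. Sharp clusters
with a negative step feed the down set, positive the up set; if several
clusters of one sign qualify, all of their members are taken.

# Network construction

Edges carry confidence scores in [0, 1] (an integer 0–999 dialect is
auto-detected on input and divided by 1000). Filtering uses an inclusive
cutoff (score ≥ threshold) at the six conventional thresholds 0.4–0.9, so
higher-threshold networks are always subsets of lower-threshold ones.

The active subnetwork keeps edges whose **both** endpoints are active.
Active proteins with no surviving interaction are kept as *isolates* and
reported separately, so network sizes can be stated with and without them;
the smallest with-isolates size across the series drives the shared
selection size k below. Regulatory arcs are kept when both TF and target
belong to the active network (connected or isolated); this both-endpoint
rule is the default and a `rule = "either"` variant is provided, because
the verbal definition of "active regulatory interaction" is ambiguous
between the two readings.

Integration keeps the layers distinct over one node set. In the arc
accounting a PPI edge is two directed arcs and a regulatory arc is one:
`totalArcs = 2·|PPI| + |reg|`, asserted in every constructed network. A
pair connected in both layers is *not* deduplicated at this stage.

Duplicate input edges resolve to the last occurrence, with a warning.

# Centrality ranking

Hubs and bottlenecks are captured by degree and unweighted betweenness on
the undirected active PPI layer — centrality precedes integration in the
pipeline, and isolates are excluded since they cannot be either. Both
centralities get fractional (average) ranks, 1 = most central; the ranking
statistic is the mean of the two ranks. Residual ties break by protein id.

The selection size is one k for all six networks:
`k = max(1, round(percent · N_min))` with `percent = 0.02` and N_min the
smallest with-isolates node count — using one k keeps the per-network lists
comparable. Frequency aggregation counts, per protein, how many per-network
key lists contain it; within equal frequencies the mean within-list rank
orders the table (then id). The tie-break is a package choice — frequency
alone is the defined statistic, the rest is presentation determinism.

# Motif analysis

## Mixed-graph triads

The integrated network is a mixed graph: a PPI edge is modelled as a mutual
arc pair, a regulatory arc as a single arc. Between two nodes the state is
none / single (either direction) / mutual. Two degenerate situations are
resolved before analysis:

* a pair carrying both a PPI edge and a regulatory arc has no slot in the
  mutual/single dichotomy; the PPI edge wins, the arc is dropped from motif
  analysis, and the affected fraction is reported (`nHybrid`);
* two opposing regulatory arcs on one pair form a mutual pattern and are
  promoted to the mutual layer.

There are 13 isomorphism classes of connected 3-node mixed graphs. Each is
given a canonical code — the minimum over vertex orderings of a base-4
encoding of the three pair states — plus a display name ("Co-regulated
PPI", "Protein Clique", "Bi-feedforward Loop", …). The names are bound to
explicit structural definitions in `triadPatterns`; for example
"Bi-feedforward Loop" is a PPI pair that both regulate a third protein,
"Feedback with a PPI" a directed cycle through a PPI edge, and "PPI
Regulating" / "Regulated PPI" distinguish an arc leaving versus entering a
PPI pair. Classification is label-invariant by construction (tested
exhaustively over all 64 pair-state combinations).

The census enumerates every connected induced 3-node subgraph exactly once
(paths counted at their centre node, triangles at their least node) in a
C++ kernel, and is verified against an all-triples R oracle.

## Null model and significance

The null preserves every node's (single-in, single-out, mutual) degree
triple exactly: single arcs swap only with single arcs, mutual pairs only
with mutual pairs, and a proposed swap is rejected if it would create a
self-loop, a duplicate, or any connection on an already-connected pair — so
the layers never merge. Defaults are 1000 randomizations with
100 · (|edges| + |arcs|) swap attempts each, both configurable; the
attempt multiple is the common choice for switching nulls and empirically
drives the edge-set Jaccard overlap with the original below 0.5.

Per class: $z = (\text{real} - \bar{c}_{null})/s_{null}$ and one-sided
empirical $p = $ fraction of null counts ≥ the real count
(over-representation; the ≤ direction is reported as `pUnder` but never
called active). When $s_{null} = 0$, z is reported as ±Inf (or 0 if real
equals the null mean) and the empirical p remains valid.

A class is an **active motif** when significant (z > 2, p < 0.05) in at
least `quorum = 5` of the 6 thresholded networks — "all or most", with most
meaning 5. **Exclusive** motifs are active classes absent from a supplied
conserved-class list (an input file; deriving it is out of scope).

# Module detection

Modules are sought in the undirected PPI subnetwork among the
motif-involved proteins, restricted to its largest connected component
(ties broken toward the component containing the smallest node id).

`annealModules` maximizes Newman–Girvan modularity
$M = \sum_i (e_{ii} - a_i^2)$ by simulated annealing from a singleton
start: single-node moves (including into a fresh module), plus occasional
pairwise merges and random splits as collective moves, with Metropolis
acceptance $\exp(\Delta M/T)$ and geometric cooling. Schedule defaults:

* T0 calibrated so ≈ half of initially worsening node moves are accepted
  (measured on 200 probe moves);
* cooling factor 0.995;
* n² node-move proposals per temperature (capped at 20 000), plus ~n/2
  collective proposals;
* stop after 50 temperatures without improvement of the best M (or 3000
  temperatures).

The best-seen partition is returned; its M is recomputed exactly by direct
summation before return, and a partition worse than the single-module
baseline (M = 0) is replaced by that baseline. An independent
direct-summation oracle and igraph's modularity agree with the reported M
in the test suite.

# Enrichment

One-sided hypergeometric upper-tail tests ($P[X \ge k]$) per annotation
term, with term membership intersected with the background first; k = 0 is
reported as p = 1. Benjamini–Hochberg step-up adjustment across the tested
terms. Terms smaller than 2 or larger than 0.8 · background are skipped
and flagged — a standard guard against uninformative terms. The default
background is the post-filter expression universe, with a supplied genome
list as the configurable alternative; both are legitimate readings of
"compared to the whole genome" and the choice materially affects p-values,
so it is explicit. No mid-p or conditional corrections are applied.

The proportion comparison reports |query ∩ category|/|query| against
|category|/|genome| and their ratio, for categories such as EET proteins or
signal-processing proteins.

# The synthetic-data generator

`generateProteomics` draws trajectories as archetype template + iid
Gaussian noise on the abundance scale. Templates (before a +2 baseline
shift that keeps abundances non-negative; rare negative excursions are
truncated at 0):

| pattern | S1..S6 |
|---|---|
| sharp_decrease | 1, 1, 1, −1, −1, −1 |
| sharp_increase | −1, −1, −1, 1, 1, 1 |
| fast_then_slow_decrease | 1.5, 0.5, 0, −0.2, −0.4, −0.5 |
| late_increase | 0, 0, 0, 0, 0.2, 1.5 |
| flat | 0 (constant) |
| all_zero | exactly 0, no noise |

The default noise sd of 0.2 against a step of magnitude 2 makes the
archetypes clearly separated but not trivial. `generateInteractome` is an
Erdős–Rényi background with Beta(2, 2) confidence scores, so every
threshold between 0.4 and 0.9 retains an informative subset (if no edge
reaches 0.9 by chance, the strongest edge is redrawn from (0.9, 1) to keep
the series non-degenerate). `generateRegulon` draws TFs from the node pool
with a fixed out-degree. `plantMotifs` embeds disjoint triad instances on
fresh nodes (census-additive by construction); `plantMotifTriples` embeds
them into the background lists on designated proteins with high-confidence
edges, so the instances survive thresholding and active-set induction —
this is how the end-to-end pipeline gets planted motif excesses.
`generateAnnotations` plants one term with a designed query overlap.

What the generator does **not** emulate: peptide-level mass-spectrometry
noise, abundance-dependent missingness (only all-zero rows), the degree
heavy-tail of real interactomes (the background is Poisson-degree; the
planted structure, not the degree law, is what the recovery tests probe),
evidence-channel structure in confidence scores, and operon/regulon overlap
structure. Passing recovery tests therefore show the machinery is correct
and well-calibrated on clean planted structure — not that real proteomes
behave this way.

# Study conditions used in tests and the acceptance script

Problem sizes are chosen to exercise every stage meaningfully at desk
scale: the end-to-end run simulates 950 proteins (250/200/200/150 in the
four archetypes, 100 flat, 50 all-zero), a mean-degree-6 interactome over
the expressed proteins, 30 TFs × 8 targets, four planted motif classes × 25
instances (three of them off the conserved list, so the expected exclusive
set is exactly those three), and a planted annotation term of size 40 with
38 members in the active set. Motif significance uses the full 1000
randomizations; recovery claims are checked over multiple seeds (5 for
clustering and motif z, 20 for the annealer). Smaller fixtures (25–80
nodes) back the brute-force oracle comparisons, which are exact, not
statistical.

# Known limitations

* The sharp-cluster rule assumes exactly one dominant step location; more
  complex designs (multiple transitions) need a different rule.
* Betweenness is unweighted; confidence scores gate edges but do not weight
  paths.
* The annealer is a stochastic optimizer: determinism holds per seed, but
  different seeds may return different near-optimal partitions; only M and
  the recovery behaviour are asserted, not a unique partition.
* Empirical motif p-values are lower-bounded by 1/nRandom; z-scores carry
  the usual normal-approximation caveat for rare classes.
* The number of modules in real data is not a validated quantity here; no
  test asserts one.
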