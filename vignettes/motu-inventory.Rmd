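---
title: "Distance-threshold mOTU inventories: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-threshold mOTU inventories: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motuinv)
```

## The problem

Hyperdiverse tropical insect groups can hold thousands of species of which
only a fraction are formally described. A practical inventory sequences
short mitochondrial fragments (here cox1, rrnL and nad5) from thousands of
voucher specimens ("terminals"), clusters them into molecular operational
taxonomic units (mOTUs) at a fixed distance threshold, and treats each mOTU
as a putative species. The mOTU partition, joined with voucher geography,
yields the quantities conservation planning needs: species counts per
region, the ratio of analyzed to described diversity, endemism, and
turnover across sea barriers. `motuinv` implements that analysis layer plus
the quality screens and tree-comparison machinery used around a constrained
phylogenetic analysis, and a generator of synthetic datasets with known
truth to validate the whole chain.

## Distances

The package works in uncorrected p-distances: the fraction of mismatching
sites among sites where both sequences carry an unambiguous nucleotide.
Pairwise deletion (rather than complete deletion) is used because fragment
coverage is ragged: most terminals carry cox1, roughly half carry rrnL or
nad5, and complete deletion would discard most of the matrix. IUPAC partial
ambiguities (R, Y, ...) are treated as missing rather than as fractional
matches; this is conservative and avoids inventing a weighting the data do
not support.

A pair with fewer than `min_overlap` jointly resolved sites (default 100)
has an *undefined* distance. Undefined pairs never link during clustering —
a 60-site overlap can easily be identical by chance, and treating it as
distance 0 would lump unrelated clusters. The default of 100 sites keeps
the binomial standard error of a p-distance estimate below about 0.03 at
p = 0.1, small enough for 2–5% thresholds to be meaningful.

## mOTU delimitation

Two clustering rules are provided.

* **Single linkage** (the reference method for headline counts): mOTUs are
  the connected components of the graph linking pairs with defined
  `d <= t`. It is order-independent, deterministic, and matches the
  intuition that conspecific terminals chain through intermediate
  haplotypes.
* **Greedy, CD-HIT style** (for comparability with similarity-based
  pipelines): terminals are processed in descending ungapped length, ties
  broken by lexicographically smallest id; each joins the first existing
  cluster whose *representative* is within `t`, else founds a new cluster.
  CD-HIT's similarity `s` corresponds to `t = 1 - s`, so 0.98 is the 2%
  and 0.95 the 5% threshold. Distances are taken from the given multiple
  alignment, not from an alignment-free identity, so the two methods share
  one distance currency. Greedy can only split more finely than single
  linkage (a chain within `t` of each other may exceed `t` to the
  founder), and the suite asserts that inequality on random instances.

Cluster representatives (for pruning a dataset to one terminal per putative
species) are the member with the most unambiguous nucleotides, ties broken
by smallest id. Counting at a threshold excludes clusters whose members all
lack the required fragment (cox1 by default), mirroring how inventories
disregard mOTUs without the barcode marker.

Thresholds are compared inclusively (`d <= t`). The default sweep grid is
1–10% in 1% steps; the grid is an argument everywhere because published
similarity grids are not always internally consistent.

## Alignment quality screens

Before phylogenetic work, per-partition screens flag data that violate the
stationarity/reversibility/homogeneity (SRH) assumptions of standard
substitution models:

* **RCFV** — per-taxon nucleotide frequencies over resolved sites, summed
  absolute deviation from the across-taxa mean, divided by the number of
  taxa. Zero means identical composition; a partition is dropped when
  RCFV ≥ 0.1 (the conventional "high heterogeneity" cutoff).
* **Bowker's maximum symmetry test** — for each taxon pair, the 4×4
  substitution count matrix `n` gives
  `S = Σ_{i<j, n_ij+n_ji>0} (n_ij − n_ji)² / (n_ij + n_ji)`, chi-square
  with one degree of freedom per included pair. Pairs with no off-diagonal
  counts are degenerate and report p = 1. A partition is dropped when its
  *minimum* pairwise p-value falls below α = 0.05; the proportion of
  failing pairs is reported alongside. Aggregating by min-p is the stricter
  of the two natural choices; both the cutoff and α are arguments, and a
  `max_pairs` cap bounds runtime on large partitions (pairs are taken in
  deterministic row order).
* **Completeness** `Ca` — the fraction of matrix cells that are unambiguous
  nucleotides, overall and per taxon.

The suite verifies Bowker's type-I calibration by simulating pairs under
Jukes–Cantor (stationary and reversible, so the null holds): at α = 0.05
over 2000 pairs of 500 sites at distance 0.2, the rejection rate must fall
within 0.05 ± 0.02.

## Trees: stability, constraints

Replicate ML searches over thousands of mtDNA terminals are seed-sensitive,
so stability is quantified with Robinson–Foulds distances: trees are
restricted to their shared leaves, split sets are compared, and the raw
symmetric-difference count is normalized by `2(n − 3)` — the maximum for
binary trees. Multifurcating inputs are allowed; their attainable maximum
is below 1 and the value is deliberately not rescaled. "Wandering"
terminals are ranked by a pruning score: the mean drop in normalized RF
across tree pairs when the leaf is removed from both trees. This replaces
visual cophylogeny inspection with a reproducible surrogate.

A backbone constraint is a (possibly multifurcating) tree over anchor taxa
— typically a few dozen terminals anchored by phylogenomic data — written
as plain newick for a constrained search (IQ-TREE's `-g` convention:
unlisted taxa are free). Compliance of a full tree is checked by
restriction: every nontrivial backbone split must occur in the full tree
restricted to the anchors, which makes the verdict invariant to where free
taxa attach.

## Quartet support and likelihood mapping

Per-branch quartet support mirrors what ASTRAL prints with `-t 2`: each
internal branch of a binary species tree defines a quadripartition; for
quartets with one leaf per block (enumerated, or uniformly sampled above a
cap), each gene tree's induced quartet is classified as the species-tree
resolution or one of the two alternatives, and frequencies are reported
over resolved observations. Gene-tree branches at or below a support
threshold can be collapsed first so weak branches count as unresolved.

Four-cluster likelihood mapping evaluates, for quartets drawn one taxon
from each of four predefined groups, the maximized log-likelihood of the
three quartet topologies under JC69 with per-branch numerical optimization,
converts them to normalized weights, and attributes the quartet to the
basin of its best topology; ties (within 1e-6 log-likelihood) are
unresolved. JC69 suffices because the method's mechanics — relative support
among three topologies for the same data — do not hinge on a rich model at
desk scale; richer models belong to external phylogenetics software, which
this package deliberately does not wrap. The classical seven-region simplex
is not implemented: published summaries are basin percentages, and the
three-basin-plus-ties partition reproduces exactly that. Quartet sampling
above the cap (default 1000) requires a seed and is reproducible.

## The synthetic-data generator

The generator emulates the statistical structure the inventory relies on:

* **A barcode gap.** Species are tips of a Yule tree rescaled so the
  minimum inter-tip path is the interspecific floor (default 0.08 expected
  substitutions/site); terminals hang off species tips with pendant
  branches uniform on [0, intra_max/2] (default intra_max 0.005), so
  conspecific pairs are at most 0.005 apart in expectation. Distances are
  stated in expected substitutions/site and convert to expected
  p-distances through the JC formula `P(d) = ¾(1 − e^{−4d/3})`; 0.08
  converts to about 0.076, comfortably above the 5% threshold, and the
  intra/inter separation is several binomial standard deviations at 1000
  sites, so recovery of the true species count at both 2% and 5% is the
  expected outcome, not a tuned one.
* **Fragment missingness** per terminal per fragment; defaults (cox1
  0.077, rrnL 0.63, nad5 0.50) reproduce the coverage profile of a real
  three-fragment mtDNA inventory in which nearly all terminals carry the
  barcode fragment and roughly half carry each of the others.
* **Geography with tunable endemism.** Each species is endemic to one
  landmass with probability 0.95 (high single-landmass endemism being the
  empirical norm for poorly dispersing beetles); otherwise it adds further
  landmasses with probability 0.5 each. Terminals are spread so every
  occupied landmass receives one when the species has enough terminals,
  which makes the species-level occupancy truth recoverable from the
  emitted metadata. The default island set (New Guinea, Australia,
  Sulawesi, Moluccas, Borneo, Luzon) carries a barrier map with one shelf
  pair (New Guinea–Australia, the Sahul shelf) and deep sea elsewhere;
  barrier maps are data, never hard-coded.
* **Sequences** evolve under JC69 (optionally with discrete-gamma rate
  heterogeneity), site-independent.

One master seed drives all stages through documented derived seeds
(`derive_seed(seed, stage)`), so each stage is individually reproducible
and two runs at the same seed are byte-identical.

What the generator does **not** emulate: alignment error and indel
placement, compositional heterogeneity, saturation beyond JC expectations,
introgression or incomplete lineage sorting between close species,
pseudogenes/numts, and geographically structured intraspecific variation.
Passing recovery tests therefore shows the thresholding and accounting
machinery is correct under a clean barcode gap — not that a 2% or 5%
threshold is biologically right for any particular empirical group.

## Numerical conventions

* Ratios in inventory tables are rounded half away from zero to two
  decimals (`round_half_up`), matching how published diversity tables are
  printed; base R's half-to-even would differ on exact halves. Rounding is
  applied exactly once, at table assembly, and emitted ratios are always
  recomputable from the emitted integer columns.
* A described count of zero renders the ratio as missing ("—"), never as
  infinity.
* Missing-fragment fill is `?`, distinct from the alignment gap `-`; both
  are missing downstream, but the distinction survives round-trips.
* Partition coordinates are 1-based inclusive in files (RAxML-style
  `DNA, cox1 = 1-1100`).
* NJ/UPGMA tree building is delegated to the standard implementations in
  `ape` and `phangorn`; undefined distances are a hard error with advice to
  remove or impute, rather than being silently imputed.
* Degenerate inputs: Bowker with no off-diagonal counts reports p = 1 with
  a flag; RCFV excludes zero-resolved taxa with a warning; quartet support
  for a branch with no usable quartet is `NA`, not 0.

## Problem sizes in the tests

The suite runs at desk scale by design: 500 random clustering instances of
at most 12 terminals against an exhaustive component oracle, 200 random
8-leaf tree pairs against an independent RF implementation, a 50-species ×
5-terminal recovery regime at 1000 sites, 2000 Bowker replicate pairs of
500 sites, and FcLM on 16-quartet problems. These sizes keep the whole
suite under a minute while leaving the asymptotic regime (thousands of
terminals) to the vectorized distance-matrix path, which scales as the
product of terminal pairs and sites through four indicator-matrix products.

## Known limitations

* Distance thresholds are a pragmatic species proxy; the package
  deliberately implements no coalescent or likelihood-based delimitation.
* ML tree search, model selection and dating are out of scope; trees are
  inputs (or desk-scale NJ/UPGMA stand-ins).
* FcLM under JC69 is not a substitute for likelihood mapping under
  partitioned empirical models on genomic supermatrices; it reproduces the
  method's logic, not published genome-scale percentages.
* Quadripartition support requires a binary species tree; resolve or prune
  polytomies first.
* The greedy clusterer is quadratic in the worst case and intended for
  datasets up to a few thousand terminals.
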