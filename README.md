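# motuinv

DNA-based biodiversity inventorying for hyperdiverse insect groups, at the
scale where formal taxonomy cannot keep up. `motuinv` implements the
analysis layer of a voucher-based mtDNA inventory: molecular operational
taxonomic units (mOTUs) are delimited from short mitochondrial fragments
(cox1, rrnL, nad5) by uncorrected pairwise-distance thresholds, screened
alignments feed constrained phylogenetic work, replicate trees are compared
for stability, and the resulting partitions are turned into regional
diversity, endemism and turnover tables. A synthetic-data generator with a
controllable barcode gap provides known truth for end-to-end validation.

The target users are systematists and biodiversity researchers running
continental-scale inventories of groups such as tropical beetles, where
thousands of terminals and a backbone of a few dozen phylogenomically
anchored taxa must be combined into species counts per region.

## What it computes

* **Distances and clustering.** Uncorrected p-distance with pairwise
  deletion, `p(a,b) = mismatches / jointly resolved sites`, undefined below
  a minimum overlap (default 100 sites). mOTUs at a threshold `t` are
  either the connected components of the graph linking pairs with
  `p <= t` (single linkage, the reference method) or greedy CD-HIT-style
  clusters (terminals in descending ungapped length, each joining the
  first representative within `t`; similarity `s` maps to `t = 1 - s`).
  Threshold sweeps (default 1–10%) expose the barcode-gap plateau.
* **Alignment QC.** Relative composition frequency variation,
  `RCFV = sum_taxa sum_states |f_ts - mean_s| / n_taxa` (drop when
  `RCFV >= 0.1`); Bowker's maximum symmetry test,
  `S = sum_{i<j} (n_ij - n_ji)^2 / (n_ij + n_ji)` with one df per included
  pair (drop when the minimum pairwise p < 0.05); completeness score `Ca`
  (fraction of unambiguous nucleotide cells).
* **Tree machinery.** Robinson–Foulds distances (raw and normalized by
  `2(n-3)`) over replicate runs, a pruning-based instability score for
  "wandering" terminals, backbone-constraint files over anchor taxa, and
  compliance checks of full trees against a backbone.
* **Quartets.** ASTRAL-style per-branch quartet support from gene trees
  (frequencies of the three resolutions of each internode's
  quadripartition) and four-cluster likelihood mapping (FcLM) under JC69
  with numerically optimized branch lengths.
* **Inventory accounting.** Described-vs-analyzed tables per region with
  half-up two-decimal ratios, endemism proportions, and cross-landmass
  turnover classified by sea-barrier depth (deep sea > 200 m vs inundated
  shelf < 100 m), driven by a data-supplied barrier map.

## Worked example

Simulate a 20-species inventory (4 vouchers per species, realistic
fragment missingness, island geography), then delimit and account:

```r
library(motuinv)

cfg <- sim_config(n_species = 20, terminals_per_species = 4, seed = 11)
ds  <- emit_dataset(cfg)
cox1 <- ds$fragments$cox1          # 69 of 80 terminals carry cox1

D  <- distance_matrix(cox1, min_overlap = 100)
p2 <- cluster_single_linkage(D, 0.02, aln = cox1)
p5 <- cluster_single_linkage(D, 0.05, aln = cox1)
p5
#> mOTU partition (single_linkage, t = 0.05): 20 cluster(s) over 69 terminal(s)

threshold_sweep(D, seq(0.01, 0.10, by = 0.01))
#>    threshold count
#> 1       0.01    20
#> ...
#> 7       0.07    20
#> 8       0.08    19
#> 10      0.10    18
```

Both thresholds recover exactly the 20 true species, and the sweep is flat
across 1–7% — the barcode gap (intraspecific ≤ 0.5%, interspecific ≥ 8%
expected substitutions/site) makes the count insensitive to the threshold
until clusters start lumping beyond 8%. The accounting layer then gives:

```r
described <- aggregate(list(described = ds$truth$species),
                       by = list(unit = ds$truth$region),
                       FUN = function(x) length(unique(x)))
aggregate_regions(list(`2pct` = p2, `5pct` = p5), ds$metadata, described)
#>                    unit described motus_2pct motus_5pct ratio_2pct ratio_5pct
#> 1            Australian         8          8          8          1          1
#> 2           Philippines         4          4          4          1          1
#> 3             Sundaland         6          6          6          1          1
#> 4              Wallacea         2          2          2          1          1
#> 5 Total (by occurrence)        20         20         20          1          1
#> 6  Total (unique mOTUs)        20         20         20          1          1

turnover(p5, ds$metadata, cfg$barriers)$counts
#>   deep_sea      shelf contiguous
#>          0          0          0

endemism_table(p5, ds$metadata, level = "landmass")$global_proportion
#> [1] 1
```

Every mOTU is confined to a single landmass here (the generator's default
endemism probability is 0.95), so no turnover is recorded across either
barrier class. `run_pipeline()` wires the same stages — simulate or load,
QC, distances, clustering, sweep, representatives, optional backbone
compliance, reports — behind one YAML config and writes a checksummed
output manifest.

## Vignette

`vignettes/motu-inventory.Rmd` documents the model assumptions, parameter
choices and units, what the synthetic generator does and does not emulate,
numerical conventions (tie-breaking, rounding, degenerate inputs), and
known limitations.
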