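# subtadscope

Differential 3D-chromatin-architecture analysis on binned Hi-C contact
matrices, for the comparative setting where a control cell line is measured
against two perturbed clones (for example after heterozygous loss of the
insulator protein CTCF). The package answers the questions that drive such
studies: which TAD and subTAD boundaries are constant, lost or gained; how
altered CTCF/histone-mark binding colocalizes with altered boundaries; how
contact structure around altered sites changes in aggregate; and how boundary
changes couple to gene expression.

## What it computes

* **Matrix numerics** — ICE-style balancing (iterative proportional fitting
  with square-root damping), per-chromosome distance-decay expected profiles,
  obs/exp transforms, and diamond-window insulation scores
  `score(i) = log2(S(i) / mean S)`, where `S(i)` sums contacts crossing bin
  `i` within a window (100 kb for the TAD scan, 50 kb for subTADs).
* **Two-level boundary calling** — insulation minima filtered by topographic
  prominence, with positions refined to the domain edge; subTAD boundaries
  are fine-scan minima away from TAD boundaries.
* **Cross-condition classification** — one-to-one matching within ±10 kb
  across control and two clones: constant / lost / gained / discordant, with
  percentages relative to the control boundary count.
* **Differential occupancy** — library-normalized peak densities, pooled-
  variance z-test on log2 densities, BH adjustment; classes by
  FDR/logFC thresholds (CTCF: FDR < 0.01, |logFC| > 1; marks: FDR < 0.05).
* **Colocalization enrichment** — observed/expected overlap of features with
  boundaries against uniform permutation nulls, empirical p =
  (1 + k)/(n + 1); gained-next-to-lost boundary adjacency.
* **Pileups** — aggregate obs/exp submatrices around anchors or anchor pairs,
  and average insulation profiles by anchor class.
* **Expression integration** — per-boundary-class mean log2FC with rank-sum
  tests, mark-vs-expression delta-delta correlations, DE classification
  (basemean > 100, |log2FC| > 1, padj < 0.05), and Spearman correlation
  ranking against a reference gene across samples.
* **Synthetic data** — a paired-condition genome generator (nested
  TAD/subTAD hierarchy, Poisson contacts with distance decay and boundary
  insulation, CTCF/mark/expression features) with a machine-readable
  ground-truth change record, so the whole workflow is testable end to end.

## Worked example

```r
library(subtadscope)

cfg <- default_config(seed = 20260927)   # 2 x 20 Mb at 10-kb bins
report <- run_differential_architecture(cfg)

report$partitions$subtad
#>      class count       pct pct_rounded
#> 1 constant   100 84.745763          85
#> 2   gained     9  7.627119           8
#> 3     lost    18 15.254237          15

report$truth_recovery$lost_subtad_f1
#> [1] 0.9473684

report$adjacency$ratio
#> [1] 16.75
```

Read: of 118 control subTAD boundaries, 15% are lost and 8% gained in both
clones (the generator implanted 17% and 11%); classification recovers the
implanted subTAD losses with F1 0.95; gained boundaries sit ~17x closer to
lost boundaries than uniform placement would put them (empirical p = 0.005
at 199 permutations). `report$ctcf_diff`, `report$enrichment`,
`report$association`, `report$delta_delta` and `report$pileups` hold the
corresponding peak-level, colocalization, expression and pileup results.

The `analysis/` directory holds the same workflow as numbered narrative
scripts (`01_simulate.R` … `06_pileups.R`), each writing its tables under
`results/`:

```sh
Rscript analysis/01_simulate.R && Rscript analysis/03_domains.R
```

## Vignette

`vignettes/differential-architecture.Rmd` documents the models, the
generator's assumptions (and what it deliberately does not emulate), the
prominence-threshold calibration, and the numerical conventions.
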