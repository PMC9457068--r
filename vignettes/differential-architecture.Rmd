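---
title: "Differential TAD/subTAD architecture analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential TAD/subTAD architecture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models behind `subtadscope`, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
design decisions taken where several reasonable implementations exist. It
states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The scientific setting

Mammalian chromosomes fold into topologically associating domains (TADs,
roughly 100 kb to 1 Mb) containing smaller self-interacting subTADs. Domain
borders are largely anchored by the insulator protein CTCF. When cellular
CTCF levels drop (for example through single-allele copy-number loss), a
subset of weakly bound CTCF sites empties, preferentially dissolving subTAD
boundaries; loss of insulation permits de novo contacts, redistribution of
activating histone marks (H3K27ac, H3K4me3), and transcriptional
reprogramming. This package implements the comparative workflow for that
setting: binned Hi-C contact matrices from a control and two perturbed
clones, plus peak/expression tables, in; classified boundary changes,
colocalization enrichments, aggregate pileups and expression couplings, out.

## Contact-matrix numerics

**Balancing.** `balance()` performs iterative proportional fitting on the
symmetric count matrix: at each step every valid-bin row sum is scaled toward
the mean, dividing the matrix by the outer product of the *square roots* of
the per-bin factors. The square-root damping is needed because the plain
symmetric update oscillates on strongly structured matrices; with damping the
residual decays geometrically. Convergence is declared when all valid row
sums agree with their mean to a relative `tol` (default 1e-3); zero-coverage
bins are masked first and excluded everywhere downstream.

**Expected profile and obs/exp.** The expected value at separation `d` bins
is the mean balanced contact over valid pairs on that diagonal, per
chromosome (all analyses here are cis). Obs/exp is the pixel-wise ratio.

**Insulation score.** For bin *i* and window *w* bins,
`S(i) = sum of contacts between bins (i-w..i-1) and (i+1..i+w)` (the diamond
crossing *i*), and the score is `log2(S(i) / mean(S))` with the mean taken
over valid bins of the chromosome. Scores are undefined within *w* bins of
the chromosome ends and wherever the window touches a masked bin. Two window
scales are used: 100 kb for the TAD scan and 50 kb for the subTAD scan, at
10-kb bins — windows of the order of the domain scale they are meant to
detect. The score is computed after balancing and is invariant to global
scaling of the matrix.

One numerical caveat worth knowing: on a finite chromosome the combination of
balancing and chromosome-mean normalization bends the insulation track upward
near the ends, so a completely boundary-free decay matrix still has a single
shallow interior minimum. On structured genomes this is inconsequential (the
minimum is capped by real boundaries), but degenerate "no structure" checks
should use a constant matrix, for which the track is exactly flat.

## Boundary calling and the prominence thresholds

Boundaries are local minima of the insulation score filtered by *topographic
prominence*: on each side of a minimum, scan to the nearest strictly deeper
point (or the end of the defined segment) and record the highest intervening
score; the prominence is the smaller of the two barriers minus the minimum.
This is scale-free in the sense that a shallow dip sitting between two deep
true boundaries cannot inherit their depth.

The reported boundary position is the *domain edge*, not the argmin bin: a
boundary between bins `b-1` and `b` depresses `S` almost equally at both
bins, so the argmin jitters between them under noise while the edge — taken
between the minimum and its lower-scoring neighbor — is stable. This matters
directly for cross-sample matching at a ±10 kb tolerance on 10-kb bins,
where a two-bin jitter would otherwise break a match.

`call_hierarchy()` runs the coarse scan for TADs and the fine scan for
subTADs, then removes fine-scan boundaries within one bin of a TAD boundary.
The prominence defaults are **2.0 log2 units (TAD)** and **0.5 (subTAD)**.
These values were chosen by measuring the prominence distributions the
generator's deeply covered maps actually produce: TAD minima fall at 4.3-6.4,
subTAD minima at 0.5-1.8, and noise/geometry pseudo-minima below 0.25. The
TAD threshold therefore doubles as the level separator — a single low
threshold at both scales would absorb every subTAD boundary into the TAD
level, because window size alone does not separate the levels (an insulation
dip survives averaging at any window that fits inside the flanking domains).
On real, shallower data these thresholds should be re-tuned; they are plain
per-level parameters.

## Cross-condition boundary classification

`classify_boundaries()` matches boundary sets one-to-one within ±10 kb
(greedy by distance with deterministic tie-breaking toward smaller
coordinates, which attains maximum matching cardinality on 1-d point sets —
verified against an exhaustive matcher in the tests). A control boundary
matched in both clones is *constant*, in neither *lost*, in exactly one
*discordant*; clone-only boundaries present in both clones are *gained*, and
one-clone novelties are *discordant*. Requiring "in both clones" for gains as
well as losses is a symmetry choice: it keeps both calls robust to
single-sample caller noise, at the cost of routing genuine single-clone
biology into the discordant class. Percentages are reported against the
control boundary count, the only denominator under which a gain of 810
boundaries over 11,580 control boundaries reads as 7%.

## Permutation statistics

All empirical p-values use the `(1 + k) / (n + 1)` convention and are never
zero. `oe_boundary_enrichment()` re-places the feature set uniformly on the
valid bins of its own chromosome (`n_perm` times, default 999) and reports
observed / mean(null) with a two-sided p (double the smaller tail, capped at
1). `gained_lost_adjacency()` uses the median distance from each gained
boundary to its nearest lost boundary, against uniform re-placement of the
gained set; distances never cross chromosomes, and the analysis pools both
boundary levels because added boundaries are placed near removed boundaries
of either level. Sub-seeding (`derive_seed`) gives every stage an independent
reproducible stream from one master seed.

## Differential occupancy

Peak densities are library-size normalized (reads-per-million over the peak
interval). The test is a z-statistic on the difference of condition means of
log2 densities, with the variance pooled across all peaks — at two replicates
per condition, per-peak variances are essentially noise, and pooling is the
stable choice; the cost is miscalibration if a subset of peaks is genuinely
more variable. Reported logFC is `log2((mean_t + 1)/(mean_c + 1))` (the
pseudo-count guards empty peaks), BH adjustment across peaks gives the FDR,
and classes use FDR < 0.01 with |logFC| > 1 for CTCF-style calls and
FDR < 0.05 for histone marks.

## The synthetic-data generator

The generator's defaults define the study conditions used by the tests and
the acceptance script: two 20-Mb chromosomes at 10-kb bins; TAD sizes uniform
on 100 kb-1 Mb with up to 3 subTADs per TAD (subTADs at least ~100 kb so a
50-kb window resolves them); expected contacts
`depth * (1+d)^-alpha * e(i,j) * f(i,j)` with `depth = 100`, `alpha = 1`,
within-TAD enrichment 3 and within-subTAD enrichment 2, Poisson counts.
`f(i,j)` multiplies the insulation factor of every boundary between the two
bins: TAD boundaries retain 5-20% of cross-boundary contacts, subTAD
boundaries 60-80%. The asymmetry is deliberate and matches the field's
picture of subTADs as weaker, more dynamic boundaries; it is also what makes
two-level calling a well-posed problem.

The perturbation removes 17%/11% of subTAD boundaries (removed/added) and
10%/7% at the TAD level — the turnover pattern of a moderate CTCF-depletion
experiment — and places added boundaries uniformly within 100 kb of a removed
one (the paper-scale adjacency is qualitative; no distance is stated, so the
window is a generator choice). Both clones share the perturbed hierarchy and
differ only in Poisson noise.

Features: a CTCF peak sits at every boundary plus uniform background; peaks
at removed boundaries are truth-lost (probability = coupling, default 1) and
start from two-fold weaker control occupancy than constant peaks, dropping
four-fold on depletion. Gained marks appear at added subTAD boundaries,
lost marks at removed ones (coupling 0.8). Genes are uniform (20 per Mb, one
guaranteed near each added subTAD boundary); genes near added subTAD
boundaries receive a +1 log2FC offset. A disjoint subset of ~300 genes gets
mark sites at their TSSs whose true logFC correlates with the gene's true
log2FC at 0.64 (H3K27ac) and 0.45 (H3K4me3) — the couplings one expects for
activating marks. Expression p-values are not drawn from a distribution:
replicate counts are simulated (2 vs 2, negative binomial, dispersion 0.05)
and pushed through the same pooled-z test used for peaks, so the thresholds
act on realistically distributed padj values.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no read-level artifacts, mappability structure or
restriction-fragment effects; no A/B compartments or trans contacts; no
overdispersion beyond Poisson at the matrix level; boundary changes are
binary (a boundary is present or absent, never weakened); and there is no de
novo loop/dot mechanism, so gained mark sites form new *insulation* rather
than new contact hubs — the enhancer-contact-gain pattern of the real system
is out of the generator's vocabulary (the paired-pileup dot test constructs
its dot directly in a matrix fixture instead).

## Degenerate inputs and numerical conventions

Coordinates are 0-based half-open everywhere internally; BED/bedGraph pass
through unchanged; the TSS of a minus-strand gene is `end - 1`. Rows with
missing adjusted p-values are rejected, not imputed. Zero-coverage bins are
masked, not dropped, so bin indices remain stable. `depth = 0` yields the
all-zero matrix (the zero-intensity limit) rather than an error; negative
depth errors. Matching ties break toward smaller coordinates so that class
counts are reproducible to the byte under a fixed seed.

## Problem sizes

The test-suite and acceptance runs use the default two 20-Mb chromosomes
(2,000 bins each) for end-to-end checks, 8-Mb single chromosomes for
repeated-simulation checks (20 seeds), 200 seeds for p-value calibration at
99 permutations, and <= 100-bin instances for brute-force oracle
equivalence. These sizes keep a full run in minutes on one core while every
statistic retains enough events (tens of boundaries per level, hundreds of
peaks and genes) to be meaningfully tested.

## Known limitations

The prominence thresholds are calibrated to deep, clean maps and must be
lowered for shallow real libraries. The pooled-variance z-test trades
per-peak calibration for stability at n = 2. The boundary classifier treats
boundary *position* only; strength changes without displacement are
invisible to it (the insulation-profile analyses cover that axis). Gene-set
enrichment uses simple TSS-proximity mapping (±3 kb), not
regulatory-domain assignment.
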