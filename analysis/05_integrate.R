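#!/usr/bin/env Rscript
# Integration analyses: O/E colocalization of altered CTCF/marks with altered
# boundaries, expression change of genes at boundary classes, delta-delta
# coupling of mark and expression changes, gene-set enrichment of lost-CTCF
# genes against equinumerous constant subsets, and correlation ranking against
# a reference gene in a synthetic cohort.

source("analysis/00_config.R")
study <- get_study()
d <- outdir("integrate")
rpt <- run_differential_architecture(CONFIG, sim = study)

write_tsv(rpt$association, d, "boundary_expression.tsv")
ga <- rpt$association[rpt$association$class == "gained", ]
message(sprintf("genes at gained subTAD boundaries: mean log2FC %.2f +/- %.2f (p = %.2g)",
                ga$mean_log2fc, ga$sem, ga$p))

enr <- do.call(rbind, lapply(names(rpt$enrichment), function(nm) {
  e <- rpt$enrichment[[nm]]
  data.frame(comparison = nm, observed = e$observed, expected = e$expected,
             oe = e$oe, p = e$p)
}))
write_tsv(enr, d, "oe_enrichment.tsv")
print(enr)

dd <- rpt$delta_delta
message(sprintf("H3K27ac logFC vs expression log2FC: rho %.2f (n = %d, p = %.2g)",
                dd$r, dd$n, dd$p))

# gene-set enrichment at lost CTCF sites vs 100 equinumerous constant subsets;
# synthetic gene sets: one enriched for genes near truth-lost sites, two random
ctcf <- rpt$ctcf_diff
lost_fs <- feature_set(ctcf[ctcf$class == "lost", ])
const_fs <- feature_set(ctcf[ctcf$class == "constant", ])
genes <- study$features$genes
set.seed(derive_seed(SEED, 50))
near_lost <- sapply(seq_len(nrow(genes)), function(i) {
  s <- lost_fs[lost_fs$chrom == genes$chrom[i], ]
  nrow(s) > 0 && min(abs((s$start + s$end) / 2 - genes$tss[i])) <= 3e3
})
sets <- list(
  lost_targets_synthetic = sample(genes$gene_id[near_lost],
                                  min(40, sum(near_lost))),
  random_a = sample(genes$gene_id, 40),
  random_b = sample(genes$gene_id, 40))
gs <- geneset_enrichment_vs_constant(lost_fs, const_fs, genes, sets,
                                     n_subsets = 100, tol = 3e3,
                                     seed = derive_seed(SEED, 51))
write_tsv(gs, d, "geneset_enrichment.tsv")
print(gs)

# correlation ranking in a synthetic 60-sample cohort: 30 genes tracking the
# reference (positively or negatively), the rest independent
set.seed(derive_seed(SEED, 52))
n_s <- 60; n_g <- 200
ref <- rnorm(n_s)
expr_m <- matrix(rnorm(n_g * n_s), n_g, n_s,
                 dimnames = list(sprintf("G%03d", seq_len(n_g)), NULL))
coupled <- sample(n_g, 30)
signs <- sample(c(-1, 1), 30, replace = TRUE)
expr_m[coupled, ] <- 0.7 * signs * matrix(ref, 30, n_s, byrow = TRUE) +
  sqrt(1 - 0.49) * expr_m[coupled, ]
expr_m <- rbind(expr_m, REF = ref)
rk <- correlation_ranking(expr_m, "REF")
write_tsv(rk, d, "correlation_ranking.tsv")
top <- rk$gene[1:20]
message(sprintf("correlation ranking: %d of top 20 are implanted positives",
                sum(top %in% rownames(expr_m)[coupled[signs > 0]])))
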