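#!/usr/bin/env Rscript
# Differential occupancy: classify CTCF peaks and histone-mark sites as
# constant / lost / gained from the 2 vs 2 replicate densities (pooled-z test,
# BH), annotate the genomic context of each class, and build a TSS
# metaprofile of control CTCF signal at up- vs unaltered genes.

source("analysis/00_config.R")
study <- get_study()
d <- outdir("diffbind")
cond <- rep(c("ctl", "trt"), each = 2)
dens <- function(df) as.matrix(df[, grep("^(ctl|trt)_", names(df))])

ctcf <- classify_differential(dens(study$features$ctcf), cond,
                              fdr_max = 0.01, logfc_min = 1,
                              peaks = study$features$ctcf)
ctcf$truth_class <- study$features$ctcf$truth_class
write_tsv(ctcf, d, "ctcf_differential.tsv")
tab <- table(called = ctcf$class, truth = ctcf$truth_class)
message("CTCF classes (called x truth):"); print(tab)
message(sprintf("lost-call sensitivity %.2f, empirical FDR %.2f",
                tab["lost", "lost"] / sum(tab[, "lost"]),
                1 - tab["lost", "lost"] / sum(tab["lost", ])))

for (mk in names(study$features$marks)) {
  m <- study$features$marks[[mk]]
  md <- classify_differential(dens(m), cond, fdr_max = 0.05, logfc_min = 1,
                              peaks = m)
  md$truth_class <- m$truth_class
  write_tsv(md, d, sprintf("%s_differential.tsv", mk))
  message(mk, ": ", sum(md$class == "gained"), " gained, ",
          sum(md$class == "lost"), " lost of ", nrow(md))
}

ctx <- annotate_context(ctcf, study$features$genes, promoter_flank = 3000)
ctx_tab <- as.data.frame(prop.table(table(class = ctcf$class, context = ctx),
                                    margin = 1))
write_tsv(ctx_tab, d, "ctcf_context_fractions.tsv")
message("context fractions by class:")
print(round(xtabs(Freq ~ class + context, ctx_tab), 2))

# control CTCF signal track (occupancy summed into 10-kb bins)
res <- CONFIG$resolution
track <- do.call(rbind, lapply(names(CONFIG$chrom_sizes), function(ch) {
  p <- study$features$ctcf[study$features$ctcf$chrom == ch, ]
  n <- CONFIG$chrom_sizes[[ch]] / res
  v <- numeric(n)
  b <- floor((p$start + p$end) / 2 / res) + 1
  for (i in seq_along(b)) v[b[i]] <- v[b[i]] + p$occ_ctl[i]
  data.frame(chrom = ch, start = (seq_len(n) - 1) * res, end = seq_len(n) * res,
             score = v)
}))
expr <- study$features$expression
for (cls in c("up", "unaltered")) {
  g <- expr[expr$class == cls, ]
  if (nrow(g) == 0) next
  prof <- tss_metaprofile(feature_set(track), g, flank = 5e4)
  write_tsv(data.frame(offset = attr(prof, "offsets"), mean_signal = prof),
            d, sprintf("tss_profile_%s.tsv", cls))
}
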