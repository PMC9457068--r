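#!/usr/bin/env Rscript
# Simulate the paired-condition synthetic study: a control genome of nested
# TADs/subTADs, a perturbed genome shared by two clones, CTCF/histone-mark
# peak sets with ground-truth classes, and an RNA-seq-style expression table.
# Writes the plain-text inputs consumed by the later scripts.

source("analysis/00_config.R")
study <- get_study()
d <- outdir("sim")

# ground-truth change record and boundary tables
write_tsv(study$record, d, "truth_changes.tsv")
for (ch in names(study$hier_ctl$chroms)) {
  for (lv in c("tad", "subtad")) {
    write_tsv(study$hier_ctl$chroms[[ch]][[lv]],
              d, sprintf("boundaries_%s_%s_control.tsv", ch, lv))
  }
}

# features as BED/TSV
write_feature_set(study$features$ctcf, file.path(d, "ctcf_peaks.bed"))
write_feature_set(study$features$marks$h3k27ac, file.path(d, "h3k27ac_sites.bed"))
write_feature_set(study$features$marks$h3k4me3, file.path(d, "h3k4me3_sites.bed"))
write_tsv(study$features$ctcf, d, "ctcf_peaks_full.tsv")
write_expression_table(study$features$expression, file.path(d, "expression.tsv"))
write_tsv(study$features$genes, d, "genes.tsv")
writeLines(paste(names(CONFIG$chrom_sizes), CONFIG$chrom_sizes, sep = "\t"),
           file.path(d, "chrom.sizes"))

# contact matrices are large: store under scratch/ as sparse triplet text
ms <- "scratch/sim"
dir.create(ms, recursive = TRUE, showWarnings = FALSE)
for (ch in names(study$matrices)) {
  for (cond in names(study$matrices[[ch]])) {
    write_contact_matrix(study$matrices[[ch]][[cond]],
                         file.path(ms, sprintf("%s_%s.triplet.tsv", ch, cond)))
  }
}

n_b <- table(study$record$level, study$record$change)
message("simulated ", length(CONFIG$chrom_sizes), " chromosomes at ",
        CONFIG$resolution / 1e3, " kb bins")
message("boundary changes:")
print(n_b)
message(nrow(study$features$ctcf), " CTCF peaks (",
        sum(study$features$ctcf$truth_class == "lost"), " truth-lost), ",
        nrow(study$features$expression), " genes")
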