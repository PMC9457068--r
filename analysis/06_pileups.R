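#!/usr/bin/env Rscript
# Aggregate Hi-C views: pileups around truth-lost vs constant CTCF sites in
# control and perturbed maps (insulation loss appears as filled-in
# cross-boundary quadrants), insulation profiles at removed subTAD
# boundaries, and paired pileups between gained H3K27ac sites.

source("analysis/00_config.R")
study <- get_study()
d <- outdir("pileups")
ch <- names(study$matrices)[1]
res <- CONFIG$resolution

cm_ctl <- balance(study$matrices[[ch]]$ctl)
cm_cl <- balance(study$matrices[[ch]]$clone1)

pk <- study$features$ctcf[study$features$ctcf$chrom == ch, ]
anchors <- list(lost = (pk$start + pk$end)[pk$truth_class == "lost"] / 2,
                constant = (pk$start + pk$end)[pk$truth_class == "constant"] / 2)
for (cls in names(anchors)) {
  for (cond in c("ctl", "clone")) {
    cm <- if (cond == "ctl") cm_ctl else cm_cl
    pr <- anchor_pileup(cm, anchors[[cls]], flank = 2e5,
                        n_random_sets = 10, seed = derive_seed(SEED, 60))
    write_tsv(as.data.frame(pr$matrix),
              d, sprintf("pileup_%s_%s.tsv", cls, cond))
    k <- pr$center - 1
    cross <- mean(c(pr$matrix[1:k, (k + 2):(2 * k + 1)],
                    pr$matrix[(k + 2):(2 * k + 1), 1:k]), na.rm = TRUE)
    message(sprintf("%s sites, %s: cross-quadrant mean obs/exp %.3f (%d anchors)",
                    cls, cond, cross, pr$n_anchors))
  }
}

rm_sub <- study$record[study$record$change == "removed" &
                         study$record$level == "subtad" &
                         study$record$chrom == ch, ]
prof <- insulation_profile(list(ctl = insulation_track(cm_ctl, 5e4),
                                clone1 = insulation_track(cm_cl, 5e4)),
                           rm_sub$pos + res / 2, flank = 2e5)
write_tsv(cbind(offset = as.numeric(rownames(prof)), as.data.frame(prof)),
          d, "insulation_profile_removed_subtad.tsv")
ctr <- (nrow(prof) + 1) / 2
message(sprintf("insulation at removed subTAD boundaries (offset 0): ctl %.2f -> clone %.2f",
                prof[ctr, "ctl"], prof[ctr, "clone1"]))

# paired pileups between gained H3K27ac sites in both conditions: in this
# generator gained sites mark newly formed subTAD boundaries, so the clone
# map shows the contacts BETWEEN them being insulated away relative to the
# control (boundary formation, not enhancer-hub formation; see the methods
# vignette for why the generator does not model de novo contact gains
# between regulatory elements)
k27 <- study$features$marks$h3k27ac
gained_sites <- k27[k27$truth_class == "gained" & k27$chrom == ch, ]
if (nrow(gained_sites) >= 2) {
  for (cond in c("ctl", "clone")) {
    cm <- if (cond == "ctl") cm_ctl else cm_cl
    pp <- paired_pileup(cm, gained_sites, gained_sites, flank = 5e4,
                        min_sep = 2e5, max_sep = 2e6)
    write_tsv(as.data.frame(pp$matrix),
              d, sprintf("paired_pileup_gained_h3k27ac_%s.tsv", cond))
    message(sprintf("gained-H3K27ac paired pileup, %s: center obs/exp %.2f (%d pairs)",
                    cond, pp$center_value, pp$n_pairs))
  }
}
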