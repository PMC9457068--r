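#' Default parameters for the synthetic feature generator
#'
#' Effect sizes and densities emulate a CTCF-depletion ChIP/RNA-seq design:
#' CTCF peaks anchor every boundary, truth-lost peaks start from weaker
#' occupancy than constant ones and drop four-fold on depletion, activating
#' histone marks are gained at newly formed subTAD boundaries and lost at
#' dissolved ones, genes near gained subTAD boundaries are up-regulated by a
#' +1 log2FC offset, and a subset of mark sites is correlation-coupled to
#' expression changes (default couplings 0.64 for H3K27ac and 0.45 for
#' H3K4me3, the strength typical of activating-mark/expression coupling).
#'
#' @return named list of generator parameters.
#' @export
feature_sim_params <- function() {
  list(
    peak_width = 1000,          # bp, CTCF/mark site width
    bg_peaks_per_mb = 10,       # background CTCF peaks
    ctcf_coupling = 1,          # P(removed-boundary peak is truth-lost)
    bg_lost_frac = 0.05, bg_gained_frac = 0.02,
    occ_log2_constant = 5, occ_log2_lost = 4, occ_log2_gained = 3,
    occ_log2_sd = 0.7,
    lfc_lost = -2, lfc_gained = 2,
    rep_noise = 0.3,            # log2 sd per replicate density
    n_reps = 2,
    bg_marks_per_mb = 15,
    mark_coupling = 0.8,        # P(mark change at an altered subTAD boundary)
    expr_coupling = c(h3k27ac = 0.64, h3k4me3 = 0.45),
    n_coupled_per_chrom = 150,  # TSS mark sites correlation-coupled to expression
    coupled_lfc_sd = 1.2,
    genes_per_mb = 20,
    gene_length = c(2e3, 5e4),
    boundary_lfc = 1,           # implanted log2FC offset near added subTAD boundaries
    expr_boundary_coupling = 1, # P(a gene near an added subTAD boundary gets the offset)
    near_tol = 1e4,             # bp, "near a boundary"
    nb_dispersion = 0.05,       # RNA-seq negative-binomial dispersion (2 vs 2)
    basemean_meanlog = log(300), basemean_sdlog = 0.8
  )
}

rep_densities <- function(occ_ctl, occ_trt, n_reps, rep_noise) {
  n <- length(occ_ctl)
  dens <- cbind(
    matrix(occ_ctl * 2^stats::rnorm(n * n_reps, 0, rep_noise), n, n_reps),
    matrix(occ_trt * 2^stats::rnorm(n * n_reps, 0, rep_noise), n, n_reps))
  colnames(dens) <- c(paste0("ctl_", seq_len(n_reps)), paste0("trt_", seq_len(n_reps)))
  dens
}

#' Simulate CTCF peaks, histone-mark sites and an expression table
#'
#' Placement is driven by the original hierarchy and the perturbation record:
#' a CTCF peak sits at every TAD/subTAD boundary (plus uniform background);
#' peaks at removed boundaries are truth-lost with probability
#' `ctcf_coupling`; mark sites are gained at added subTAD boundaries and lost
#' at removed ones with probability `mark_coupling`; genes near added subTAD
#' boundaries receive a `boundary_lfc` log2FC offset. RNA-seq replicate counts
#' are simulated (2 vs 2 negative binomial) and passed through the same
#' pooled-z test used for differential binding, so padj values behave like
#' real ones. Every feature row carries its ground-truth class.
#'
#' @param hier the original (control) `domain_hierarchy`.
#' @param record the `change_record` from [perturb_hierarchy()].
#' @param params list from [feature_sim_params()] (entries may be overridden).
#' @param seed integer seed.
#' @return list with `ctcf` (feature_set + truth + replicate densities),
#'   `marks` (named list per mark), `expression` (`expression_table` with
#'   truth columns), `genes` (gene model).
#' @export
simulate_features <- function(hier, record, params = feature_sim_params(), seed = 1) {
  p <- utils::modifyList(feature_sim_params(), params)
  assert_that(p$ctcf_coupling >= 0 && p$ctcf_coupling <= 1 &&
                p$mark_coupling >= 0 && p$mark_coupling <= 1,
              "coupling strengths must be in [0, 1]")
  set.seed(seed)
  res <- hier$resolution
  chrom_len <- vapply(hier$chroms, function(c) c$n_bins * res, 0)
  removed <- record[record$change == "removed", , drop = FALSE]
  added_sub <- record[record$change == "added" & record$level == "subtad", , drop = FALSE]
  removed_sub <- removed[removed$level == "subtad", , drop = FALSE]

  ## ---- CTCF peaks -------------------------------------------------------
  half <- p$peak_width / 2
  bpos <- do.call(rbind, lapply(names(hier$chroms), function(ch) {
    b <- c(hier$chroms[[ch]]$tad$bin, hier$chroms[[ch]]$subtad$bin)
    data.frame(chrom = ch, pos = sort(b) * res)
  }))
  at_removed <- mapply(function(ch, pos) {
    any(removed$chrom == ch & removed$pos == pos)
  }, bpos$chrom, bpos$pos)
  lost_draw <- stats::runif(nrow(bpos)) < p$ctcf_coupling
  bnd_class <- ifelse(at_removed & lost_draw, "lost", "constant")
  n_bg <- round(sum(chrom_len) / 1e6 * p$bg_peaks_per_mb)
  bg_chrom <- sample(names(chrom_len), n_bg, replace = TRUE,
                     prob = chrom_len / sum(chrom_len))
  bg_pos <- vapply(bg_chrom, function(ch)
    round(stats::runif(1, 2 * res, chrom_len[[ch]] - 2 * res)), 0)
  u <- stats::runif(n_bg)
  bg_class <- ifelse(u < p$bg_lost_frac, "lost",
                     ifelse(u < p$bg_lost_frac + p$bg_gained_frac, "gained", "constant"))
  ctcf <- data.frame(chrom = c(bpos$chrom, bg_chrom),
                     pos = c(bpos$pos, bg_pos),
                     at_boundary = c(rep(TRUE, nrow(bpos)), rep(FALSE, n_bg)),
                     truth_class = c(bnd_class, bg_class))
  ctcf$start <- pmax(0, ctcf$pos - half)
  ctcf$end <- ctcf$pos + half
  nc <- nrow(ctcf)
  base_log2 <- ifelse(ctcf$truth_class == "lost", p$occ_log2_lost,
                      ifelse(ctcf$truth_class == "gained", p$occ_log2_gained,
                             p$occ_log2_constant))
  occ_ctl <- 2^stats::rnorm(nc, base_log2, p$occ_log2_sd)
  lfc_true <- ifelse(ctcf$truth_class == "lost", p$lfc_lost,
                     ifelse(ctcf$truth_class == "gained", p$lfc_gained, 0))
  occ_trt <- occ_ctl * 2^lfc_true
  ctcf$occ_ctl <- occ_ctl; ctcf$occ_trt <- occ_trt; ctcf$logFC_true <- lfc_true
  ctcf <- cbind(ctcf, rep_densities(occ_ctl, occ_trt, p$n_reps, p$rep_noise))

  ## ---- genes and expression --------------------------------------------
  genes <- do.call(rbind, lapply(names(chrom_len), function(ch) {
    n_g <- round(chrom_len[[ch]] / 1e6 * p$genes_per_mb)
    tss <- round(stats::runif(n_g, 1e4, chrom_len[[ch]] - 1e4))
    # guarantee a gene near every added subTAD boundary on this chromosome
    add <- added_sub$pos[added_sub$chrom == ch]
    tss <- c(tss, round(add + stats::runif(length(add), -5e3, 5e3)))
    data.frame(chrom = ch, tss = tss)
  }))
  ng <- nrow(genes)
  genes$strand <- sample(c("+", "-"), ng, replace = TRUE)
  glen <- round(stats::runif(ng, p$gene_length[1], p$gene_length[2]))
  genes$start <- ifelse(genes$strand == "+", genes$tss, pmax(0, genes$tss - glen + 1))
  genes$end <- ifelse(genes$strand == "+", genes$tss + glen, genes$tss + 1)
  genes$gene_id <- sprintf("G%05d", seq_len(ng))
  near_added <- vapply(seq_len(ng), function(i) {
    a <- added_sub$pos[added_sub$chrom == genes$chrom[i]]
    length(a) > 0 && min(abs(a - genes$tss[i])) <= p$near_tol
  }, TRUE)
  true_lfc <- stats::rnorm(ng, 0, 0.2)
  hit <- near_added & stats::runif(ng) < p$expr_boundary_coupling
  true_lfc[hit] <- p$boundary_lfc + stats::rnorm(sum(hit), 0, 0.2)
  # correlation-coupled genes for the delta-delta analyses (kept clear of
  # added boundaries so the implanted offset is not diluted)
  n_coupled <- min(p$n_coupled_per_chrom * length(chrom_len), sum(!near_added))
  coupled_idx <- sample(which(!near_added), n_coupled)
  true_lfc[coupled_idx] <- stats::rnorm(n_coupled, 0, p$coupled_lfc_sd)
  genes$true_log2fc <- true_lfc
  genes$near_added_subtad <- near_added
  basemean_true <- stats::rlnorm(ng, p$basemean_meanlog, p$basemean_sdlog)
  size <- 1 / p$nb_dispersion
  cts <- cbind(
    matrix(stats::rnbinom(ng * 2, mu = rep(basemean_true, 2), size = size), ng, 2),
    matrix(stats::rnbinom(ng * 2, mu = rep(basemean_true * 2^true_lfc, 2), size = size), ng, 2))
  tst <- pooled_z_test(log2(cts + 1), c("ctl", "ctl", "trt", "trt"))
  expr <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                     tss = genes$tss, strand = genes$strand,
                     basemean = rowMeans(cts),
                     log2FC = log2((rowMeans(cts[, 3:4]) + 1) / (rowMeans(cts[, 1:2]) + 1)),
                     padj = stats::p.adjust(tst$pvalue, method = "BH"))
  expr <- expression_table(expr)
  expr$true_log2fc <- true_lfc

  ## ---- histone marks ----------------------------------------------------
  make_mark <- function(mark) {
    rho <- p$expr_coupling[[mark]]
    rows <- list()
    n_bg <- round(sum(chrom_len) / 1e6 * p$bg_marks_per_mb)
    ch_bg <- sample(names(chrom_len), n_bg, replace = TRUE,
                    prob = chrom_len / sum(chrom_len))
    rows$bg <- data.frame(
      chrom = ch_bg,
      pos = vapply(ch_bg, function(ch)
        round(stats::runif(1, 2 * res, chrom_len[[ch]] - 2 * res)), 0),
      truth_class = "constant", coupled = FALSE,
      logFC_true = stats::rnorm(n_bg, 0, 0.3))
    hit_g <- stats::runif(nrow(added_sub)) < p$mark_coupling
    if (any(hit_g)) rows$gained <- data.frame(
      chrom = added_sub$chrom[hit_g], pos = added_sub$pos[hit_g],
      truth_class = "gained", coupled = FALSE,
      logFC_true = p$lfc_gained + stats::rnorm(sum(hit_g), 0, 0.3))
    hit_l <- stats::runif(nrow(removed_sub)) < p$mark_coupling
    if (any(hit_l)) rows$lost <- data.frame(
      chrom = removed_sub$chrom[hit_l], pos = removed_sub$pos[hit_l],
      truth_class = "lost", coupled = FALSE,
      logFC_true = p$lfc_lost + stats::rnorm(sum(hit_l), 0, 0.3))
    g <- genes[coupled_idx, ]
    lfc_m <- rho * g$true_log2fc +
      sqrt(1 - rho^2) * stats::rnorm(nrow(g), 0, p$coupled_lfc_sd)
    rows$coupled <- data.frame(chrom = g$chrom, pos = g$tss,
                               truth_class = "coupled", coupled = TRUE,
                               logFC_true = lfc_m)
    m <- do.call(rbind, rows)
    m$start <- pmax(0, m$pos - half); m$end <- m$pos + half
    occ_ctl <- 2^stats::rnorm(nrow(m), p$occ_log2_constant, p$occ_log2_sd)
    occ_ctl[m$truth_class == "gained"] <- 2^stats::rnorm(sum(m$truth_class == "gained"),
                                                         p$occ_log2_gained, p$occ_log2_sd)
    occ_trt <- occ_ctl * 2^m$logFC_true
    m$occ_ctl <- occ_ctl; m$occ_trt <- occ_trt
    cbind(m, rep_densities(occ_ctl, occ_trt, p$n_reps, p$rep_noise))
  }
  marks <- list(h3k27ac = make_mark("h3k27ac"), h3k4me3 = make_mark("h3k4me3"))

  # returned as sorted feature sets so row order is stable for all consumers
  list(ctcf = feature_set(ctcf), marks = lapply(marks, feature_set),
       expression = expr,
       genes = genes[order(genes$chrom, genes$start),
                     c("gene_id", "chrom", "start", "end", "strand", "tss",
                       "true_log2fc", "near_added_subtad")])
}
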