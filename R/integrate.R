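#' Observed/expected enrichment of features at boundaries
#'
#' Counts features whose midpoint falls within +/- `tol` of any boundary, then
#' compares against `n_perm` uniform re-placements of the features on the
#' valid positions of their own chromosome. O/E is observed / mean(null); the
#' empirical p is two-sided (double the smaller tail, capped at 1), using the
#' (1 + k)/(n + 1) convention so it is never zero.
#'
#' @param features a `feature_set` (non-empty).
#' @param boundaries data.frame with `chrom` and `pos` (bp), or a numeric
#'   vector of positions when `features` live on one chromosome.
#' @param valid_positions named list (per chromosome) of candidate bp
#'   positions for random placement.
#' @param tol colocalization tolerance in bp (default 10 kb).
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed.
#' @return an `enrichment_result`: list(observed, expected, oe, p, n_perm).
#' @export
oe_boundary_enrichment <- function(features, boundaries, valid_positions,
                                   tol = 1e4, n_perm = 999, seed = 1) {
  assert_that(n_perm >= 99, "n_perm must be >= 99")
  assert_that(nrow(features) > 0, "empty feature set")
  if (!is.data.frame(boundaries)) {
    assert_that(length(unique(features$chrom)) == 1,
                "positional boundaries require single-chromosome features")
    boundaries <- data.frame(chrom = features$chrom[1], pos = as.numeric(boundaries))
  }
  assert_that(nrow(boundaries) > 0, "empty boundary set")
  mid <- (features$start + features$end) / 2
  count_near <- function(chrom, pos) {
    sum(vapply(seq_along(pos), function(i) {
      b <- boundaries$pos[boundaries$chrom == chrom[i]]
      length(b) > 0 && min(abs(b - pos[i])) <= tol
    }, TRUE))
  }
  observed <- count_near(features$chrom, mid)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_perm), function(k) {
    pos <- vapply(features$chrom, function(ch)
      sample(valid_positions[[ch]], 1), 0)
    count_near(features$chrom, pos)
  }, 0)
  p_hi <- empirical_p(sum(null_counts >= observed), n_perm)
  p_lo <- empirical_p(sum(null_counts <= observed), n_perm)
  structure(list(observed = observed, expected = mean(null_counts),
                 oe = observed / mean(null_counts),
                 p = min(1, 2 * min(p_hi, p_lo)), n_perm = n_perm),
            class = "enrichment_result")
}

# genes with TSS within +/- tol of any interval in a site set
genes_near_sites <- function(sites, genes, tol) {
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    s <- sites[sites$chrom == genes$chrom[i], , drop = FALSE]
    nrow(s) > 0 && any(genes$tss[i] >= s$start - tol & genes$tss[i] < s$end + tol)
  }, TRUE)
  unique(genes$gene_id[hit])
}

#' Gene-set enrichment at query sites versus equinumerous constant subsets
#'
#' Maps each site set to genes with a TSS within +/- `tol`, then compares the
#' per-gene-set hit count of the query sites against `n_subsets` random
#' subsets of the constant pool of the same size as the query. Reports the
#' ratio of the query count to the subset mean, the SEM across subsets, and an
#' empirical p.
#'
#' @param query,constant_pool `feature_set`s (|constant_pool| >= |query|).
#' @param genes gene model with `gene_id`, `chrom`, `tss`.
#' @param gene_sets named list of gene-id vectors (e.g. from [load_gmt()]).
#' @param n_subsets number of constant subsets (default 100).
#' @param tol gene-proximity window in bp (default 3 kb).
#' @param seed integer seed (each gene set consumes an independent sub-seed).
#' @return data.frame with set, query_count, subset_mean, subset_sem, ratio,
#'   p, n_subsets.
#' @export
geneset_enrichment_vs_constant <- function(query, constant_pool, genes, gene_sets,
                                           n_subsets = 100, tol = 3000, seed = 1) {
  assert_that(nrow(constant_pool) >= nrow(query),
              "constant pool smaller than the query set")
  q_genes <- genes_near_sites(query, genes, tol)
  set.seed(seed)
  sub_hits <- lapply(seq_len(n_subsets), function(k) {
    idx <- sample(nrow(constant_pool), nrow(query))
    genes_near_sites(constant_pool[idx, , drop = FALSE], genes, tol)
  })
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- gene_sets[[nm]]
    if (!any(gs %in% genes$gene_id)) {
      warning("gene set ", nm, " has no mappable genes; skipped")
      return(NULL)
    }
    qc <- sum(q_genes %in% gs)
    sc <- vapply(sub_hits, function(h) sum(h %in% gs), 0)
    data.frame(set = nm, query_count = qc, subset_mean = mean(sc),
               subset_sem = stats::sd(sc) / sqrt(n_subsets),
               ratio = qc / mean(sc),
               p = empirical_p(sum(sc >= qc), n_subsets),
               n_subsets = n_subsets)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expression change of genes colocalizing with boundary classes
#'
#' Assigns a gene to a boundary class when its TSS lies within +/- `tol` of a
#' boundary of that class (a gene may belong to several classes), then reports
#' per-class mean log2FC, SEM, and a two-sided rank-sum p against all genes.
#'
#' @param table a `boundary_class_table` with a `chrom` column, or a
#'   data.frame with `chrom`, `pos`, `class`.
#' @param expr an `expression_table` (needs `chrom`, `tss`, `log2FC`).
#' @param tol colocalization tolerance in bp (default 10 kb).
#' @return data.frame with class, n_genes, mean_log2fc, sem, p.
#' @export
boundary_expression_association <- function(table, expr, tol = 1e4) {
  assert_that(all(c("chrom", "pos", "class") %in% names(table)),
              "boundary table needs chrom, pos, class")
  rows <- lapply(sort(unique(table$class)), function(cl) {
    b <- table[table$class == cl, , drop = FALSE]
    hit <- vapply(seq_len(nrow(expr)), function(i) {
      pb <- b$pos[b$chrom == expr$chrom[i]]
      length(pb) > 0 && min(abs(pb - expr$tss[i])) <= tol
    }, TRUE)
    lfc <- expr$log2FC[hit]
    if (length(lfc) == 0)
      return(data.frame(class = cl, n_genes = 0L, mean_log2fc = NA_real_,
                        sem = NA_real_, p = NA_real_))
    data.frame(class = cl, n_genes = length(lfc), mean_log2fc = mean(lfc),
               sem = stats::sd(lfc) / sqrt(length(lfc)),
               p = suppressWarnings(stats::wilcox.test(lfc, expr$log2FC)$p.value))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between feature occupancy changes and expression changes
#'
#' Pairs each gene with its nearest feature whose midpoint is within +/- `tol`
#' of the TSS (one feature per gene, so a gene flanked by several altered
#' sites is not double-counted) and correlates feature logFC with gene log2FC.
#'
#' @param features data.frame with `chrom`, `start`, `end`, `logFC`.
#' @param expr expression table with `chrom`, `tss`, `log2FC`.
#' @param tol pairing window in bp (default 3 kb).
#' @param method "spearman" (default) or "pearson".
#' @return list with `r`, `p`, `n` (number of pairs).
#' @export
delta_delta_correlation <- function(features, expr, tol = 3000,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  mid <- (features$start + features$end) / 2
  pair_lfc <- vapply(seq_len(nrow(expr)), function(i) {
    j <- which(features$chrom == expr$chrom[i] & abs(mid - expr$tss[i]) <= tol)
    if (length(j) == 0) return(NA_real_)
    features$logFC[j[which.min(abs(mid[j] - expr$tss[i]))]]
  }, 0)
  ok <- !is.na(pair_lfc)
  assert_that(sum(ok) >= 3, "fewer than 3 colocalized (feature, gene) pairs")
  ct <- suppressWarnings(stats::cor.test(pair_lfc[ok], expr$log2FC[ok], method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Rank genes by correlation with a reference gene across samples
#'
#' For every gene, computes the Spearman correlation (rho, p) with the
#' reference gene's expression across samples and the signed score
#' sign(rho) * (-log10 p); returns genes sorted by score, so the strongest
#' positive correlates rank first. Zero-variance genes are excluded with a
#' warning; a zero-variance reference is an error.
#'
#' @param expr_matrix numeric matrix, genes x samples, with gene rownames.
#' @param reference_gene rowname of the reference gene.
#' @return data.frame with gene, rho, p, score, sorted by score descending.
#' @export
correlation_ranking <- function(expr_matrix, reference_gene) {
  assert_that(ncol(expr_matrix) >= 5, "need >= 5 samples")
  assert_that(reference_gene %in% rownames(expr_matrix),
              paste("reference gene not found:", reference_gene))
  ref <- expr_matrix[reference_gene, ]
  assert_that(stats::sd(ref) > 0, "reference gene has zero variance")
  keep <- apply(expr_matrix, 1, stats::sd) > 0
  if (!all(keep)) warning(sum(!keep), " zero-variance genes excluded")
  genes <- setdiff(rownames(expr_matrix)[keep], reference_gene)
  rows <- lapply(genes, function(g) {
    ct <- suppressWarnings(stats::cor.test(expr_matrix[g, ], ref, method = "spearman"))
    data.frame(gene = g, rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$score <- sign(out$rho) * (-log10(pmax(out$p, .Machine$double.xmin)))
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  out
}
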