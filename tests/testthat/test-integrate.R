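test_that("O/E boundary enrichment matches the overlap oracle and detects placement", {
  valid <- list(c1 = seq(0, 5e6, 1e4))
  bnd <- data.frame(chrom = "c1", pos = seq(2e5, 4.8e6, 2.5e5))
  feats <- feature_set(data.frame(chrom = "c1", start = bnd$pos - 500,
                                  end = bnd$pos + 500))
  r <- oe_boundary_enrichment(feats, bnd, valid, tol = 1e4, n_perm = 99, seed = 2)
  expect_equal(r$observed, nrow(feats))
  expect_gt(r$oe, 1)
  expect_equal(r$p, 2 / 100)  # both tails use (1+k)/(n+1); upper tail is minimal

  set.seed(9)
  rnd <- feature_set(data.frame(chrom = "c1", start = st <- sample(seq(0, 4.9e6, 1e4), 40),
                                end = st + 800))
  r2 <- oe_boundary_enrichment(rnd, bnd, valid, tol = 1e4, n_perm = 199, seed = 3)
  mids <- (rnd$start + rnd$end) / 2
  expect_equal(r2$observed,
               bf_overlap_count(mids, rnd$chrom, bnd$pos, bnd$chrom, 1e4))
  expect_gt(r2$p, 0.05)  # uniform features are unenriched
  expect_error(oe_boundary_enrichment(rnd[0, ], bnd, valid), "empty feature")
})

test_that("gene-set enrichment versus constant subsets flags constructed signal", {
  set.seed(11)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:200), chrom = "c1",
                      tss = sort(sample(seq(1e4, 5e6, 2e4), 200)))
  sets <- list(target = genes$gene_id[1:40], other = genes$gene_id[101:140])
  # query sites adjacent to 'target' genes; constant pool uniform
  query <- feature_set(data.frame(chrom = "c1",
                                  start = genes$tss[1:25] - 200,
                                  end = genes$tss[1:25] + 200))
  pool <- feature_set(data.frame(chrom = "c1",
                                 start = st <- sample(seq(0, 5e6, 5e3), 300),
                                 end = st + 400))
  res <- geneset_enrichment_vs_constant(query, pool, genes, sets,
                                        n_subsets = 100, seed = 12)
  expect_equal(res$n_subsets, c(100, 100))  # bookkeeping: all subsets contribute
  tgt <- res[res$set == "target", ]
  expect_gt(tgt$ratio, res$ratio[res$set == "other"])
  expect_lte(tgt$p, 0.05)
  # a query drawn from the pool itself is unenriched everywhere
  set.seed(13)
  q0 <- pool[sample(nrow(pool), 25), ]
  res0 <- geneset_enrichment_vs_constant(q0, pool, genes, sets,
                                         n_subsets = 100, seed = 14)
  expect_true(all(res0$p > 0.05))
  expect_warning(
    geneset_enrichment_vs_constant(query, pool, genes,
                                   list(empty = c("zz1", "zz2")), seed = 1),
    "no mappable")
})

test_that("boundary-expression association equals the direct per-class means", {
  tab <- data.frame(chrom = "c1", pos = c(1e5, 3e5, 5e5, 7e5),
                    class = c("gained", "gained", "lost", "constant"))
  expr <- expression_table(data.frame(
    gene_id = sprintf("g%d", 1:6), chrom = "c1",
    tss = c(1.05e5, 2.95e5, 5.02e5, 7.01e5, 9e5, 1.2e6),
    strand = "+", basemean = 200,
    log2FC = c(1.2, 0.8, -0.5, 0.1, 0, 0.05), padj = rep(0.5, 6)))
  res <- boundary_expression_association(tab, expr, tol = 1e4)
  expect_equal(res$mean_log2fc[res$class == "gained"], mean(c(1.2, 0.8)))
  expect_equal(res$mean_log2fc[res$class == "lost"], -0.5)
  expect_equal(res$n_genes[res$class == "constant"], 1)
  # flat expression: class means are zero
  expr0 <- expr; expr0$log2FC <- 0
  res0 <- suppressWarnings(boundary_expression_association(tab, expr0, tol = 1e4))
  expect_true(all(res0$mean_log2fc == 0))
})

test_that("delta-delta correlation pairs nearest features and matches rank formula", {
  feats <- data.frame(chrom = "c1", start = seq(1e4, 8e4, 1e4) - 300,
                      end = seq(1e4, 8e4, 1e4) + 300,
                      logFC = c(2, -1, 0.5, 1.5, -2, 0.2, -0.7, 1))
  expr <- expression_table(data.frame(
    gene_id = sprintf("g%d", 1:8), chrom = "c1", tss = seq(1e4, 8e4, 1e4) + 100,
    strand = "+", basemean = 150, log2FC = feats$logFC, padj = 0.5))
  r1 <- delta_delta_correlation(feats, expr, tol = 3000)
  expect_equal(r1$r, 1)
  expect_equal(r1$n, 8)

  expr2 <- expr; expr2$log2FC <- c(0.3, 1.8, -0.2, 0.9, -1.1, 2, 0.1, -0.4)
  r2 <- delta_delta_correlation(feats, expr2, tol = 3000, method = "spearman")
  expect_equal(r2$r, cor(rank(feats$logFC), rank(expr2$log2FC)))
  expect_error(delta_delta_correlation(feats[1, ], expr[1, ], tol = 10), "fewer than 3")
})

test_that("correlation ranking orders by signed -log10 p with exact small-n p-values", {
  set.seed(21)
  m <- matrix(rnorm(6 * 6), 6, 6, dimnames = list(sprintf("g%d", 1:6), NULL))
  m["g2", ] <- m["g1", ]             # identical to the reference
  rk <- correlation_ranking(m, "g1")
  expect_equal(rk$gene[1], "g2")
  expect_equal(rk$rho[1], 1)
  # p agrees with exhaustive permutation enumeration at n = 6
  for (g in c("g3", "g4")) {
    p_exact <- bf_spearman_perm_p(m["g1", ], m[g, ])
    expect_equal(rk$p[rk$gene == g], p_exact, tolerance = 0.02)
  }
  m2 <- rbind(m, gz = rep(1, 6))
  expect_warning(rk2 <- correlation_ranking(m2, "g1"), "zero-variance")
  expect_false("gz" %in% rk2$gene)
  expect_error(correlation_ranking(m2, "gz"), "zero variance")
})

test_that("independent genes yield roughly uniform correlation p-values", {
  set.seed(31)
  ps <- unlist(lapply(1:10, function(s) {
    m <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(sprintf("g%d", 1:30), NULL))
    correlation_ranking(m, "g1")$p
  }))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})
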