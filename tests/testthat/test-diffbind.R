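mk_binned_track <- function(values, res = 100, chrom = "c1") {
  feature_set(data.frame(chrom = chrom, start = seq_along(values) * res - res,
                         end = seq_along(values) * res, score = values))
}

test_that("peak scoring equals the direct bp-weighted oracle", {
  set.seed(2)
  vals <- rpois(100, 10)
  tr <- mk_binned_track(vals)
  libsize <- sum(vals * 100)
  peaks <- feature_set(data.frame(chrom = "c1",
                                  start = st <- sample(0:9000, 10),
                                  end = st + sample(c(150, 400, 730), 10, TRUE)))
  sc <- score_peaks(peaks, list(r1 = tr))
  for (p in 1:10) {
    bp <- (peaks$start[p]):(peaks$end[p] - 1)
    direct <- mean(vals[bp %/% 100 + 1]) * 1e6 / libsize
    expect_equal(unname(sc[p, 1]), direct, tolerance = 1e-12)
  }
  # zero track scores zero; overlapping peaks are scored independently
  z <- score_peaks(peaks, list(r1 = mk_binned_track(rep(0, 100))))
  expect_true(all(z == 0))
  ov <- feature_set(data.frame(chrom = "c1", start = c(1000, 1100),
                               end = c(1400, 1500)))
  sc2 <- score_peaks(ov, list(r1 = tr))
  expect_equal(unname(sc2[1, 1]), mean(vals[11:14]) * 1e6 / libsize)
  expect_equal(unname(sc2[2, 1]), mean(vals[12:15]) * 1e6 / libsize)
  out <- feature_set(data.frame(chrom = "c1", start = 9900, end = 10500))
  expect_error(score_peaks(out, list(r1 = tr)), "outside")
})

test_that("differential classification recovers implanted losses and respects thresholds", {
  set.seed(7)
  n <- 400
  truth <- rep(c("constant", "lost", "gained"), c(300, 70, 30))
  occ <- 2^rnorm(n, 5, 0.7)
  lfc <- ifelse(truth == "lost", -2, ifelse(truth == "gained", 2, 0))
  dens <- cbind(occ * 2^rnorm(n, 0, 0.3), occ * 2^rnorm(n, 0, 0.3),
                occ * 2^lfc * 2^rnorm(n, 0, 0.3), occ * 2^lfc * 2^rnorm(n, 0, 0.3))
  res <- classify_differential(dens, c("ctl", "ctl", "trt", "trt"),
                               fdr_max = 0.01, logfc_min = 1)
  sens <- sum(res$class == "lost" & truth == "lost") / sum(truth == "lost")
  fdr <- sum(res$class == "lost" & truth != "lost") / max(1, sum(res$class == "lost"))
  expect_gte(sens, 0.8)
  expect_lte(fdr, 0.1)
  # class rule: significant + logFC below -1 is lost, above +1 gained
  expect_true(all(res$FDR[res$class == "lost"] < 0.01))
  expect_true(all(res$logFC[res$class == "lost"] < -1))
  expect_true(all(res$logFC[res$class == "gained"] > 1))
  # FDR equals the BH step-up oracle on the same p-values
  expect_equal(res$FDR, bh_stepup(res$pvalue))

  same <- cbind(occ, occ, occ, occ)
  res0 <- classify_differential(same, c("ctl", "ctl", "trt", "trt"))
  expect_true(all(res0$logFC == 0))
  expect_true(all(res0$class == "constant"))
  expect_error(classify_differential(dens[, c(1, 3, 4)], c("ctl", "trt", "trt")),
               "2 replicates")
})

test_that("library scaling leaves logFC and classes unchanged", {
  set.seed(8)
  vals <- rpois(200, 8)
  peaks <- feature_set(data.frame(chrom = "c1", start = st <- seq(100, 15000, 1500),
                                  end = st + 500))
  tracks <- list(c1 = mk_binned_track(vals), c2 = mk_binned_track(rpois(200, 8)),
                 t1 = mk_binned_track(rpois(200, 16)), t2 = mk_binned_track(rpois(200, 16)))
  scaled <- lapply(tracks, function(tr) { tr$score <- tr$score * 13; tr })
  d1 <- classify_differential(score_peaks(peaks, tracks), c("c", "c", "t", "t"))
  d2 <- classify_differential(score_peaks(peaks, scaled), c("c", "c", "t", "t"))
  expect_equal(d1$logFC, d2$logFC)
  expect_equal(d1$class, d2$class)
})

test_that("genomic context annotation partitions features with promoter precedence", {
  genes <- data.frame(chrom = "c1", start = c(10000, 50000), end = c(20000, 70000),
                      tss = c(10000, 69999), strand = c("+", "-"))
  feats <- feature_set(data.frame(
    chrom = "c1",
    start = c(9500, 15000, 30000, 68000),
    end = c(10500, 15500, 30500, 68500)))
  ctx <- annotate_context(feats, genes, promoter_flank = 3000)
  expect_equal(ctx, c("promoter", "gene body", "distal intergenic", "promoter"))
  expect_equal(sum(table(ctx)), nrow(feats))  # partition
  expect_warning(ctx0 <- annotate_context(feats, genes[0, ]), "empty gene model")
  expect_true(all(ctx0 == "distal intergenic"))
})

test_that("TSS metaprofiles average windows with strand reversal", {
  vals <- c(rep(1, 40), 5, rep(1, 59))   # spike at bin 41
  tr <- mk_binned_track(vals)
  genes <- data.frame(chrom = "c1", tss = c(4050), strand = "+")
  prof <- tss_metaprofile(tr, genes, flank = 500)
  expect_equal(as.numeric(prof), c(1, 1, 1, 1, 1, 5, 1, 1, 1, 1, 1))
  # minus strand reverses the window
  gm <- data.frame(chrom = "c1", tss = 4250, strand = "-")
  pm <- tss_metaprofile(tr, gm, flank = 500)
  expect_equal(as.numeric(pm), rev(as.numeric(tss_metaprofile(
    tr, data.frame(chrom = "c1", tss = 4250, strand = "+"), flank = 500))))
  # direct oracle over several genes
  set.seed(5)
  g5 <- data.frame(chrom = "c1", tss = sample(2000:8000, 5), strand = "+")
  p5 <- tss_metaprofile(tr, g5, flank = 300)
  direct <- rowMeans(sapply(g5$tss, function(t) vals[(t %/% 100 + 1 - 3):(t %/% 100 + 1 + 3)]))
  expect_equal(as.numeric(p5), direct)
  # uniform track gives a flat profile at its value
  pu <- tss_metaprofile(mk_binned_track(rep(2.5, 100)), g5, flank = 300)
  expect_true(all(pu == 2.5))
  expect_error(tss_metaprofile(tr, genes[0, ], 500), "empty gene subset")
})
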