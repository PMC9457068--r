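sizes1 <- c(cA = 8e6)  # small genome for generator unit tests

test_that("hierarchy generation is deterministic and respects nesting", {
  h1 <- generate_domain_hierarchy(sizes1, seed = 5)
  h2 <- generate_domain_hierarchy(sizes1, seed = 5)
  expect_identical(h1, h2)
  h3 <- generate_domain_hierarchy(sizes1, seed = 6)
  expect_false(identical(h1$chroms$cA$tad$bin, h3$chroms$cA$tad$bin))

  # every subTAD boundary lies strictly inside exactly one TAD
  tads <- domain_intervals(h1, "cA", "tad")
  for (b in h1$chroms$cA$subtad$bin) {
    hits <- sum(b > tads$start_bin & b < tads$end_bin)
    expect_equal(hits, 1)
    expect_false(b %in% h1$chroms$cA$tad$bin)
  }
  # finest level tiles the chromosome without gaps or overlap
  fin <- domain_intervals(h1, "cA", "subtad")
  expect_equal(fin$start_bin[1], 0)
  expect_equal(fin$end_bin[nrow(fin)], h1$chroms$cA$n_bins)
  expect_true(all(fin$start_bin[-1] == fin$end_bin[-nrow(fin)]))

  h0 <- generate_domain_hierarchy(sizes1, subtads_per_tad = 0, seed = 5)
  expect_equal(nrow(h0$chroms$cA$subtad), 0)

  expect_error(generate_domain_hierarchy(c(cA = 1.5e6)), "shorter")
})

test_that("simulated contacts decay with the requested exponent", {
  # flat genome (no domains) so the diagonal means isolate the decay law
  h <- generate_domain_hierarchy(c(cA = 8e6), tad_size = c(1e5, 1e6),
                                 subtads_per_tad = 0, seed = 3)
  h$chroms$cA$tad <- h$chroms$cA$tad[0, ]
  for (alpha in c(0.8, 1.2)) {
    cm <- simulate_contact_matrix(h, "cA", depth = 1e4, alpha = alpha,
                                  e_tad = 1, e_subtad = 1, seed = 11)
    dm <- bf_diag_means(cm$counts)[1:40]
    fit <- lm(log(dm) ~ log(1 + 0:39))
    expect_lt(abs(coef(fit)[2] + alpha) / alpha, 0.10)
  }
  cm0 <- simulate_contact_matrix(h, "cA", depth = 0, seed = 1)
  expect_true(all(cm0$counts == 0))
  expect_error(simulate_contact_matrix(h, "cA", depth = -1), "depth")
})

test_that("subTAD enrichment raises within-domain obs/exp above cross-boundary", {
  h <- generate_domain_hierarchy(sizes1, seed = 9)
  cm <- simulate_contact_matrix(h, "cA", depth = 100, e_subtad = 2, seed = 2)
  dm <- bf_diag_means(cm$counts)
  fin <- domain_intervals(h, "cA", "subtad")
  dom_of <- findInterval(0:(h$chroms$cA$n_bins - 1), fin$start_bin)
  tad_of <- findInterval(0:(h$chroms$cA$n_bins - 1), c(0, h$chroms$cA$tad$bin))
  n <- h$chroms$cA$n_bins
  within <- c(); cross <- c()
  set.seed(4)
  for (q in 1:4000) {   # sampled bin pairs at short range
    i <- sample(n - 20, 1); j <- i + sample(3:20, 1)
    oe <- cm$counts[i, j] / dm[j - i + 1]
    if (dom_of[i] == dom_of[j]) within <- c(within, oe)
    else if (tad_of[i] == tad_of[j]) cross <- c(cross, oe)
  }
  expect_gt(mean(within), mean(cross))
})

test_that("perturbation removes/adds the requested boundary counts and keeps records consistent", {
  h <- generate_domain_hierarchy(c(cA = 2e7, cB = 2e7), seed = 21)
  n_sub <- sum(sapply(h$chroms, function(c) nrow(c$subtad)))
  n_tad <- sum(sapply(h$chroms, function(c) nrow(c$tad)))

  p0 <- perturb_hierarchy(h, 0, 0, 0, 0, seed = 1)
  expect_identical(p0$hierarchy, h)
  expect_equal(nrow(p0$record), 0)

  p <- perturb_hierarchy(h, seed = 8)
  rec <- p$record
  expect_equal(sum(rec$level == "subtad" & rec$change == "removed"), round(0.17 * n_sub))
  expect_equal(sum(rec$level == "subtad" & rec$change == "added"), round(0.11 * n_sub))
  expect_equal(sum(rec$level == "tad" & rec$change == "removed"), round(0.10 * n_tad))
  expect_equal(sum(rec$level == "tad" & rec$change == "added"), round(0.07 * n_tad))

  for (ch in names(h$chroms)) {
    orig_tad <- h$chroms[[ch]]$tad$bin
    rem <- rec$bin[rec$chrom == ch & rec$level == "tad" & rec$change == "removed"]
    add <- rec$bin[rec$chrom == ch & rec$level == "tad" & rec$change == "added"]
    expect_true(all(rem %in% orig_tad))          # removed subset of original
    expect_length(intersect(add, orig_tad), 0)   # added disjoint from original
    # merge arithmetic: TAD count changes by additions - removals
    expect_equal(nrow(p$hierarchy$chroms[[ch]]$tad),
                 length(orig_tad) - length(rem) + length(add))
    # bin count conserved
    expect_equal(p$hierarchy$chroms[[ch]]$n_bins, h$chroms[[ch]]$n_bins)
  }
})

test_that("added boundaries concentrate near removed ones", {
  h <- generate_domain_hierarchy(c(cA = 2e7, cB = 2e7), seed = 31)
  p <- perturb_hierarchy(h, seed = 32)
  rec <- p$record
  added <- rec[rec$change == "added", ]
  removed <- rec[rec$change == "removed", ]
  d <- sapply(seq_len(nrow(added)), function(i) {
    r <- removed$pos[removed$chrom == added$chrom[i]]
    min(abs(r - added$pos[i]))
  })
  expect_gt(mean(d <= 1e5), 0.8)  # placement window is 100 kb
})

test_that("feature simulation honors coupling contracts and occupancy ordering", {
  h <- generate_domain_hierarchy(sizes1, seed = 41)
  p <- perturb_hierarchy(h, seed = 42)
  f <- simulate_features(h, p$record, list(ctcf_coupling = 1), seed = 43)

  removed_sub <- p$record[p$record$change == "removed" & p$record$level == "subtad", ]
  lost_peaks <- f$ctcf[f$ctcf$truth_class == "lost", ]
  for (i in seq_len(nrow(removed_sub))) {
    mids <- (lost_peaks$start + lost_peaks$end) / 2
    d <- abs(mids[lost_peaks$chrom == removed_sub$chrom[i]] - removed_sub$pos[i])
    expect_lte(min(d), 1e4)  # coupling 1: truth-lost peak within +/-10 kb
  }
  expect_lt(mean(f$ctcf$occ_ctl[f$ctcf$truth_class == "lost"]),
            mean(f$ctcf$occ_ctl[f$ctcf$truth_class == "constant"]))

  # truth classes partition each feature set
  expect_true(all(f$ctcf$truth_class %in% c("constant", "lost", "gained")))
  expect_true(all(f$marks$h3k27ac$truth_class %in%
                    c("constant", "lost", "gained", "coupled")))

  # genes near added subTAD boundaries carry the implanted offset
  g <- f$genes
  expect_gt(mean(g$true_log2fc[g$near_added_subtad]), 0.7)
  expect_lt(abs(mean(g$true_log2fc[!g$near_added_subtad])), 0.25)
})

test_that("boundary-loss and peak-loss decouple at coupling zero", {
  h <- generate_domain_hierarchy(sizes1, seed = 51)
  p <- perturb_hierarchy(h, seed = 52)
  removed <- p$record[p$record$change == "removed", c("chrom", "pos")]
  cors <- sapply(1:30, function(s) {
    f <- simulate_features(h, p$record,
                           list(ctcf_coupling = 0, bg_lost_frac = 0.3), seed = s)
    pk <- f$ctcf
    near_removed <- sapply(seq_len(nrow(pk)), function(i) {
      r <- removed$pos[removed$chrom == pk$chrom[i]]
      length(r) > 0 && min(abs(r - pk$pos[i])) <= 1e4
    })
    suppressWarnings(cor(as.numeric(near_removed),
                         as.numeric(pk$truth_class == "lost")))
  })
  expect_lt(abs(mean(cors, na.rm = TRUE)), 0.1)
})

test_that("the full synthetic study is reproducible under a fixed seed", {
  cfg <- default_config(seed = 77)
  cfg$chrom_sizes <- c(cA = 6e6)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$record, s2$record)
  expect_identical(s1$matrices$cA$ctl$counts, s2$matrices$cA$ctl$counts)
  expect_identical(s1$features$expression$log2FC, s2$features$expression$log2FC)
})
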