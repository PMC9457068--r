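test_that("anchor pileups equal the direct window average and keep symmetry", {
  cm <- toy_decay_matrix(100, depth = 200, seed = 41)
  cmb <- balance(cm)
  oe <- oe_matrix(cmb)
  anchors <- c(30, 52, 71) * 1e4 - 5e3  # bin centers (1-based bins 30, 52, 71)
  pr <- anchor_pileup(cmb, anchors, flank = 5e4, n_random_sets = 0)
  expect_equal(pr$n_anchors, 3)
  expect_equal(pr$matrix, bf_anchor_pileup(oe, c(30, 52, 71), 5), tolerance = 1e-12)
  expect_equal(pr$matrix, t(pr$matrix), tolerance = 1e-12)  # reflection symmetry

  # single anchor: the pileup is exactly that anchor's window
  p1 <- anchor_pileup(cmb, anchors[1], flank = 5e4, n_random_sets = 0)
  expect_equal(p1$matrix, oe[25:35, 25:35], ignore_attr = TRUE)

  # matrix equal to its expectation: obs/exp pileup is 1 everywhere
  flat <- toy_decay_matrix(100, depth = 200)  # noiseless decay
  attr(flat, "balanced") <- TRUE
  pf <- anchor_pileup(flat, anchors, flank = 5e4, n_random_sets = 0)
  expect_lt(max(abs(pf$matrix - 1)), 1e-10)
  pfn <- anchor_pileup(flat, anchors, flank = 5e4, n_random_sets = 5, seed = 1)
  expect_lt(max(abs(pfn$matrix - 1)), 1e-10)

  expect_error(anchor_pileup(cmb, c(1e4), flank = 5e5), "no usable anchors")
})

test_that("pileups at insulated boundaries deplete the cross-boundary quadrants", {
  h <- generate_domain_hierarchy(c(cA = 1e7), seed = 91)
  cm <- simulate_contact_matrix(h, "cA", depth = 100, seed = 92)
  anchors <- h$chroms$cA$tad$bin * 1e4 + 5e3
  pr <- anchor_pileup(balance(cm), anchors, flank = 1e5, n_random_sets = 0)
  k <- pr$center - 1
  on_diag <- c(pr$matrix[1:k, 1:k], pr$matrix[(k + 2):(2 * k + 1), (k + 2):(2 * k + 1)])
  off_diag <- c(pr$matrix[1:k, (k + 2):(2 * k + 1)], pr$matrix[(k + 2):(2 * k + 1), 1:k])
  expect_lt(mean(off_diag), mean(on_diag))
})

test_that("paired pileups match the enumeration oracle and detect implanted dots", {
  n <- 120
  cm <- toy_decay_matrix(n, depth = 300)   # noiseless expectation
  # implant a reciprocal dot between bins 40 and 80
  m <- cm$counts
  m[38:42, 78:82] <- m[38:42, 78:82] * 3
  m[78:82, 38:42] <- t(m[38:42, 78:82])
  cmd <- contact_matrix(m, "chrT", 1e4)
  attr(cmd, "balanced") <- TRUE
  a <- 40 * 1e4 - 5e3; b <- 80 * 1e4 - 5e3
  pp <- paired_pileup(cmd, a, b, flank = 5e4, min_sep = 1.5e5, max_sep = 3e6)
  expect_equal(pp$n_pairs, 1)
  expect_gt(pp$center_ring_ratio, 1.2)
  # direct oracle: with one pair the window is read straight off obs/exp
  oe <- oe_matrix(cmd)
  expect_equal(pp$matrix, oe[35:45, 75:85], ignore_attr = TRUE)

  # null case: A = B on the noiseless matrix gives a flat pileup at 1
  attr(cm, "balanced") <- TRUE
  ps <- paired_pileup(cm, c(30, 60, 90) * 1e4, c(30, 60, 90) * 1e4,
                      flank = 3e4, min_sep = 1e5, max_sep = 3e6)
  expect_lt(max(abs(ps$matrix - 1)), 1e-10)
  expect_error(paired_pileup(cm, a, b, flank = 5e4, min_sep = 9e4), "min_sep")
})

test_that("insulation profiles stack windows and show the boundary V-shape", {
  tr0 <- structure(list(chrom = "c", resolution = 1e4, window = 5e4,
                        score = rep(0, 200)), class = "insulation_track")
  prof0 <- insulation_profile(list(x = tr0), c(5e5, 1e6), flank = 1e5)
  expect_true(all(prof0 == 0))

  h <- generate_domain_hierarchy(c(cA = 1e7), seed = 95)
  cm <- simulate_contact_matrix(h, "cA", depth = 100, seed = 96)
  tr <- insulation_track(balance(cm), 5e4)
  anchors <- h$chroms$cA$tad$bin * 1e4
  prof <- insulation_profile(list(ctl = tr), anchors + 5e3, flank = 1e5)
  k <- (nrow(prof) - 1) / 2
  expect_lt(prof[k + 1, "ctl"], prof[1, "ctl"])       # V-shape
  expect_lt(prof[k + 1, "ctl"], prof[nrow(prof), "ctl"])
  expect_lte(abs(unname(which.min(prof[, "ctl"])) - (k + 1)), 1)

  # direct stacking oracle on a handful of anchors
  bins <- floor((anchors[1:5] + 5e3) / 1e4) + 1
  direct <- rowMeans(sapply(bins, function(b) tr$score[(b - 10):(b + 10)]))
  expect_equal(as.numeric(insulation_profile(list(a = tr), anchors[1:5] + 5e3, 1e5)),
               direct)
  expect_error(insulation_profile(list(a = tr), numeric(), 1e5), "empty anchor")
})
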