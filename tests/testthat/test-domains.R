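mk_track <- function(score, res = 1e4) {
  structure(list(chrom = "c", resolution = res, window = 5e4, score = score),
            class = "insulation_track")
}

test_that("boundary calling finds prominent minima and nothing on flat tracks", {
  expect_equal(nrow(call_boundaries(mk_track(rep(0.3, 50)))), 0)

  # deterministic track with two strong minima and one weak dip
  x <- rep(0, 60)
  x[20] <- -2; x[21] <- -2.1          # strong (plateau-ish) minimum
  x[40] <- -0.08                      # weak dip below default prominence
  b <- call_boundaries(mk_track(x), min_prominence = 0.15)
  expect_equal(b$bin, 20)             # 0-based argmin at index 21
  expect_gt(b$strength, 2)

  # raising the threshold never increases the count
  set.seed(9)
  noisy <- cumsum(rnorm(200, 0, 0.2))
  counts <- sapply(seq(0, 1.5, 0.1), function(mp)
    nrow(call_boundaries(mk_track(noisy), mp)))
  expect_true(all(diff(counts) <= 0))

  expect_error(call_boundaries(mk_track(rep(NA_real_, 30))), "all-missing")
})

test_that("implanted boundaries are recovered from simulated matrices", {
  h <- generate_domain_hierarchy(c(cA = 1e7), f_tad = c(0.1, 0.3),
                                 subtads_per_tad = 0, seed = 71)
  cm <- simulate_contact_matrix(h, "cA", depth = 100, seed = 72)
  tr <- insulation_track(balance(cm), 1e5)
  b <- call_boundaries(tr, min_prominence = 0.5)
  truth <- h$chroms$cA$tad$bin * 1e4
  hit <- sapply(truth, function(p) min(abs(b$pos - p)) <= 1e4)  # +/- 1 bin
  expect_gte(mean(hit), 0.9)
})

test_that("two-scale calling separates TAD and subTAD levels", {
  h <- generate_domain_hierarchy(c(cA = 1e7), seed = 81)
  cm <- simulate_contact_matrix(h, "cA", depth = 100, seed = 82)
  bh <- call_hierarchy(cm)
  # no subTAD call within one bin of a TAD call
  expect_false(any(sapply(bh$subtad$bin, function(b) any(abs(bh$tad$bin - b) <= 1))))
  # uniform single domain (constant contact matrix): no boundaries at all
  cm0 <- contact_matrix(matrix(8, 300, 300), "cA", 1e4)
  bh0 <- call_hierarchy(cm0)
  expect_equal(nrow(bh0$tad), 0)
  expect_equal(nrow(bh0$subtad), 0)
  expect_error(call_hierarchy(cm, coarse_window = 5e4, fine_window = 1e5), "exceed")
})

test_that("boundary classification matches identity, tolerance and partition contracts", {
  s <- c(1e5, 5e5, 9e5)
  t0 <- classify_boundaries(s, s, s, tol = 1e4)
  expect_equal(t0$class, rep("constant", 3))

  t1 <- classify_boundaries(1e5, 1.08e5, 1.08e5, tol = 1e4)
  expect_equal(t1$class, "constant")   # 8 kb shift within tolerance

  t2 <- classify_boundaries(c(1e5, 5e5), c(1e5), c(1e5, 8e5), tol = 1e4)
  expect_setequal(t2$class[t2$pos == 1e5], "constant")
  expect_equal(t2$class[t2$pos == 5e5], "lost")
  expect_equal(t2$class[t2$pos == 8e5], "discordant")
})

test_that("classification agrees with an exhaustive matching oracle on random sets", {
  for (seed in 1:12) {
    set.seed(seed)
    ctl <- sort(sample(seq(0, 2e6, 1e4), sample(3:8, 1)))
    c1 <- sort(ctl + sample(c(-2e4, -1e4, 0, 1e4, 2e4), length(ctl), TRUE))
    c1 <- c1[runif(length(c1)) > 0.3]
    c2 <- sort(sample(seq(0, 2e6, 1e4), sample(3:8, 1)))
    tab <- classify_boundaries(ctl, c1, c2, tol = 1e4)
    # greedy matching attains maximum cardinality
    expect_equal(nrow(match_positions(ctl, c1, 1e4)), bf_max_matching(ctl, c1, 1e4))
    expect_equal(nrow(match_positions(ctl, c2, 1e4)), bf_max_matching(ctl, c2, 1e4))
    # classes partition the merged boundary entities
    expect_equal(sum(table(tab$class)), nrow(tab))
    expect_equal(sum(tab$source == "control"), length(ctl))
    # swapping the clones leaves the classes unchanged
    tab_sw <- classify_boundaries(ctl, c2, c1, tol = 1e4)
    expect_equal(sort(table(tab$class)), sort(table(tab_sw$class)))
    expect_equal(tab$class[tab$source == "control"],
                 tab_sw$class[tab_sw$source == "control"])
  }
})

test_that("gained-lost adjacency detects constructed proximity and stays null otherwise", {
  valid <- seq(0, 2e7, 1e4)
  set.seed(3)
  lost <- sort(sample(valid, 25))
  gained_near <- lost[1:12] + sample(c(-5e4, -2e4, 2e4, 5e4), 12, TRUE)
  r1 <- gained_lost_adjacency(gained_near, lost, valid, n_random = 999, seed = 4)
  expect_gt(r1$ratio, 1)
  expect_lte(r1$p, 0.05)

  ratios <- sapply(1:15, function(s) {
    set.seed(s + 100)
    g <- sample(valid, 12)
    gained_lost_adjacency(g, lost, valid, n_random = 199, seed = s)$ratio
  })
  expect_lt(abs(median(ratios) - 1), 0.35)
  expect_error(gained_lost_adjacency(numeric(), lost, valid), "at least one")
})
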