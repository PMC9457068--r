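# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use direct enumeration / textbook formulas, not the
# package's own code paths.

bf_diag_means <- function(m, mask = rep(TRUE, nrow(m))) {
  n <- nrow(m)
  sapply(0:(n - 1), function(d) {
    v <- c()
    for (i in 1:(n - d)) if (mask[i] && mask[i + d]) v <- c(v, m[i, i + d])
    if (length(v)) mean(v) else NA_real_
  })
}

bf_insulation <- function(m, w, mask = rep(TRUE, nrow(m))) {
  n <- nrow(m)
  s <- rep(NA_real_, n)
  for (i in 1:n) {
    if (i - w < 1 || i + w > n) next
    if (!all(mask[(i - w):(i + w)])) next
    tot <- 0
    for (a in (i - w):(i - 1)) for (b in (i + 1):(i + w)) tot <- tot + m[a, b]
    s[i] <- tot
  }
  log2(s / mean(s, na.rm = TRUE))
}

bf_pearson_oe_pixels <- function(ma, mb, maxd) {
  n <- nrow(ma)
  ea <- bf_diag_means(ma); eb <- bf_diag_means(mb)
  xa <- c(); xb <- c()
  for (i in 1:n) for (j in i:n) {
    d <- j - i
    if (d > maxd) next
    xa <- c(xa, ma[i, j] / ea[d + 1]); xb <- c(xb, mb[i, j] / eb[d + 1])
  }
  cor(xa, xb)
}

bf_overlap_count <- function(mids, chroms, bpos, bchrom, tol) {
  sum(sapply(seq_along(mids), function(i) {
    b <- bpos[bchrom == chroms[i]]
    length(b) > 0 && min(abs(b - mids[i])) <= tol
  }))
}

# exhaustive maximum one-to-one matching cardinality within tol (n small)
bf_max_matching <- function(x, y, tol) {
  best <- 0
  recur <- function(i, used_y, count) {
    if (count + (length(x) - i + 1) <= best) return()
    if (i > length(x)) { best <<- max(best, count); return() }
    recur(i + 1, used_y, count)   # leave x[i] unmatched
    for (j in seq_along(y)) {
      if (!used_y[j] && abs(x[i] - y[j]) <= tol) {
        used_y[j] <- TRUE
        recur(i + 1, used_y, count + 1)
        used_y[j] <- FALSE
      }
    }
  }
  recur(1, logical(length(y)), 0)
  best
}

bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (k in n:1) {
    running <- min(running, p[o[k]] * n / k)
    adj[o[k]] <- running
  }
  adj
}

# exact two-sided permutation p for Spearman rho, n <= 7
bf_spearman_perm_p <- function(x, y) {
  rho_of <- function(a, b) cor(rank(a), rank(b))
  obs <- abs(rho_of(x, y))
  perms <- combinat_perms(length(y))
  stats <- apply(perms, 1, function(idx) abs(rho_of(x, y[idx])))
  mean(stats >= obs - 1e-12)
}

combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(1:n, function(k) {
    rest <- setdiff(1:n, k)
    cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

bf_anchor_pileup <- function(oe, bins, k) {
  acc <- array(NA_real_, c(2 * k + 1, 2 * k + 1, length(bins)))
  for (q in seq_along(bins)) {
    b <- bins[q]
    acc[, , q] <- oe[(b - k):(b + k), (b - k):(b + k)]
  }
  apply(acc, c(1, 2), mean, na.rm = TRUE)
}

# small deterministic contact matrix fixtures
toy_decay_matrix <- function(n, depth = 100, alpha = 1, seed = NULL) {
  d <- abs(outer(1:n, 1:n, "-"))
  lam <- depth * (1 + d)^(-alpha)
  if (!is.null(seed)) {
    set.seed(seed)
    m <- matrix(0, n, n)
    ut <- upper.tri(lam, diag = TRUE)
    m[ut] <- rpois(sum(ut), lam[ut])
    m <- m + t(m) - diag(diag(m))
  } else m <- lam
  contact_matrix(m, "chrT", 1e4)
}

random_symmetric_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(rpois(n * n, 20), n, n)
  m <- m + t(m)
  contact_matrix(m * 1.0, "chrT", 1e4)
}
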