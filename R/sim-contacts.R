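#' Simulate a Hi-C contact matrix from a domain hierarchy
#'
#' Expected counts follow a power-law distance decay modulated by domain
#' enrichment and boundary insulation:
#' lambda(i, j) = depth * (1 + |i - j|)^(-alpha) * e(i, j) * f(i, j),
#' where e multiplies `e_tad` when both bins share a TAD and additionally
#' `e_subtad` when they share a subTAD, and f is the product of the insulation
#' factors of every boundary separating i from j. Realized counts are Poisson
#' draws symmetrized over the matrix; `noise = "none"` returns the expectation
#' itself (useful for oracle tests).
#'
#' @param hier a `domain_hierarchy`.
#' @param chrom chromosome name.
#' @param depth expected count at distance 0 outside domains (>= 0; deep
#'   paired-condition designs correspond to depth of order 50-100 at 10-kb
#'   bins).
#' @param alpha distance-decay exponent (> 0; cis Hi-C is near 1).
#' @param e_tad,e_subtad within-domain contact enrichments (>= 1).
#' @param noise "poisson" or "none".
#' @param seed integer seed.
#' @return a `contact_matrix`.
#' @export
simulate_contact_matrix <- function(hier, chrom, depth = 100, alpha = 1,
                                    e_tad = 3, e_subtad = 2,
                                    noise = c("poisson", "none"), seed = 1) {
  noise <- match.arg(noise)
  assert_that(depth >= 0, "depth must be >= 0")
  assert_that(alpha > 0, "alpha must be > 0")
  assert_that(e_tad >= 1 && e_subtad >= 1, "enrichments must be >= 1")
  ch <- hier$chroms[[chrom]]
  assert_that(!is.null(ch), paste("unknown chromosome:", chrom))
  n <- ch$n_bins
  bins <- seq_len(n) - 1L
  d <- abs(outer(bins, bins, "-"))
  tad_id <- findInterval(bins, ch$tad$bin)
  sub_id <- findInterval(bins, sort(c(ch$tad$bin, ch$subtad$bin)))
  e <- 1 + (e_tad - 1) * outer(tad_id, tad_id, "==")
  e <- e * (1 + (e_subtad - 1) * outer(sub_id, sub_id, "=="))
  # f(i,j): product of insulation factors of boundaries in (min(i,j), max(i,j)]
  logf_at <- numeric(n)
  bnd <- rbind(ch$tad, ch$subtad)
  if (nrow(bnd)) logf_at[bnd$bin + 1L] <- log(bnd$f)
  P <- cumsum(logf_at)
  f <- exp(abs(outer(P, P, "-")) * -1)  # |P_i - P_j| = -log f for i < j
  lambda <- depth * (1 + d)^(-alpha) * e * f
  if (noise == "none") {
    m <- lambda
  } else {
    set.seed(seed)
    m <- matrix(0, n, n)
    ut <- upper.tri(lambda, diag = TRUE)
    m[ut] <- stats::rpois(sum(ut), lambda[ut])
    m <- m + t(m) - diag(diag(m))
  }
  contact_matrix(m, chrom, hier$resolution)
}
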