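#' Aggregate obs/exp pileup around single anchors
#'
#' Averages the (2k+1) x (2k+1) obs/exp submatrix centered on (anchor, anchor)
#' over all usable anchors (k = flank / resolution). With `n_random_sets > 0`
#' the average is further divided, element-wise, by the mean pileup over that
#' many equinumerous uniform anchor sets, normalizing against the genome-wide
#' average local interaction. Anchors whose window leaves the matrix are
#' dropped and counted.
#'
#' @param cm a `contact_matrix` (balanced internally if needed).
#' @param anchors a `feature_set` on `cm$chrom`, or numeric bp positions.
#' @param flank half-window in bp (multiple of the resolution; 200 kb is the
#'   usual domain-scale choice).
#' @param n_random_sets random anchor sets for normalization (default 10;
#'   0 disables normalization).
#' @param seed integer seed.
#' @param stat "mean" (default) or "median" aggregation across anchors.
#' @return a `pileup_result`: list with `matrix`, `center`, `flank`,
#'   `n_anchors`, `n_dropped`, `normalized`.
#' @export
anchor_pileup <- function(cm, anchors, flank, n_random_sets = 10, seed = 1,
                          stat = c("mean", "median")) {
  stat <- match.arg(stat)
  res <- cm$resolution
  assert_that(flank %% res == 0, "flank must be a multiple of the resolution")
  k <- as.integer(flank / res)
  if (!isTRUE(attr(cm, "balanced"))) cm <- balance(cm)
  oe <- oe_matrix(cm)
  n <- nrow(oe)
  pos <- if (is.data.frame(anchors)) (anchors$start + anchors$end) / 2 else as.numeric(anchors)
  bins <- floor(pos / res) + 1L
  usable <- bins > k & bins <= n - k
  assert_that(any(usable), "no usable anchors (all windows leave the matrix)")
  stack_mean <- function(b) {
    acc <- array(NA_real_, c(2 * k + 1, 2 * k + 1, length(b)))
    for (i in seq_along(b)) acc[, , i] <- oe[(b[i] - k):(b[i] + k), (b[i] - k):(b[i] + k)]
    apply(acc, c(1, 2), stat, na.rm = TRUE)
  }
  m <- stack_mean(bins[usable])
  if (n_random_sets > 0) {
    set.seed(seed)
    interior <- which(cm$mask)
    interior <- interior[interior > k & interior <= n - k]
    norm <- Reduce(`+`, lapply(seq_len(n_random_sets), function(s)
      stack_mean(sample(interior, sum(usable), replace = TRUE)))) / n_random_sets
    m <- m / norm
  }
  structure(list(matrix = m, center = k + 1L, flank = flank,
                 n_anchors = sum(usable), n_dropped = sum(!usable),
                 normalized = n_random_sets > 0),
            class = "pileup_result")
}

#' Aggregate obs/exp pileup between two anchor sets
#'
#' For every (a, b) pair with separation in [min_sep, max_sep] on the
#' chromosome, averages the obs/exp window centered on pixel (a, b). The
#' central pixel and the mean of the window's outer ring are reported for
#' enrichment scoring (a loop-like gain shows center/ring > 1).
#'
#' @param cm a `contact_matrix`.
#' @param anchorsA,anchorsB `feature_set`s or bp position vectors.
#' @param flank half-window in bp (e.g. 50 kb).
#' @param min_sep,max_sep separation bounds in bp; min_sep must exceed
#'   2 * flank so windows stay off the diagonal (defaults 100 kb and 2 Mb).
#' @return a `pileup_result` with additional `center_value`, `ring_mean`,
#'   `center_ring_ratio`, `n_pairs`.
#' @export
paired_pileup <- function(cm, anchorsA, anchorsB, flank, min_sep = 1e5,
                          max_sep = 2e6) {
  res <- cm$resolution
  assert_that(flank %% res == 0, "flank must be a multiple of the resolution")
  assert_that(min_sep > 2 * flank, "min_sep must exceed 2 * flank")
  k <- as.integer(flank / res)
  if (!isTRUE(attr(cm, "balanced"))) cm <- balance(cm)
  oe <- oe_matrix(cm)
  n <- nrow(oe)
  to_bins <- function(a) {
    pos <- if (is.data.frame(a)) (a$start + a$end) / 2 else as.numeric(a)
    floor(pos / res) + 1L
  }
  ba <- to_bins(anchorsA); bb <- to_bins(anchorsB)
  pairs <- expand.grid(a = ba, b = bb)
  sep <- abs(pairs$a - pairs$b) * res
  i <- pmin(pairs$a, pairs$b); j <- pmax(pairs$a, pairs$b)
  ok <- sep >= min_sep & sep <= max_sep & i > k & j <= n - k
  assert_that(any(ok), "no valid anchor pairs in the separation range")
  i <- i[ok]; j <- j[ok]
  acc <- matrix(0, 2 * k + 1, 2 * k + 1)
  cnt <- matrix(0, 2 * k + 1, 2 * k + 1)
  for (q in seq_along(i)) {
    w <- oe[(i[q] - k):(i[q] + k), (j[q] - k):(j[q] + k)]
    fin <- is.finite(w)
    acc[fin] <- acc[fin] + w[fin]
    cnt <- cnt + fin
  }
  m <- acc / cnt
  ring <- m[c(1, 2 * k + 1), ]
  ring_mean <- mean(c(ring, m[2:(2 * k), c(1, 2 * k + 1)]), na.rm = TRUE)
  structure(list(matrix = m, center = k + 1L, flank = flank,
                 n_pairs = length(i),
                 center_value = m[k + 1, k + 1], ring_mean = ring_mean,
                 center_ring_ratio = m[k + 1, k + 1] / ring_mean,
                 normalized = FALSE),
            class = "pileup_result")
}

#' Average insulation-score profile around anchors
#'
#' Stacks each condition's insulation track in windows of +/- `flank` around
#' the anchors and averages per offset (missing bins excluded per offset).
#' A boundary-like anchor shows a V-shaped profile with its minimum at 0.
#'
#' @param tracks named list of `insulation_track`s (one per condition).
#' @param anchors a `feature_set` or numeric bp positions (non-empty).
#' @param flank half-window in bp (multiple of the resolution).
#' @return matrix offsets x conditions, with bp offsets as rownames.
#' @export
insulation_profile <- function(tracks, anchors, flank) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  res <- tracks[[1]]$resolution
  assert_that(flank %% res == 0, "flank must be a multiple of the resolution")
  k <- as.integer(flank / res)
  pos <- if (is.data.frame(anchors)) (anchors$start + anchors$end) / 2 else as.numeric(anchors)
  assert_that(length(pos) > 0, "empty anchor set")
  bins <- floor(pos / res) + 1L
  out <- sapply(tracks, function(tr) {
    n <- length(tr$score)
    acc <- matrix(NA_real_, length(bins), 2 * k + 1)
    for (i in seq_along(bins)) {
      b <- bins[i]
      if (b - k >= 1 && b + k <= n) acc[i, ] <- tr$score[(b - k):(b + k)]
    }
    colMeans(acc, na.rm = TRUE)
  })
  out <- as.matrix(out)
  rownames(out) <- seq(-k, k) * res
  out
}
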