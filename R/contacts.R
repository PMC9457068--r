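#' Balance a contact matrix by iterative proportional fitting
#'
#' ICE-style correction: bins with zero coverage are masked, then row/column
#' scaling factors are iterated until all valid-bin row sums agree with their
#' mean within `tol` (relative). Masked rows/columns are zeroed.
#'
#' @param cm a `contact_matrix`.
#' @param tol relative tolerance on valid row sums (default 1e-3).
#' @param max_iter maximum iterations.
#' @return balanced `contact_matrix` (zero-sum bins added to the mask).
#' @export
balance <- function(cm, tol = 1e-3, max_iter = 200) {
  m <- cm$counts
  mask <- cm$mask & (rowSums(m) > 0)
  m[!mask, ] <- 0
  m[, !mask] <- 0
  if (!any(mask)) stop("balance: no valid bins", call. = FALSE)
  resid <- Inf
  for (it in seq_len(max_iter)) {
    s <- rowSums(m)
    sm <- s / mean(s[mask])
    resid <- max(abs(sm[mask] - 1))
    if (resid <= tol) {
      out <- contact_matrix(m, cm$chrom, cm$resolution, mask)
      attr(out, "balanced") <- TRUE
      return(out)
    }
    sm[!mask] <- 1
    # square-root damping keeps the symmetric update from oscillating
    m <- m / outer(sqrt(sm), sqrt(sm))
  }
  stop(sprintf("balance: no convergence in %d iterations (residual %.3g > tol %.3g)",
               max_iter, resid, tol), call. = FALSE)
}

#' Distance-decay expected profile
#'
#' Entry d+1 is the mean contact over valid bin pairs at separation d bins
#' (entry 1 = main diagonal). Separations with no valid pair are NA.
#'
#' @param cm a `contact_matrix` (normally balanced).
#' @return numeric vector of length `n_bins(cm)`.
#' @export
expected_profile <- function(cm) {
  m <- cm$counts
  n <- nrow(m)
  valid <- cm$mask
  out <- rep(NA_real_, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    ok <- valid[i] & valid[i + d]
    if (any(ok)) out[d + 1] <- mean(m[cbind(i[ok], i[ok] + d)])
  }
  out
}

#' Observed/expected transform of a contact matrix
#'
#' Divides each pixel by the expected value at its separation. Pixels at
#' separations with undefined expectation, and masked bins, become NA.
#'
#' @param cm a `contact_matrix`.
#' @param expected optional precomputed [expected_profile()].
#' @return numeric matrix of obs/exp values.
#' @export
oe_matrix <- function(cm, expected = NULL) {
  if (is.null(expected)) expected <- expected_profile(cm)
  n <- nrow(cm$counts)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  e <- matrix(expected[d + 1], n, n)
  oe <- cm$counts / e
  oe[!cm$mask, ] <- NA
  oe[, !cm$mask] <- NA
  oe
}

#' Diamond-window insulation score
#'
#' For bin i, S(i) sums contacts between the w bins upstream and the w bins
#' downstream of i (the "diamond" crossing bin i); the score is
#' log2(S(i) / mean of S over valid bins). Scores are missing (NA) within w
#' bins of the chromosome ends and wherever the window touches a masked bin.
#'
#' @param cm a `contact_matrix` (balance first for coverage-corrected scores).
#' @param window window size in bp; must be a multiple of the resolution and
#'   span at least 2 bins.
#' @param normalization currently only "chrom_mean".
#' @return object of class `insulation_track`: list with `chrom`, `resolution`,
#'   `window`, and per-bin `score` (NA where undefined).
#' @export
insulation_track <- function(cm, window, normalization = "chrom_mean") {
  normalization <- match.arg(normalization, "chrom_mean")
  res <- cm$resolution
  assert_that(window %% res == 0, "window must be a multiple of the resolution")
  w <- as.integer(window / res)
  assert_that(w >= 2, "window must span at least 2 bins")
  n <- nrow(cm$counts)
  assert_that(2 * w + 1 <= n, "window larger than chromosome")
  m <- cm$counts
  s <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {  # 1-based centers with a full window
    up <- (i - w):(i - 1); dn <- (i + 1):(i + w)
    if (all(cm$mask[c(up, i, dn)])) s[i] <- sum(m[up, dn])
  }
  ok <- !is.na(s)
  assert_that(any(ok), "insulation_track: no defined bins")
  score <- rep(NA_real_, n)
  score[ok] <- log2(s[ok] / mean(s[ok]))
  structure(list(chrom = cm$chrom, resolution = res, window = window,
                 score = score),
            class = "insulation_track")
}

#' Export an insulation track as bedGraph intervals
#' @param track an `insulation_track`.
#' @return a `feature_set` with one row per defined bin and the score column.
#' @export
insulation_to_bedgraph <- function(track) {
  idx <- which(!is.na(track$score))
  feature_set(data.frame(chrom = track$chrom,
                         start = (idx - 1) * track$resolution,
                         end = idx * track$resolution,
                         score = track$score[idx]))
}

#' Correlation between two contact matrices
#'
#' Pearson correlation over obs/exp values of valid bin pairs (upper triangle)
#' with separation up to `max_distance`. Used to compare samples/conditions;
#' an all-pairs sample-by-sample matrix is assembled by calling this for each
#' pair.
#'
#' @param a,b `contact_matrix` objects on the same chromosome, resolution and
#'   mask.
#' @param max_distance separation cap in bp (default 2 Mb).
#' @return Pearson correlation coefficient.
#' @export
matrix_correlation <- function(a, b, max_distance = 2e6) {
  assert_that(a$chrom == b$chrom && a$resolution == b$resolution,
              "matrices must share chromosome and resolution")
  n <- nrow(a$counts)
  assert_that(n == nrow(b$counts), "matrices must have equal bin counts")
  assert_that(identical(a$mask, b$mask), "matrices must share the bin mask")
  maxd <- as.integer(max_distance / a$resolution)
  oa <- oe_matrix(a); ob <- oe_matrix(b)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  sel <- upper.tri(d, diag = TRUE) & d <= maxd &
    is.finite(oa) & is.finite(ob)
  assert_that(sum(sel) >= 2, "no shared valid pixels to correlate")
  stats::cor(oa[sel], ob[sel], method = "pearson")
}
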