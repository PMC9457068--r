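#' Score peaks against per-replicate signal tracks
#'
#' For each peak and each replicate track, computes the library-size
#' normalized mean signal over the peak interval: the bp-weighted mean of the
#' track value across the peak, scaled to reads-per-million by
#' 1e6 / sum(value * width) of the whole track. Track gaps count as zero
#' signal, but a peak extending beyond the track extent on its chromosome is
#' an error. Overlapping peaks are scored independently.
#'
#' @param peaks a `feature_set`.
#' @param tracks named list of bedGraph `feature_set`s (one per replicate),
#'   each with a `score` column and non-overlapping sorted intervals.
#' @return numeric matrix, peaks x replicates.
#' @export
score_peaks <- function(peaks, tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  if (is.null(names(tracks))) names(tracks) <- paste0("rep", seq_along(tracks))
  out <- matrix(NA_real_, nrow(peaks), length(tracks),
                dimnames = list(NULL, names(tracks)))
  for (t in seq_along(tracks)) {
    tr <- tracks[[t]]
    assert_that("score" %in% names(tr), "track needs a score column")
    libsize <- sum(tr$score * (tr$end - tr$start))
    scale <- if (libsize > 0) 1e6 / libsize else 0
    by_chrom <- split(tr, tr$chrom)
    for (p in seq_len(nrow(peaks))) {
      seg <- by_chrom[[peaks$chrom[p]]]
      assert_that(!is.null(seg) &&
                    peaks$start[p] >= min(seg$start) &&
                    peaks$end[p] <= max(seg$end),
                  sprintf("peak %d outside track extent", p))
      ov <- pmin(seg$end, peaks$end[p]) - pmax(seg$start, peaks$start[p])
      ov[ov < 0] <- 0
      out[p, t] <- sum(seg$score * ov) / (peaks$end[p] - peaks$start[p]) * scale
    }
  }
  out
}

#' Pooled-variance z-test on log2 signal
#'
#' Per-feature difference of condition means on the log2 scale, tested with a
#' variance pooled across all features (stable with two replicates per
#' condition, where per-feature variances are uninformative). Two-sided normal
#' p-values.
#'
#' @param log2mat features x replicates matrix of log2-transformed signal.
#' @param condition character/factor of length ncol(log2mat) with two levels;
#'   the second level is the treatment.
#' @return data.frame with `delta` (log2 treatment - control), `z`, `pvalue`.
#' @export
pooled_z_test <- function(log2mat, condition) {
  condition <- as.factor(condition)
  assert_that(nlevels(condition) == 2, "condition must have exactly two levels")
  lev <- levels(condition)
  n_c <- sum(condition == lev[1]); n_t <- sum(condition == lev[2])
  assert_that(n_c >= 2 && n_t >= 2, "need >= 2 replicates per condition")
  mc <- rowMeans(log2mat[, condition == lev[1], drop = FALSE])
  mt <- rowMeans(log2mat[, condition == lev[2], drop = FALSE])
  # residuals computed against each replicate's own condition mean
  resid <- log2mat
  resid[, condition == lev[1]] <- log2mat[, condition == lev[1], drop = FALSE] - mc
  resid[, condition == lev[2]] <- log2mat[, condition == lev[2], drop = FALSE] - mt
  df <- nrow(log2mat) * (n_c - 1 + n_t - 1)
  s2 <- sum(resid^2) / df
  se <- sqrt(s2 * (1 / n_c + 1 / n_t))
  z <- (mt - mc) / se
  data.frame(delta = mt - mc, z = z, pvalue = 2 * stats::pnorm(-abs(z)))
}

#' Classify differential occupancy of peaks
#'
#' logFC is log2((mean_treat + 1) / (mean_ctl + 1)) on normalized densities
#' (pseudo-count 1 guards zero densities); significance comes from
#' [pooled_z_test()] on log2(density + 1) with BH adjustment across peaks.
#' Class is `lost` when FDR < fdr_max and logFC < -logfc_min, `gained` when
#' FDR < fdr_max and logFC > logfc_min, else `constant`.
#'
#' @param densities peaks x replicates matrix of normalized densities.
#' @param condition two-level factor over the columns; second level = treatment.
#' @param fdr_max FDR threshold (0.01 for CTCF-style calls, 0.05 for marks).
#' @param logfc_min minimum |logFC| (default 1).
#' @param peaks optional `feature_set` of peak intervals to carry along.
#' @return a `differential_feature_table`: data.frame with per-condition mean
#'   densities, `logFC`, `pvalue`, `FDR`, `class` (plus interval columns when
#'   `peaks` is given).
#' @export
classify_differential <- function(densities, condition, fdr_max = 0.01,
                                  logfc_min = 1, peaks = NULL) {
  condition <- as.factor(condition)
  lev <- levels(condition)
  tst <- pooled_z_test(log2(densities + 1), condition)
  mc <- rowMeans(densities[, condition == lev[1], drop = FALSE])
  mt <- rowMeans(densities[, condition == lev[2], drop = FALSE])
  logFC <- log2((mt + 1) / (mc + 1))
  FDR <- stats::p.adjust(tst$pvalue, method = "BH")
  cls <- rep("constant", nrow(densities))
  cls[FDR < fdr_max & logFC < -logfc_min] <- "lost"
  cls[FDR < fdr_max & logFC > logfc_min] <- "gained"
  out <- data.frame(mean_ctl = mc, mean_treat = mt, logFC = logFC,
                    pvalue = tst$pvalue, FDR = FDR, class = cls)
  if (!is.null(peaks)) out <- cbind(as.data.frame(peaks)[, c("chrom", "start", "end")], out)
  class(out) <- c("differential_feature_table", "data.frame")
  out
}

#' Annotate features by genomic context
#'
#' Assigns each feature to `promoter` (within +/- promoter_flank of a TSS),
#' `gene body` (overlapping a gene extent), or `distal intergenic`, with
#' precedence promoter > gene body > distal.
#'
#' @param features a `feature_set`.
#' @param genes gene model data.frame with `chrom`, `start`, `end`, `tss`.
#' @param promoter_flank promoter half-width in bp (default 3 kb).
#' @return character vector of categories, one per feature.
#' @export
annotate_context <- function(features, genes, promoter_flank = 3000) {
  if (nrow(genes) == 0) {
    warning("empty gene model: all features annotated distal intergenic")
    return(rep("distal intergenic", nrow(features)))
  }
  out <- character(nrow(features))
  for (ch in unique(features$chrom)) {
    fi <- which(features$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    for (k in fi) {
      s <- features$start[k]; e <- features$end[k]
      if (nrow(g) > 0 &&
          any(s < g$tss + promoter_flank + 1 & e > g$tss - promoter_flank)) {
        out[k] <- "promoter"
      } else if (nrow(g) > 0 && any(s < g$end & e > g$start)) {
        out[k] <- "gene body"
      } else out[k] <- "distal intergenic"
    }
  }
  out
}

#' Average signal profile around TSSs
#'
#' Averages a binned signal track in windows of +/- `flank` around each TSS;
#' minus-strand windows are reversed before averaging so that positive offsets
#' always point downstream of transcription. Genes whose window leaves the
#' track extent are dropped (count in attribute `n_dropped`).
#'
#' @param track a binned bedGraph `feature_set` with uniform bin width.
#' @param genes data.frame with `chrom`, `tss`, `strand` (non-empty).
#' @param flank half-window in bp (multiple of the track bin width).
#' @return numeric vector of per-offset means with attributes `offsets` (bp),
#'   `n_used`, `n_dropped`.
#' @export
tss_metaprofile <- function(track, genes, flank) {
  assert_that(nrow(genes) > 0, "empty gene subset")
  widths <- unique(track$end - track$start)
  res <- min(widths)
  assert_that(flank %% res == 0, "flank must be a multiple of the track bin width")
  k <- as.integer(flank / res)
  vecs <- lapply(split(track, track$chrom), function(tr) {
    n <- as.integer(max(tr$end) / res)
    v <- numeric(n)
    v[(tr$start / res) + 1] <- tr$score
    v
  })
  acc <- matrix(NA_real_, nrow(genes), 2 * k + 1)
  used <- 0; dropped <- 0
  for (i in seq_len(nrow(genes))) {
    v <- vecs[[genes$chrom[i]]]
    b <- floor(genes$tss[i] / res) + 1
    if (is.null(v) || b - k < 1 || b + k > length(v)) { dropped <- dropped + 1; next }
    w <- v[(b - k):(b + k)]
    if (identical(genes$strand[i], "-")) w <- rev(w)
    used <- used + 1
    acc[used, ] <- w
  }
  assert_that(used > 0, "no gene window fits the track extent")
  out <- colMeans(acc[seq_len(used), , drop = FALSE])
  attr(out, "offsets") <- seq(-k, k) * res
  attr(out, "n_used") <- used
  attr(out, "n_dropped") <- dropped
  out
}
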